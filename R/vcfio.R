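# VCF input/output. Reading goes through VariantAnnotation; writing is a
# deterministic formatter so that write -> read -> write round-trips are
# byte-identical, which the simulators rely on for truth logging.

.vcfHeaderLines <- function(chrom, hasGQ, hasAnnot) {
  h <- c("##fileformat=VCFv4.2",
         "##source=demosel",
         sprintf("##contig=<ID=%s>", chrom),
         "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">")
  if (hasAnnot) h <- c(h,
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=RPRS,Number=1,Type=Float,Description=\"Read position rank sum\">")
  h <- c(h, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (hasGQ) h <- c(h,
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  h
}

#' Write haplotypes or genotypes to a VCF file
#'
#' \linkS4class{HaplotypeData} is written with phased genotypes
#' (\code{0|1}) and the ancestral allele in the \code{AA} INFO tag.
#' \linkS4class{GenotypeData} is written unphased, with \code{GQ} and the
#' \code{QD}/\code{FS}/\code{RPRS} site annotations when present. Output is
#' canonical: writing, reading back and writing again yields a
#' byte-identical file.
#'
#' @param x a \linkS4class{HaplotypeData} or \linkS4class{GenotypeData}
#' @param path output path (plain text, VCF 4.2)
#' @return \code{path}, invisibly
#' @export
writeVcfFile <- function(x, path) {
  rr <- SummarizedExperiment::rowRanges(x)
  mc <- S4Vectors::mcols(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  if (!length(chrom)) stop("no sites to write")
  pos <- BiocGenerics::start(rr)
  cd <- SummarizedExperiment::colData(x)
  if (is(x, "HaplotypeData")) {
    h <- haplotypeMatrix(x)
    if (ncol(h) %% 2L != 0L) stop("haplotype count must be even")
    samples <- cd$sample[cd$hapIndex == 1L]
    gtxt <- matrix(paste0(h[, seq(1, ncol(h), 2), drop = FALSE], "|",
                          h[, seq(2, ncol(h), 2), drop = FALSE]),
                   nrow = nrow(h))
    fmt <- "GT"; hasGQ <- FALSE; hasAnnot <- FALSE
    info <- paste0("AA=", ifelse(is.na(mc$ancestral), ".", mc$ancestral))
  } else if (is(x, "GenotypeData")) {
    g <- genotypeMatrix(x)
    samples <- cd$sample
    code <- c("0/0", "0/1", "1/1")
    gtxt <- matrix("./.", nrow(g), ncol(g))
    gtxt[!is.na(g)] <- code[g[!is.na(g)] + 1L]
    hasGQ <- "GQ" %in% SummarizedExperiment::assayNames(x)
    if (hasGQ) {
      gq <- SummarizedExperiment::assay(x, "GQ")
      gtxt <- matrix(paste0(gtxt, ":",
                            ifelse(is.na(gq), ".", format(gq, trim = TRUE,
                                                          scientific = FALSE))),
                     nrow = nrow(g))
    }
    fmt <- if (hasGQ) "GT:GQ" else "GT"
    hasAnnot <- any(c("QD", "FS", "ReadPosRankSum") %in% colnames(mc))
    info <- paste0("AA=", ifelse(is.na(mc$ancestral), ".", mc$ancestral))
    fmtnum <- function(v) ifelse(is.na(v), NA,
                                 sub("\\.?0+$", "",
                                     formatC(v, format = "f", digits = 4)))
    for (tag in c("QD", "FS", "ReadPosRankSum")) {
      key <- if (tag == "ReadPosRankSum") "RPRS" else tag
      if (tag %in% colnames(mc)) {
        v <- fmtnum(mc[[tag]])
        info <- ifelse(is.na(v), info, paste0(info, ";", key, "=", v))
      }
    }
  } else stop("unsupported object")
  lines <- c(.vcfHeaderLines(chrom[1], hasGQ, hasAnnot),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             paste(chrom, pos, ".", mc$ref, mc$alt, ".", ".", info, fmt,
                   apply(gtxt, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

.gtToDosage <- function(gt) {
  # "0/1", "0|1", "./." -> derived-allele dosage
  d <- rep(NA_integer_, length(gt))
  d[gt %in% c("0/0", "0|0")] <- 0L
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[gt %in% c("1/1", "1|1")] <- 2L
  d
}

#' Read a phased VCF into a HaplotypeData object
#'
#' @param path VCF file with fully phased GT fields
#' @return a \linkS4class{HaplotypeData}; the \code{AA} INFO tag (when
#'   present) populates the ancestral-allele site metadata
#' @export
readPhasedVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (any(!grepl("|", gt, fixed = TRUE)))
    stop("unphased genotypes in a phased VCF")
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt))
  H <- matrix(0L, nrow(gt), 2 * ncol(gt))
  H[, seq(1, ncol(H), 2)] <- a1
  H[, seq(2, ncol(H), 2)] <- a2
  rr <- SummarizedExperiment::rowRanges(vcf)
  obj <- HaplotypeData(H, BiocGenerics::start(rr),
                       chrom = as.character(GenomicRanges::seqnames(rr))[1],
                       samples = colnames(gt))
  mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(obj))
  mc$ref <- as.character(VariantAnnotation::ref(vcf))
  mc$alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  info <- VariantAnnotation::info(vcf)
  if ("AA" %in% colnames(info)) {
    aa <- as.character(info$AA)
    aa[aa == "."] <- NA_character_
    mc$ancestral <- aa
  }
  S4Vectors::mcols(SummarizedExperiment::rowRanges(obj)) <- mc
  obj
}
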