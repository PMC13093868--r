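# Stage orchestration. A pipeline configuration (R list or YAML/JSON file)
# names the stages to run, their inputs, thresholds and seeds; stages run in
# dependency order, write plain-text artifacts into the output directory and
# append to a manifest recording seeds and md5 checksums, so a rerun with
# the same configuration reproduces every stochastic stage bit-identically.

.stochasticStages <- c("simulate", "structure", "scan")

.validatePipelineConfig <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (is.null(config$stages) || !length(config$stages))
    stop("config$stages is required")
  known <- c("simulate", "qc", "stats", "structure", "scan")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  for (st in intersect(config$stages, .stochasticStages)) {
    if (is.null(config[[st]]$seed))
      stop("stochastic stage '", st, "' needs an explicit seed")
  }
  invisible(TRUE)
}

#' Run the analysis pipeline described by a configuration
#'
#' Supported stages: \code{simulate} (two-population synthetic data written
#' as a phased VCF plus truth log), \code{qc} (filtered genotype loading),
#' \code{stats} (windowed diversity), \code{structure} (PCA and the
#' panmixia permutation test) and \code{scan} (XP-EHH with candidate
#' regions, and Hudson FST blocks). Stages run in that order; later stages
#' consume the artifacts of earlier ones (or paths given in the config).
#' Every stochastic stage must carry an explicit seed.
#'
#' @param config a named list, or path to a YAML/JSON file holding one
#' @return the manifest (data.frame), invisibly; also written as
#'   \code{manifest.json} in the output directory
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::yaml.load_file(config)
  }
  .validatePipelineConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, files, seed = NA) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = files,
      md5 = as.character(tools::md5sum(files)), seed = seed)
  }
  art <- list()

  if ("simulate" %in% config$stages) {
    sc <- config$simulate
    cfg <- demographyConfig(
      N_ref = sc$N_ref, N1 = sc$N1, N2 = sc$N2,
      b1 = sc$b1 %||% 1, b2 = sc$b2 %||% 1,
      T_split = sc$T_split, T_contact = sc$T_contact %||% 0,
      m12 = sc$m12 %||% 0, m21 = sc$m21 %||% 0)
    hap <- simulateTwoPop(cfg, L = sc$L, n1 = sc$n1, n2 = sc$n2,
                          seed = sc$seed)
    vcf <- file.path(config$out_dir, "simulated.vcf")
    writeVcfFile(hap, vcf)
    truthF <- file.path(config$out_dir, "sim_truth.tsv")
    tr <- simTruth(hap)
    utils::write.table(
      data.frame(key = c("kind", "L", "n1", "n2", "seed"),
                 value = c(tr$kind, tr$L, tr$n1, tr$n2, tr$seed)),
      truthF, sep = "\t", row.names = FALSE, quote = FALSE)
    popF <- file.path(config$out_dir, "populations.tsv")
    cd <- SummarizedExperiment::colData(hap)
    utils::write.table(unique(data.frame(sample = cd$sample,
                                         population = cd$population)),
                       popF, sep = "\t", row.names = FALSE, quote = FALSE)
    note("simulate", c(vcf, truthF, popF), sc$seed)
    art$vcf <- vcf; art$hap <- hap; art$populations <- popF
  }

  if ("qc" %in% config$stages) {
    qc <- config$qc %||% list()
    vcf <- qc$vcf %||% art$vcf
    if (is.null(vcf)) stop("qc: no VCF available (missing simulate output)")
    pops <- NULL
    popFile <- qc$populations %||% art$populations
    if (!is.null(popFile)) {
      pt <- utils::read.delim(popFile)
      pops <- stats::setNames(pt$population, pt$sample)
    }
    thr <- qcThresholds()
    for (nm in intersect(names(qc), names(thr))) thr[[nm]] <- qc[[nm]]
    gm <- loadFilteredVcf(vcf, mask = qc$mask, thresholds = thr,
                          populations = pops)
    gtF <- file.path(config$out_dir, "qc_sites.tsv")
    utils::write.table(
      data.frame(chrom = as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(gm))),
        pos = sitePositions(gm)),
      gtF, sep = "\t", row.names = FALSE, quote = FALSE)
    note("qc", gtF)
    art$gm <- gm
  }

  if ("stats" %in% config$stages) {
    if (is.null(art$gm)) stop("stats: qc output required")
    sw <- config$stats %||% list()
    wd <- windowDiversity(art$gm, window = sw$window %||% 1e4)
    wdF <- file.path(config$out_dir, "window_stats.tsv")
    utils::write.table(wd, wdF, sep = "\t", row.names = FALSE, quote = FALSE)
    note("stats", wdF)
  }

  if ("structure" %in% config$stages) {
    if (is.null(art$gm)) stop("structure: qc output required")
    st <- config$structure %||% list()
    pc <- pcaGenotypes(ldPrune(art$gm), nComponents = st$n_components %||% 5)
    pcF <- file.path(config$out_dir, "pca_scores.tsv")
    utils::write.table(data.frame(sample = rownames(pc$scores),
                                  round(pc$scores, 6)),
                       pcF, sep = "\t", row.names = FALSE, quote = FALSE)
    pm <- panmixiaTest(art$gm, n_perm = st$n_perm %||% 200, seed = st$seed)
    pmF <- file.path(config$out_dir, "panmixia.json")
    jsonlite::write_json(list(p_value = pm$p_value,
                              chisq_obs = pm$chisq_obs),
                         pmF, auto_unbox = TRUE, digits = NA)
    note("structure", c(pcF, pmF), st$seed)
  }

  if ("scan" %in% config$stages) {
    if (is.null(art$hap)) stop("scan: simulate output required")
    sc <- config$scan %||% list()
    cd <- SummarizedExperiment::colData(art$hap)
    pops <- unique(cd$population)
    hA <- art$hap[, cd$population == pops[1]]
    hB <- art$hap[, cd$population == pops[2]]
    tr <- xpehhScan(hA, hB, fdr = sc$fdr %||% 0.05,
                    sig_p = sc$sig_p %||% 1e-4)
    trF <- file.path(config$out_dir, "xpehh.tsv")
    utils::write.table(tr, trF, sep = "\t", row.names = FALSE, quote = FALSE)
    cr <- candidateRegions(tr)
    crF <- file.path(config$out_dir, "xpehh_regions.tsv")
    utils::write.table(cr, crF, sep = "\t", row.names = FALSE, quote = FALSE)
    ab <- alleleCountsByPop(art$hap)
    fb <- fstBlocks(ab[[1]]$ac, ab[[2]]$ac, ab[[1]]$an, ab[[2]]$an,
                    sitePositions(art$hap),
                    blockSize = sc$block_size %||% 1000)
    fbF <- file.path(config$out_dir, "fst_blocks.tsv")
    utils::write.table(fb, fbF, sep = "\t", row.names = FALSE, quote = FALSE)
    note("scan", c(trF, crF, fbF), sc$seed)
  }

  man <- do.call(rbind, manifest)
  jsonlite::write_json(man, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(man)
}
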