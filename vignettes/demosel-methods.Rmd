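---
title: "Models and methods in demosel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in demosel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

demosel analyses whole-genome SNP data from two (or more) populations of a
diploid organism: quality control and polarization of the variant calls,
descriptive diversity and differentiation statistics, diffusion-based
fitting of divergence models to the joint site frequency spectrum (jSFS),
haplotype-based selection scans, and simulation-trained classification of
selective sweeps. A built-in simulator generates data with the statistical
structure these analyses assume, so the whole pipeline can be exercised and
validated without access to any sequencing data. This vignette documents
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic data do and do not emulate.

## The divergence models

The demographic component considers a pair of populations descended from a
common ancestral population of diploid effective size $N_\mathrm{ref}$.
Eight nested models combine four gene-flow histories with an optional
exponential size change:

* **SI** — strict isolation: the populations split $T_s$ ago (time in units
  of $2N_\mathrm{ref}$ generations) and never exchange migrants;
* **IM** — isolation with continuous migration throughout the divergence;
* **AM** — ancient migration: gene flow from the split until $T_c$ ago,
  isolation since;
* **SC** — secondary contact: strict isolation from the split until $T_c$
  ago, migration since;
* each optionally **+G**: population $i$ changes size exponentially from
  $\nu_i N_\mathrm{ref}$ at the split to $b_i \nu_i N_\mathrm{ref}$ at
  present. We apply the exponential trajectory over the entire post-split
  period (not only the contact phase), the conventional reading of the "G"
  extension in this model family; $b_i = 1$ recovers the constant-size
  variant exactly, which the test suite checks as a nesting identity.

Scaled units follow the diffusion convention: sizes $\nu_i =
N_i/N_\mathrm{ref}$, times in $2N_\mathrm{ref}$ generations, migration
$M_{ij} = 2N_\mathrm{ref}\,m_{ij}$ with $m_{ij}$ the fraction of population
$i$ replaced by migrants from population $j$ per generation. Because
outgroup polarization is imperfect, every model carries an orientation
parameter $O$: the expected spectrum is $O\,M + (1-O)\,\mathrm{rev}(M)$
where rev reverses both axes. Parameter bounds are $\nu, b \in (0.01,
100)$, $T \in (0, 10)$, $M \in (0, 50)$ and $O \in (0.01, 0.99)$.
Internally the contact time is optimised as a fraction of the split time so
that $T_c \le T_s$ holds by construction.

### Expected spectra

`expectedJsfs()` solves the two-population Wright–Fisher diffusion for the
density $\phi(x, y)$ of derived-allele frequencies. The solver uses:

* a sigmoid grid concentrated near the frequency boundaries;
* implicit-Euler time stepping with alternating-direction (ADI) splitting —
  each direction's drift-plus-migration operator is tridiagonal and solved
  exactly;
* conservative central differencing for drift and *fully upwinded*
  migration advection, which makes each one-directional operator an
  M-matrix and keeps the density non-negative at any migration rate;
* mutation injection at the first interior grid point of each axis each
  step (the 1D analogue reproduces the equilibrium $\phi = \theta/x$ to a
  few tenths of a percent, which the test suite verifies);
* sampling to a jSFS by binomial quadrature, and quadratic Richardson
  extrapolation across three grid sizes (default $n$, $n+10$, $n+20$ for
  haploid sample size $n$).

Two numerical consequences are worth knowing. First, operator splitting
orders the directional sweeps, so label equivariance (swapping populations
and transposing) holds only to the splitting error, about 1–2% on small
cells; the nesting identities (SC with $T_c = T_s$ versus IM, $m = 0$
versus SI, $b = 1$ versus constant) are exact because they follow the same
code path. Second, the default time step (0.004, capped at 400 steps per
epoch) trades a little accuracy at long divergence times for speed; the
engine agrees with an independent structured-coalescent Monte-Carlo
estimate of the same spectra within Monte-Carlo error in the tests.

### Likelihood, fitting and model choice

`compositeLoglik()` treats unmasked jSFS cells as independent Poisson
counts — a composite likelihood, as linked sites are not independent — and
profiles the overall $\theta$ multiplier analytically
($\hat\theta = \sum \mathrm{obs} / \sum \mathrm{model}$). The monomorphic
corners are always masked; model cells below $10^{-12}$ are floored.

`fitModel()` optimises in transformed coordinates (log for positive
parameters, logit for $O$ and for $T_c/T_s$). Random starts drawn
log-uniformly within the bounds are screened on a single coarse grid, the
best are refined by Nelder–Mead, and the winner is polished on the full
three-grid engine by Nelder–Mead plus a bounded BFGS step. The 9-parameter
SC+G surface has a strong ridge toward large $\nu_1$ on which purely random
restarts can strand; the default `scheme = "cascade"` therefore also seeds
the optimiser with the optima of the nested simpler models (SI first, then
the constant-size variant of the requested history) — the same
simple-to-complex strategy as the hot/cold annealing protocols commonly
used with this model family. Growth variants get ladder starts over a grid
of size-change factors with the split sizes rescaled by $1/\sqrt{b}$ (so
the geometric-mean size, which sets the coalescent intensity, is
preserved) and over a grid of contact-time fractions; every purposeful
start is refined, the best few are polished on the full grid, and
`tries > 1` repeats the whole protocol with shifted internal seeds keeping
the best likelihood. `fitAllModels()` shares the cascade across the
eight-model tournament and adds two correction passes -- a nesting rescue
(a child model refit from the embedded parent optimum whenever it scores
below a nested parent, which is impossible at the true optima) and a
competition polish (models near the AIC leader refit from the leader's
embedded solution) -- so the final ranking reflects the models rather than
optimiser luck. Every restart's achieved log-likelihood is kept in the fit
object, and a flag is raised when most refined restarts end on a parameter
bound.

Model choice uses AIC with $k$ counting all optimised parameters including
the profiled $\theta$; models within $\Delta\mathrm{AIC} < 10$ of the best
are retained. Parameter uncertainty comes from a parametric bootstrap
(Poisson resampling of the unmasked cells, warm-started refits, normal
intervals from the bootstrap standard error by default) rather than a
Godambe information-matrix correction; with warm starts the refits are
cheap and the interval construction is transparent.

### Natural units

With $\hat\theta$ in hand, $N_\mathrm{ref} = \hat\theta/(4\mu L)$,
$N_i = \nu_i N_\mathrm{ref}$, times convert through $2N_\mathrm{ref}$
generations and a generation time of 0.09 years (11 generations per year —
the two published conventions differ by 1%, well inside every tolerance;
we use the printed 0.09 in conversions and 11/year in the simulator),
migrant fractions $m_{ij} = M_{ij}/(2N_\mathrm{ref})$ and effective migrant
numbers $N_i\, m_{ij}$. `scaledFromNatural()` inverts the map, which is how
the acceptance script builds its ground truth. When generating reference
spectra we set $O = 0.98$ — a 2% misorientation rate, typical of outgroup
consensus polarization — since the published table does not report $O$.

## The synthetic-data generator

### Backward in time

`simulateSinglePop()` and `simulateTwoPop()` draw samples from a
structured coalescent with piecewise epochs, exponential within-epoch size
change, migration, and merge events, with event times drawn by thinning
against an epoch-wise rate bound. Mutations fall on branches as a Poisson
process at $\mu = 3.5\times10^{-9}$ per bp per generation by default.

Recombination is approximated by *independent non-recombining chunks*
(default 5 kb) concatenated along the chromosome. Marginally — per-site
allele frequencies, SFS and jSFS shapes, FST, $\pi$, Watterson's $\theta$,
Tajima's D in expectation — this is the exact coalescent; what it distorts
is linkage: $r^2$ is that of full linkage within a chunk and free
recombination between chunks, rather than decaying smoothly with distance.
Tests that rely on linkage (LD decay tails, EHH-based scans on neutral
data) use between-chunk comparisons or are interpreted accordingly, and
passing them demonstrates correct behaviour under this stylised linkage
structure, not under a realistic recombination map.

### Forward in time: sweep regions

`simulateSweepRegion()` generates 110-kb regions that are neutral or carry
a single beneficial mutation. Sweeps are simulated forward in time in a
Wright–Fisher population with additive selection ($1, 1+s/2, 1+s$),
per-generation recombination and mutation, initialised from a coalescent
draw of the whole population at mutation–drift equilibrium; the beneficial
allele enters at one copy (hard) or at frequency $f_0 > 1/2N$ on
independently chosen haplotypes (soft, i.e. selection on standing
variation with multiple backgrounds), and runs are restarted until it
fixes, then continued for the requested post-fixation age. The demography
is rescaled so the forward population holds 500 diploids by default;
$\theta = 4N\mu$, $\rho = 4Nr$ and $\alpha = 2Ns$ are preserved and the
factor is recorded in the truth log. A rescaling this aggressive (a factor
of 200 for the $N_e \approx 10^5$ histories used in the tests) slightly
inflates drift relative to selection during the sweep; it is the standard
trade-off that makes conditioned forward simulation feasible on one CPU.

Training sets for the classifier (`buildTrainingSet()`) draw the scaled
selection strength uniformly on $\alpha \in (100, 1000)$, soft-sweep
initial frequencies uniformly on $(1/2N, 0.2)$, fixation ages uniformly on
$(0, 0.05 \cdot 4N_e)$ generations, and place the selected site in the
central 10-kb subwindow (focal classes) or uniformly in a flanking
subwindow ("linked" classes).

## Quality control defaults

Sites must be biallelic SNPs inside the accessibility mask passing
QD $\ge 5$, FS $\le 60$ and ReadPosRankSum $\ge -8$ (sites missing an
annotation are kept and counted — annotations are caller-specific);
genotypes need GQ strictly greater than 20; then sites with $\ge 5\%$
missingness are dropped, then samples with $\ge 10\%$ — in that order, so
the retained site set never depends on sample order. Polarization against
an outgroup consensus flips dosages where the outgroup matches the
alternate allele and flags mismatches as unpolarized (excluded from
unfolded spectra); applying it twice restores the input. Molecular sexing
calls females above an X-to-genome coverage ratio of 0.80 and males below
0.70 — a 0.75 midpoint with a ±0.05 ambiguity band, since XX individuals
sit near 1 and X0/XY near 0.5. Relatedness uses PLINK-style
method-of-moments IBD coefficients with a removal threshold of
$\hat\pi = 0.5$ (flagging first-degree pairs; the member with more missing
data is suggested for removal). LD pruning applies a MAF $> 1\%$ filter,
then removes the later SNP of every pair with Rogers–Huff $r^2 > 0.01$ in
500-SNP windows stepped by 250, iterating to a fixed point (keep-first
tie-breaking).

## Windowed statistics and scans

Diversity statistics use 10-kb non-overlapping, 0-based half-open windows;
$\pi$ and $\theta_W$ are per accessible bp, and Tajima's D is `NA` (never
0) when a window has no segregating sites. Folded spectra can be scaled by
$k(n-k)/n$, which is flat with value $\theta$ under constant size;
projection to smaller samples uses exact hypergeometric expectations.
Hudson's FST is the ratio-of-averages estimator with a delete-one
block-jackknife (default block: the same 1000-SNP unit used for the genome
scan) giving a z-score and two-sided normal p-value. ROH segments come
from a two-state Poisson HMM on heterozygote counts in 20-kb windows
(background rate from the cohort-wide heterozygosity, ROH rate 5% of it,
switch probability $10^{-3}$); 100 kb is retained as the minimum length
contributing to $F_\mathrm{ROH}$. We use 20-kb emission windows rather
than coarser ones because boundary quantisation of coarse windows cannot
reach 90% base-level recall on megabase-scale tracts. IBD detection is a
deliberate simplification of genotype-likelihood methods: runs of 10-kb
windows free of opposite homozygotes spanning at least 300 kb.

XP-EHH integrates the site-level extended haplotype homozygosity (the
probability two random haplotypes are identical from the core outward,
normalised at the core) by the trapezoid rule, truncating below 0.05 or at
gaps over 20 kb, takes the log-ratio between populations and standardises
genome-wide without frequency binning. Both significance conventions are
carried on the track: BH-adjusted $q < 0.05$ and raw $p < 10^{-4}$;
candidate regions are 10-kb windows holding at least 3 significant
markers, merged when adjacent. The 1000-SNP FST blocks flag the top 1% by
construction — an outlier ranking, not a test, so identical populations
still yield flagged blocks (documented behaviour).

The panmixia test compares the observed jSFS to the mean spectrum over
label permutations with a chi-square statistic; cells with expectation
below 1 are pooled, and significance is the empirical fraction of permuted
spectra at least as extreme — asymptotic chi-square quantiles on sparse
jSFS cells are anti-conservative, which is why the reference distribution
is permutational.

## Sweep classification

Each 110-kb window is summarised by 12 statistics in 11 subwindows of
10 kb: $\pi$, $\theta_W$, Tajima's D, the variance/skew/kurtosis of the
pairwise Manhattan genotype distance, the number of distinct multilocus
genotypes, the Garud genotype homozygosities $J_1$, $J_{12}$, $J_2/J_1$,
the mean pairwise genotype $r^2$ ($Z_{nS}$) and the Kim–Nielsen
$\omega_\mathrm{max}$. Each statistic's 11 values are normalised to sum to
one, so only the spatial shape across the region survives — this also
makes the features invariant to an overall rescaling of $\theta$. Rows
with (near-)zero sum are encoded uniform and flagged. The classifier is
gradient-boosted trees over the flattened 132-vector: the architecture is
a contract (performance floors on held-out simulations), not a mandate,
and trees are deterministic and fast at desk scale where a convolutional
network would not be. Five classes are distinguished: hard, hard-linked,
soft, soft-linked, neutral.

The replicated-run protocol trains the classifier on independent simulated
datasets and reports, per genomic window and run, the class probabilities.
A window is *retained* as a sweep call when its probability of being
neutral is at most 0.01 in at least 50% of the runs — we read the
protocol's neutrality filter in the direction that discards windows with
appreciable neutral probability, the only reading under which the filter
removes noise — and its consensus label is the modal non-neutral class
among qualifying runs, ties resolving to the less specific "linked"
variant.

## Problem sizes in the test suite

The validation suite runs the full protocol at sizes chosen for a single
CPU: self-consistency refits on spectra projected to 20 diploids per
population with 20 random restarts; the eight-model tournament on 20
Poisson-resampled spectra projected to 8 diploids per population, with
reference fits on the noise-free spectrum and brief warm-started
continuation refits per replicate (the same strategy `bootstrapCi` uses);
panmixia calibration on 200 label-scrambled replicates and power at a
simulated FST near 0.05 on 4-Mb chromosomes; scan calibration on 20
panmictic replicates and sweep recovery on planted strong sweeps embedded
in 1-Mb neutral scans; classifier floors on 200 training and 100 test
regions per class under a constant $N_e = 10^5$ history. These sizes are
stated here as the package's validation design; all thresholds are the
protocol's own.

One finding from this validation deserves explicit statement. On spectra
the secondary-contact-with-growth model itself generated, the best
continuous-migration fit (IM+G) lies a quantifiable distance below the
SC+G optimum: about 17 composite-log-likelihood units at 8 diploids per
population and about 40 at 20 diploids per population (measured against
the exactly known saturated likelihood at the generating truth). AIC
therefore prefers the generating model decisively at the study's full
projection. At reduced projections, however, the SC+G likelihood surface
develops a broad plateau shared with IM+G, and optimisation from
non-truth-informed starts reliably terminates there; fitted SC+G and IM+G
then tie and the one-parameter parsimony penalty hands first rank to IM+G
in most Poisson replicates, even though SC+G stays within the
$\Delta\mathrm{AIC} < 10$ retention set throughout. In other words, at
desk scale the secondary-contact timing is near-unidentifiable against
continuous migration, and the test suite reports exactly that: retention
of the generating model passes; first-rank does not. Running the
tournament at the full projection would resolve it but takes hours per
replicate set.

## Known limitations

* Linkage in backward-time simulations is chunked, not map-based; EHH-type
  statistics on neutral simulated data decay faster at chunk boundaries
  than on real chromosomes.
* The diffusion solver's splitting error breaks exact label symmetry at
  the 1–2% level on small cells; fits are unaffected because both
  orderings are fitted with the same engine.
* The IBD detector ignores genotype likelihoods and allele frequencies; it
  is a planted-tract detector, not a replacement for likelihood-based IBD
  callers on noisy data.
* The composite likelihood ignores linkage between sites, as is standard
  for SFS-based inference; AIC differences are therefore on a composite
  scale and the retention threshold of 10 inherits that caveat.
* Forward rescaling to a few hundred diploids compresses the drift
  timescale during sweeps; classifier floors are validated under the same
  rescaling used for training, as in any simulation-trained sweep scan.
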