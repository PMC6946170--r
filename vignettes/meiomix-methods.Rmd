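---
title: "Inferring modified meiosis and paternal genome loss from single-worm sequencing"
author: "meiomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring modified meiosis and paternal genome loss from single-worm sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiomix)
```

## The biological problem

In the cross of *Caenorhabditis nouraguensis* females to *C. becei* males,
rare viable offspring arise by two coupled anomalies: the oocyte retains a
*diploid* maternal genome instead of the usual haploid product, and the
paternal genome can be eliminated completely (gynogenesis, producing fertile
maternal-only offspring), retained completely (sterile triploid hybrids),
or retained in only a subset of cells (sterile diploid–triploid mosaics).
Single-worm whole-genome sequencing of offspring from heterozygous
NIC59/JU1825 mothers lets one read off *which two* maternal chromatids each
chromosome inherited, because the four chromatids of a bivalent are
genetically distinct once a crossover has occurred.

`meiomix` implements this entire analysis as testable code: a forward
simulator of the modified meiosis, a generator of realistic sequencing
observables, the windowed genotyping and segmentation pipeline, the
karyotype classifier, and the model-comparison statistics.

## Meiosis model

Each chromosome forms one bivalent with exactly **one crossover**, placed
by a two-component mixture: with probability `1 - p_center_crossover`
uniform on the two arms (each `arm_fraction` of the length, default 0.3 per
end), otherwise uniform in the center. *Caenorhabditis* recombination is
strongly arm-biased; the 10% center mass keeps central crossovers possible
without a positional interference model (with one crossover per bivalent
none is needed). Coordinates are 0-based half-open and crossover positions
are integers.

The four chromatids are the non-recombinant N and J copies (`N1`, `J2`) and
the reciprocal recombinants (`N2`, `J1`). **Dyads** — the chromatid pairs
that co-segregate at anaphase I — are defined by shared haplotype along the
*long side* of the crossover, mirroring how crossover position dictates
which side retains cohesion in holocentric *C. elegans* meiosis. This is
what makes sister-pair inheritance produce homozygosity over chromosome
*centers* with heterozygosity beyond the crossover, the signature used to
distinguish sister from homolog retention.

Maternal inheritance modes:

* `CANONICAL` — one random chromatid, two polar bodies.
* `CENTRAL_FUSION` — one chromatid from each dyad (uniform over the 4
  pairs). This is automictic central fusion: meiosis I segregation happens
  but both half-bivalents stay in the oocyte.
* `SISTER_FUSION` — one whole dyad (meiosis II failure).
* `APOMIXIS` — `N1` + `J2`: a clone of the mother.
* `ENDOREPLICATION` — one random chromatid duplicated.
* `RANDOM_TWO` — any of the 6 pairs, uniform.

Polar bodies: canonical meiosis extrudes two. After MI failure the two
half-bivalents either share one MII spindle (one polar body) or use two
(two polar bodies); `p_shared_spindle` defaults to 0.5, consistent with
roughly half of hybrid embryos showing a single polar body. We assign one
polar body to sister fusion (MII failed after a normal MI), none to an
apomictic (mitotic) egg, and two to endoreplication (a canonical meiosis
followed by genome doubling); the data constrain only the central-fusion
case, the rest are the package's own conventions.

The X missegregates with probability `p_X_loss` (default 0), leaving one X
chromatid and producing males; no rate model is claimed.

Paternal fates are `FULL`, `NONE`, `MOSAIC(f)` (complete haploid set in a
fraction *f* of cells), `PARTIAL` (independent per-chromosome retention —
the aneuploid outcome), and `UV_DESTROYED`. Sperm from X0 fathers carry the
X with probability 0.5; the zygote records both whether the sperm carried
the X (`sperm_X`, what embryo PCR detects) and whether it was retained
(`has_X`). Viability follows the cross's observed rules: any retained
paternal X is lethal, partial paternal retention is lethal (aneuploidy),
a haploid maternal complement is lethal, diploid maternal with no paternal
DNA is fertile, and diploid maternal plus a complete paternal autosome set
is sterile-viable.

A cytological check: with one obligate crossover per homologous set, a
diploid oocyte shows 6 DAPI-staining bodies (6 bivalents) and a triploid
12 (6 bivalents + 6 univalents); `count_dapi_bodies()` encodes exactly
this.

## Read model

The pipeline starts downstream of alignment: its observables are per-SNP
allele depths and per-window coverages, not reads. Informative SNPs are
fixed NIC59/JU1825 differences at mean spacing `snp_spacing` (default
217 bp, the density obtained from the strains' bulk sequencing after
filtering); positions are exponential-spaced. At a SNP with true N-allele
fraction $f$ (the fraction of maternal copies of origin N), the observed
fraction is shifted by contamination, $f' = (1-c)f + c f_{\mathrm{cont}}$,
and by symmetric per-read errors. Total depth is Poisson(`mean_depth`) and
the N count is beta-binomial given the total with intra-class correlation
`overdispersion` (rho, default 0.05), a stand-in for the jackpotting of
single-worm whole-genome amplification; rho = 0 reduces exactly to
binomial sampling. Window coverage is proportional to per-cell copy number
(`mean_depth` corresponds to the diploid maternal level) with
multiplicative gamma noise of variance rho, plus a 0.15% cross-mapping
floor on the paternal assembly matching the 0.1–0.2% of reads that map to
the other species' genome even in maternal-only controls. The backcross
contaminant is modeled as pure N or pure J DNA (sperm retained from
fertility testing), with `contamination` < 0.5.

What the generator deliberately does not emulate: mapping bias between the
two references (the study removed it by SNP-tolerant remapping, upstream
of our interface), within-species diversity coverage dropouts, GC tracks,
scaffold fragmentation, and bacterial contamination. Passing tests
therefore show correctness of the inference given allele counts, not
robustness to alignment pathologies.

## Genotyping

SNP filtering mirrors the fixed-difference selection: quality ≥ 100,
non-reference frequency < 5% in one strain control and > 95% in the other
(either orientation), control depths within a typical range (default
5–50), and zero depth in the other-species controls. Each criterion's
removal count is reported.

Window allele frequencies pool read counts over 50-kb windows (the pooled
ratio, not the mean of per-SNP ratios, so deep SNPs weigh more); windows
with no reads are flagged missing, excluded from segmentation and attached
to the enclosing segment afterwards.

Contamination is estimated by locating the heterozygous mode $m$ of the
window-frequency density in [0.2, 0.8] and inverting the mixture,
$\hat c = (0.5 - m)/(0.5 - f_{\mathrm{cont}})$, clipped to [0, 0.5).

Change points are found by **circular binary segmentation**, authored in
this package (Rcpp): for each region the arc maximizing the
arc-vs-complement mean-shift t statistic is located, the split is accepted
when its permutation p-value is below `alpha` (default 0.01, `n_perm`
default 1000 with early stopping once significance is unreachable), and
the pieces are segmented recursively. Every segment must span at least
`min_width` (3) non-missing windows; adjacent segments closer than
`merge_tol` (0.05) in mean are merged. Segmentation is deterministic given
`seed`. The reference analysis used DNAcopy with unreported parameters, so
no parameter parity is claimed; ours are validated by the end-to-end
recovery properties in the test suite.

Segment states use corrected means $f = (\bar f - c f_{\mathrm{cont}})/(1-c)$:
`HET` in [0.35, 0.65], `HOM_N` ≥ 0.85, `HOM_J` ≤ 0.15, otherwise `AMBIG`.
The bands are our calibration of "approximately 0.5 / 1.0 / 0.0" and are
configurable.

## Karyotype classification

Copy number comes first: per-chromosome 10%-trimmed-mean coverages are
normalized so that *C. nouraguensis* chromosome I equals two; maternal
chromosomes round to the nearest of {0, 1, 2, 3} (one copy = hemizygous X,
three = triploid), and a paternal chromosome's normalized coverage *is*
its mosaic-fraction estimate (haploid in all cells gives 1), flagged
`ABSENT` (≤ 0.1), `MOSAIC`, or `FULL` (≥ 0.9).

For two-copy chromosomes the merged state-run pattern decides the class:
all-HET is `HOMOLOGS_3`; a HET body with a homozygous terminal run is
`HOMOLOGS_1`/`HOMOLOGS_2` (N/J); a homozygous body with a HET terminal run
is `SISTERS_1`/`SISTERS_2`; a single homozygous state is
`FULL_HOM_N`/`FULL_HOM_J`. Two design points deserve note:

* A two-run chromosome is classified by its pattern *regardless of where
  the crossover fell*. The class is a property of which chromatids were
  combined, not of crossover position, and this keeps the data-driven
  classifier exactly consistent with the noise-free pairing oracle
  (`classify_pair_truth()`), which the tests verify. `terminal_fraction`
  (0.30) is used only to bound the ambiguous end runs accepted by the
  `HOMOLOGS_AMBIGUOUS` rule; a terminal homozygous run narrower than
  2 windows is treated as noise.
* A doubled *recombinant* chromatid (possible under endoreplication) is
  homozygous everywhere but switches strain at the crossover; it is
  labeled `FULL_HOM_N`/`FULL_HOM_J` by the haplotype of its longer,
  center-containing run, since the distinguishable-class taxonomy has no
  separate label for it.

Individuals combine these calls: `MATERNAL_ONLY` needs a paternal-read
fraction ≤ 0.01 (an order of magnitude above the cross-mapping floor) and
no paternal chromosome called present; `TRIPLOID_HYBRID` a complete
paternal autosome set at $\hat f \ge 0.9$; `MOSAIC_HYBRID` a complete set
at $0.1 < \hat f < 0.9$; anything else is `AMBIGUOUS` (our criteria — the
reference analysis excluded its ambiguous individuals by hand).

## Inference

Expected class frequencies under each inheritance model are obtained by
enumerating the chromatid pairs the model allows and classifying each with
the pairing oracle — never hard-coded. Random retention of any two
chromatids gives (1/6, 1/6, 1/6, 1/6, 1/3) over (Sisters_1, Sisters_2,
Homologs_1, Homologs_2, Homologs_3); homolog-only retention (central
fusion) gives (0, 0, 1/4, 1/4, 1/2); sister-only retention (1/2, 1/2, 0,
0, 0).

Observed counts are compared with an **exact multinomial goodness-of-fit
test** under the probability-ordering definition: the p-value is the total
probability of all tables no more probable than the observed one. The
reference figure legends call their comparison a Fisher's exact test
without specifying its construction; since the expected frequencies are
model probabilities rather than a second observed margin, the exact
multinomial test is the cleanly defined analogue, and we do not claim
p-value parity with the published numbers. Totals up to `max_exact_n` (60)
are fully enumerated (all $\binom{n+4}{4}$ tables for five classes);
larger totals use seeded Monte Carlo with the add-one estimator. Occupied
zero-probability classes force p = 0. Hemizygous X, triploid and ambiguous
chromosomes are excluded from tallies, as in the source analysis.
Likelihood-ratio G is reported as the test statistic.

`predict_embryo_markers()` forward-simulates fertilizations to predict the
embryo PCR quantities: heterozygosity at a central maternal marker (1 under
homolog retention with arm-restricted crossovers, and under apomixis),
maternal-only fraction at a species marker, and the 50% paternal-X carriage
expected from X0 fathers.

## Numerical and reproducibility choices

* All stochastic entry points either use the caller's RNG stream or take a
  `seed` and restore the caller's RNG state on exit; pipeline stages derive
  fixed per-stage substreams from the root seed, so reruns are
  byte-identical.
* CBS permutation tests stop early once the exceedance count makes
  significance unreachable; ties in the arc statistic resolve to the first
  maximum, making segmentation deterministic given the seed.
* The exact test's outcome enumeration is cached per (n, k); log
  probabilities are computed in log space throughout.
* Degenerate inputs: constant (zero-variance) regions never split; empty
  windows are missing, not zero-frequency; an all-missing chromosome yields
  no segments and an `AMBIGUOUS` class.

## Problem sizes used by the tests

The default genome uses six chromosomes at *C. elegans*-like lengths
(13.8–20.9 Mb) with 50-kb windows and 217-bp SNP spacing. The test suite
runs the same machinery at reduced sizes chosen as its own analysis
conditions: unit tests use 1–5 Mb chromosomes; the 500-zygote
chromosome-class recovery study uses full-length chromosomes with 3-kb SNP
spacing and 200 CBS permutations; the 200-replicate model-discrimination
study (55 autosomes per replicate, the scale of the combined
fertile + sterile tally) uses full-length autosomes with 5-kb spacing and
100 permutations. Full-length chromosomes matter for those two studies: on
strongly scaled-down chromosomes, a crossover falling within `min_width`
windows of a chromosome end leaves its terminal segment unresolvable,
which inflates Homologs_3 at the expense of Homologs_1/2. The same
resolution limit is why noise-free oracle-equivalence tests condition on
crossovers at least one window from chromosome ends.

## Known limitations

* Windowed segmentation cannot see haplotype runs shorter than
  `min_width` windows; classes whose diagnostic terminal segment falls
  below that scale degrade into `HOMOLOGS_3` or `FULL_HOM_*`.
* The triploid maternal case is detected by copy number but its
  three-haplotype dosage genotype is reported descriptively, not
  classified into chromatid combinations.
* The becei assembly is modeled with the maternal karyotype's chromosome
  ids and lengths; scaffold-level coordinates, synteny and assembly gaps
  are out of scope.
* The contamination estimator assumes a genome-wide heterozygous mode; a
  genome with no heterozygous chromosomes returns $\hat c = 0$ with a
  warning.

## A worked example

```{r example, eval = FALSE}
library(meiomix)

cfg <- run_config(seed = 1, n_individuals = 4,
                  spec = genome_spec(),
                  mode_mix = c(CENTRAL_FUSION = 1),
                  fate_mix = c(NONE = 0.5, FULL = 0.25, MOSAIC = 0.25))
res <- run_pipeline(cfg, "meiomix_run")
res$counts   # distinguishable class counts across the cohort
res$gof      # exact multinomial comparison against the inheritance models
```
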