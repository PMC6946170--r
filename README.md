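# meiomix

Simulation and inference of modified female meiosis and paternal genome
loss in interspecies *Caenorhabditis* hybrids.

## The problem

Crossing *C. nouraguensis* females to *C. becei* males yields mostly dead
embryos, plus rare viable offspring with remarkable genetics: fertile
individuals carry a **diploid maternal genome and no paternal DNA**
(gynogenesis — sperm-dependent parthenogenesis), while sterile individuals
add a complete haploid paternal genome in all cells (triploid hybrids) or
only a subset of cells (diploid–triploid mosaics). When the mother is
heterozygous for two strains (NIC59 "N" / JU1825 "J"), whole-genome
sequencing of single worms reveals *which two chromatids* of each maternal
bivalent were inherited, because one arm-biased crossover makes all four
chromatids genetically distinct.

`meiomix` is an R package for scientists analyzing such crosses. It
implements, end to end:

- a **meiosis simulator**: one crossover per bivalent placed by an
  arm/center mixture, dyad formation, and competing chromatid-retention
  modes (canonical meiosis, central fusion, sister fusion, apomixis,
  endoreplication, random-two), plus paternal-genome fates (retention,
  loss, mosaicism, partial/aneuploid, UV-inactivated) with the cross's
  viability rules, polar-body counts and DAPI-body predictions;
- a **read simulator** producing per-SNP allele depths (beta-binomial
  whole-genome-amplification overdispersion, allele-flip errors, backcross
  contamination) and per-window coverage on both species' assemblies;
- the **genotyping pipeline**: fixed-difference SNP filtering, pooled
  allele frequencies in 50-kb windows, contamination estimation, circular
  binary segmentation (CBS, implemented in C++ with a permutation null),
  and heterozygous/homozygous state calls;
- a **karyotype classifier** mapping segment patterns and normalized
  coverage to the chromatid-combination classes (Sisters_1/2,
  Homologs_1/2/3, fully homozygous, hemizygous X, triploid) and to
  individual categories (maternal-only / triploid hybrid / mosaic hybrid);
- **inference**: class frequencies expected under each inheritance model,
  derived by enumeration of the bivalent's chromatid pairs —
  random-two gives (1/6, 1/6, 1/6, 1/6, 1/3) over (Sisters_1, Sisters_2,
  Homologs_1, Homologs_2, Homologs_3), homolog-only (central fusion)
  gives (0, 0, 1/4, 1/4, 1/2) — compared with observed counts by an exact
  multinomial goodness-of-fit test (probability-ordering p-value, full
  enumeration up to n = 60, seeded Monte Carlo beyond), plus forward
  predictions for embryo PCR markers.

See `vignettes/meiomix-methods.Rmd` for the model, parameter meanings and
defaults, and the package's numerical choices.

## A worked example

Simulate four offspring of a heterozygous mother under central-fusion
automixis with mixed paternal fates, genotype them from their simulated
sequencing tables, and test the pooled class counts against the
inheritance models:

```r
library(meiomix)

cfg <- run_config(seed = 1, n_individuals = 4,
                  spec = genome_spec(),
                  mode_mix = c(CENTRAL_FUSION = 1),
                  fate_mix = c(NONE = 0.5, FULL = 0.25, MOSAIC = 0.25))
res <- run_pipeline(cfg, "meiomix_run")

res$counts
#>  SISTERS_1  SISTERS_2 HOMOLOGS_1 HOMOLOGS_2 HOMOLOGS_3
#>          0          0          6          7         11

res$gof
#>          model  statistic     p_value method
#> 1   RANDOM_TWO 19.7061844 0.002763002  exact
#> 2 HOMOLOG_ONLY  0.2438592 0.896513847  exact
#> 3  SISTER_ONLY        Inf 0.000000000  exact
```

Every chromosome of every simulated individual is heterozygous over its
center — only homolog pairs were retained — so the sister-only model is
impossible (p = 0), random retention of any two chromatids is rejected
(no sister classes appeared in 24 chromosomes), and the homolog-only
(central fusion) model fits. Per-individual summaries in `res$summaries`
report each worm's category: with seed 1 the cohort comes out as two
sterile triploid hybrids (paternal fate `FULL`, no paternal X) and two
fertile maternal-only individuals (paternal fate `NONE`), matching the
fates recorded in the run manifest. The whole run takes about ten
seconds.

The cytology side of the model is one call:

```r
count_dapi_bodies(2, 6)   # diploid oocyte: 6 DAPI-staining bodies
count_dapi_bodies(3, 6)   # triploid: 6 bivalents + 6 univalents = 12
```

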