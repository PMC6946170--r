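# Scaled-down genome used throughout the tests: same structure as the
# default spec (five autosomes + X, arm-biased single crossover, 50-kb
# windows) but shorter chromosomes and sparser SNPs so that replicate
# studies stay fast. 5 Mb / 50 kb = 100 windows per chromosome.
toy_spec <- function(len = 5e6, snp_spacing = 2000, ...) {
  genome_spec(lengths = c(I = len, II = len, III = len, IV = len,
                          V = len, X = len),
              x_chrom = "X", snp_spacing = snp_spacing, ...)
}

# Even smaller spec for pipeline/file-format tests.
tiny_spec <- function() {
  genome_spec(lengths = c(I = 1e6, II = 1e6, III = 1e6, IV = 1e6,
                          V = 1e6, X = 1e6),
              x_chrom = "X", snp_spacing = 5000)
}

# A zygote whose maternal copies are given explicitly as chromatid block
# tables; used to test the read simulator against known genotypes.
manual_zygote <- function(spec, maternal, paternal_retained = character(0),
                          mosaic_fraction = 0, sperm_X = FALSE) {
  structure(list(
    spec = spec, mode = "CENTRAL_FUSION", maternal = maternal,
    paternal = list(type = if (length(paternal_retained)) "FULL" else "NONE",
                    retained = paternal_retained,
                    mosaic_fraction = mosaic_fraction,
                    sperm_X = sperm_X,
                    has_X = spec$x_chrom %in% paternal_retained),
    polar_bodies = 1L), class = "zygote")
}

# Uniform chromatid of one origin over a whole chromosome.
plain_chromatid <- function(spec, chrom, origin) {
  data.frame(chrom = chrom, start = 0, end = chrom_length_test(spec, chrom),
             origin = origin, stringsAsFactors = FALSE)
}

chrom_length_test <- function(spec, chrom) {
  spec$chromosomes$length[match(chrom, spec$chromosomes$chrom)]
}

# Segment table builder for classifier tests: breaks are fractions of the
# chromosome length.
seg_table <- function(states, breaks, len = 5e6, chrom = "I",
                      window = 50000) {
  edges <- round(c(0, breaks, 1) * len)
  means <- vapply(states, function(s)
    switch(s, HOM_N = 0.98, HET = 0.5, HOM_J = 0.02, AMBIG = 0.75),
    numeric(1))
  data.frame(chrom = chrom, start = edges[-length(edges)], end = edges[-1],
             n_windows = pmax(1, round(diff(edges) / window)),
             mean_freq = means, corrected_freq = means, state = states,
             stringsAsFactors = FALSE)
}

# Window table builder from a vector of frequencies (NA = missing window).
window_table <- function(freq, chrom = "I", window = 50000) {
  n <- length(freq)
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * window,
             end = seq_len(n) * window,
             depth_N = ifelse(is.na(freq), 0, 100 * freq),
             depth_J = ifelse(is.na(freq), 0, 100 * (1 - freq)),
             n_snps = ifelse(is.na(freq), 0L, 5L),
             freq = freq, stringsAsFactors = FALSE)
}

# TRUE when every true genotype-run boundary of the zygote lies at least
# `margin` bp from both chromosome ends. Windowed segmentation cannot
# resolve runs narrower than min_width windows, so noise-free equivalence
# checks condition on resolvable zygotes.
truth_resolvable <- function(zygote, margin = 2e5) {
  for (ch in names(zygote$maternal)) {
    cts <- zygote$maternal[[ch]]
    if (length(cts) != 2) next
    runs <- meiomix:::pair_state_runs(cts[[1]], cts[[2]])
    L <- max(runs$end)
    inner <- runs$end[-nrow(runs)]
    if (length(inner) && any(inner < margin | inner > L - margin))
      return(FALSE)
  }
  TRUE
}

sim_resolvable_zygote <- function(spec, mode, paternal = paternal_fate("NONE"),
                                  margin = 2e5, max_tries = 50) {
  for (i in seq_len(max_tries)) {
    zy <- simulate_zygote(spec, mode, paternal)
    if (truth_resolvable(zy, margin)) return(zy)
  }
  stop("no resolvable zygote in ", max_tries, " tries")
}

# Truth classes of every chromosome of a zygote (enumeration oracle).
truth_classes <- function(zygote) {
  vapply(names(zygote$maternal), function(ch) {
    cts <- zygote$maternal[[ch]]
    if (length(cts) != 2) return(NA_character_)
    classify_pair_truth(cts)
  }, character(1))
}
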