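test_that("SNP filtering applies every fixed-difference criterion", {
  base <- data.frame(qual = 200, freq_a = 0.02, freq_b = 0.98,
                     depth_a = 20, depth_b = 20, other_species_depth = 0)
  snps <- rbind(
    base,                                  # passes
    transform(base, qual = 99),            # quality below 100
    transform(base, freq_a = 0.04, freq_b = 0.96),  # passes (fixed)
    transform(base, freq_a = 0.96, freq_b = 0.04),  # passes (other phase)
    transform(base, freq_a = 0.5),         # not a fixed difference
    transform(base, depth_a = 2),          # control depth out of range
    transform(base, depth_b = 80),         # control depth out of range
    transform(base, other_species_depth = 1))  # cross-maps to other species
  out <- filter_snps(snps, snp_filter_config())
  expect_equal(nrow(out), 3)
  removed <- attr(out, "removed")
  expect_equal(unname(removed["quality"]), 1)
  expect_equal(unname(removed["not_fixed"]), 1)
  expect_equal(unname(removed["depth"]), 2)
  expect_equal(unname(removed["other_species"]), 1)

  expect_error(filter_snps(base[, -1]), "missing required column")
})

test_that("window frequencies pool counts rather than averaging ratios", {
  spec <- genome_spec(lengths = c(I = 2e5), x_chrom = "I")
  d <- data.frame(chrom = "I",
                  pos = c(1000, 2000, 60000, 110000),
                  depth_N = c(9, 1, 30, 0),
                  depth_J = c(1, 19, 10, 0))
  w <- window_allele_freq(d, spec)
  expect_equal(nrow(w), 4)            # 200 kb / 50 kb
  # pooled (9+1)/(10+20), not mean(0.9, 0.05)
  expect_equal(w$freq[1], 10 / 30)
  expect_equal(w$freq[2], 0.75)
  expect_true(is.na(w$freq[3]))       # zero-depth SNPs -> missing window
  expect_true(is.na(w$freq[4]))       # empty window
  expect_equal(w$depth_N[1] + w$depth_J[1], 30)

  # all-N window
  dN <- data.frame(chrom = "I", pos = 0:4 * 100, depth_N = 5, depth_J = 0)
  expect_equal(window_allele_freq(dN, spec)$freq[1], 1.0)
})

test_that("contamination is recovered by inverting the heterozygous mode", {
  set.seed(201)
  # clean heterozygous genome: mode at 0.5, c = 0
  w0 <- window_table(stats::rnorm(200, 0.5, 0.01))
  c0 <- estimate_contamination(w0, "J")
  expect_lt(abs(unname(c0)), 0.02)

  # mode shifted to 0.4 by a JU1825 contaminant: c = 0.2
  w4 <- window_table(c(stats::rnorm(150, 0.4, 0.01),
                       stats::rnorm(50, 0.92, 0.01)))
  c4 <- estimate_contamination(w4, "J")
  expect_lt(abs(unname(c4) - 0.2), 0.03)

  # an NIC59 contaminant shifts the mode up instead
  wN <- window_table(stats::rnorm(200, 0.6, 0.01))
  cN <- estimate_contamination(wN, "N")
  expect_lt(abs(unname(cN) - 0.2), 0.03)

  expect_error(estimate_contamination(window_table(rep(0.5, 10)), "J"),
               "at least 50")
  expect_warning(
    cz <- estimate_contamination(window_table(stats::rnorm(100, 0.97, 0.005)),
                                 "J"),
    "no heterozygous mode")
  expect_equal(as.numeric(cz), 0)
})

test_that("contamination recovery works end-to-end on simulated reads", {
  spec <- toy_spec()
  set.seed(211)
  zy <- simulate_zygote(spec, "APOMIXIS", paternal_fate("NONE"))
  m <- read_model(mean_depth = 30, contamination = 0.1,
                  contaminant_origin = "J")
  d <- simulate_allele_depths(zy, spec, m)
  w <- window_allele_freq(d, spec)
  c_hat <- estimate_contamination(w, "J")
  expect_lt(abs(unname(c_hat) - 0.1), 0.03)
})

test_that("CBS finds exact change points on clean series", {
  # constant series: a single segment
  segs <- segment_cbs(window_table(rep(0.5, 80)), seed = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$mean_freq, 0.5)
  expect_equal(segs$n_windows, 80)

  # noiseless step 1.0 -> 0.5 at window 40 of 100
  x <- c(rep(1.0, 40), rep(0.5, 60))
  segs <- segment_cbs(window_table(x), seed = 1)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$end[1], 40 * 50000)
  expect_equal(segs$mean_freq, c(1.0, 0.5))

  # agrees with a brute-force single change-point maximizer
  brute_split <- function(x) {
    n <- length(x)
    stat <- vapply(1:(n - 1), function(k) {
      m1 <- mean(x[1:k]); m2 <- mean(x[(k + 1):n])
      abs(m1 - m2) / sqrt(1 / k + 1 / (n - k))
    }, numeric(1))
    which.max(stat)
  }
  expect_equal(brute_split(x), 40L)

  # reversal: mirrored breakpoint
  segs_rev <- segment_cbs(window_table(rev(x)), seed = 1)
  expect_equal(nrow(segs_rev), 2)
  expect_equal(segs_rev$end[1], 60 * 50000)
})

test_that("CBS localizes noisy change points and bounds segment counts", {
  set.seed(221)
  hits <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    x <- c(rep(0.5, 40), rep(1.0, 60)) + stats::rnorm(100, 0, 0.05)
    segs <- segment_cbs(window_table(x), seed = r)
    bps <- segs$end[-nrow(segs)] / 50000
    if (any(abs(bps - 40) <= 2)) hits <- hits + 1L
    expect_lte(nrow(segs), ceiling(100 / 3))
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("missing windows join the enclosing segment", {
  x <- c(rep(1, 30), NA, NA, rep(1, 8), rep(0.5, 40))
  segs <- segment_cbs(window_table(x), seed = 2)
  expect_equal(sum(segs$end - segs$start), 80 * 50000)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$end[1], 40 * 50000)

  # chromosome with all windows missing yields no segments
  segs2 <- segment_cbs(window_table(rep(NA_real_, 20)), seed = 2)
  expect_null(segs2)
})

test_that("segment states follow the frequency bands with correction", {
  segs <- data.frame(chrom = "I", start = c(0, 1, 2, 3) * 5e4,
                     end = c(1, 2, 3, 4) * 5e4, n_windows = 1,
                     mean_freq = c(0.50, 0.98, 0.75, 0.02))
  st <- call_segment_states(segs)
  expect_equal(st$state, c("HET", "HOM_N", "AMBIG", "HOM_J"))

  # J contamination at c = 0.2: raw 0.4 corrects to 0.5
  segs2 <- data.frame(chrom = "I", start = 0, end = 5e4, n_windows = 1,
                      mean_freq = 0.4)
  st2 <- call_segment_states(segs2, contamination = 0.2,
                             contaminant_origin = "J")
  expect_equal(st2$corrected_freq, 0.5)
  expect_equal(st2$state, "HET")

  # N contamination shifts the other way
  st3 <- call_segment_states(
    data.frame(chrom = "I", start = 0, end = 5e4, n_windows = 1,
               mean_freq = 0.6),
    contamination = 0.2, contaminant_origin = "N")
  expect_equal(st3$corrected_freq, 0.5)
})

test_that("noise-free segmentation reproduces the true haplotype blocks", {
  spec <- toy_spec()
  set.seed(231)
  for (i in 1:5) {
    # condition on crossovers resolvable at window resolution
    zy <- sim_resolvable_zygote(spec, "RANDOM_TWO")
    d <- simulate_allele_depths(zy, spec,
                                read_model(mean_depth = 30, error_rate = 0,
                                           exact = TRUE))
    w <- window_allele_freq(d, spec)
    segs <- call_segment_states(segment_cbs(w, seed = i))
    for (ch in names(zy$maternal)) {
      runs <- meiomix:::pair_state_runs(zy$maternal[[ch]][[1]],
                                        zy$maternal[[ch]][[2]])
      s <- segs[segs$chrom == ch, ]
      # same state sequence...
      expect_equal(s$state, runs$state)
      # ...with breakpoints within one window of the true crossover
      if (nrow(s) == 2)
        expect_lt(abs(s$end[1] - runs$end[1]), 50000 + 1)
    }
  }
})
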