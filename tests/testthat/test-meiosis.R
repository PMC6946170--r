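test_that("crossover placement follows the arm/center mixture", {
  spec <- toy_spec()
  L <- 5e6

  set.seed(11)
  no_center <- genome_spec(lengths = c(I = L), x_chrom = "I",
                           arm_fraction = 0.3, p_center_crossover = 0)
  pos <- replicate(1000, draw_crossover_position(no_center, "I"))
  in_arm <- pos < 0.3 * L | pos >= 0.7 * L
  expect_true(all(in_arm))
  expect_true(all(pos >= 1 & pos <= L - 1))

  # arms covering everything: uniform over the chromosome
  all_arm <- genome_spec(lengths = c(I = L), x_chrom = "I",
                         arm_fraction = 0.5, p_center_crossover = 0.1)
  pos <- replicate(4000, draw_crossover_position(all_arm, "I"))
  expect_gt(suppressWarnings(stats::ks.test(pos / L, "punif")$p.value), 1e-3)

  # binomial check of the configured center mass
  mix <- genome_spec(lengths = c(I = L), x_chrom = "I",
                     arm_fraction = 0.3, p_center_crossover = 0.1)
  pos <- replicate(10000, draw_crossover_position(mix, "I"))
  f_center <- mean(pos >= 0.3 * L & pos < 0.7 * L)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(f_center - 0.1), 3 * se)

  expect_error(draw_crossover_position(spec, "nope"), "unknown chromosome")
})

test_that("bivalents have one reciprocal exchange and conserved origins", {
  spec <- toy_spec()
  set.seed(21)
  for (i in 1:20) {
    biv <- make_bivalent(spec, "II")
    L <- biv$length
    cts <- biv$chromatids
    grid <- seq(0, L - 1, length.out = 101)

    expect_true(all(origin_at(cts$N1, grid) == "N"))
    expect_true(all(origin_at(cts$J2, grid) == "J"))
    # N2 and J1 are reciprocal at every position
    expect_true(all(origin_at(cts$N2, grid) != origin_at(cts$J1, grid)))

    # conservation: summed origin-N length across the four chromatids = 2L
    n_len <- sum(vapply(cts, function(ct)
      sum((ct$end - ct$start)[ct$origin == "N"]), numeric(1)))
    expect_equal(n_len, 2 * L)

    # dyad members share their haplotype along the long side
    x <- biv$crossover
    long_side <- if (x >= L / 2) grid[grid < x] else grid[grid >= x]
    for (dy in biv$dyads) {
      expect_equal(origin_at(cts[[dy[1]]], long_side),
                   origin_at(cts[[dy[2]]], long_side))
    }
  }
})

test_that("maternal chromatid selection honors each mode's contract", {
  spec <- toy_spec()
  set.seed(31)
  biv <- make_bivalent(spec, "I")
  dyad_keys <- vapply(biv$dyads, function(d) paste(sort(d), collapse = "+"),
                      character(1))

  # central fusion never returns a dyad, and uses both dyads
  for (i in 1:300) {
    sel <- select_maternal_chromatids(biv, "CENTRAL_FUSION")
    key <- paste(sort(sel$names), collapse = "+")
    expect_false(key %in% dyad_keys)
  }

  # sister fusion returns exactly a dyad
  for (i in 1:50) {
    sel <- select_maternal_chromatids(biv, "SISTER_FUSION")
    expect_true(paste(sort(sel$names), collapse = "+") %in% dyad_keys)
  }

  # apomixis: clone of the heterozygous mother
  sel <- select_maternal_chromatids(biv, "APOMIXIS")
  expect_setequal(sel$names, c("N1", "J2"))
  grid <- seq(0, biv$length - 1, length.out = 201)
  expect_true(all(origin_at(sel$chromatids[[1]], grid) !=
                    origin_at(sel$chromatids[[2]], grid)))

  # endoreplication: two identical copies
  sel <- select_maternal_chromatids(biv, "ENDOREPLICATION")
  expect_identical(sel$chromatids[[1]], sel$chromatids[[2]])

  # canonical: a single chromatid and two polar bodies
  sel <- select_maternal_chromatids(biv, "CANONICAL")
  expect_length(sel$chromatids, 1)
  expect_identical(sel$polar_bodies, 2L)
})

test_that("RANDOM_TWO samples the six pairs uniformly", {
  spec <- toy_spec()
  set.seed(41)
  biv <- make_bivalent(spec, "III")
  n <- 60000
  keys <- character(n)
  for (i in seq_len(n)) {
    sel <- select_maternal_chromatids(biv, "RANDOM_TWO")
    keys[i] <- paste(sort(sel$names), collapse = "+")
  }
  freq <- table(keys) / n
  expect_length(freq, 6)
  # single joint uniformity check (avoids multiplicity over the six bins)
  expect_gt(stats::chisq.test(table(keys))$p.value, 1e-3)
  se <- sqrt((1 / 6) * (5 / 6) / n)
  expect_true(all(abs(freq - 1 / 6) < 4 * se))
})

test_that("pair classification matches the chromatid-combination signatures", {
  spec <- toy_spec()
  set.seed(51)
  biv <- make_bivalent(spec, "IV")
  cts <- biv$chromatids

  # exhaustive enumeration of the six pairs of one bivalent
  pairs <- utils::combn(names(cts), 2, simplify = FALSE)
  classes <- vapply(pairs, function(p) classify_pair_truth(cts[p]),
                    character(1))
  expect_equal(sort(as.integer(table(classes))), c(1, 1, 1, 1, 2))
  expect_equal(sum(classes == "HOMOLOGS_3"), 2)
  expect_setequal(unique(classes),
                  c("SISTERS_1", "SISTERS_2", "HOMOLOGS_1", "HOMOLOGS_2",
                    "HOMOLOGS_3"))

  # the two non-recombinants are heterozygous throughout
  expect_equal(classify_pair_truth(cts[c("N1", "J2")]), "HOMOLOGS_3")

  # a dyad is homozygous over the center, heterozygous past the crossover
  for (dy in biv$dyads) {
    cls <- classify_pair_truth(cts[dy])
    expect_true(cls %in% c("SISTERS_1", "SISTERS_2"))
  }

  # identical copies are fully homozygous
  expect_equal(classify_pair_truth(list(cts$N1, cts$N1)), "FULL_HOM_N")
  expect_equal(classify_pair_truth(list(cts$J2, cts$J2)), "FULL_HOM_J")

  other <- make_bivalent(spec, "V")
  expect_error(classify_pair_truth(list(cts$N1, other$chromatids$N1)),
               "different chromosomes")
})

test_that("zygote assembly and fate rules reproduce the viability model", {
  spec <- toy_spec()
  set.seed(61)

  # gynogenetic outcome: diploid maternal, no paternal DNA, fertile
  zy <- simulate_zygote(spec, "CENTRAL_FUSION", paternal_fate("NONE"))
  expect_true(all(maternal_copy_number(zy) == 2))
  expect_length(zy$paternal$retained, 0)
  expect_equal(zy$fate, "FERTILE_VIABLE")

  # normal fertilization in this cross: haploid maternal + full paternal
  zy <- simulate_zygote(spec, "CANONICAL",
                        paternal_fate("FULL", include_X = FALSE))
  expect_true(all(maternal_copy_number(zy) == 1))
  expect_setequal(zy$paternal$retained, c("I", "II", "III", "IV", "V"))
  expect_equal(zy$fate, "DEAD")

  # sterile triploid hybrid: 2 maternal + 1 paternal autosome copies
  zy <- simulate_zygote(spec, "CENTRAL_FUSION",
                        paternal_fate("FULL", include_X = FALSE))
  expect_equal(zy$fate, "STERILE_VIABLE")
  expect_equal(zy$paternal$mosaic_fraction, 1)

  # paternal X is toxic
  zy <- simulate_zygote(spec, "CENTRAL_FUSION",
                        paternal_fate("FULL", include_X = TRUE))
  expect_equal(zy$fate, "DEAD")
  expect_match(zy$fate_reason, "paternal X")

  # haploid maternal with no paternal rescue dies
  zy <- simulate_zygote(spec, "CANONICAL", paternal_fate("NONE"))
  expect_equal(zy$fate, "DEAD")
  expect_match(zy$fate_reason, "haploid")

  # UV-destroyed sperm genome leaves no paternal blocks
  zy <- simulate_zygote(spec, "CENTRAL_FUSION",
                        paternal_fate("UV_DESTROYED"))
  expect_length(zy$paternal$retained, 0)
  expect_false(zy$paternal$sperm_X)

  # X missegregation produces a single maternal X
  zy <- simulate_zygote(spec, "CENTRAL_FUSION", paternal_fate("NONE"),
                        p_X_loss = 1)
  expect_equal(unname(maternal_copy_number(zy)[["X"]]), 1L)

  expect_error(paternal_fate("MOSAIC", fraction = 1.2), "strictly in")
})

test_that("polar-body counts follow the shared-spindle model", {
  set.seed(71)
  expect_true(all(replicate(50, draw_polar_bodies("CANONICAL")) == 2L))
  expect_true(all(replicate(50,
    draw_polar_bodies("CENTRAL_FUSION", p_shared_spindle = 1)) == 1L))
  pb <- replicate(2000, draw_polar_bodies("CENTRAL_FUSION",
                                          p_shared_spindle = 0.5))
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(mean(pb == 1) - 0.5), 3 * se)
  expect_equal(draw_polar_bodies("APOMIXIS"), 0L)
  expect_equal(draw_polar_bodies("SISTER_FUSION"), 1L)
})

test_that("DAPI-body counts follow the bivalent/univalent rule", {
  expect_equal(count_dapi_bodies(2, 6), 6L)
  expect_equal(count_dapi_bodies(3, 6), 12L)
  expect_equal(count_dapi_bodies(1, 6), 6L)
  expect_equal(count_dapi_bodies(4, 6), 18L)
  expect_equal(count_dapi_bodies(2, 5), 5L)
  expect_error(count_dapi_bodies(0, 6), "positive")
})

test_that("seeded meiosis simulation is reproducible", {
  spec <- toy_spec()
  set.seed(123)
  a <- simulate_zygote(spec, "RANDOM_TWO", paternal_fate("PARTIAL"))
  set.seed(123)
  b <- simulate_zygote(spec, "RANDOM_TWO", paternal_fate("PARTIAL"))
  expect_identical(a, b)
})
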