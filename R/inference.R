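INHERITANCE_MODELS <- c("RANDOM_TWO", "HOMOLOG_ONLY", "SISTER_ONLY",
                        "APOMIXIS", "ENDOREPLICATION")

#' Expected genotype-class frequencies under an inheritance model
#'
#' Computed by enumeration over the chromatid pairs a bivalent can
#' contribute, never hard-coded: a reference bivalent with an arm crossover
#' is built, the pairs allowed by the model are listed (all six for
#' `RANDOM_TWO`; the four homolog pairs for `HOMOLOG_ONLY`, i.e. central
#' fusion; the two dyads for `SISTER_ONLY`; the two non-recombinant
#' chromatids for `APOMIXIS`; each chromatid doubled for
#' `ENDOREPLICATION`), each pair is classified with the noise-free oracle
#' [classify_pair_truth()], and the classes are tallied with equal weight.
#'
#' @param model One of `"RANDOM_TWO"`, `"HOMOLOG_ONLY"`, `"SISTER_ONLY"`,
#'   `"APOMIXIS"`, `"ENDOREPLICATION"`.
#' @return Named probability vector summing to one. For the pairing models
#'   its names are the five distinguishable classes (Sisters_1, Sisters_2,
#'   Homologs_1, Homologs_2, Homologs_3); endoreplication places its mass on
#'   the fully homozygous classes.
#' @examples
#' expected_class_frequencies("RANDOM_TWO")
#' @export
expected_class_frequencies <- function(model = INHERITANCE_MODELS) {
  model <- match.arg(model)
  spec1 <- genome_spec(lengths = c(I = 1e6), x_chrom = "I",
                       arm_fraction = 0.3, p_center_crossover = 0)
  # fixed arm crossover: class frequencies do not depend on its position
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(1L)
  biv <- make_bivalent(spec1, "I")
  cts <- biv$chromatids
  pairs <- switch(model,
    RANDOM_TWO = utils::combn(names(cts), 2, simplify = FALSE),
    HOMOLOG_ONLY = {
      # one chromatid from each dyad (central fusion): 2 x 2 pairs
      out <- list()
      for (a in biv$dyads[[1]]) for (b in biv$dyads[[2]])
        out <- c(out, list(c(a, b)))
      out
    },
    SISTER_ONLY = biv$dyads,
    APOMIXIS = list(c("N1", "J2")),
    ENDOREPLICATION = lapply(names(cts), function(nm) c(nm, nm))
  )
  classes <- vapply(pairs, function(p)
    classify_pair_truth(cts[p]), character(1))
  tab <- table(classes) / length(classes)
  base <- stats::setNames(numeric(length(DISTINGUISHABLE_CLASSES)),
                          DISTINGUISHABLE_CLASSES)
  extra <- setdiff(names(tab), names(base))
  probs <- c(base, stats::setNames(numeric(length(extra)), extra))
  probs[names(tab)] <- as.numeric(tab)
  probs
}

.outcome_cache <- new.env(parent = emptyenv())

# all compositions of n into k non-negative parts, via stars and bars;
# memoized, as replicate studies evaluate the same (n, k) repeatedly
multinomial_outcomes <- function(n, k) {
  key <- paste0("n", n, "k", k)
  hit <- .outcome_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- multinomial_outcomes_raw(n, k)
  .outcome_cache[[key]] <- out
  out
}

# log multinomial coefficients of the outcome table, cached alongside it
outcome_log_coef <- function(n, k) {
  key <- paste0("c", n, "k", k)
  hit <- .outcome_cache[[key]]
  if (!is.null(hit)) return(hit)
  x <- multinomial_outcomes(n, k)
  out <- lgamma(n + 1) - rowSums(lgamma(x + 1))
  .outcome_cache[[key]] <- out
  out
}

multinomial_outcomes_raw <- function(n, k) {
  if (k == 1) return(matrix(n, nrow = 1))
  bars <- utils::combn(n + k - 1, k - 1)
  if (k == 2) {
    counts <- rbind(bars - 1, n + k - 1 - bars)
  } else {
    counts <- rbind(bars[1, ] - 1,
                    bars[-1, , drop = FALSE] -
                      bars[-(k - 1), , drop = FALSE] - 1,
                    n + k - 1 - bars[k - 1, ])
  }
  t(counts)
}

log_dmultinom_rows <- function(x, prob) {
  lp <- lgamma(rowSums(x) + 1) - rowSums(lgamma(x + 1))
  pos <- prob > 0
  if (any(pos))
    lp <- lp + as.numeric(x[, pos, drop = FALSE] %*% log(prob[pos]))
  if (any(!pos)) {
    bad <- rowSums(x[, !pos, drop = FALSE]) > 0
    lp[bad] <- -Inf
  }
  lp
}

#' Exact multinomial goodness-of-fit test of class counts
#'
#' Tests observed genotype-class counts against the class probabilities of
#' an inheritance model. The p-value uses the probability-ordering
#' definition of the exact multinomial test: the total probability of all
#' outcome tables (same total count) whose multinomial probability does not
#' exceed that of the observed table. For totals up to `max_exact_n` every
#' outcome is enumerated; beyond that, `n_mc` Monte Carlo tables are drawn
#' (with the add-one p-value estimator) under a fixed seed. A class with
#' model probability zero but positive observed count forces p = 0.
#'
#' @param observed Named (or model-ordered) non-negative integer counts.
#' @param model An inheritance model name, or `NULL` when `probs` is given.
#' @param probs Optional explicit probability vector (overrides `model`).
#' @param max_exact_n Largest total count for full enumeration.
#' @param n_mc Number of Monte Carlo tables beyond that.
#' @param seed Seed for the Monte Carlo draw.
#' @return An object of class `gof_result`: `observed`, `expected_probs`,
#'   `statistic` (likelihood-ratio G), `p_value`, `method`, `seed`, `n`.
#' @export
goodness_of_fit <- function(observed, model = NULL, probs = NULL,
                            max_exact_n = 60, n_mc = 1e5, seed = 1L) {
  if (is.null(probs)) {
    if (is.null(model)) stop("give either a model name or probs")
    probs <- expected_class_frequencies(model)
  }
  if (any(observed < 0)) stop("negative counts")
  if (!is.null(names(observed))) {
    extra <- setdiff(names(observed), names(probs))
    if (length(extra))
      stop("observed classes not in the model: ", paste(extra, collapse = ", "))
    obs <- stats::setNames(numeric(length(probs)), names(probs))
    obs[names(observed)] <- observed
  } else {
    if (length(observed) != length(probs))
      stop("unnamed observed counts must match the probability vector length")
    obs <- stats::setNames(as.numeric(observed), names(probs))
  }
  n <- sum(obs)
  if (n < 1) stop("total count must be at least 1")
  p <- as.numeric(probs)
  exp_counts <- n * p
  pos <- obs > 0
  statistic <- 2 * sum(obs[pos] * (log(obs[pos]) - log(exp_counts[pos])))

  lp_obs <- log_dmultinom_rows(matrix(obs, nrow = 1), p)
  tol <- 1e-9
  if (n <= max_exact_n) {
    outcomes <- multinomial_outcomes(n, length(p))
    lp <- outcome_log_coef(n, length(p))
    pos <- p > 0
    if (any(pos))
      lp <- lp + as.numeric(outcomes[, pos, drop = FALSE] %*% log(p[pos]))
    if (any(!pos))
      lp[rowSums(outcomes[, !pos, drop = FALSE]) > 0] <- -Inf
    keep <- lp <= lp_obs + tol & is.finite(lp)
    p_value <- sum(exp(lp[keep]))
    p_value <- min(p_value, 1)
    if (!is.finite(lp_obs)) p_value <- 0
    method <- "exact"
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    draws <- t(stats::rmultinom(n_mc, n, p))
    lp <- log_dmultinom_rows(draws, p)
    hits <- sum(lp <= lp_obs + tol)
    p_value <- (hits + 1) / (n_mc + 1)
    if (!is.finite(lp_obs)) p_value <- 0
    method <- "monte_carlo"
  }
  structure(list(observed = obs, expected_probs = stats::setNames(p, names(probs)),
                 statistic = statistic, p_value = p_value, method = method,
                 seed = seed, n = n),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("exact multinomial goodness-of-fit (", x$method, ")\n", sep = "")
  tab <- rbind(observed = x$observed,
               expected = round(x$n * x$expected_probs, 2))
  print(tab)
  cat(sprintf("G = %.3f, n = %d, p = %.4g\n", x$statistic, x$n, x$p_value))
  invisible(x)
}

#' Model-based predictions for embryo marker genotypes
#'
#' Forward-simulates zygotes under a maternal inheritance mode and paternal
#' fate and tallies the marker-level quantities scored in embryo PCR
#' genotyping: the fraction heterozygous (N/J) at a maternal marker
#' position, the fraction carrying no paternal copy of the marker
#' chromosome (maternal-only at a species-diagnostic marker), and the
#' fraction inheriting a paternal X (0.5 when the sperm X is Bernoulli,
#' fathers being X0).
#'
#' @param mode Maternal inheritance mode (see
#'   [select_maternal_chromatids()]); `"HOMOLOG_ONLY"` is accepted as an
#'   alias for `"CENTRAL_FUSION"`.
#' @param spec A [genome_spec()].
#' @param marker_chrom Chromosome carrying the maternal marker.
#' @param marker_pos Marker position in bp (default: chromosome center).
#' @param paternal A [paternal_fate()] descriptor.
#' @param n_sim Number of simulated fertilizations.
#' @param seed Optional seed.
#' @return Named vector: `frac_het_marker`, `frac_maternal_only_marker`,
#'   `frac_paternal_X`, plus attribute `n_sim`.
#' @export
predict_embryo_markers <- function(mode, spec = genome_spec(),
                                   marker_chrom = "I", marker_pos = NULL,
                                   paternal = paternal_fate("PARTIAL"),
                                   n_sim = 1000, seed = NULL) {
  if (identical(mode, "HOMOLOG_ONLY")) mode <- "CENTRAL_FUSION"
  mode <- match.arg(mode, MATERNAL_MODES)
  if (is.null(marker_pos))
    marker_pos <- floor(chrom_length(spec, marker_chrom) / 2)
  if (marker_pos < 0 || marker_pos >= chrom_length(spec, marker_chrom))
    stop("marker position outside the chromosome")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  het <- logical(n_sim); mat_only <- logical(n_sim); pat_X <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    zy <- simulate_zygote(spec, mode, paternal)
    cts <- zy$maternal[[marker_chrom]]
    ori <- vapply(cts, function(ct) origin_at(ct, marker_pos), character(1))
    het[i] <- length(unique(ori)) > 1
    mat_only[i] <- !(marker_chrom %in% zy$paternal$retained)
    # whole-embryo PCR detects the paternal X whenever the sperm carried it:
    # mosaic elimination still leaves it present in some cells
    pat_X[i] <- zy$paternal$sperm_X
  }
  structure(c(frac_het_marker = mean(het),
              frac_maternal_only_marker = mean(mat_only),
              frac_paternal_X = mean(pat_X)),
            n_sim = n_sim)
}
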