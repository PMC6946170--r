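#' Single-worm sequencing read model
#'
#' Describes the noise structure of whole-genome-amplified single-worm
#' sequencing downstream of alignment: per-SNP depth, beta-binomial
#' overdispersion of the allele split (WGA "jackpotting"), per-read allele
#' flip errors, contamination by reads from a known maternal haplotype (e.g.
#' sperm DNA retained after backcross fertility testing) and the low-level
#' cross-mapping floor onto the paternal species' assembly.
#'
#' @param mean_depth Mean reads per SNP (and per-window diploid-equivalent
#'   coverage).
#' @param overdispersion Beta-binomial intra-class correlation `rho` in
#'   `[0, 1)`; 0 gives binomial sampling.
#' @param error_rate Per-read probability of reporting the other haplotype.
#' @param contamination Fraction of reads from the contaminant, in `[0, 0.5)`.
#' @param contaminant_origin `"N"` or `"J"`: the contaminant haplotype.
#' @param becei_floor Fraction of reads cross-mapping to the paternal
#'   (*C. becei*) assembly even with no paternal DNA (the 0.1--0.2%
#'   cross-mapping floor seen in maternal-only samples).
#' @param exact If `TRUE`, depths are deterministic expectations (no
#'   sampling); used for noise-free oracle checks.
#' @return An object of class `read_model`.
#' @export
read_model <- function(mean_depth = 30, overdispersion = 0.05,
                       error_rate = 0.001, contamination = 0,
                       contaminant_origin = c("J", "N"),
                       becei_floor = 0.0015, exact = FALSE) {
  contaminant_origin <- match.arg(contaminant_origin)
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (overdispersion < 0 || overdispersion >= 1)
    stop("overdispersion must be in [0, 1)")
  if (contamination < 0 || contamination >= 0.5)
    stop("contamination must be in [0, 0.5)")
  if (error_rate < 0 || error_rate > 0.5)
    stop("error_rate must be in [0, 0.5]")
  structure(list(mean_depth = mean_depth, overdispersion = overdispersion,
                 error_rate = error_rate, contamination = contamination,
                 contaminant_origin = contaminant_origin,
                 becei_floor = becei_floor, exact = isTRUE(exact)),
            class = "read_model")
}

# beta-binomial sampler parameterized by intra-class correlation rho
rbetabinom_icc <- function(n, size, prob, rho) {
  prob <- rep_len(prob, n)
  if (rho == 0) return(stats::rbinom(n, size, prob))
  p <- prob
  mid <- prob > 0 & prob < 1  # keep exact 0/1 outcomes degenerate
  if (any(mid)) {
    a <- prob[mid] * (1 - rho) / rho
    b <- (1 - prob[mid]) * (1 - rho) / rho
    p[mid] <- stats::rbeta(sum(mid), a, b)
  }
  stats::rbinom(n, size, p)
}

contaminant_freq <- function(model) {
  if (model$contaminant_origin == "N") 1 else 0
}

#' Simulate per-SNP maternal allele depths for a zygote
#'
#' Places informative SNPs at exponential spacings (mean `spec$snp_spacing`)
#' along each chromosome with at least one maternal copy. The true NIC59
#' ("N") fraction at a SNP is the fraction of maternal copies with origin N;
#' it is shifted by contamination, `f_obs = (1-c) f_true + c f_cont`, and by
#' symmetric per-read errors. Total SNP depth is Poisson(`mean_depth`) and
#' the N-allele count is beta-binomial given the total (binomial when
#' `overdispersion = 0`). With `exact = TRUE` the depths are rounded
#' expectations, giving a noise-free table.
#'
#' @param zygote A [simulate_zygote()] result.
#' @param spec A [genome_spec()].
#' @param model A [read_model()].
#' @return Data frame (`allele_depth_table`) with columns `chrom`, `pos`,
#'   `depth_N`, `depth_J`; positions strictly increasing within chromosome.
#' @export
simulate_allele_depths <- function(zygote, spec, model = read_model()) {
  copies <- maternal_copy_number(zygote)
  if (all(copies == 0)) stop("zygote has an empty maternal complement")
  c0 <- model$contamination
  fc <- contaminant_freq(model)
  e <- model$error_rate
  out <- vector("list", length(zygote$maternal))
  for (i in seq_along(zygote$maternal)) {
    ch <- names(zygote$maternal)[i]
    cts <- zygote$maternal[[i]]
    if (length(cts) == 0) next
    L <- chrom_length(spec, ch)
    n_draw <- ceiling(L / spec$snp_spacing * 1.4) + 25
    pos <- cumsum(stats::rexp(n_draw, 1 / spec$snp_spacing))
    pos <- floor(pos[pos < L])
    pos <- unique(pos)
    if (length(pos) == 0) next
    f_true <- rowMeans(vapply(cts, function(ct) origin_at(ct, pos) == "N",
                              logical(length(pos))))
    f_obs <- (1 - c0) * f_true + c0 * fc
    f_err <- f_obs * (1 - e) + (1 - f_obs) * e
    if (model$exact) {
      depth <- rep(round(model$mean_depth), length(pos))
      dN <- round(depth * f_err)
    } else {
      depth <- stats::rpois(length(pos), model$mean_depth)
      dN <- rbetabinom_icc(length(pos), depth, f_err, model$overdispersion)
    }
    out[[i]] <- data.frame(chrom = ch, pos = pos, depth_N = dN,
                           depth_J = depth - dN, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("allele_depth_table", "data.frame")
  res
}

#' Simulate per-window coverage on both species' assemblies
#'
#' Mean per-window depth is proportional to locus copy number averaged over
#' cells: `mean_depth * copies / 2` for the maternal (*C. nouraguensis*)
#' assembly, and `mean_depth * mosaic_fraction * copies / 2` plus the
#' cross-mapping floor for the paternal (*C. becei*) assembly (the paternal
#' karyotype is modeled with the same chromosome ids and lengths).
#' Multiplicative gamma noise with coefficient of variation
#' `sqrt(overdispersion)` emulates WGA coverage roughness; `exact = TRUE`
#' suppresses it.
#'
#' @inheritParams simulate_allele_depths
#' @return Data frame (`coverage_table`) with columns `species`
#'   (`"nouraguensis"`/`"becei"`), `chrom`, `start`, `end`, `depth`.
#' @export
simulate_coverage <- function(zygote, spec, model = read_model()) {
  ws <- spec$window_size
  rho <- model$overdispersion
  mat <- maternal_copy_number(zygote)
  pat <- zygote$paternal
  rows <- list()
  for (ch in spec$chromosomes$chrom) {
    L <- chrom_length(spec, ch)
    starts <- seq(0, L - 1, by = ws)
    ends <- pmin(starts + ws, L)
    n <- length(starts)
    noise <- function(n) {
      if (model$exact || rho == 0) rep(1, n)
      else stats::rgamma(n, shape = 1 / rho, rate = 1 / rho)
    }
    mu_m <- model$mean_depth * mat[[ch]] / 2
    rows[[length(rows) + 1]] <- data.frame(
      species = "nouraguensis", chrom = ch, start = starts, end = ends,
      depth = mu_m * noise(n), stringsAsFactors = FALSE)
    p_copies <- as.integer(ch %in% pat$retained)
    mu_p <- model$mean_depth *
      (pat$mosaic_fraction * p_copies / 2 + model$becei_floor)
    rows[[length(rows) + 1]] <- data.frame(
      species = "becei", chrom = ch, start = starts, end = ends,
      depth = mu_p * noise(n), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("coverage_table", "data.frame")
  res
}
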