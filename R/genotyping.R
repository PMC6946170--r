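#' SNP filter configuration for fixed-difference calling
#'
#' Thresholds used to select high-quality fixed differences between the two
#' maternal strains from a candidate SNP table: a minimum variant quality, a
#' fixed-difference requirement on the non-reference allele frequency in the
#' two strain controls (one below `max_minor_freq`, the other above
#' `min_major_freq`), per-control read-depth ranges guarding against
#' collapsed repeats and dropouts, and zero depth in the other-species
#' controls so no marker cross-maps onto the paternal genome.
#'
#' @param min_qual Minimum SNP quality score.
#' @param max_minor_freq Maximum non-reference frequency for the strain fixed
#'   for the reference allele.
#' @param min_major_freq Minimum non-reference frequency for the strain fixed
#'   for the alternative allele.
#' @param depth_range Length-2 numeric: allowed control read-depth range,
#'   applied to each strain control.
#' @param max_other_species_depth Maximum allowed depth in the other-species
#'   control samples.
#' @return An object of class `snp_filter_config`.
#' @export
snp_filter_config <- function(min_qual = 100, max_minor_freq = 0.05,
                              min_major_freq = 0.95, depth_range = c(5, 50),
                              max_other_species_depth = 0) {
  if (!(max_minor_freq >= 0 && max_minor_freq < min_major_freq &&
        min_major_freq <= 1))
    stop("need 0 <= max_minor_freq < min_major_freq <= 1")
  structure(list(min_qual = min_qual, max_minor_freq = max_minor_freq,
                 min_major_freq = min_major_freq, depth_range = depth_range,
                 max_other_species_depth = max_other_species_depth),
            class = "snp_filter_config")
}

#' Filter candidate SNPs to high-quality fixed differences
#'
#' Retains rows that pass all criteria of a [snp_filter_config()]:
#' quality, fixed opposite alleles in the two strain controls (in either
#' orientation), control depth in range, and no coverage in the other-species
#' control. The number of rows removed by each criterion (counted
#' independently) is attached as attribute `"removed"`.
#'
#' @param snps Data frame with columns `qual`, `freq_a`, `freq_b`
#'   (non-reference frequencies in the two strain controls), `depth_a`,
#'   `depth_b` (control depths), `other_species_depth`.
#' @param config A [snp_filter_config()].
#' @return The retained rows, with attribute `removed`.
#' @export
filter_snps <- function(snps, config = snp_filter_config()) {
  req <- c("qual", "freq_a", "freq_b", "depth_a", "depth_b",
           "other_species_depth")
  miss <- setdiff(req, names(snps))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  ok_qual <- snps$qual >= config$min_qual
  fixed_ab <- snps$freq_a < config$max_minor_freq &
    snps$freq_b > config$min_major_freq
  fixed_ba <- snps$freq_b < config$max_minor_freq &
    snps$freq_a > config$min_major_freq
  ok_fixed <- fixed_ab | fixed_ba
  dr <- config$depth_range
  ok_depth <- snps$depth_a >= dr[1] & snps$depth_a <= dr[2] &
    snps$depth_b >= dr[1] & snps$depth_b <= dr[2]
  ok_other <- snps$other_species_depth <= config$max_other_species_depth
  keep <- ok_qual & ok_fixed & ok_depth & ok_other
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(quality = sum(!ok_qual),
                            not_fixed = sum(!ok_fixed),
                            depth = sum(!ok_depth),
                            other_species = sum(!ok_other))
  out
}

#' Pooled allele frequencies in tiling windows
#'
#' Tiles each chromosome of the spec with `window_size` windows and pools
#' allele-depth counts across the SNPs of each window; the window frequency
#' is the pooled N count divided by the pooled total (not the mean of
#' per-SNP frequencies, so deep SNPs weigh more). Windows without reads are
#' flagged missing (`freq = NA`).
#'
#' @param depths An allele-depth table (see [simulate_allele_depths()] or
#'   [read_allele_depths()]).
#' @param spec A [genome_spec()].
#' @return Data frame with columns `chrom`, `start`, `end`, `depth_N`,
#'   `depth_J`, `n_snps`, `freq`.
#' @export
window_allele_freq <- function(depths, spec) {
  ws <- spec$window_size
  out <- list()
  for (ch in spec$chromosomes$chrom) {
    L <- chrom_length(spec, ch)
    starts <- seq(0, L - 1, by = ws)
    n_win <- length(starts)
    d <- depths[depths$chrom == ch, , drop = FALSE]
    dN <- numeric(n_win); dJ <- numeric(n_win); ns <- integer(n_win)
    if (nrow(d)) {
      w <- pmin(d$pos %/% ws + 1L, n_win)
      dN <- as.numeric(rowsum(d$depth_N, w, reorder = TRUE)[
        match(seq_len(n_win), sort(unique(w)))])
      dJ <- as.numeric(rowsum(d$depth_J, w, reorder = TRUE)[
        match(seq_len(n_win), sort(unique(w)))])
      cnt <- table(factor(w, levels = seq_len(n_win)))
      ns <- as.integer(cnt)
      dN[is.na(dN)] <- 0
      dJ[is.na(dJ)] <- 0
    }
    tot <- dN + dJ
    out[[ch]] <- data.frame(
      chrom = ch, start = starts, end = pmin(starts + ws, L),
      depth_N = dN, depth_J = dJ, n_snps = ns,
      freq = ifelse(tot > 0, dN / tot, NA_real_),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate backcross-contamination fraction from window frequencies
#'
#' Contaminating DNA from a known maternal haplotype shifts the whole
#' genome's allele frequencies towards that haplotype; in particular the
#' heterozygous mode of the window-frequency distribution moves off 0.5.
#' This locates the mode `m` of a kernel density estimate restricted to
#' `[0.2, 0.8]` and inverts the mixture: `c = (0.5 - m) / (0.5 - f_cont)`
#' with `f_cont = 1` for an N contaminant and 0 for J, clipped to
#' `[0, 0.5)`.
#'
#' @param windows A [window_allele_freq()] table.
#' @param contaminant_origin `"N"` or `"J"`.
#' @return Estimated contamination fraction (named `c_hat`), with attribute
#'   `het_mode`.
#' @export
estimate_contamination <- function(windows, contaminant_origin = c("J", "N")) {
  contaminant_origin <- match.arg(contaminant_origin)
  f <- windows$freq[!is.na(windows$freq)]
  if (length(f) < 50)
    stop("need at least 50 non-missing windows, got ", length(f))
  in_band <- f[f >= 0.2 & f <= 0.8]
  if (length(in_band) < 5) {
    warning("no heterozygous mode found in [0.2, 0.8]; returning c = 0")
    return(structure(c(c_hat = 0), het_mode = NA_real_))
  }
  d <- stats::density(f, n = 1024, from = 0, to = 1)
  sel <- d$x >= 0.2 & d$x <= 0.8
  m <- d$x[sel][which.max(d$y[sel])]
  f_cont <- if (contaminant_origin == "N") 1 else 0
  c_hat <- (0.5 - m) / (0.5 - f_cont)
  c_hat <- min(max(c_hat, 0), 0.5 - 1e-9)
  structure(c(c_hat = c_hat), het_mode = m)
}

# recursive CBS over a vector of window frequencies; returns sorted internal
# breakpoints (boundary b means "between elements b and b+1", 1-based)
cbs_breakpoints <- function(x, alpha, min_width, n_perm) {
  n <- length(x)
  if (n < 2 * min_width) return(integer(0))
  res <- cbs_split_test(x, min_width, n_perm, alpha)
  if (!res$significant) return(integer(0))
  bps <- c(if (res$i > 0) res$i, if (res$j < n) res$j)
  edges <- c(0L, as.integer(bps), n)
  out <- as.integer(bps)
  for (p in seq_len(length(edges) - 1)) {
    s <- edges[p]; e <- edges[p + 1]
    sub <- cbs_breakpoints(x[(s + 1):e], alpha, min_width, n_perm)
    out <- c(out, s + sub)
  }
  sort(unique(out))
}

merge_segments <- function(bps, x, merge_tol) {
  repeat {
    edges <- c(0L, bps, length(x))
    means <- vapply(seq_len(length(edges) - 1), function(k)
      mean(x[(edges[k] + 1):edges[k + 1]]), numeric(1))
    if (length(means) < 2) return(bps)
    diffs <- abs(diff(means))
    if (all(diffs >= merge_tol)) return(bps)
    drop <- which.min(diffs)
    bps <- bps[-drop]
  }
}

#' Segment windowed allele frequencies by circular binary segmentation
#'
#' Recursive change-point detection on the per-window allele-frequency
#' series of each chromosome: at every step the arc maximizing the
#' arc-vs-complement mean-shift t statistic is found, the split is accepted
#' if its permutation p-value is below `alpha`, and the resulting pieces are
#' segmented recursively. Adjacent segments whose means differ by less than
#' `merge_tol` are merged. Missing windows are excluded from the statistic
#' and assigned to the enclosing (preceding) segment afterwards. Results are
#' deterministic given `seed`.
#'
#' @param windows A [window_allele_freq()] table (one or more chromosomes).
#' @param alpha Permutation significance level for accepting a split.
#' @param min_width Minimum segment width in (non-missing) windows.
#' @param n_perm Number of permutations per split test.
#' @param merge_tol Minimum absolute mean difference between adjacent
#'   segments.
#' @param seed Optional integer seed controlling the permutation stream; the
#'   caller's RNG state is restored on exit.
#' @return Data frame with columns `chrom`, `start`, `end` (bp), `n_windows`
#'   (non-missing windows in the segment), `mean_freq`.
#' @export
segment_cbs <- function(windows, alpha = 0.01, min_width = 3, n_perm = 1000,
                        merge_tol = 0.05, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    nm <- which(!is.na(w$freq))
    if (length(nm) == 0) next
    x <- w$freq[nm]
    bps <- if (length(x) >= 2 * min_width)
      cbs_breakpoints(x, alpha, min_width, n_perm) else integer(0)
    bps <- merge_segments(bps, x, merge_tol)
    edges <- c(0L, bps, length(x))
    n_seg <- length(edges) - 1
    # segment k starts at its first non-missing window; gaps between
    # segments attach to the preceding segment
    seg_start_win <- vapply(seq_len(n_seg), function(k)
      if (k == 1) 1L else nm[edges[k] + 1], integer(1))
    seg_end_win <- c(seg_start_win[-1] - 1L, nrow(w))
    means <- vapply(seq_len(n_seg), function(k)
      mean(x[(edges[k] + 1):edges[k + 1]]), numeric(1))
    out[[length(out) + 1]] <- data.frame(
      chrom = ch,
      start = w$start[seg_start_win],
      end = w$end[seg_end_win],
      n_windows = diff(edges),
      mean_freq = means,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' State thresholds for segment calls
#'
#' @param het_band Length-2 numeric: corrected mean frequencies inside this
#'   closed interval are called heterozygous.
#' @param hom_n_min Minimum corrected mean for a homozygous-NIC59 call.
#' @param hom_j_max Maximum corrected mean for a homozygous-JU1825 call.
#' @return A list of thresholds.
#' @export
state_thresholds <- function(het_band = c(0.35, 0.65), hom_n_min = 0.85,
                             hom_j_max = 0.15) {
  list(het_band = het_band, hom_n_min = hom_n_min, hom_j_max = hom_j_max)
}

#' Call genotype states for segments
#'
#' Applies the contamination correction
#' `f_true = (f - c * f_cont) / (1 - c)` to each segment mean and assigns a
#' state: `HET` inside the heterozygous band, `HOM_N`/`HOM_J` beyond the
#' homozygous thresholds, `AMBIG` otherwise.
#'
#' @param segments A [segment_cbs()] table.
#' @param contamination Contamination fraction `c` (e.g. from
#'   [estimate_contamination()]).
#' @param contaminant_origin `"N"` or `"J"`.
#' @param thresholds A [state_thresholds()] list.
#' @return `segments` with added columns `corrected_freq` and `state`.
#' @export
call_segment_states <- function(segments, contamination = 0,
                                contaminant_origin = c("J", "N"),
                                thresholds = state_thresholds()) {
  contaminant_origin <- match.arg(contaminant_origin)
  f_cont <- if (contaminant_origin == "N") 1 else 0
  f <- (segments$mean_freq - contamination * f_cont) / (1 - contamination)
  f <- pmin(pmax(f, 0), 1)
  th <- thresholds
  state <- ifelse(f >= th$het_band[1] & f <= th$het_band[2], "HET",
           ifelse(f >= th$hom_n_min, "HOM_N",
           ifelse(f <= th$hom_j_max, "HOM_J", "AMBIG")))
  segments$corrected_freq <- f
  segments$state <- state
  segments
}

# save/restore the global RNG state (so seeded helpers do not disturb the
# caller's stream)
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
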