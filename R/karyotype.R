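#' Classify a chromosome into a chromatid-combination genotype class
#'
#' Maps the ordered state sequence of a chromosome's segments to the genotype
#' classes distinguishable by single-worm sequencing. Copy number overrides
#' the pattern: one copy is a hemizygous X, three copies a triploid
#' chromosome. Otherwise adjacent segments with equal states are merged,
#' terminal homozygous runs narrower than `min_terminal_windows` are absorbed
#' into their neighbor (a noise guard against single-window artifacts), and
#' the run pattern decides the class: all-heterozygous is `HOMOLOGS_3`, a
#' heterozygous body with a homozygous terminal run is
#' `HOMOLOGS_1`/`HOMOLOGS_2` (N/J terminal), a homozygous body with a
#' heterozygous terminal run is `SISTERS_1`/`SISTERS_2`, a single homozygous
#' state is `FULL_HOM_N`/`FULL_HOM_J`, a heterozygous body with ambiguous
#' ends (each within `terminal_fraction` of the length) is
#' `HOMOLOGS_AMBIGUOUS`, anything else `AMBIGUOUS`. Because the class is
#' defined by which chromatids were combined, not by where the crossover
#' fell, a two-run pattern is classified whatever the terminal run's length;
#' this keeps the classifier exactly consistent with the noise-free pairing
#' oracle [classify_pair_truth()].
#'
#' @param segments State-called segments of one chromosome (see
#'   [call_segment_states()]), tiling the chromosome in order.
#' @param copy_number Integer copy number of the chromosome (from
#'   [normalize_and_call_copy_number()]), default 2.
#' @param terminal_fraction Maximum fraction of the chromosome length an
#'   ambiguous end run may span in the `HOMOLOGS_AMBIGUOUS` rule.
#' @param min_terminal_windows Noise guard: minimum width (windows) of a
#'   terminal homozygous run.
#' @return A single class label.
#' @export
classify_chromosome <- function(segments, copy_number = 2,
                                terminal_fraction = 0.30,
                                min_terminal_windows = 2) {
  if (is.null(segments) || nrow(segments) == 0)
    stop("empty segment list")
  if (length(unique(segments$chrom)) != 1)
    stop("segments must come from a single chromosome")
  if (copy_number == 1) return("HEMIZYGOUS_X")
  if (copy_number == 3) return("TRIPLOID")
  if (copy_number == 0) return("AMBIGUOUS")
  segments <- segments[order(segments$start), , drop = FALSE]
  states <- segments$state
  lens <- segments$end - segments$start
  wins <- segments$n_windows
  # merge adjacent equal states
  grp <- cumsum(c(TRUE, states[-1] != states[-length(states)]))
  states <- tapply(states, grp, `[`, 1)
  lens <- as.numeric(tapply(lens, grp, sum))
  wins <- as.numeric(tapply(wins, grp, sum))
  # drop noise-scale terminal homozygous runs
  repeat {
    k <- length(states)
    if (k < 2) break
    drop <- NULL
    if (states[1] %in% c("HOM_N", "HOM_J") && wins[1] < min_terminal_windows)
      drop <- 1L
    else if (states[k] %in% c("HOM_N", "HOM_J") &&
             wins[k] < min_terminal_windows)
      drop <- k
    if (is.null(drop)) break
    keep <- setdiff(seq_len(k), drop)
    states <- states[keep]; lens <- lens[keep]; wins <- wins[keep]
    grp <- cumsum(c(TRUE, states[-1] != states[-length(states)]))
    lens <- as.numeric(tapply(lens, grp, sum))
    wins <- as.numeric(tapply(wins, grp, sum))
    states <- as.character(tapply(states, grp, `[`, 1))
  }
  classify_runs(as.character(states), lens, terminal_fraction)
}

#' Normalize window coverage and call per-chromosome copy number
#'
#' Computes a 10%-trimmed mean of window depths per (species, chromosome),
#' robust to WGA coverage jackpots, and normalizes every chromosome to the
#' *C. nouraguensis* chromosome I trimmed mean, which is set to two (the
#' maternal genome is diploid). Maternal chromosomes get the nearest integer
#' copy number in `{0, 1, 2, 3}`; paternal (becei) chromosomes get a mosaic
#' fraction estimate equal to their normalized coverage (a haploid set in
#' all cells gives 1), flagged `MOSAIC` when it falls in `(0.1, 0.9)`,
#' `ABSENT` below and `FULL` above.
#'
#' @param coverage A [simulate_coverage()]-style table (`species`, `chrom`,
#'   `start`, `end`, `depth`).
#' @param trim Trim fraction for the per-chromosome mean.
#' @return Data frame with columns `species`, `chrom`, `norm_cov`, `copy`
#'   (maternal only, else `NA`), `mosaic_f` (paternal only, else `NA`),
#'   `flag`.
#' @export
normalize_and_call_copy_number <- function(coverage, trim = 0.10) {
  key <- interaction(coverage$species, coverage$chrom, drop = TRUE)
  tm <- tapply(coverage$depth, key, mean, trim = trim)
  parts <- strsplit(names(tm), ".", fixed = TRUE)
  species <- vapply(parts, `[`, "", 1)
  chrom <- vapply(parts, function(p) paste(p[-1], collapse = "."), "")
  ref <- tm[species == "nouraguensis" & chrom == "I"]
  if (length(ref) != 1 || is.na(ref) || ref <= 0)
    stop("nouraguensis chromosome I coverage missing; cannot normalize")
  norm <- 2 * as.numeric(tm) / as.numeric(ref)
  maternal <- species == "nouraguensis"
  copy <- ifelse(maternal, pmin(pmax(round(norm), 0), 3), NA_real_)
  mosaic_f <- ifelse(maternal, NA_real_, pmin(pmax(norm, 0), 1))
  flag <- rep("", length(norm))
  flag[!maternal] <- ifelse(mosaic_f[!maternal] <= 0.1, "ABSENT",
                     ifelse(mosaic_f[!maternal] >= 0.9, "FULL", "MOSAIC"))
  out <- data.frame(species = species, chrom = chrom,
                    norm_cov = norm, copy = as.integer(copy),
                    mosaic_f = mosaic_f, flag = flag,
                    stringsAsFactors = FALSE)
  out <- out[order(out$species, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize an individual: genotype classes, ploidy and hybrid category
#'
#' Combines per-chromosome genotype classes, copy-number calls and the
#' genome-wide fraction of reads mapping to the paternal assembly into an
#' individual-level category: `MATERNAL_ONLY` (gynogenetically produced;
#' becei read fraction at the cross-mapping floor and no paternal
#' chromosome called present), `TRIPLOID_HYBRID` (complete paternal autosome
#' set in essentially all cells), `MOSAIC_HYBRID` (complete set in a
#' fraction of cells), otherwise `AMBIGUOUS`. Paternal X presence and the
#' maternal X copy number are reported separately.
#'
#' @param genotypes Data frame with columns `chrom`, `class` for the
#'   maternal chromosomes.
#' @param copy_calls A [normalize_and_call_copy_number()] table.
#' @param becei_fraction Fraction of all reads mapping to the paternal
#'   assembly.
#' @param maternal_only_max_fraction Threshold on `becei_fraction` for a
#'   `MATERNAL_ONLY` call.
#' @param spec A [genome_spec()] naming the autosomes and the X.
#' @return List of class `individual_summary`: `genotypes`, `category`,
#'   `becei_fraction`, `paternal_X_present`, `maternal_X_copies`,
#'   `paternal_autosome_f`.
#' @export
classify_individual <- function(genotypes, copy_calls, becei_fraction,
                                maternal_only_max_fraction = 0.01,
                                spec = genome_spec()) {
  autos <- autosome_ids(spec)
  if (!all(c(autos, spec$x_chrom) %in% genotypes$chrom))
    stop("genotypes must cover all chromosomes of the spec")
  pat <- copy_calls[copy_calls$species == "becei", , drop = FALSE]
  pat_auto <- pat[pat$chrom %in% autos, , drop = FALSE]
  pat_X <- pat[pat$chrom == spec$x_chrom, , drop = FALSE]
  mat_X <- copy_calls[copy_calls$species == "nouraguensis" &
                        copy_calls$chrom == spec$x_chrom, , drop = FALSE]
  f_auto <- pat_auto$mosaic_f
  x_present <- nrow(pat_X) > 0 && pat_X$mosaic_f[1] > 0.1
  category <- if (becei_fraction <= maternal_only_max_fraction &&
                  (nrow(pat_auto) == 0 || all(pat_auto$flag == "ABSENT"))) {
    "MATERNAL_ONLY"
  } else if (nrow(pat_auto) == length(autos) && all(f_auto >= 0.9)) {
    "TRIPLOID_HYBRID"
  } else if (nrow(pat_auto) == length(autos) &&
             all(f_auto > 0.1 & f_auto < 0.9)) {
    "MOSAIC_HYBRID"
  } else {
    "AMBIGUOUS"
  }
  structure(list(
    genotypes = genotypes,
    category = category,
    becei_fraction = becei_fraction,
    paternal_X_present = x_present,
    maternal_X_copies = if (nrow(mat_X)) mat_X$copy[1] else NA_integer_,
    paternal_autosome_f = if (nrow(pat_auto))
      stats::setNames(pat_auto$mosaic_f, pat_auto$chrom) else NULL
  ), class = "individual_summary")
}

#' @export
print.individual_summary <- function(x, ...) {
  cat("individual:", x$category,
      sprintf("(becei read fraction %.4f)", x$becei_fraction), "\n")
  cat("  paternal X:", if (x$paternal_X_present) "present" else "absent",
      " maternal X copies:", x$maternal_X_copies, "\n")
  for (i in seq_len(nrow(x$genotypes)))
    cat(sprintf("  %-4s %s\n", x$genotypes$chrom[i], x$genotypes$class[i]))
  invisible(x)
}

#' Fraction of reads mapping to the paternal assembly
#'
#' Length-weighted total depth on the becei assembly over the total on both
#' assemblies; the sequencing-based evidence used to separate maternal-only
#' from hybrid individuals.
#'
#' @param coverage A coverage table (`species`, `chrom`, `start`, `end`,
#'   `depth`).
#' @return A single fraction.
#' @export
becei_read_fraction <- function(coverage) {
  wlen <- coverage$end - coverage$start
  tot <- tapply(coverage$depth * wlen, coverage$species, sum)
  b <- if ("becei" %in% names(tot)) tot[["becei"]] else 0
  b / sum(tot)
}

#' Genotype all chromosomes of one individual from sequencing tables
#'
#' The per-individual genotyping pipeline: window allele frequencies,
#' optional contamination estimation, CBS segmentation, state calls,
#' copy-number normalization and per-chromosome classification, combined
#' into an [classify_individual()] summary.
#'
#' @param depths Allele-depth table.
#' @param coverage Coverage table for both assemblies.
#' @param spec A [genome_spec()].
#' @param model Optional [read_model()] whose `contaminant_origin` is used
#'   when `estimate_c = TRUE`.
#' @param estimate_c If `TRUE`, estimate the contamination fraction from the
#'   window frequencies; otherwise use `contamination`.
#' @param contamination Known contamination fraction.
#' @param alpha,min_width,n_perm,merge_tol,seed Passed to [segment_cbs()].
#' @param thresholds Passed to [call_segment_states()].
#' @return List: `windows`, `segments`, `copy_calls`, `summary` (an
#'   `individual_summary`), `contamination`.
#' @export
genotype_individual <- function(depths, coverage, spec,
                                model = read_model(),
                                estimate_c = FALSE, contamination = 0,
                                alpha = 0.01, min_width = 3, n_perm = 1000,
                                merge_tol = 0.05, seed = NULL,
                                thresholds = state_thresholds()) {
  windows <- window_allele_freq(depths, spec)
  if (estimate_c) {
    contamination <- unname(
      estimate_contamination(windows, model$contaminant_origin))
  }
  segs <- segment_cbs(windows, alpha = alpha, min_width = min_width,
                      n_perm = n_perm, merge_tol = merge_tol, seed = seed)
  segs <- call_segment_states(segs, contamination = contamination,
                              contaminant_origin = model$contaminant_origin,
                              thresholds = thresholds)
  copy_calls <- normalize_and_call_copy_number(coverage)
  classes <- vapply(spec$chromosomes$chrom, function(ch) {
    s <- segs[segs$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) return("AMBIGUOUS")
    cn <- copy_calls$copy[copy_calls$species == "nouraguensis" &
                            copy_calls$chrom == ch]
    classify_chromosome(s, copy_number = if (length(cn)) cn else 2)
  }, character(1))
  genotypes <- data.frame(chrom = spec$chromosomes$chrom,
                          class = unname(classes), stringsAsFactors = FALSE)
  summ <- classify_individual(genotypes, copy_calls,
                              becei_read_fraction(coverage), spec = spec)
  list(windows = windows, segments = segs, copy_calls = copy_calls,
       summary = summ, contamination = contamination)
}
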