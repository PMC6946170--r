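#' Genome specification for meiosis and read simulation
#'
#' Describes the maternal karyotype used throughout the package: chromosome
#' identities and lengths, which chromosome is the X, how much of each
#' chromosome end counts as an "arm" for crossover placement, the probability
#' that the single obligate crossover falls in the chromosome center rather
#' than an arm, the mean spacing of informative fixed-difference SNPs, and the
#' window size used for allele-frequency and coverage summaries.
#'
#' Coordinates are 0-based, half-open throughout the package. Defaults mirror
#' a typical *Caenorhabditis* karyotype: five autosomes plus one X, one
#' crossover per bivalent strongly biased towards the chromosome arms, one
#' informative SNP every ~217 bp and 50-kb analysis windows.
#'
#' @param lengths Named integer vector of chromosome lengths in bp. Names are
#'   chromosome ids.
#' @param x_chrom Id of the X chromosome; must name exactly one entry of
#'   `lengths`.
#' @param arm_fraction Fraction of each chromosome end treated as an arm,
#'   in (0, 0.5].
#' @param p_center_crossover Probability that the crossover falls in the
#'   central (non-arm) region, in \[0, 1\].
#' @param snp_spacing Mean distance in bp between informative SNPs.
#' @param window_size Analysis window size in bp.
#' @return An object of class `genome_spec`.
#' @examples
#' spec <- genome_spec()
#' spec$chromosomes
#' @export
genome_spec <- function(lengths = c(I = 15.1e6, II = 15.3e6, III = 13.8e6,
                                    IV = 17.5e6, V = 20.9e6, X = 17.7e6),
                        x_chrom = "X",
                        arm_fraction = 0.3,
                        p_center_crossover = 0.1,
                        snp_spacing = 217,
                        window_size = 50000L) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("'lengths' must be a named vector with unique chromosome ids")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (!x_chrom %in% names(lengths))
    stop("x_chrom '", x_chrom, "' is not a chromosome id")
  if (arm_fraction <= 0 || arm_fraction > 0.5)
    stop("arm_fraction must be in (0, 0.5]")
  if (p_center_crossover < 0 || p_center_crossover > 1)
    stop("p_center_crossover must be in [0, 1]")
  if (snp_spacing <= 0) stop("snp_spacing must be positive")
  if (window_size <= 0) stop("window_size must be positive")
  chroms <- data.frame(
    chrom = names(lengths),
    length = as.numeric(lengths),
    is_X = names(lengths) == x_chrom,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      chromosomes = chroms,
      n_autosomes = sum(!chroms$is_X),
      x_chrom = x_chrom,
      arm_fraction = arm_fraction,
      p_center_crossover = p_center_crossover,
      snp_spacing = snp_spacing,
      window_size = as.integer(window_size)
    ),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", nrow(x$chromosomes), "chromosomes (",
      x$n_autosomes, "autosomes + X =", x$x_chrom, ")\n")
  cat("  lengths:", paste0(x$chromosomes$chrom, "=",
                           formatC(x$chromosomes$length, format = "d"),
                           collapse = ", "), "\n")
  cat("  arm_fraction:", x$arm_fraction,
      " p_center_crossover:", x$p_center_crossover, "\n")
  cat("  snp_spacing:", x$snp_spacing,
      "bp  window_size:", x$window_size, "bp\n")
  invisible(x)
}

chrom_length <- function(spec, chrom) {
  i <- match(chrom, spec$chromosomes$chrom)
  if (is.na(i)) stop("unknown chromosome id: ", chrom)
  spec$chromosomes$length[i]
}

autosome_ids <- function(spec) {
  spec$chromosomes$chrom[!spec$chromosomes$is_X]
}
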