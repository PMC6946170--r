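#' @useDynLib meiomix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

MATERNAL_MODES <- c("CANONICAL", "CENTRAL_FUSION", "SISTER_FUSION",
                    "APOMIXIS", "ENDOREPLICATION", "RANDOM_TWO")

GENOTYPE_CLASSES <- c("SISTERS_1", "SISTERS_2", "HOMOLOGS_1", "HOMOLOGS_2",
                      "HOMOLOGS_3", "HOMOLOGS_AMBIGUOUS", "FULL_HOM_N",
                      "FULL_HOM_J", "HEMIZYGOUS_X", "TRIPLOID", "AMBIGUOUS")

# The five classes distinguishable by short-read genotyping of a chromatid pair
DISTINGUISHABLE_CLASSES <- c("SISTERS_1", "SISTERS_2", "HOMOLOGS_1",
                             "HOMOLOGS_2", "HOMOLOGS_3")

new_chromatid <- function(chrom, length, starts, origins) {
  stopifnot(length(starts) == length(origins), starts[1] == 0)
  data.frame(chrom = chrom, start = starts,
             end = c(starts[-1], length), origin = origins,
             stringsAsFactors = FALSE)
}

#' Haplotype origin of a chromatid at given positions
#'
#' @param chromatid A chromatid block table as produced by [make_bivalent()]
#'   (columns `chrom`, `start`, `end`, `origin`; 0-based half-open blocks).
#' @param pos Numeric vector of positions in bp.
#' @return Character vector of origins (`"N"`, `"J"` or `"B"`).
#' @export
origin_at <- function(chromatid, pos) {
  chromatid$origin[findInterval(pos, chromatid$start)]
}

#' Draw the position of the obligate crossover
#'
#' Each bivalent receives exactly one crossover. With probability
#' `1 - p_center_crossover` the position is uniform over the two arm regions
#' (`[0, a*L)` and `[(1-a)*L, L)` with `a = arm_fraction`), otherwise uniform
#' over the center, reflecting the strong arm bias of *Caenorhabditis*
#' recombination. Positions are integers in `[1, L-1]`.
#'
#' @param spec A [genome_spec()].
#' @param chrom Chromosome id.
#' @return Integer crossover position in bp.
#' @export
draw_crossover_position <- function(spec, chrom) {
  L <- chrom_length(spec, chrom)
  a <- spec$arm_fraction
  in_center <- stats::runif(1) < spec$p_center_crossover
  if (in_center && a < 0.5) {
    pos <- stats::runif(1, a * L, (1 - a) * L)
  } else {
    # uniform over the two arms: draw one arm-length offset, mirror half of it
    u <- stats::runif(1, 0, 2 * a * L)
    pos <- if (u < a * L) u else L - (u - a * L)
  }
  pos <- floor(pos)
  min(max(pos, 1), L - 1)
}

#' Form a bivalent: four chromatids with one reciprocal crossover
#'
#' Builds the four chromatids of one bivalent for a NIC59/JU1825 ("N"/"J")
#' heterozygous mother: the non-recombinant N and J chromatids (`N1`, `J2`)
#' and the reciprocal recombinants (`N2`, `J1`) exchanged at a single drawn
#' crossover position. Dyads (the chromatid pairs that co-segregate at
#' anaphase I) pair each non-recombinant with the recombinant that shares its
#' haplotype on the long side of the crossover, so that sister-pair
#' inheritance yields homozygosity over the chromosome center.
#'
#' @inheritParams draw_crossover_position
#' @return A list of class `bivalent` with elements `chrom`, `length`,
#'   `crossover` (bp), `chromatids` (named list `N1`, `N2`, `J1`, `J2`) and
#'   `dyads` (list of two character vectors of chromatid names).
#' @export
make_bivalent <- function(spec, chrom) {
  L <- chrom_length(spec, chrom)
  x <- draw_crossover_position(spec, chrom)
  chromatids <- list(
    N1 = new_chromatid(chrom, L, 0, "N"),
    N2 = new_chromatid(chrom, L, c(0, x), c("N", "J")),
    J1 = new_chromatid(chrom, L, c(0, x), c("J", "N")),
    J2 = new_chromatid(chrom, L, 0, "J")
  )
  # long side of the crossover decides dyad membership
  dyads <- if (x >= L / 2) {
    list(c("N1", "N2"), c("J2", "J1"))
  } else {
    list(c("N1", "J1"), c("J2", "N2"))
  }
  structure(list(chrom = chrom, length = L, crossover = x,
                 chromatids = chromatids, dyads = dyads),
            class = "bivalent")
}

#' Number of polar bodies for a maternal inheritance mode
#'
#' Canonical meiosis extrudes two polar bodies. When meiosis I fails and both
#' half-bivalents stay in the oocyte (central fusion / random two-chromatid
#' retention), the two half-bivalents either share one meiosis II spindle
#' (one polar body, probability `p_shared_spindle`) or segregate on separate
#' spindles (two polar bodies). Sister fusion (failed meiosis II) yields one;
#' an apomictic (mitotic) egg yields none; endoreplication follows a
#' canonical meiosis and yields two.
#'
#' @param mode A maternal inheritance mode (see [select_maternal_chromatids()]).
#' @param p_shared_spindle Probability that MI-failure products share one
#'   MII spindle.
#' @return Integer polar-body count in `{0, 1, 2}`.
#' @export
draw_polar_bodies <- function(mode, p_shared_spindle = 0.5) {
  mode <- match.arg(mode, MATERNAL_MODES)
  switch(mode,
    CANONICAL = 2L,
    ENDOREPLICATION = 2L,
    APOMIXIS = 0L,
    SISTER_FUSION = 1L,
    CENTRAL_FUSION = ,
    RANDOM_TWO = if (stats::runif(1) < p_shared_spindle) 1L else 2L
  )
}

#' Select the maternal chromatids retained by the oocyte
#'
#' Applies one of the competing inheritance modes to a bivalent:
#' \describe{
#'   \item{CANONICAL}{one random chromatid of the four (normal meiosis).}
#'   \item{CENTRAL_FUSION}{two chromatids from *different* dyads, uniform over
#'     the four such pairs; this is the automictic mode that retains central
#'     heterozygosity.}
#'   \item{SISTER_FUSION}{one whole dyad (uniform over the two).}
#'   \item{APOMIXIS}{the two non-recombinant chromatids `N1` and `J2`
#'     (a clone of the mother).}
#'   \item{ENDOREPLICATION}{two identical copies of one random chromatid.}
#'   \item{RANDOM_TWO}{any unordered pair of the four, uniform over the six.}
#' }
#'
#' @param bivalent A [make_bivalent()] result.
#' @param mode One of the modes above.
#' @param p_shared_spindle Passed to [draw_polar_bodies()].
#' @return List with `chromatids` (list of retained chromatid block tables),
#'   `names` (their names within the bivalent), and `polar_bodies`.
#' @export
select_maternal_chromatids <- function(bivalent, mode,
                                       p_shared_spindle = 0.5) {
  mode <- match.arg(mode, MATERNAL_MODES)
  cts <- bivalent$chromatids
  all4 <- names(cts)
  pick <- switch(mode,
    CANONICAL = sample(all4, 1),
    CENTRAL_FUSION = c(sample(bivalent$dyads[[1]], 1),
                       sample(bivalent$dyads[[2]], 1)),
    SISTER_FUSION = bivalent$dyads[[sample.int(2, 1)]],
    APOMIXIS = c("N1", "J2"),
    ENDOREPLICATION = rep(sample(all4, 1), 2),
    RANDOM_TWO = {
      pairs <- utils::combn(all4, 2)
      pairs[, sample.int(ncol(pairs), 1)]
    }
  )
  list(chromatids = unname(cts[pick]), names = pick,
       polar_bodies = draw_polar_bodies(mode, p_shared_spindle))
}

# Collapse a pair of chromatids into runs of genotype states
# (HOM_N / HET / HOM_J) along the chromosome.
pair_state_runs <- function(a, b) {
  stopifnot(a$chrom[1] == b$chrom[1])
  bounds <- sort(unique(c(a$start, b$start)))
  oa <- origin_at(a, bounds)
  ob <- origin_at(b, bounds)
  state <- ifelse(oa == ob, ifelse(oa == "N", "HOM_N", "HOM_J"), "HET")
  keep <- c(TRUE, state[-1] != state[-length(state)])
  runs <- data.frame(state = state[keep], start = bounds[keep],
                     stringsAsFactors = FALSE)
  runs$end <- c(runs$start[-1], max(a$end))
  runs$len <- runs$end - runs$start
  runs
}

# Classify a sequence of state runs into a chromatid-combination genotype.
# Rules shared by the truth classifier and the data-driven classifier so the
# two agree exactly on noise-free input.
classify_runs <- function(states, lens, terminal_fraction = 0.30) {
  k <- length(states)
  total <- sum(lens)
  if (any(states == "AMBIG")) {
    inner <- states[states != "AMBIG"]
    ambig_ends <- (states[1] == "AMBIG" && lens[1] <= terminal_fraction * total) ||
      (states[k] == "AMBIG" && lens[k] <= terminal_fraction * total)
    core_het <- length(inner) > 0 && all(inner == "HET")
    if (core_het && ambig_ends && all(which(states == "AMBIG") %in% c(1L, k)))
      return("HOMOLOGS_AMBIGUOUS")
    return("AMBIGUOUS")
  }
  if (k == 1) {
    return(switch(states, HET = "HOMOLOGS_3", HOM_N = "FULL_HOM_N",
                  HOM_J = "FULL_HOM_J", "AMBIGUOUS"))
  }
  if (k == 2) {
    term <- if (lens[1] < lens[2]) 1L else 2L
    body <- 3L - term
    bs <- states[body]; ts <- states[term]
    if (bs == "HET" && ts == "HOM_N") return("HOMOLOGS_1")
    if (bs == "HET" && ts == "HOM_J") return("HOMOLOGS_2")
    if (bs == "HOM_N" && ts == "HET") return("SISTERS_1")
    if (bs == "HOM_J" && ts == "HET") return("SISTERS_2")
    # fully homozygous but strain switches at the crossover (doubled
    # recombinant chromatid): label by the central haplotype
    if (bs == "HOM_N" && ts == "HOM_J") return("FULL_HOM_N")
    if (bs == "HOM_J" && ts == "HOM_N") return("FULL_HOM_J")
    return("AMBIGUOUS")
  }
  "AMBIGUOUS"
}

#' Noise-free genotype class of a maternal chromatid pair
#'
#' The enumeration oracle for the data-driven classifier: given the two
#' retained chromatids, computes the exact genotype state along the
#' chromosome and maps it to one of the chromatid-combination classes.
#' A sister (dyad) pair gives homozygosity over the chromosome center and
#' heterozygosity beyond the crossover (`SISTERS_1`/`SISTERS_2`); a homolog
#' pair gives central heterozygosity with a homozygous terminal segment
#' (`HOMOLOGS_1`/`HOMOLOGS_2`) or heterozygosity throughout (`HOMOLOGS_3`);
#' two identical chromatids give `FULL_HOM_N`/`FULL_HOM_J`.
#'
#' @param pair List of two chromatid block tables from the same chromosome.
#' @return A single class label.
#' @export
classify_pair_truth <- function(pair) {
  stopifnot(length(pair) == 2)
  if (pair[[1]]$chrom[1] != pair[[2]]$chrom[1])
    stop("chromatids come from different chromosomes")
  runs <- pair_state_runs(pair[[1]], pair[[2]])
  classify_runs(runs$state, runs$len)
}

#' Paternal genome fate descriptor
#'
#' @param type One of `"FULL"` (complete haploid paternal set in all cells),
#'   `"NONE"` (clean paternal genome loss), `"MOSAIC"` (complete set in a
#'   fraction `fraction` of cells), `"PARTIAL"` (independent per-chromosome
#'   retention with probability `p_retain`), `"UV_DESTROYED"` (sperm genome
#'   inactivated; no paternal DNA inherited).
#' @param fraction Mosaic fraction of cells carrying paternal DNA, strictly
#'   in (0, 1); required for `"MOSAIC"`.
#' @param p_retain Per-chromosome retention probability for `"PARTIAL"`.
#' @param include_X `NA` to draw the sperm X with probability 0.5 (fathers are
#'   X0 so half of sperm carry the X), or `TRUE`/`FALSE` to fix it.
#' @return An object of class `paternal_fate`.
#' @export
paternal_fate <- function(type = c("NONE", "FULL", "MOSAIC", "PARTIAL",
                                   "UV_DESTROYED"),
                          fraction = NULL, p_retain = 0.5, include_X = NA) {
  type <- match.arg(type)
  if (type == "MOSAIC") {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1)
      stop("MOSAIC requires a fraction strictly in (0, 1)")
  } else {
    fraction <- NULL
  }
  structure(list(type = type, fraction = fraction, p_retain = p_retain,
                 include_X = include_X),
            class = "paternal_fate")
}

#' Simulate one zygote under a maternal mode and paternal fate
#'
#' For each chromosome independently, forms a bivalent, applies the maternal
#' chromatid-selection mode, and optionally missegregates the X (with
#' probability `p_X_loss` only one X chromatid is retained, producing males).
#' The paternal complement is attached according to the fate descriptor, the
#' polar-body count is drawn once for the zygote, and the developmental fate
#' is assigned by [zygote_fate()].
#'
#' @inheritParams draw_crossover_position
#' @param mode Maternal inheritance mode; see [select_maternal_chromatids()].
#' @param paternal A [paternal_fate()] descriptor.
#' @param p_X_loss Probability that the oocyte retains only one X chromatid.
#' @param p_shared_spindle Passed to [draw_polar_bodies()].
#' @return An object of class `zygote`: `maternal` (per-chromosome list of
#'   chromatid block tables), `paternal` (retained chromosome set, mosaic
#'   fraction, `sperm_X` = whether the sperm carried the X, `has_X` =
#'   whether it was retained), `polar_bodies`, `mode`, `fate` and
#'   `fate_reason`.
#' @export
simulate_zygote <- function(spec, mode, paternal = paternal_fate("NONE"),
                            p_X_loss = 0, p_shared_spindle = 0.5) {
  mode <- match.arg(mode, MATERNAL_MODES)
  stopifnot(inherits(paternal, "paternal_fate"))
  chroms <- spec$chromosomes$chrom
  maternal <- vector("list", length(chroms))
  names(maternal) <- chroms
  for (ch in chroms) {
    biv <- make_bivalent(spec, ch)
    sel <- select_maternal_chromatids(biv, mode, p_shared_spindle)
    kept <- sel$chromatids
    if (ch == spec$x_chrom && length(kept) == 2 &&
        stats::runif(1) < p_X_loss) {
      kept <- kept[sample.int(2, 1)]
    }
    maternal[[ch]] <- kept
  }

  has_X <- if (is.na(paternal$include_X)) stats::runif(1) < 0.5
           else isTRUE(paternal$include_X)
  autos <- autosome_ids(spec)
  retained <- character(0)
  frac <- 0
  if (paternal$type %in% c("FULL", "MOSAIC")) {
    retained <- c(autos, if (has_X) spec$x_chrom)
    frac <- if (paternal$type == "FULL") 1 else paternal$fraction
  } else if (paternal$type == "PARTIAL") {
    cand <- c(autos, if (has_X) spec$x_chrom)
    retained <- cand[stats::runif(length(cand)) < paternal$p_retain]
    frac <- if (length(retained)) 1 else 0
  }

  zy <- structure(list(
    spec = spec,
    mode = mode,
    maternal = maternal,
    paternal = list(type = paternal$type, retained = retained,
                    mosaic_fraction = frac,
                    sperm_X = has_X && paternal$type != "UV_DESTROYED",
                    has_X = spec$x_chrom %in% retained),
    polar_bodies = draw_polar_bodies(mode, p_shared_spindle)
  ), class = "zygote")
  ft <- zygote_fate(zy)
  zy$fate <- ft$fate
  zy$fate_reason <- ft$reason
  zy
}

#' Maternal copy number per chromosome of a zygote
#' @param zygote A [simulate_zygote()] result.
#' @return Named integer vector of retained maternal chromatid counts.
#' @export
maternal_copy_number <- function(zygote) {
  vapply(zygote$maternal, length, integer(1))
}

#' Developmental fate of a zygote
#'
#' Encodes the viability model of the cross: any paternal X is toxic and
#' kills the embryo; a haploid maternal complement is lethal; maternal
#' autosomal aneuploidy is lethal unless a complete paternal set restores a
#' uniform karyotype; partial (aneuploid) paternal retention is lethal.
#' A diploid maternal genome with no paternal DNA develops into a fertile
#' adult (gynogenetic reproduction); a diploid maternal genome plus a
#' complete paternal autosome set (in all cells or a fraction of cells) and
#' no paternal X develops into a sterile triploid or diploid-triploid
#' mosaic hybrid.
#'
#' @param zygote A [simulate_zygote()] result.
#' @return List with `fate` (one of `"FERTILE_VIABLE"`, `"STERILE_VIABLE"`,
#'   `"DEAD"`) and `reason`.
#' @export
zygote_fate <- function(zygote) {
  spec <- zygote$spec
  autos <- autosome_ids(spec)
  mat <- maternal_copy_number(zygote)
  pat <- zygote$paternal
  complete_pat <- length(pat$retained) > 0 && all(autos %in% pat$retained)
  empty_pat <- length(pat$retained) == 0

  if (pat$has_X)
    return(list(fate = "DEAD", reason = "paternal X chromosome is toxic"))
  if (!empty_pat && !complete_pat)
    return(list(fate = "DEAD",
                reason = "partial paternal retention causes aneuploidy"))
  if (all(mat[autos] == 1))
    return(list(fate = "DEAD", reason = "haploid maternal complement"))
  if (!all(mat[autos] == 2))
    return(list(fate = "DEAD", reason = "maternal autosomal aneuploidy"))
  if (empty_pat)
    return(list(fate = "FERTILE_VIABLE",
                reason = "diploid maternal genome, no paternal DNA"))
  list(fate = "STERILE_VIABLE",
       reason = sprintf(
         "diploid maternal genome plus complete paternal autosomes (f = %g)",
         pat$mosaic_fraction))
}

#' @export
print.zygote <- function(x, ...) {
  cat("zygote:", x$mode, "/", x$paternal$type,
      if (x$paternal$type == "MOSAIC")
        sprintf("(f = %g)", x$paternal$mosaic_fraction), "\n")
  cat("  maternal copies:",
      paste0(names(x$maternal), "=", maternal_copy_number(x),
             collapse = " "), "\n")
  cat("  paternal retained:",
      if (length(x$paternal$retained))
        paste(x$paternal$retained, collapse = " ") else "none", "\n")
  cat("  polar bodies:", x$polar_bodies, " fate:", x$fate,
      "(", x$fate_reason, ")\n")
  invisible(x)
}

#' Predicted number of DAPI-staining bodies in a mature oocyte
#'
#' With one obligate crossover per homologous chromosome set, two homologs
#' always pair as a bivalent; any additional copies remain univalents. A
#' diploid with six chromosome types therefore shows 6 DAPI-staining bodies,
#' a triploid 6 bivalents + 6 univalents = 12, and a haploid 6 univalents.
#'
#' @param ploidy Copies of each chromosome type (positive integer).
#' @param n_chrom_types Number of chromosome types (default 6).
#' @return Integer body count.
#' @examples
#' count_dapi_bodies(2, 6)  # 6
#' count_dapi_bodies(3, 6)  # 12
#' @export
count_dapi_bodies <- function(ploidy, n_chrom_types = 6L) {
  if (length(ploidy) != 1 || is.na(ploidy) || ploidy < 1 ||
      ploidy != round(ploidy))
    stop("ploidy must be a positive integer")
  n <- as.integer(n_chrom_types)
  if (ploidy == 1) return(n)
  n + n * (as.integer(ploidy) - 2L)
}
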