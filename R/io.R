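#' Write an allele-depth table as TSV
#'
#' @param depths Allele-depth table (`chrom`, `pos`, `depth_N`, `depth_J`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_depths_tsv <- function(depths, path) {
  utils::write.table(depths[, c("chrom", "pos", "depth_N", "depth_J")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an allele-depth table as a minimal VCF with an AD field
#'
#' Encodes each SNP as a biallelic site whose REF is the NIC59 ("N") allele
#' and ALT the JU1825 ("J") allele, with per-sample allelic depths in the
#' `AD` FORMAT field. Positions are converted to the 1-based VCF convention.
#'
#' @param depths Allele-depth table.
#' @param path Output path (plain-text `.vcf`).
#' @param sample Sample name for the single genotype column.
#' @return `path`, invisibly.
#' @export
write_allele_depths_vcf <- function(depths, path, sample = "worm1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=meiomix",
    "##INFO=<ID=.,Number=0,Type=Flag,Description=\"none\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths (N allele, J allele)\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")), con)
  gt <- ifelse(depths$depth_N > 0 & depths$depth_J > 0, "0/1",
        ifelse(depths$depth_N > 0, "0/0",
        ifelse(depths$depth_J > 0, "1/1", "./.")))
  writeLines(paste(depths$chrom, depths$pos + 1L, ".", "A", "T", ".",
                   "PASS", ".", "GT:AD",
                   paste0(gt, ":", depths$depth_N, ",", depths$depth_J),
                   sep = "\t"), con)
  invisible(path)
}

#' Read an allele-depth table from TSV or VCF
#'
#' TSV input must carry the columns written by [write_allele_depths_tsv()].
#' VCF input is validated line-by-line (malformed lines are reported with
#' their line number) and parsed with the vcfR package; allelic depths are
#' taken from the `AD` FORMAT field, REF count first.
#'
#' @param path Input path ending in `.tsv`/`.txt` or `.vcf`.
#' @return An allele-depth table (`chrom`, `pos`, `depth_N`, `depth_J`),
#'   positions 0-based.
#' @export
read_allele_depths <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    body <- which(!startsWith(lines, "#"))
    nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length,
                     integer(1))
    bad <- body[nfield < 10]
    if (length(bad))
      stop("malformed VCF record at line ", bad[1], ": expected >= 10 fields, found ",
           nfield[match(bad[1], body)])
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(v, element = "AD")[, 1]
    parts <- strsplit(ad, ",", fixed = TRUE)
    out <- data.frame(
      chrom = unname(v@fix[, "CHROM"]),
      pos = as.integer(v@fix[, "POS"]) - 1L,
      depth_N = as.integer(vapply(parts, `[`, "", 1)),
      depth_J = as.integer(vapply(parts, `[`, "", 2)),
      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    req <- c("chrom", "pos", "depth_N", "depth_J")
    miss <- setdiff(req, names(out))
    if (length(miss))
      stop("allele-depth TSV is missing column(s): ",
           paste(miss, collapse = ", "))
  }
  class(out) <- c("allele_depth_table", "data.frame")
  out
}

#' Write a coverage table as BED4-per-species
#'
#' One BED-like row per window: chrom, start, end, mean depth, species.
#'
#' @param coverage Coverage table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_bed <- function(coverage, path) {
  utils::write.table(
    coverage[, c("chrom", "start", "end", "depth", "species")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a coverage table written by [write_coverage_bed()]
#' @param path Input path.
#' @return Coverage table.
#' @export
read_coverage_bed <- function(path) {
  out <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "depth",
                                         "species"))
  out <- out[, c("species", "chrom", "start", "end", "depth")]
  class(out) <- c("coverage_table", "data.frame")
  out
}

#' Write state-called segments as BED
#'
#' Columns: chrom, start, end, mean frequency, state.
#'
#' @param segments A [call_segment_states()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  utils::write.table(
    data.frame(segments$chrom, segments$start, segments$end,
               signif(segments$mean_freq, 6), segments$state),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the zygote truth as a haplotype track plus JSON sidecar
#'
#' The BED-like track lists, for every maximal interval with constant
#' chromatid origins, the origin of each retained maternal copy
#' (`copy1_origin`, `copy2_origin`, optionally `copy3_origin`). The JSON
#' sidecar records mode, fate, polar bodies, paternal retention and mosaic
#' fraction.
#'
#' @param zygote A [simulate_zygote()] result.
#' @param bed_path Path for the haplotype track.
#' @param json_path Path for the JSON sidecar.
#' @param extra Named list merged into the sidecar (e.g. seed).
#' @return `bed_path`, invisibly.
#' @export
write_zygote_truth <- function(zygote, bed_path, json_path = NULL,
                               extra = list()) {
  rows <- list()
  for (ch in names(zygote$maternal)) {
    cts <- zygote$maternal[[ch]]
    if (length(cts) == 0) next
    bounds <- sort(unique(unlist(lapply(cts, `[[`, "start"))))
    ends <- c(bounds[-1], max(cts[[1]]$end))
    origins <- vapply(cts, function(ct) origin_at(ct, bounds),
                      character(length(bounds)))
    origins <- matrix(origins, nrow = length(bounds))
    df <- data.frame(chrom = ch, start = bounds, end = ends,
                     stringsAsFactors = FALSE)
    for (k in seq_len(ncol(origins)))
      df[[paste0("copy", k, "_origin")]] <- origins[, k]
    rows[[ch]] <- df
  }
  ncopy_max <- max(vapply(rows, ncol, integer(1))) - 3L
  rows <- lapply(rows, function(df) {
    for (k in seq_len(ncopy_max)) {
      col <- paste0("copy", k, "_origin")
      if (is.null(df[[col]])) df[[col]] <- "."
    }
    df
  })
  utils::write.table(do.call(rbind, rows), bed_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(json_path)) {
    side <- c(list(mode = zygote$mode,
                   fate = zygote$fate,
                   fate_reason = zygote$fate_reason,
                   polar_bodies = zygote$polar_bodies,
                   paternal_type = zygote$paternal$type,
                   paternal_retained = zygote$paternal$retained,
                   mosaic_fraction = zygote$paternal$mosaic_fraction,
                   paternal_X = zygote$paternal$has_X),
              extra)
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(bed_path)
}

#' Read a class-count table
#'
#' A two-column TSV (`class`, `count`) or a wide one-row table with one
#' column per class.
#'
#' @param path Input path.
#' @return Named integer vector of counts.
#' @export
read_class_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (all(c("class", "count") %in% names(tab)))
    return(stats::setNames(as.integer(tab$count), tab$class))
  if (nrow(tab) == 1)
    return(stats::setNames(as.integer(unlist(tab[1, ])), names(tab)))
  stop("class-count file needs columns 'class' and 'count', or one row of ",
       "per-class columns")
}
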