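#' Run configuration for the simulate/genotype/infer pipeline
#'
#' Bundles every tunable of a reproducible run: the root seed (all stage
#' randomness is derived from it through fixed per-stage substreams), the
#' genome spec, the mixture of maternal inheritance modes and paternal
#' fates individuals are drawn from, the read model, the genotyping
#' parameters and the inference models.
#'
#' @param seed Root integer seed.
#' @param n_individuals Number of individuals to simulate.
#' @param spec A [genome_spec()].
#' @param mode_mix Named probability vector over maternal modes.
#' @param fate_mix Named probability vector over paternal fate types;
#'   `MOSAIC` fates draw their cell fraction uniformly from
#'   `mosaic_fraction_range`.
#' @param mosaic_fraction_range Range of mosaic cell fractions.
#' @param p_X_loss,p_shared_spindle Passed to [simulate_zygote()].
#' @param read Read-model parameters, a [read_model()].
#' @param alpha,min_width,n_perm,merge_tol Passed to [segment_cbs()].
#' @param thresholds Passed to [call_segment_states()].
#' @param models Inheritance models compared by [cmd_infer()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_individuals = 4L, spec = genome_spec(),
                       mode_mix = c(CENTRAL_FUSION = 1),
                       fate_mix = c(NONE = 0.5, FULL = 0.25, MOSAIC = 0.25),
                       mosaic_fraction_range = c(0.2, 0.8),
                       p_X_loss = 0, p_shared_spindle = 0.5,
                       read = read_model(),
                       alpha = 0.01, min_width = 3, n_perm = 1000,
                       merge_tol = 0.05,
                       thresholds = state_thresholds(),
                       models = c("RANDOM_TWO", "HOMOLOG_ONLY",
                                  "SISTER_ONLY")) {
  stopifnot(abs(sum(mode_mix) - 1) < 1e-8, abs(sum(fate_mix) - 1) < 1e-8)
  if (!all(names(mode_mix) %in% MATERNAL_MODES))
    stop("unknown maternal mode in mode_mix")
  if (!all(names(fate_mix) %in% c("NONE", "FULL", "MOSAIC", "PARTIAL",
                                  "UV_DESTROYED")))
    stop("unknown paternal fate in fate_mix")
  cfg <- list(seed = as.integer(seed), n_individuals = as.integer(n_individuals),
              spec = spec, mode_mix = mode_mix, fate_mix = fate_mix,
              mosaic_fraction_range = mosaic_fraction_range,
              p_X_loss = p_X_loss, p_shared_spindle = p_shared_spindle,
              read = read, alpha = alpha, min_width = min_width,
              n_perm = n_perm, merge_tol = merge_tol,
              thresholds = thresholds, models = models)
  class(cfg) <- "run_config"
  cfg
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

config_json <- function(config) {
  jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE, digits = NA)
}

#' Short FNV-1a hash of a run configuration
#'
#' Stamped into every output file of a run so that outputs produced under
#' different configurations cannot be mixed silently.
#'
#' @param config A [run_config()].
#' @return An 8-hex-digit string.
#' @export
config_hash <- function(config) {
  bytes <- utf8ToInt(as.character(config_json(config)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor on the low 16 bits (b < 2^8), then a 32-bit modular multiply done
    # in 16-bit halves so every intermediate stays exact in double precision
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    hi <- h %/% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stage_seed <- function(config, stage, index = 0L) {
  offs <- c(simulate = 100000L, reads = 200000L, genotype = 300000L,
            infer = 400000L)
  (config$seed * 7L + offs[[stage]] + as.integer(index)) %% .Machine$integer.max
}

draw_from_mix <- function(mix) {
  names(mix)[sample.int(length(mix), 1, prob = mix)]
}

#' Simulate a cohort of individuals and write all observables
#'
#' For each individual: draws a maternal mode and paternal fate from the
#' configured mixtures, simulates the zygote, and writes the truth haplotype
#' track (+ JSON sidecar), the per-SNP allele depths (TSV and, if `vcf`,
#' VCF) and the per-window coverage BED. A run manifest with the
#' configuration and its hash is written as `manifest.json`. Identical
#' seeds give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @param vcf Also write allele depths as VCF.
#' @return The manifest, invisibly.
#' @export
cmd_simulate <- function(config, out_dir, vcf = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("output path not writable: ", out_dir)
  hash <- config_hash(config)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  individuals <- list()
  n <- config$n_individuals
  for (i in seq_len(n)) {
    set.seed(stage_seed(config, "simulate", i))
    mode <- draw_from_mix(config$mode_mix)
    fate_type <- draw_from_mix(config$fate_mix)
    fate <- if (fate_type == "MOSAIC") {
      paternal_fate("MOSAIC",
                    fraction = stats::runif(1,
                                            config$mosaic_fraction_range[1],
                                            config$mosaic_fraction_range[2]))
    } else paternal_fate(fate_type)
    zy <- simulate_zygote(config$spec, mode, fate,
                          p_X_loss = config$p_X_loss,
                          p_shared_spindle = config$p_shared_spindle)
    id <- sprintf("ind_%03d", i)
    set.seed(stage_seed(config, "reads", i))
    depths <- simulate_allele_depths(zy, config$spec, config$read)
    coverage <- simulate_coverage(zy, config$spec, config$read)
    write_zygote_truth(zy, file.path(out_dir, paste0(id, "_truth.bed")),
                       file.path(out_dir, paste0(id, "_truth.json")),
                       extra = list(id = id, seed = config$seed,
                                    config_hash = hash))
    write_allele_depths_tsv(depths,
                            file.path(out_dir, paste0(id, "_depths.tsv")))
    if (vcf)
      write_allele_depths_vcf(depths,
                              file.path(out_dir, paste0(id, "_depths.vcf")),
                              sample = id)
    write_coverage_bed(coverage,
                       file.path(out_dir, paste0(id, "_coverage.bed")))
    individuals[[i]] <- list(id = id, mode = mode,
                             paternal_type = fate_type, fate = zy$fate,
                             polar_bodies = zy$polar_bodies)
  }
  manifest <- list(config_hash = hash, seed = config$seed,
                   n_individuals = n, individuals = individuals,
                   config = jsonlite::fromJSON(config_json(config),
                                               simplifyVector = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Genotype one simulated or real individual from its files
#'
#' Reads allele depths (TSV or VCF) and the two-species coverage BED,
#' runs the genotyping pipeline (windowed frequencies, optional
#' contamination estimate, CBS, state calls, copy number, classification)
#' and writes the window table, segment BED and a JSON summary, each
#' stamped with the configuration hash.
#'
#' @param depths_path Allele-depth TSV/VCF.
#' @param coverage_path Coverage BED.
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param id Output file prefix.
#' @param estimate_c Estimate contamination from the data.
#' @return The [genotype_individual()] result, invisibly.
#' @export
cmd_genotype <- function(depths_path, coverage_path, config, out_dir,
                         id = "sample", estimate_c = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # refuse to mix files produced under a different configuration
  manifest_path <- file.path(dirname(depths_path), "manifest.json")
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path)
    if (!is.null(man$config_hash) &&
        !identical(man$config_hash, config_hash(config)))
      stop("config hash mismatch: inputs were simulated under ",
           man$config_hash, " but this run is ", config_hash(config))
  }
  depths <- read_allele_depths(depths_path)
  coverage <- read_coverage_bed(coverage_path)
  res <- genotype_individual(
    depths, coverage, config$spec, model = config$read,
    estimate_c = estimate_c, alpha = config$alpha,
    min_width = config$min_width, n_perm = config$n_perm,
    merge_tol = config$merge_tol, seed = stage_seed(config, "genotype"),
    thresholds = config$thresholds)
  hash <- config_hash(config)
  utils::write.table(res$windows,
                     file.path(out_dir, paste0(id, "_windows.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_segments_bed(res$segments,
                     file.path(out_dir, paste0(id, "_segments.bed")))
  summ <- res$summary
  jsonlite::write_json(
    list(id = id, config_hash = hash, category = summ$category,
         becei_fraction = summ$becei_fraction,
         paternal_X_present = summ$paternal_X_present,
         maternal_X_copies = summ$maternal_X_copies,
         contamination = res$contamination,
         genotypes = summ$genotypes,
         copy_calls = res$copy_calls),
    file.path(out_dir, paste0(id, "_summary.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Compare observed class counts against inheritance models
#'
#' Runs the exact multinomial goodness-of-fit test of the observed
#' chromosome-genotype counts against each requested model and returns a
#' comparison table. Ambiguous classes must be excluded by the caller (the
#' pipeline's tallies already exclude them).
#'
#' @param counts Named count vector, or path to a class-count TSV.
#' @param models Character vector of model names.
#' @param config A [run_config()] (supplies the seed and, if `NULL`
#'   `models`, the model list).
#' @param out_path Optional JSON output path.
#' @return Data frame with one row per model: `model`, `statistic`,
#'   `p_value`, `method`.
#' @export
cmd_infer <- function(counts, models = NULL, config = run_config(),
                      out_path = NULL) {
  if (is.character(counts) && length(counts) == 1 && file.exists(counts))
    counts <- read_class_counts(counts)
  if (is.null(models)) models <- config$models
  res <- lapply(models, function(m)
    goodness_of_fit(counts, model = m, seed = stage_seed(config, "infer")))
  tab <- data.frame(model = models,
                    statistic = vapply(res, `[[`, 0, "statistic"),
                    p_value = vapply(res, `[[`, 0, "p_value"),
                    method = vapply(res, `[[`, "", "method"),
                    stringsAsFactors = FALSE)
  if (!is.null(out_path)) {
    jsonlite::write_json(
      list(config_hash = config_hash(config),
           observed = as.list(res[[1]]$observed), results = tab),
      out_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  tab
}

#' Tally distinguishable genotype classes across individuals
#'
#' Pools per-chromosome classes, keeping only the five classes
#' distinguishable by sequencing; hemizygous X, triploid and ambiguous
#' chromosomes are excluded, mirroring how observed counts are tabulated
#' before model comparison.
#'
#' @param genotype_tables List of data frames with a `class` column (or one
#'   such data frame).
#' @return Named count vector over the five distinguishable classes.
#' @export
tally_classes <- function(genotype_tables) {
  if (is.data.frame(genotype_tables)) genotype_tables <- list(genotype_tables)
  cls <- unlist(lapply(genotype_tables, `[[`, "class"))
  cls <- cls[cls %in% DISTINGUISHABLE_CLASSES]
  tab <- table(factor(cls, levels = DISTINGUISHABLE_CLASSES))
  stats::setNames(as.integer(tab), names(tab))
}

#' Run the full simulate-genotype-infer pipeline in one call
#'
#' Simulates a cohort with [cmd_simulate()], genotypes each individual's
#' files with [cmd_genotype()], tallies the distinguishable classes, and
#' compares them against the configured inheritance models with
#' [cmd_infer()].
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return List: `manifest`, `summaries`, `counts`, `gof` (the comparison
#'   table).
#' @export
run_pipeline <- function(config, out_dir) {
  manifest <- cmd_simulate(config, out_dir)
  summaries <- list()
  tables <- list()
  for (ind in manifest$individuals) {
    id <- ind$id
    res <- cmd_genotype(file.path(out_dir, paste0(id, "_depths.tsv")),
                        file.path(out_dir, paste0(id, "_coverage.bed")),
                        config, out_dir, id = id)
    summaries[[id]] <- res$summary
    tables[[id]] <- res$summary$genotypes
  }
  counts <- tally_classes(tables)
  gof <- if (sum(counts) > 0)
    cmd_infer(counts, config = config,
              out_path = file.path(out_dir, "gof.json"))
  else NULL
  list(manifest = manifest, summaries = summaries, counts = counts,
       gof = gof)
}
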