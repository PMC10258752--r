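#' Build a pipeline run configuration
#'
#' Collects the analysis constants: clones need >= `min_count` reads and a
#' productive rearrangement; repertoires are rarefied to
#' `normalize_target` reads (50,000 within-cohort; use 30,000 when
#' comparing against shallower control repertoires); B-cell clones are
#' called hypermutated below `identity_threshold_pct` germline identity;
#' episodes terminate after `gap_days` non-qualifying days; subjects need
#' diary completeness above `min_completeness`; clones with Pgen above
#' `public_threshold` are public.
#'
#' @param repertoire_dir directory of clonotype TSVs (one per subject).
#' @param diary_path long-format diary TSV.
#' @param covariates_path covariate TSV with `subject_id` and
#'   `older_siblings`.
#' @param out_dir output directory.
#' @param model_path optional generative-model JSON for Pgen annotation.
#' @param locus `"TRB"` or `"IGH"`.
#' @param normalize_target rarefaction depth.
#' @param min_count minimum reads per clone.
#' @param productive_only drop non-productive clones.
#' @param identity_threshold_pct SHM germline-identity threshold (percent).
#' @param gap_days episode termination gap.
#' @param min_completeness diary completeness cut (strict >).
#' @param public_threshold Pgen cut for public clonotypes.
#' @param metrics metric columns to regress on.
#' @param years year boundaries of the cumulative counts.
#' @param seed master seed for rarefaction.
#' @return List of class `run_config`.
#' @export
run_config <- function(repertoire_dir, diary_path, covariates_path, out_dir,
                       model_path = NULL,
                       locus = c("TRB", "IGH"),
                       normalize_target = 50000L,
                       min_count = 2L,
                       productive_only = TRUE,
                       identity_threshold_pct = 98,
                       gap_days = 3L,
                       min_completeness = 0.8,
                       public_threshold = 1e-9,
                       metrics = c("clonality", "shannon_bits",
                                   "simpson_diversity", "richness"),
                       years = 1:4,
                       seed = 1L) {
  locus <- match.arg(locus)
  structure(list(repertoire_dir = repertoire_dir, diary_path = diary_path,
                 covariates_path = covariates_path, out_dir = out_dir,
                 model_path = model_path, locus = locus,
                 normalize_target = as.integer(normalize_target),
                 min_count = as.integer(min_count),
                 productive_only = productive_only,
                 identity_threshold_pct = identity_threshold_pct,
                 gap_days = as.integer(gap_days),
                 min_completeness = min_completeness,
                 public_threshold = public_threshold,
                 metrics = metrics, years = as.integer(years),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON path for serialization.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, pretty = TRUE,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, logical(1))])
}

#' Run the full analysis pipeline
#'
#' Stages: read clonotype tables -> filter (productivity, minimum count)
#' -> rarefy to a common depth (subjects below the target depth are
#' excluded and listed in the manifest) -> optional Pgen annotation ->
#' per-repertoire metrics; in parallel, diaries -> episodes -> cumulative
#' counts; finally the completeness-filtered cohort table and the adjusted
#' linear and Poisson fits per metric. Identical config and inputs give
#' byte-identical outputs.
#'
#' Outputs written to `config$out_dir`: `metrics.tsv`, `episodes.tsv`,
#' `effects.json`, `run_manifest.json`.
#'
#' @param config a [run_config()] or path to its JSON serialization.
#' @return Invisibly, a list with the metrics table, episodes, cohort
#'   table, effects and manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  paths <- sort(list.files(config$repertoire_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
  if (length(paths) == 0L) {
    stop(sprintf("stage read: no clonotype tables found in '%s'",
                 config$repertoire_dir), call. = FALSE)
  }
  reps <- lapply(paths, function(p) {
    tryCatch(read_clonotype_table(p, locus = config$locus),
             error = function(e) stop(sprintf("stage read, file '%s': %s",
                                              basename(p), conditionMessage(e)),
                                      call. = FALSE))
  })
  ids <- vapply(reps, `[[`, character(1), "subject_id")
  names(reps) <- ids

  reps <- lapply(reps, filter_repertoire, min_count = config$min_count,
                 productive_only = config$productive_only)

  depths <- vapply(reps, `[[`, numeric(1), "total_reads")
  deep_enough <- depths >= config$normalize_target
  excluded_depth <- ids[!deep_enough]
  reps <- reps[deep_enough]
  subject_seeds <- with_seed(config$seed,
    stats::setNames(sample.int(.Machine$integer.max - 1L, length(reps)),
                    names(reps)))
  reps <- lapply(names(reps), function(id) {
    downsample_reads(reps[[id]], config$normalize_target, subject_seeds[[id]])
  })
  names(reps) <- names(subject_seeds)

  model <- if (!is.null(config$model_path)) read_model(config$model_path)
  metrics <- metrics_table(reps, pgen_model = model,
                           public_threshold = config$public_threshold)
  write_tsv(metrics, file.path(config$out_dir, "metrics.tsv"))

  diaries <- read_diaries(config$diary_path)
  episodes <- lapply(diaries, call_episodes, gap_days = config$gap_days)
  epi_long <- do.call(rbind, lapply(names(episodes), function(id) {
    e <- episodes[[id]]
    if (nrow(e) == 0L) return(NULL)
    cbind(subject_id = id, e, stringsAsFactors = FALSE)
  }))
  if (is.null(epi_long)) {
    epi_long <- data.frame(subject_id = character(0), start_day = integer(0),
                           end_day = integer(0), n_symptom_days = integer(0))
  }
  write_tsv(epi_long, file.path(config$out_dir, "episodes.tsv"))

  covariates <- read_tsv(config$covariates_path)
  covariates$older_siblings <- as.logical(covariates$older_siblings)
  cohort <- build_cohort_table(metrics, diaries, covariates,
                               gap_days = config$gap_days,
                               years = config$years,
                               episodes = episodes)
  analysed <- filter_completeness(cohort, config$min_completeness)
  excluded_completeness <- attr(analysed, "excluded")

  effects <- lapply(config$metrics, function(m) {
    list(metric = m,
         linear = as.list(fit_linear_ari(analysed, m,
                                         outcome_year = max(config$years))),
         poisson = as.list(fit_poisson_ari(analysed, m,
                                           interval_years = config$years)))
  })
  jsonlite::write_json(effects, file.path(config$out_dir, "effects.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  manifest <- list(
    parameters = unclass(config),
    subject_seeds = as.list(subject_seeds),
    stages = list(
      read = list(n_input = length(ids), subjects = as.list(ids)),
      normalize = list(n_included = length(reps),
                       n_excluded = length(excluded_depth),
                       excluded = as.list(excluded_depth)),
      association = list(n_included = nrow(analysed),
                         n_excluded = length(excluded_completeness),
                         excluded = as.list(excluded_completeness))))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "run_manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(list(metrics = metrics, episodes = epi_long, cohort = cohort,
                 analysed = analysed, effects = effects,
                 manifest = manifest))
}

#' Write a simulated cohort to disk in pipeline input formats
#'
#' Writes one AIRR clonotype TSV per subject under
#' `<out_dir>/repertoires/`, plus `diary.tsv`, `covariates.tsv` and
#' `truth.json`, so a simulated cohort can be fed to [run_pipeline()]
#' unchanged.
#'
#' @param sim result of [simulate_cohort()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(sim, out_dir) {
  rep_dir <- file.path(out_dir, "repertoires")
  dir.create(rep_dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(sim$repertoires)) {
    write_clonotype_table(sim$repertoires[[id]],
                          file.path(rep_dir, paste0(id, ".tsv")))
  }
  write_diaries(sim$diaries, file.path(out_dir, "diary.tsv"))
  write_tsv(sim$covariates, file.path(out_dir, "covariates.tsv"))
  truth <- sim$truth
  truth$episodes <- lapply(truth$episodes, as.list)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
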