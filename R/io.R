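# CSV/JSON interchange with schema validation, plus the run manifest.

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.check_numeric <- function(df, cols, what) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v) || anyNA(v))
      stop(sprintf("%s column `%s` must be numeric without NAs", what, cl),
           call. = FALSE)
  }
  invisible(df)
}

#' Read and validate interchange CSV files
#'
#' `read_problems`: `problem_id, x_a, p_a, x_b, p_b, relation, is_catch`;
#' `read_trials`: `participant_id, trial_id, problem_id, choice, rt_ms`;
#' `read_fixations`: `participant_id, trial_id, aoi, onset_ms, duration_ms`
#' (AOI labels must be one of the four attribute regions), validated against
#' the trial table when given.
#'
#' @param path CSV file path.
#' @param trials optional trial table for referential checks.
#' @return validated data.frame.
#' @export
read_problems <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("problem_id", "x_a", "p_a", "x_b", "p_b", "relation",
                       "is_catch"), "problem table")
  .check_numeric(df, c("x_a", "p_a", "x_b", "p_b"), "problem table")
  df$is_catch <- as.logical(df$is_catch)
  df
}

#' @rdname read_problems
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("participant_id", "trial_id", "problem_id", "choice",
                       "rt_ms"), "trial table")
  .check_numeric(df, "rt_ms", "trial table")
  bad <- !df$choice %in% c("A", "B")
  if (any(bad))
    stop("trial table has invalid choice at row(s): ",
         paste(utils::head(which(bad)), collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_problems
#' @export
read_fixations <- function(path, trials = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("participant_id", "trial_id", "aoi", "onset_ms",
                       "duration_ms"), "fixation table")
  .check_numeric(df, c("onset_ms", "duration_ms"), "fixation table")
  bad <- !df$aoi %in% .aoi_levels
  if (any(bad))
    stop("fixation table has invalid aoi at row(s): ",
         paste(utils::head(which(bad)), collapse = ", "), call. = FALSE)
  if (!is.null(trials)) {
    key <- function(d) paste(d$participant_id, d$trial_id)
    orphan <- !key(df) %in% key(trials)
    if (any(orphan))
      stop("fixation references unknown trial at row(s): ",
           paste(utils::head(which(orphan)), collapse = ", "),
           call. = FALSE)
  }
  df
}

#' Write a synthetic dataset to a directory
#'
#' Emits `problems.csv`, `trials.csv` and `fixations.csv` in the interchange
#' schema (the trial table gains a `provenance` column naming the generating
#' model and seed) plus `ground_truth.json`.
#'
#' @param dataset a `gr_dataset` from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("problems.csv", "trials.csv", "fixations.csv",
                            "ground_truth.json"))
  utils::write.csv(dataset$problems, paths[1L], row.names = FALSE)
  tr <- dataset$trials
  tr$provenance <- sprintf("%s/%s/seed=%d", dataset$truth$variant,
                           dataset$truth$mode, dataset$truth$seed)
  utils::write.csv(tr, paths[2L], row.names = FALSE)
  utils::write.csv(dataset$fixations, paths[3L], row.names = FALSE)
  truth <- dataset$truth
  truth$participants <- lapply(truth$participants, function(pt)
    list(id = pt$id, variant = pt$variant,
         process = unclass(pt$process), gaze = unclass(pt$gaze)))
  jsonlite::write_json(truth, paths[4L], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read a run configuration (JSON)
#'
#' Validates against the known configuration schema; unknown keys are
#' rejected with an error naming the offending key.
#'
#' @param path JSON config file.
#' @return named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("paths", "design", "preprocess", "models", "fitting",
             "boundary", "population", "simulate", "out_dir", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}

# Design block of a config -> design_config
.config_design <- function(cfg) {
  d <- cfg$design
  if (is.null(d)) return(design_config())
  do.call(design_config, d[intersect(names(d),
                                     names(formals(design_config)))])
}

#' Write a machine-readable run manifest
#'
#' @param dir output directory.
#' @param stage stage name.
#' @param seed seed in effect.
#' @param inputs,outputs character vectors of file paths.
#' @param extra optional named list merged into the manifest.
#' @export
write_manifest <- function(dir, stage, seed, inputs = character(0),
                           outputs = character(0), extra = list()) {
  manifest <- c(list(stage = stage,
                     package_version =
                       as.character(utils::packageVersion("gazerisk")),
                     seed = seed, time = format(Sys.time(), tz = "UTC"),
                     inputs = inputs, outputs = outputs), extra)
  path <- file.path(dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
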