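# All floating-point file output is rendered at 12 significant digits so
# that re-running from a manifest reproduces byte-identical files.
fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 12, format = "g"))
}

format_numeric_cols <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double), fmt_num))
}

#' Write / read per-lineage outcomes as TSV
#'
#' Columns: `lineage_id, status, terminal_generation, fixation_generation,
#' repeat_at_event, ao_at_event, expanded_at_horizon, frequency_at_horizon,
#' repeat_at_horizon, seed`. Doubles are written at 12 significant digits.
#'
#' @param x A `lineage_ensemble` or an outcomes tibble.
#' @param path Output file path.
#' @return `write_outcomes_tsv()` returns `path` invisibly;
#'   `read_outcomes_tsv()` returns the outcomes tibble.
#' @export
write_outcomes_tsv <- function(x, path) {
  if (inherits(x, "lineage_ensemble")) x <- x$outcomes
  readr::write_tsv(format_numeric_cols(x), path)
  invisible(path)
}

#' @rdname write_outcomes_tsv
#' @export
read_outcomes_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    lineage_id = readr::col_integer(),
    status = readr::col_character(),
    terminal_generation = readr::col_integer(),
    fixation_generation = readr::col_integer(),
    expanded_at_horizon = readr::col_logical(),
    seed = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' Write per-generation trajectories as TSV
#'
#' Columns: `lineage_id, generation, frequency, repeat_length, ao, regime,
#' fixed`. Requires an ensemble run with `keep_trajectories = TRUE`.
#'
#' @param x A `lineage_ensemble` with trajectories retained.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories_tsv <- function(x, path) {
  if (inherits(x, "lineage_ensemble")) x <- x$trajectories
  if (is.null(x)) {
    stop("no trajectories retained; rerun with keep_trajectories = TRUE",
         call. = FALSE)
  }
  readr::write_tsv(format_numeric_cols(x), path)
  invisible(path)
}

summary_to_list <- function(s) {
  out <- unclass(s)
  out$counts <- as.list(out$counts)
  out[!vapply(out, is.null, logical(1))]
}

list_to_summary <- function(x) {
  statuses <- c("eliminated", "fixed_then_extinct", "fixed_held", "persisting")
  counts <- stats::setNames(vapply(statuses, function(f)
    as.integer(x$counts[[f]]), integer(1)), statuses)
  keep <- function(f) if (is.null(x[[f]])) NULL else lapply(x[[f]], as.numeric)
  structure(
    list(
      name = if (is.null(x$name)) NULL else as.character(x$name),
      n_lineages = as.integer(x$n_lineages),
      counts = counts,
      expanded_at_horizon = as.integer(x$expanded_at_horizon),
      elimination_generation = keep("elimination_generation"),
      fixation_generation = keep("fixation_generation"),
      repeat_at_elimination = keep("repeat_at_elimination"),
      repeat_at_fixation = keep("repeat_at_fixation"),
      ao_at_fixation = keep("ao_at_fixation"),
      frequency_at_horizon = keep("frequency_at_horizon")
    ),
    class = "ensemble_summary"
  )
}

#' Write / read an ensemble summary as JSON
#'
#' The JSON mirrors the `ensemble_summary` structure; reading it back gives
#' an object equal to the in-memory summary.
#'
#' @param x A `lineage_ensemble` or `ensemble_summary`.
#' @param path File path.
#' @return `write_summary_json()` returns `path` invisibly;
#'   `read_summary_json()` an `ensemble_summary`.
#' @export
write_summary_json <- function(x, path) {
  if (inherits(x, "lineage_ensemble")) x <- x$summary
  stopifnot(inherits(x, "ensemble_summary"))
  jsonlite::write_json(summary_to_list(x), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  list_to_summary(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Write a comparison table as TSV
#'
#' @param comparison Output of [compare_diseases()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparison, path) {
  readr::write_tsv(format_numeric_cols(comparison), path)
  invisible(path)
}

#' Run manifests
#'
#' A manifest captures everything needed to reproduce a run bit-for-bit:
#' the fully resolved configuration, the complete fertility table (plus its
#' provenance), `n`, the master seed, the package version and a timestamp.
#' [run_from_manifest()] re-executes the run and returns the ensemble;
#' outcome and summary files written from it are byte-identical to the
#' originals.
#'
#' @param ens A `lineage_ensemble`.
#' @param s The [fertility_schedule()] used for the run.
#' @param path File path for the manifest JSON.
#' @param schedule_source Optional description of where the schedule came
#'   from (e.g. `"synthetic(peak=30, spread=6)"` or a CSV path).
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   the manifest list; `run_from_manifest()` a `lineage_ensemble`.
#' @export
write_manifest <- function(ens, s, path, schedule_source = "synthetic") {
  stopifnot(inherits(ens, "lineage_ensemble"),
            inherits(s, "fertility_schedule"))
  manifest <- list(
    config = flatten_config(ens$config),
    schedule = list(
      source = schedule_source,
      window = s$window,
      age = s$ages,
      rate = s$rates
    ),
    n = ens$n,
    master_seed = ens$master_seed,
    package = "polyqsim",
    version = as.character(utils::packageVersion("polyqsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_manifest
#' @param keep_trajectories Passed to [run_ensemble()].
#' @export
run_from_manifest <- function(path, keep_trajectories = FALSE) {
  m <- read_manifest(path)
  cfg <- unflatten_config(as.list(m$config))
  s <- fertility_schedule(
    data.frame(age = as.numeric(m$schedule$age),
               rate = as.numeric(m$schedule$rate)),
    window = as.numeric(m$schedule$window)
  )
  run_ensemble(cfg, s, n = m$n, master_seed = m$master_seed,
               keep_trajectories = keep_trajectories)
}
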