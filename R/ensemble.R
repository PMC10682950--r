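outcome_row <- function(o, id) {
  tibble::tibble(
    lineage_id = id,
    status = o$status,
    terminal_generation = o$terminal_generation,
    fixation_generation = o$fixation_generation,
    repeat_at_event = o$repeat_at_event,
    ao_at_event = o$ao_at_event,
    expanded_at_horizon = o$expanded_at_horizon,
    frequency_at_horizon = o$frequency_at_horizon,
    repeat_at_horizon = o$repeat_at_horizon,
    seed = o$seed
  )
}

#' Run an ensemble of independent lineages
#'
#' Simulates `n` independent lineages of the same disease configuration and
#' aggregates their fates. Per-lineage seeds are derived deterministically
#' from `master_seed` (`set.seed(master_seed)` then
#' `sample.int(2^31 - 2, n)`), after which every lineage runs on its own
#' private stream — results do not depend on execution order.
#'
#' @param cfg A [disease_config()] or preset name (`"sca2"`/`"sca3"`).
#' @param s A [fertility_schedule()]; defaults to [default_schedule()].
#' @param n Number of lineages.
#' @param master_seed Integer master seed (required; no silent
#'   nondeterminism).
#' @param keep_trajectories Retain all per-generation trajectories (as one
#'   long tibble)? Off by default for memory.
#' @param progress Emit a message every 100 lineages?
#' @return A `lineage_ensemble`: list with `outcomes` (tibble, one row per
#'   lineage), `summary` (an `ensemble_summary`), optionally
#'   `trajectories`, plus the configuration, `n` and `master_seed`.
#'   Use [tidy()] for the outcomes and [glance()] for a one-row summary.
#' @export
#' @examples
#' ens <- run_ensemble("sca2", n = 20, master_seed = 1)
#' glance(ens)
run_ensemble <- function(cfg, s = default_schedule(), n = 1000,
                         master_seed, keep_trajectories = FALSE,
                         progress = FALSE) {
  if (is.character(cfg)) cfg <- disease_preset(cfg)
  validate_config(cfg)
  if (missing(master_seed)) stop("`master_seed` is required", call. = FALSE)
  n <- as.integer(n)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  set.seed(as.integer(master_seed))
  lineage_seeds <- sample.int(.Machine$integer.max - 1L, n)
  outcomes <- vector("list", n)
  trajs <- if (keep_trajectories) vector("list", n) else NULL
  for (i in seq_len(n)) {
    o <- simulate_lineage(cfg, s, seed = lineage_seeds[i],
                          keep_trajectory = keep_trajectories)
    if (keep_trajectories) {
      trajs[[i]] <- dplyr::mutate(o$trajectory, lineage_id = i,
                                  .before = 1L)
    }
    o$trajectory <- NULL
    outcomes[[i]] <- outcome_row(o, i)
    if (progress && i %% 100 == 0) {
      message(sprintf("[%s] %d / %d lineages simulated", cfg$name, i, n))
    }
  }
  outcomes <- dplyr::bind_rows(outcomes)
  structure(
    list(
      outcomes = outcomes,
      summary = summarize_outcomes(outcomes, name = cfg$name),
      trajectories = if (keep_trajectories) dplyr::bind_rows(trajs),
      config = cfg,
      n = n,
      master_seed = as.integer(master_seed)
    ),
    class = "lineage_ensemble"
  )
}

med_range <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NULL)
  list(median = stats::median(x), min = min(x), max = max(x))
}

#' Summarize lineage outcomes
#'
#' Aggregates an outcomes table (as produced by [run_ensemble()] or
#' [tidy()] on an ensemble) into fate counts and event statistics:
#' elimination/fixation generations (median and range), repeat length at
#' elimination (median, range) and at fixation (median, mean, range), AO at
#' fixation (mean, range) and the frequency at the horizon among persisting
#' lineages (median, IQR). Empty strata (e.g. no fixations) are reported as
#' absent, not as zero.
#'
#' @param outcomes A tibble of per-lineage outcomes.
#' @param name Optional label carried into the summary.
#' @return An `ensemble_summary` object.
#' @export
summarize_outcomes <- function(outcomes, name = NULL) {
  if (!is.data.frame(outcomes) || nrow(outcomes) == 0) {
    stop("`outcomes` must be a non-empty outcomes table", call. = FALSE)
  }
  statuses <- c("eliminated", "fixed_then_extinct", "fixed_held", "persisting")
  counts <- table(factor(outcomes$status, levels = statuses))
  counts <- stats::setNames(as.integer(counts), statuses)
  elim <- outcomes[outcomes$status == "eliminated", ]
  fixed <- outcomes[!is.na(outcomes$fixation_generation), ]
  pers <- outcomes[outcomes$status == "persisting", ]
  rep_fix <- med_range(fixed$repeat_at_event)
  if (!is.null(rep_fix)) rep_fix$mean <- mean(fixed$repeat_at_event)
  ao_fix <- if (nrow(fixed) > 0) {
    list(mean = mean(fixed$ao_at_event),
         min = min(fixed$ao_at_event), max = max(fixed$ao_at_event))
  }
  freq_hor <- if (nrow(pers) > 0) {
    list(median = stats::median(pers$frequency_at_horizon),
         iqr = stats::IQR(pers$frequency_at_horizon))
  }
  structure(
    list(
      name = name,
      n_lineages = nrow(outcomes),
      counts = counts,
      expanded_at_horizon = sum(pers$expanded_at_horizon, na.rm = TRUE),
      elimination_generation = med_range(elim$terminal_generation),
      fixation_generation = med_range(fixed$fixation_generation),
      repeat_at_elimination = med_range(elim$repeat_at_event),
      repeat_at_fixation = rep_fix,
      ao_at_fixation = ao_fix,
      frequency_at_horizon = freq_hor
    ),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary%s: %d lineages>\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "",
              x$n_lineages))
  cat(sprintf("  eliminated %d | fixed-then-extinct %d | fixed-held %d | persisting %d (expanded at horizon: %d)\n",
              x$counts[["eliminated"]], x$counts[["fixed_then_extinct"]],
              x$counts[["fixed_held"]], x$counts[["persisting"]],
              x$expanded_at_horizon))
  fmt <- function(label, mr, digits = 2) {
    if (is.null(mr)) return(invisible(NULL))
    med <- if (!is.null(mr$median)) sprintf("median %.*f", digits, mr$median)
           else sprintf("mean %.*f", digits, mr$mean)
    extra <- if (!is.null(mr$mean) && !is.null(mr$median))
      sprintf(", mean %.*f", digits, mr$mean) else ""
    cat(sprintf("  %s: %s%s (range %.*f-%.*f)\n", label, med, extra,
                digits, mr$min, digits, mr$max))
  }
  fmt("elimination generation", x$elimination_generation, 0)
  fmt("fixation generation", x$fixation_generation, 0)
  fmt("repeat at elimination", x$repeat_at_elimination)
  fmt("repeat at fixation", x$repeat_at_fixation)
  fmt("AO at fixation", x$ao_at_fixation)
  if (!is.null(x$frequency_at_horizon)) {
    cat(sprintf("  frequency at horizon (persisting): median %.3g (IQR %.3g)\n",
                x$frequency_at_horizon$median, x$frequency_at_horizon$iqr))
  }
  invisible(x)
}

#' @export
print.lineage_ensemble <- function(x, ...) {
  cat(sprintf("<lineage_ensemble: %s, n = %d, master_seed = %d>\n",
              x$config$name, x$n, x$master_seed))
  print(x$summary)
  invisible(x)
}

flatten_summary <- function(s) {
  g <- function(mr, f) if (is.null(mr) || is.null(mr[[f]])) NA_real_ else mr[[f]]
  tibble::tibble(
    name = if (is.null(s$name)) NA_character_ else s$name,
    n_lineages = s$n_lineages,
    eliminated = s$counts[["eliminated"]],
    fixed_then_extinct = s$counts[["fixed_then_extinct"]],
    fixed_held = s$counts[["fixed_held"]],
    persisting = s$counts[["persisting"]],
    expanded_at_horizon = s$expanded_at_horizon,
    elimination_gen_median = g(s$elimination_generation, "median"),
    elimination_gen_min = g(s$elimination_generation, "min"),
    elimination_gen_max = g(s$elimination_generation, "max"),
    fixation_gen_median = g(s$fixation_generation, "median"),
    fixation_gen_min = g(s$fixation_generation, "min"),
    fixation_gen_max = g(s$fixation_generation, "max"),
    repeat_at_elimination_median = g(s$repeat_at_elimination, "median"),
    repeat_at_elimination_min = g(s$repeat_at_elimination, "min"),
    repeat_at_elimination_max = g(s$repeat_at_elimination, "max"),
    repeat_at_fixation_median = g(s$repeat_at_fixation, "median"),
    repeat_at_fixation_mean = g(s$repeat_at_fixation, "mean"),
    repeat_at_fixation_min = g(s$repeat_at_fixation, "min"),
    repeat_at_fixation_max = g(s$repeat_at_fixation, "max"),
    ao_at_fixation_mean = g(s$ao_at_fixation, "mean"),
    ao_at_fixation_min = g(s$ao_at_fixation, "min"),
    ao_at_fixation_max = g(s$ao_at_fixation, "max"),
    frequency_at_horizon_median = g(s$frequency_at_horizon, "median"),
    frequency_at_horizon_iqr = g(s$frequency_at_horizon, "iqr")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-lineage outcomes of an ensemble
#'
#' @param x A `lineage_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per lineage.
#' @export
tidy.lineage_ensemble <- function(x, ...) x$outcomes

#' One-row summary of an ensemble
#'
#' @param x A `lineage_ensemble` or `ensemble_summary`.
#' @param ... Unused.
#' @return A one-row tibble of fate counts and event statistics.
#' @export
glance.lineage_ensemble <- function(x, ...) flatten_summary(x$summary)

#' @rdname glance.lineage_ensemble
#' @export
glance.ensemble_summary <- function(x, ...) flatten_summary(x)

#' Sensitivity sweep over imputed fitness SDs
#'
#' The fitness SDs of both regimes are imputations rather than observed
#' values; this sweep re-runs the full ensemble with each candidate SD
#' substituted (into both regimes by default, or one of them) and collects
#' the summaries. Every ensemble uses the same `master_seed`, so a sweep
#' value equal to the preset SD reproduces the main run exactly.
#'
#' @inheritParams run_ensemble
#' @param fitness_sd_values Numeric vector of SD values (each `>= 0`).
#' @param regimes Apply the SD to `"both"` regimes (default),
#'   `"expanded"` only, or `"normal"` only.
#' @return A tibble with one row per SD value: `fitness_sd`, the flattened
#'   summary columns, and a `summary` list-column of `ensemble_summary`
#'   objects. Empty `fitness_sd_values` give an empty tibble.
#' @export
sensitivity_sweep <- function(cfg, s = default_schedule(),
                              fitness_sd_values, n = 1000, master_seed,
                              regimes = c("both", "expanded", "normal"),
                              progress = FALSE) {
  if (is.character(cfg)) cfg <- disease_preset(cfg)
  regimes <- match.arg(regimes)
  fitness_sd_values <- as.numeric(fitness_sd_values)
  if (anyNA(fitness_sd_values) || any(fitness_sd_values < 0)) {
    stop("all fitness_sd_values must be >= 0", call. = FALSE)
  }
  rows <- purrr::map(fitness_sd_values, function(sd) {
    cfg2 <- cfg
    if (regimes %in% c("both", "expanded")) cfg2$expanded$fitness_sd <- sd
    if (regimes %in% c("both", "normal")) cfg2$normal$fitness_sd <- sd
    ens <- run_ensemble(cfg2, s, n = n, master_seed = master_seed,
                        progress = progress)
    dplyr::bind_cols(tibble::tibble(fitness_sd = sd),
                     flatten_summary(ens$summary),
                     tibble::tibble(summary = list(ens$summary)))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(fitness_sd = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Compare the fates of two ensembles
#'
#' Side-by-side fate counts for two equally sized ensembles, with a
#' two-proportion chi-square test (with continuity correction) per fate
#' class — the comparison-table presentation of elimination, fixation and
#' persistence probabilities between two loci.
#'
#' @param summary_a,summary_b `ensemble_summary` or `lineage_ensemble`
#'   objects with equal `n`.
#' @return A tibble with columns `fate`, `count_a`, `count_b`,
#'   `fraction_a`, `fraction_b`, `p_value`, with the summary labels as
#'   attributes `label_a`/`label_b`.
#' @export
compare_diseases <- function(summary_a, summary_b) {
  pick <- function(x) {
    if (inherits(x, "lineage_ensemble")) x$summary
    else if (inherits(x, "ensemble_summary")) x
    else stop("expected a lineage_ensemble or ensemble_summary", call. = FALSE)
  }
  a <- pick(summary_a)
  b <- pick(summary_b)
  if (a$n_lineages != b$n_lineages) {
    stop("ensembles have unequal n (", a$n_lineages, " vs ", b$n_lineages,
         "); comparison requires equal sizes", call. = FALSE)
  }
  n <- a$n_lineages
  fates <- names(a$counts)
  p_val <- function(xa, xb) {
    if (xa == xb) return(1)
    suppressWarnings(
      stats::prop.test(c(xa, xb), c(n, n), correct = TRUE)$p.value
    )
  }
  out <- tibble::tibble(
    fate = fates,
    count_a = as.integer(a$counts),
    count_b = as.integer(b$counts),
    fraction_a = as.numeric(a$counts) / n,
    fraction_b = as.numeric(b$counts) / n,
    p_value = purrr::map2_dbl(as.integer(a$counts), as.integer(b$counts),
                              p_val)
  )
  attr(out, "label_a") <- a$name
  attr(out, "label_b") <- b$name
  attr(out, "n") <- n
  out
}
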