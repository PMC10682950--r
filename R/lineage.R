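#' Allele-frequency recursion for a dominant late-onset expansion
#'
#' One generation of the simplified recursion
#' `p' = p * w * antcoeff * 2k`,
#' where `p` is the frequency of the tracked (expanded) allele, `w` the
#' relative fitness of carriers, `antcoeff` the anticipation coefficient
#' (see [anticipation_coefficient()]) and `k` the segregation coefficient
#' (0.5 is Mendelian). The result is clamped to `[0, 1]`: non-positive
#' products collapse to exactly 0 (elimination), products at or above 1 to
#' exactly 1 (fixation). Vectorized over all arguments.
#'
#' This simplification of the classical diploid recursion drops the
#' homozygote term (the expansion is too rare for homozygotes) and the
#' non-carrier frequency `q` (approximately 1, and the fully dominant
#' expansion cannot shelter from selection in heterozygotes).
#'
#' @param p Current allele frequency in `[0, 1]`.
#' @param w Relative fitness of carriers.
#' @param antcoeff Anticipation coefficient in `[0, 1]` (1 while the allele
#'   is in the normal range).
#' @param k Segregation coefficient.
#' @return The next-generation frequency, exactly in `[0, 1]`.
#' @export
#' @examples
#' frequency_update(1e-6, 1.5, 1, 0.404) # 1.212e-06
frequency_update <- function(p, w, antcoeff, k) {
  pmin(pmax(p * w * antcoeff * (2 * k), 0), 1)
}

#' Sample per-generation transmission parameters
#'
#' Draws `n` independent quadruples (fitness `w`, segregation `k`, repeat
#' change `delta_repeats`, AO slope `ao_slope`) from the untruncated
#' Gaussians of one regime, using R's global random stream. Draws are
#' untruncated on purpose: a rare non-positive `w` or `k` drives the
#' frequency to 0 and eliminates the lineage, which is part of the model's
#' randomness. With all SDs zero the draw equals the means exactly.
#'
#' @param regime_params A [regime_params()].
#' @param n Number of draws.
#' @return A tibble with columns `w`, `k`, `delta_repeats`, `ao_slope`.
#' @export
draw_generation_params <- function(regime_params, n = 1) {
  rp <- regime_params
  tibble::tibble(
    w = stats::rnorm(n, rp$fitness_mean, rp$fitness_sd),
    k = stats::rnorm(n, rp$segregation_mean, rp$segregation_sd),
    delta_repeats = stats::rnorm(n, rp$instability_mean, rp$instability_sd),
    ao_slope = stats::rnorm(n, rp$ao_slope_mean, rp$ao_slope_sd)
  )
}

#' Ancestral lineage state
#'
#' Generation 0 of a lineage: the founder carries the ancestral repeat at
#' the configured initial frequency and ancestral age at onset, in the
#' expanded regime.
#'
#' @param cfg A [disease_config()].
#' @return A `lineage_state` (named list): `generation`, `frequency`,
#'   `repeat_length`, `ao`, `regime`, `fixed`, `fixation_generation`.
#' @export
ancestral_state <- function(cfg) {
  structure(
    list(
      generation = 0L,
      frequency = cfg$initial_frequency,
      repeat_length = cfg$ancestral_repeat,
      ao = cfg$ancestral_ao,
      regime = if (cfg$ancestral_repeat >= cfg$pathogenic_threshold)
        "expanded" else "normal",
      fixed = FALSE,
      fixation_generation = NA_integer_
    ),
    class = "lineage_state"
  )
}

#' Advance a lineage by one generation
#'
#' Applies one transmission: (1) the repeat length changes by the sampled
#' instability; (2) the AO moves by `-delta_repeats * ao_slope` (expansion
#' anticipates onset, contraction delays it), where `ao_slope` is the locus
#' regression coefficient (`ao_slope_mean`) under the default
#' `ao_model = "regression"` or the per-transmission Gaussian draw under
#' `ao_model = "sampled"`; (3) the regime is re-derived
#' from the new repeat length versus the pathogenic threshold (inclusive);
#' (4) the anticipation coefficient is computed from the new AO when the new
#' length is expanded and is exactly 1 otherwise; (5) the frequency is
#' updated via [frequency_update()] — unless the lineage is already fixed,
#' in which case the frequency stays pinned at 1 and only the repeat/AO
#' dynamics continue.
#'
#' The draw is taken by the caller from the regime of the allele *entering*
#' the step (the transmitting parent's regime) under the default
#' `draw_regime = "entering"`; the regime for the anticipation penalty is
#' the post-step regime (the offspring's allele class).
#'
#' @param state A `lineage_state` (see [ancestral_state()]).
#' @param draw A one-row data frame with columns `w`, `k`, `delta_repeats`,
#'   `ao_slope` (see [draw_generation_params()]).
#' @param cfg A [disease_config()].
#' @param s A [fertility_schedule()].
#' @return The next `lineage_state`.
#' @export
step_lineage <- function(state, draw, cfg, s) {
  repeat2 <- state$repeat_length + draw$delta_repeats
  slope <- if (identical(cfg$ao_model, "sampled")) draw$ao_slope
           else cfg[[state$regime]]$ao_slope_mean
  ao2 <- state$ao - draw$delta_repeats * slope
  regime2 <- if (repeat2 >= cfg$pathogenic_threshold) "expanded" else "normal"
  if (state$fixed) {
    freq2 <- 1
  } else {
    antc <- if (regime2 == "expanded") {
      anticipation_coefficient(s, ao2, cfg$post_onset_birth_fraction)
    } else 1
    freq2 <- frequency_update(state$frequency, draw$w, antc, draw$k)
  }
  fixed2 <- state$fixed || freq2 >= 1
  structure(
    list(
      generation = state$generation + 1L,
      frequency = freq2,
      repeat_length = repeat2,
      ao = ao2,
      regime = regime2,
      fixed = fixed2,
      fixation_generation = if (state$fixed) state$fixation_generation
                            else if (fixed2) state$generation + 1L
                            else NA_integer_
    ),
    class = "lineage_state"
  )
}

#' Simulate one lineage to its fate
#'
#' Iterates [step_lineage()] from the ancestral state until the tracked
#' allele's frequency reaches exactly 0 (elimination), or the generation
#' horizon passes. Fixation (frequency 1) is absorbing for the frequency:
#' the repeat/AO dynamics continue, and if the AO falls to or below the
#' window minimum while the allele is expanded the fixed lineage is declared
#' extinct (`fixed_then_extinct`); a fixed lineage that survives to the
#' horizon is `fixed_held`. Lineages reaching the horizon with
#' `0 < p < 1` are `persisting`, flagged by whether their repeat is in the
#' pathogenic range at the horizon.
#'
#' Randomness: the per-lineage stream is seeded with `seed`; all
#' `max_generations` Gaussian draws for both regimes are generated up-front
#' in a fixed order (expanded w, k, delta, slope; then normal w, k, delta,
#' slope), and the step loop indexes into them by generation and the
#' regime of the allele entering the step. Identical `seed` and `cfg` give
#' bitwise-identical trajectories.
#'
#' @param cfg A validated [disease_config()].
#' @param s A [fertility_schedule()].
#' @param seed Integer seed for this lineage's private stream.
#' @param keep_trajectory Keep the full per-generation trajectory tibble?
#' @return A `lineage_outcome`: `status` (one of `eliminated`,
#'   `fixed_then_extinct`, `fixed_held`, `persisting`),
#'   `terminal_generation`, `fixation_generation`, `repeat_at_event` and
#'   `ao_at_event` (at elimination or fixation), `expanded_at_horizon`,
#'   `frequency_at_horizon`, `repeat_at_horizon`, and (optionally)
#'   `trajectory`.
#' @export
#' @examples
#' cfg <- zero_sds(disease_preset("sca2"))
#' simulate_lineage(cfg, default_schedule(), seed = 1)$terminal_generation # 10
simulate_lineage <- function(cfg, s, seed, keep_trajectory = TRUE) {
  validate_config(cfg)
  set.seed(as.integer(seed))
  G <- cfg$max_generations
  ex <- cfg$expanded
  no <- cfg$normal
  # fixed stream layout: 8 vectors of length G
  ew <- stats::rnorm(G, ex$fitness_mean, ex$fitness_sd)
  ek <- stats::rnorm(G, ex$segregation_mean, ex$segregation_sd)
  ed <- stats::rnorm(G, ex$instability_mean, ex$instability_sd)
  es <- stats::rnorm(G, ex$ao_slope_mean, ex$ao_slope_sd)
  nw <- stats::rnorm(G, no$fitness_mean, no$fitness_sd)
  nk <- stats::rnorm(G, no$segregation_mean, no$segregation_sd)
  nd <- stats::rnorm(G, no$instability_mean, no$instability_sd)
  ns <- stats::rnorm(G, no$ao_slope_mean, no$ao_slope_sd)
  if (!identical(cfg$ao_model, "sampled")) {
    # AO follows the locus regression: the coefficient is a constant, so the
    # AO stays a deterministic function of the cumulative repeat change
    es <- rep(ex$ao_slope_mean, G)
    ns <- rep(no$ao_slope_mean, G)
  }

  thr <- cfg$pathogenic_threshold
  wmin <- cfg$reproductive_window[1]
  pobf <- cfg$post_onset_birth_fraction
  post_draw <- identical(cfg$draw_regime, "post")

  # trajectory buffers (generation 0 .. terminal)
  tr_freq <- numeric(G + 1L)
  tr_rep <- numeric(G + 1L)
  tr_ao <- numeric(G + 1L)
  tr_exp <- logical(G + 1L)
  tr_fix <- logical(G + 1L)

  freq <- cfg$initial_frequency
  rep_len <- cfg$ancestral_repeat
  ao <- cfg$ancestral_ao
  expanded <- rep_len >= thr
  fixed <- FALSE
  fixation_generation <- NA_integer_
  repeat_at_event <- NA_real_
  ao_at_event <- NA_real_

  tr_freq[1L] <- freq; tr_rep[1L] <- rep_len; tr_ao[1L] <- ao
  tr_exp[1L] <- expanded; tr_fix[1L] <- FALSE

  status <- NA_character_
  terminal <- G
  g <- 0L
  while (g < G) {
    g <- g + 1L
    # instability is a property of the transmitting meiosis: always the
    # regime entering the step; w/k/slope follow draw_regime
    d <- if (expanded) ed[g] else nd[g]
    use_exp <- if (post_draw) (rep_len + d) >= thr else expanded
    if (use_exp) {
      w <- ew[g]; k <- ek[g]; slope <- es[g]
    } else {
      w <- nw[g]; k <- nk[g]; slope <- ns[g]
    }
    rep_len <- rep_len + d
    ao <- ao - d * slope
    expanded <- rep_len >= thr

    if (!fixed) {
      antc <- if (expanded) anticipation_coefficient(s, ao, pobf) else 1
      freq <- frequency_update(freq, w, antc, k)
      if (freq <= 0) {
        freq <- 0
        status <- "eliminated"
        terminal <- g
        repeat_at_event <- rep_len
        ao_at_event <- ao
      } else if (freq >= 1) {
        fixed <- TRUE
        fixation_generation <- g
        repeat_at_event <- rep_len
        ao_at_event <- ao
      }
    } else if (expanded && ao <= wmin) {
      status <- "fixed_then_extinct"
      terminal <- g
    }
    idx <- g + 1L
    tr_freq[idx] <- freq; tr_rep[idx] <- rep_len; tr_ao[idx] <- ao
    tr_exp[idx] <- expanded; tr_fix[idx] <- fixed
    if (!is.na(status)) break
  }
  if (is.na(status)) {
    status <- if (fixed) "fixed_held" else "persisting"
    terminal <- G
  }

  n_rows <- terminal + 1L
  out <- list(
    status = status,
    terminal_generation = as.integer(terminal),
    fixation_generation = fixation_generation,
    repeat_at_event = repeat_at_event,
    ao_at_event = ao_at_event,
    expanded_at_horizon = if (status == "persisting") expanded else NA,
    frequency_at_horizon = if (status == "persisting") freq else NA_real_,
    repeat_at_horizon = if (status %in% c("persisting", "fixed_held"))
      rep_len else NA_real_,
    seed = as.integer(seed)
  )
  if (keep_trajectory) {
    out$trajectory <- tibble::tibble(
      generation = 0:terminal,
      frequency = tr_freq[seq_len(n_rows)],
      repeat_length = tr_rep[seq_len(n_rows)],
      ao = tr_ao[seq_len(n_rows)],
      regime = ifelse(tr_exp[seq_len(n_rows)], "expanded", "normal"),
      fixed = tr_fix[seq_len(n_rows)]
    )
  }
  structure(out, class = "lineage_outcome")
}

#' Classify a finished lineage from its trajectory
#'
#' Re-derives the fate of a simulated lineage purely from its trajectory
#' records, independently of the bookkeeping inside [simulate_lineage()].
#' The four statuses partition all outcomes: `eliminated` (frequency hit 0
#' without prior fixation), `fixed_then_extinct` (fixed, then AO fell to or
#' below the window minimum while expanded), `fixed_held` (fixed and held to
#' the horizon), `persisting` (horizon reached with `0 < p < 1`).
#'
#' @param outcome A `lineage_outcome` with its trajectory retained.
#' @param cfg The [disease_config()] used to simulate it.
#' @return One of the four status strings.
#' @export
classify <- function(outcome, cfg) {
  tr <- outcome$trajectory
  if (is.null(tr)) stop("classify() needs the trajectory; rerun with ",
                        "keep_trajectory = TRUE", call. = FALSE)
  last <- tr[nrow(tr), ]
  ever_fixed <- any(tr$fixed)
  if (!ever_fixed && last$frequency == 0) return("eliminated")
  if (ever_fixed) {
    post_fix <- tr[tr$fixed, ]
    extinct <- any(post_fix$regime == "expanded" &
                     post_fix$ao <= cfg$reproductive_window[1])
    return(if (extinct) "fixed_then_extinct" else "fixed_held")
  }
  "persisting"
}

#' @export
print.lineage_outcome <- function(x, ...) {
  cat(sprintf("<lineage_outcome: %s at generation %d>\n",
              x$status, x$terminal_generation))
  if (!is.na(x$fixation_generation)) {
    cat(sprintf("  fixed at generation %d (repeat %.2f, AO %.2f)\n",
                x$fixation_generation, x$repeat_at_event, x$ao_at_event))
  }
  if (identical(x$status, "eliminated")) {
    cat(sprintf("  repeat at elimination %.2f, AO %.2f\n",
                x$repeat_at_event, x$ao_at_event))
  }
  if (identical(x$status, "persisting")) {
    cat(sprintf("  frequency at horizon %.3g, repeat %.2f (%s)\n",
                x$frequency_at_horizon, x$repeat_at_horizon,
                if (isTRUE(x$expanded_at_horizon)) "expanded" else "normal"))
  }
  invisible(x)
}
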