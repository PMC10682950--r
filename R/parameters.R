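#' Per-regime transmission parameters
#'
#' Bundle of Gaussian mean/SD pairs describing how one allele regime
#' (expanded, i.e. at or above the pathogenic threshold, or normal) behaves
#' during a single transmission: relative fitness `w` of carriers, the
#' segregation coefficient `k` (probability that the tracked allele is
#' transmitted in a meiosis; 0.5 is Mendelian), the meiotic instability
#' (mean change in repeat units per transmission) and the age-at-onset (AO)
#' reduction per added repeat (years/repeat).
#'
#' The AO slope is a property of the locus (the AO ~ repeat-length
#' regression), so presets carry the same slope in both regimes even though
#' it only penalises reproduction while the allele is expanded.
#'
#' @param fitness_mean,fitness_sd Relative fitness `w` (dimensionless) of
#'   carriers versus non-carriers; `fitness_mean` must be positive.
#' @param segregation_mean,segregation_sd Segregation coefficient `k`,
#'   `segregation_mean` strictly inside (0, 1).
#' @param instability_mean,instability_sd Repeat-length change per
#'   transmission (repeat units/generation); positive means expansion bias.
#' @param ao_slope_mean,ao_slope_sd AO reduction per added repeat
#'   (years/repeat).
#' @return An object of class `regime_params` (a named list).
#' @seealso [disease_preset()] for curated values.
#' @export
#' @examples
#' regime_params(1.5, 0.25, 0.404, 0.085, 2.42, 5.655, 1.877, 1.86)
regime_params <- function(fitness_mean, fitness_sd,
                          segregation_mean, segregation_sd,
                          instability_mean, instability_sd,
                          ao_slope_mean = 0, ao_slope_sd = 0) {
  structure(
    list(
      fitness_mean = as.numeric(fitness_mean),
      fitness_sd = as.numeric(fitness_sd),
      segregation_mean = as.numeric(segregation_mean),
      segregation_sd = as.numeric(segregation_sd),
      instability_mean = as.numeric(instability_mean),
      instability_sd = as.numeric(instability_sd),
      ao_slope_mean = as.numeric(ao_slope_mean),
      ao_slope_sd = as.numeric(ao_slope_sd)
    ),
    class = "regime_params"
  )
}

#' Full configuration for one disease locus
#'
#' Assembles everything a lineage simulation needs: the pathogenic repeat
#' threshold, the ancestral state (repeat length and age at onset of the
#' founder expansion), the fraction of children born after parental onset,
#' per-regime transmission parameters, and run controls.
#'
#' @param name Short label, e.g. `"sca2"`.
#' @param pathogenic_threshold Repeat length at and above which the allele is
#'   pathogenic (inclusive; the comparison is on continuous repeat values).
#' @param ancestral_repeat Founder repeat length (must be `>=` threshold).
#' @param ancestral_ao Founder age at onset, years.
#' @param post_onset_birth_fraction Fraction of children born after the onset
#'   of parental symptoms, added to the anticipation coefficient; in `[0, 1]`.
#' @param expanded,normal [regime_params()] for each allele regime.
#' @param initial_frequency Population frequency of the founder allele,
#'   strictly inside (0, 1).
#' @param max_generations Horizon of the simulation (generations; `>= 1`).
#' @param reproductive_window Two ages (years), `c(min, max)`, bounding the
#'   fertile period; onset at or before the minimum annihilates reproduction.
#' @param draw_regime Which regime supplies the per-generation random draw:
#'   `"entering"` (the parent's regime at the start of the step; default) or
#'   `"post"` (the regime after the instability update).
#' @param ao_model How the age at onset tracks the repeat length:
#'   `"regression"` (default) applies the locus regression coefficient
#'   (`ao_slope_mean`) as a constant, so the AO is a deterministic function
#'   of the cumulative repeat change, anchored at the ancestral
#'   (repeat, AO) pair; `"sampled"` draws the slope anew each transmission
#'   from its mean/SD.
#' @return An object of class `disease_config`.
#' @export
disease_config <- function(name,
                           pathogenic_threshold,
                           ancestral_repeat,
                           ancestral_ao,
                           post_onset_birth_fraction,
                           expanded,
                           normal,
                           initial_frequency = 1e-6,
                           max_generations = 650L,
                           reproductive_window = c(12, 50),
                           draw_regime = c("entering", "post"),
                           ao_model = c("regression", "sampled")) {
  draw_regime <- match.arg(draw_regime)
  ao_model <- match.arg(ao_model)
  cfg <- structure(
    list(
      name = as.character(name),
      pathogenic_threshold = as.numeric(pathogenic_threshold),
      ancestral_repeat = as.numeric(ancestral_repeat),
      ancestral_ao = as.numeric(ancestral_ao),
      post_onset_birth_fraction = as.numeric(post_onset_birth_fraction),
      expanded = expanded,
      normal = normal,
      initial_frequency = as.numeric(initial_frequency),
      max_generations = as.integer(max_generations),
      reproductive_window = as.numeric(reproductive_window),
      draw_regime = draw_regime,
      ao_model = ao_model
    ),
    class = "disease_config"
  )
  cfg
}

#' Curated disease presets
#'
#' Returns the packaged parameter set for one polyglutamine locus. Two
#' presets ship: `"sca2"` (ATXN2) and `"sca3"` (ATXN3, Machado-Joseph
#' disease). Values are literature means (SDs in parentheses below); several
#' SDs were imputed in the source meta-analyses rather than observed and are
#' marked so here:
#'
#' * `sca2` expanded: w 1.50 (0.25, imputed), k 0.404 (0.085, imputed),
#'   instability 2.42 (5.655), AO slope 1.877 (1.86) years/repeat;
#'   normal: w 1.00 (0.25, imputed), k 0.596 (0.085, imputed),
#'   instability 0.23 (0.468). Threshold 34 repeats; ancestor 34 repeats,
#'   AO 55 y; post-onset birth fraction 0.08.
#' * `sca3` expanded: w 1.45 (0.25, imputed), k 0.640 (0.085),
#'   instability 1.23 (5.126), AO slope 1.652 (1.729);
#'   normal: w 1.00 (0.25, imputed), k 0.360 (0.085), instability
#'   0.00 (imputed) (0.468, imputed from the ATXN2 normal allele).
#'   Threshold 51 repeats; ancestor 54 repeats, AO 65 y; post-onset birth
#'   fraction 0.083.
#'
#' Both presets use initial frequency 1e-6, a 650-generation horizon and a
#' 12-50 y reproductive window. The AO slope is carried in both regimes (a
#' locus-level regression); it only affects reproduction while expanded.
#'
#' @param name `"sca2"` or `"sca3"`.
#' @return A validated [disease_config()].
#' @export
#' @examples
#' disease_preset("sca2")$expanded$instability_mean # 2.42
disease_preset <- function(name) {
  name <- tolower(as.character(name)[1])
  presets <- c("sca2", "sca3")
  if (!name %in% presets) {
    stop("Unknown disease preset '", name, "'. Available presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  cfg <- switch(
    name,
    sca2 = disease_config(
      name = "sca2",
      pathogenic_threshold = 34,
      ancestral_repeat = 34,
      ancestral_ao = 55,
      post_onset_birth_fraction = 0.08,
      expanded = regime_params(1.50, 0.25, 0.404, 0.085, 2.42, 5.655,
                               1.877, 1.86),
      normal = regime_params(1.00, 0.25, 0.596, 0.085, 0.23, 0.468,
                             1.877, 1.86)
    ),
    sca3 = disease_config(
      name = "sca3",
      pathogenic_threshold = 51,
      ancestral_repeat = 54,
      ancestral_ao = 65,
      post_onset_birth_fraction = 0.083,
      expanded = regime_params(1.45, 0.25, 0.640, 0.085, 1.23, 5.126,
                               1.652, 1.729),
      normal = regime_params(1.00, 0.25, 0.360, 0.085, 0.00, 0.468,
                             1.652, 1.729)
    )
  )
  validate_config(cfg)
}

validate_regime <- function(rp, label) {
  problems <- character(0)
  if (!inherits(rp, "regime_params")) {
    return(paste0(label, ": not a regime_params object"))
  }
  bad_sd <- function(x) !is.finite(x) || x < 0
  for (f in c("fitness_sd", "segregation_sd", "instability_sd", "ao_slope_sd")) {
    if (bad_sd(rp[[f]])) {
      problems <- c(problems, sprintf("%s$%s must be >= 0 (got %g)",
                                      label, f, rp[[f]]))
    }
  }
  if (!is.finite(rp$fitness_mean) || rp$fitness_mean <= 0) {
    problems <- c(problems, sprintf("%s$fitness_mean must be > 0 (got %g)",
                                    label, rp$fitness_mean))
  }
  if (!is.finite(rp$segregation_mean) ||
      rp$segregation_mean <= 0 || rp$segregation_mean >= 1) {
    problems <- c(problems,
                  sprintf("%s$segregation_mean must be in (0,1) (got %g)",
                          label, rp$segregation_mean))
  }
  problems
}

#' Validate a disease configuration
#'
#' Checks every invariant of a [disease_config()] and returns the config
#' unchanged when all hold. All violations are reported together, each naming
#' the offending field and value.
#'
#' @param cfg A [disease_config()].
#' @return `cfg`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "disease_config")) {
    stop("`cfg` must be a disease_config object", call. = FALSE)
  }
  problems <- character(0)
  problems <- c(problems, validate_regime(cfg$expanded, "expanded"))
  problems <- c(problems, validate_regime(cfg$normal, "normal"))
  if (!is.finite(cfg$ancestral_repeat) ||
      cfg$ancestral_repeat < cfg$pathogenic_threshold) {
    problems <- c(problems,
                  sprintf("ancestral_repeat must be >= pathogenic_threshold (%g < %g)",
                          cfg$ancestral_repeat, cfg$pathogenic_threshold))
  }
  if (!is.finite(cfg$initial_frequency) ||
      cfg$initial_frequency <= 0 || cfg$initial_frequency >= 1) {
    problems <- c(problems,
                  sprintf("initial_frequency must be in (0,1) (got %g)",
                          cfg$initial_frequency))
  }
  w <- cfg$reproductive_window
  if (length(w) != 2 || !all(is.finite(w)) || w[1] >= w[2]) {
    problems <- c(problems,
                  sprintf("reproductive_window must satisfy min_age < max_age (got %s)",
                          paste(w, collapse = ", ")))
  }
  if (!is.finite(cfg$max_generations) || cfg$max_generations < 1) {
    problems <- c(problems,
                  sprintf("max_generations must be >= 1 (got %s)",
                          cfg$max_generations))
  }
  if (!is.finite(cfg$post_onset_birth_fraction) ||
      cfg$post_onset_birth_fraction < 0 || cfg$post_onset_birth_fraction > 1) {
    problems <- c(problems,
                  sprintf("post_onset_birth_fraction must be in [0,1] (got %g)",
                          cfg$post_onset_birth_fraction))
  }
  if (length(problems) > 0) {
    stop("Invalid disease_config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

#' Zero out all sampling SDs of a configuration
#'
#' Returns a copy of `cfg` in which every standard deviation is 0, so each
#' generation draws the regime means exactly. This mean-path (deterministic)
#' model is useful for analysis: its elimination generation has the closed
#' form `ceiling((ancestral_ao - window_min) / (instability * ao_slope))`.
#'
#' @param cfg A [disease_config()].
#' @return A deterministic `disease_config`.
#' @export
zero_sds <- function(cfg) {
  for (reg in c("expanded", "normal")) {
    for (f in c("fitness_sd", "segregation_sd", "instability_sd", "ao_slope_sd")) {
      cfg[[reg]][[f]] <- 0
    }
  }
  cfg
}

# flat key-value representation used by the JSON config format and manifests
flatten_config <- function(cfg) {
  out <- list(
    name = cfg$name,
    pathogenic_threshold = cfg$pathogenic_threshold,
    ancestral_repeat = cfg$ancestral_repeat,
    ancestral_ao = cfg$ancestral_ao,
    post_onset_birth_fraction = cfg$post_onset_birth_fraction,
    initial_frequency = cfg$initial_frequency,
    max_generations = cfg$max_generations,
    reproductive_window_min = cfg$reproductive_window[1],
    reproductive_window_max = cfg$reproductive_window[2],
    draw_regime = cfg$draw_regime,
    ao_model = cfg$ao_model
  )
  for (reg in c("expanded", "normal")) {
    rp <- cfg[[reg]]
    for (f in names(rp)) {
      out[[paste(reg, f, sep = ".")]] <- rp[[f]]
    }
  }
  out
}

unflatten_config <- function(x) {
  pick_regime <- function(reg) {
    g <- function(f) x[[paste(reg, f, sep = ".")]]
    regime_params(g("fitness_mean"), g("fitness_sd"),
                  g("segregation_mean"), g("segregation_sd"),
                  g("instability_mean"), g("instability_sd"),
                  g("ao_slope_mean"), g("ao_slope_sd"))
  }
  disease_config(
    name = x$name,
    pathogenic_threshold = x$pathogenic_threshold,
    ancestral_repeat = x$ancestral_repeat,
    ancestral_ao = x$ancestral_ao,
    post_onset_birth_fraction = x$post_onset_birth_fraction,
    expanded = pick_regime("expanded"),
    normal = pick_regime("normal"),
    initial_frequency = x$initial_frequency,
    max_generations = x$max_generations,
    reproductive_window = c(x$reproductive_window_min, x$reproductive_window_max),
    draw_regime = x$draw_regime,
    ao_model = if (is.null(x$ao_model)) "regression" else x$ao_model
  )
}

#' Read / write disease configurations as flat JSON
#'
#' The on-disk format is a flat key-value JSON document mirroring the
#' [disease_config()] fields, with regime parameters prefixed
#' `expanded.`/`normal.`. Round-trips exactly.
#'
#' @param cfg A [disease_config()].
#' @param path File path.
#' @return `read_config()` returns a validated `disease_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(flatten_config(cfg), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(unflatten_config(x))
}

#' @export
print.disease_config <- function(x, ...) {
  cat(sprintf("<disease_config: %s>\n", x$name))
  cat(sprintf("  pathogenic threshold: %g repeats; ancestor %g repeats, AO %g y\n",
              x$pathogenic_threshold, x$ancestral_repeat, x$ancestral_ao))
  cat(sprintf("  initial frequency %g, horizon %d generations, window %g-%g y\n",
              x$initial_frequency, x$max_generations,
              x$reproductive_window[1], x$reproductive_window[2]))
  fmt <- function(rp) {
    sprintf("w %.3g (%.3g), k %.3g (%.3g), instability %.3g (%.3g), AO slope %.3g (%.3g)",
            rp$fitness_mean, rp$fitness_sd, rp$segregation_mean, rp$segregation_sd,
            rp$instability_mean, rp$instability_sd, rp$ao_slope_mean, rp$ao_slope_sd)
  }
  cat("  expanded:", fmt(x$expanded), "\n")
  cat("  normal:  ", fmt(x$normal), "\n")
  invisible(x)
}
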