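# shared fixtures and independent oracles, all built in code

uniform_schedule <- function() {
  fertility_schedule(data.frame(age = 12:50, rate = 1), window = c(12, 50))
}

random_schedule <- function() {
  n_ages <- sample(5:40, 1)
  ages <- sort(sample(seq(10, 55, by = 0.5), n_ages))
  rates <- stats::runif(n_ages, 0, 0.2)
  rates[sample(n_ages, 1)] <- rates[sample(n_ages, 1)] + 0.05 # ensure area > 0
  tryCatch(fertility_schedule(data.frame(age = ages, rate = rates)),
           error = function(e) NULL)
}

# brute-force integration of the raw (windowed, linearly interpolated) rate
# table, independent of the package's cumulative machinery: trapezoid over a
# grid containing every table knot, the window bounds and the query point,
# which is exact for a piecewise-linear integrand
oracle_cumfrac <- function(tab, window, age) {
  f <- stats::approxfun(tab$age, tab$rate, rule = 2)
  fw <- function(a) {
    out <- f(a)
    out[a < max(window[1], min(tab$age)) |
          a > min(window[2], max(tab$age))] <- 0
    out
  }
  lo <- max(window[1], min(tab$age))
  hi <- min(window[2], max(tab$age))
  a <- min(max(age, lo), hi)
  grid_to <- function(upper) {
    g <- sort(unique(c(lo, tab$age[tab$age > lo & tab$age < upper], upper)))
    sum(diff(g) * (fw(utils::head(g, -1)) + fw(utils::tail(g, -1))) / 2)
  }
  total <- grid_to(hi)
  part <- if (a <= lo) 0 else grid_to(a)
  min(max(part / total, 0), 1)
}

# closed-form elimination generation for the mean-path (all SDs zero) model:
# AO falls by instability * slope each generation from the ancestral AO until
# it reaches the window minimum
oracle_elimination_generation <- function(ancestral_ao, instability, slope,
                                          window_min = 12) {
  ceiling((ancestral_ao - window_min) / (instability * slope))
}

# minimal valid config for engine property tests
toy_config <- function(ancestral_ao, instability_mean, ao_slope_mean,
                       max_generations = 1000L, ...) {
  disease_config(
    name = "toy",
    pathogenic_threshold = 40,
    ancestral_repeat = 40,
    ancestral_ao = ancestral_ao,
    post_onset_birth_fraction = 0,
    expanded = regime_params(1.0, 0, 0.4, 0, instability_mean, 0,
                             ao_slope_mean, 0),
    normal = regime_params(1.0, 0, 0.4, 0, 0, 0, ao_slope_mean, 0),
    max_generations = max_generations,
    ...
  )
}
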