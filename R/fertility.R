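#' Age-specific fertility schedules
#'
#' A `fertility_schedule` holds a tabulated age -> fertility-rate curve
#' (births/woman/year) together with a reproductive window over which the
#' area under the (linearly interpolated) curve is normalized to 1. The
#' normalized cumulative area is the building block of the anticipation
#' coefficient: it measures how much of a carrier's lifetime reproductive
#' output is still ahead of (or behind) a given age.
#'
#' Rates outside the window contribute nothing to the area. Between
#' tabulated ages the rate is linear, so the cumulative area is piecewise
#' quadratic and exact.
#'
#' @param table A data frame with numeric columns `age` (years, strictly
#'   increasing) and `rate` (non-negative).
#' @param window Two ages `c(min, max)` bounding the fertile period.
#' @return An object of class `fertility_schedule`.
#' @export
#' @examples
#' sched <- fertility_schedule(data.frame(age = 12:50, rate = 1))
#' cumulative_fraction(sched, 31) # 0.5
fertility_schedule <- function(table, window = c(12, 50)) {
  if (!is.data.frame(table) || !all(c("age", "rate") %in% names(table))) {
    stop("`table` must be a data frame with columns `age` and `rate`",
         call. = FALSE)
  }
  if (nrow(table) == 0) stop("fertility table is empty", call. = FALSE)
  if (nrow(table) < 2) {
    stop("fertility table needs at least 2 rows, got ", nrow(table),
         call. = FALSE)
  }
  ages <- as.numeric(table$age)
  rates <- as.numeric(table$rate)
  if (anyNA(ages) || anyNA(rates)) {
    stop("fertility table contains missing values", call. = FALSE)
  }
  if (any(diff(ages) <= 0)) {
    i <- which(diff(ages) <= 0)[1] + 1
    stop("ages must be strictly increasing; violation at age ", ages[i],
         " (row ", i, ")", call. = FALSE)
  }
  if (any(rates < 0)) {
    i <- which(rates < 0)[1]
    stop("negative fertility rate ", rates[i], " at age ", ages[i],
         call. = FALSE)
  }
  window <- as.numeric(window)
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("`window` must be c(min_age, max_age) with min < max", call. = FALSE)
  }

  # knots of the effective (windowed) rate curve: tabulated ages clipped to
  # the window, plus the window bounds where the table spans them
  rate_at <- function(a) {
    r <- stats::approx(ages, rates, xout = a, rule = 1)$y
    r[is.na(r)] <- 0
    r
  }
  kx <- sort(unique(c(ages[ages >= window[1] & ages <= window[2]],
                      pmax(pmin(window, max(ages)), min(ages)))))
  kx <- kx[kx >= window[1] & kx <= window[2]]
  if (length(kx) < 2) stop("fertility table does not overlap the window",
                           call. = FALSE)
  ky <- rate_at(kx)
  # cumulative exact trapezoid areas at the knots
  seg <- diff(kx) * (utils::head(ky, -1) + utils::tail(ky, -1)) / 2
  kcum <- c(0, cumsum(seg))
  total <- kcum[length(kcum)]
  if (total <= 0) {
    stop("total fertility area over the window is 0; cannot normalize",
         call. = FALSE)
  }
  structure(
    list(ages = ages, rates = rates, window = window,
         knot_age = kx, knot_rate = ky, knot_cum = kcum, total_area = total),
    class = "fertility_schedule"
  )
}

#' Deterministic synthetic fertility schedule
#'
#' Builds a unimodal schedule on integer ages 12..50 with a Gaussian-bump
#' shape: peak near the typical age at childbearing, near-zero rates at both
#' window edges. It emulates the shape of the 2019 EUROSTAT age-specific
#' fertility curve for European women and is the packaged default, so no
#' external data download is required; any real single-year-of-age schedule
#' can be supplied instead via [read_fertility_csv()].
#'
#' @param peak_age Age of maximum fertility, strictly inside (12, 50).
#' @param spread Width (SD, years) of the bump; must be positive.
#' @param peak_rate Rate at the peak (births/woman/year); the scale cancels
#'   in the normalization and only matters for plotting.
#' @return A [fertility_schedule()] on ages 12..50.
#' @export
#' @examples
#' s <- make_synthetic_schedule(30, 6)
make_synthetic_schedule <- function(peak_age = 30, spread = 6,
                                    peak_rate = 0.11) {
  if (!is.finite(peak_age) || peak_age <= 12 || peak_age >= 50) {
    stop("peak_age must lie strictly inside the (12, 50) window; got ",
         peak_age, call. = FALSE)
  }
  if (!is.finite(spread) || spread <= 0) {
    stop("spread must be > 0; got ", spread, call. = FALSE)
  }
  age <- 12:50
  rate <- peak_rate * exp(-0.5 * ((age - peak_age) / spread)^2)
  fertility_schedule(tibble::tibble(age = age, rate = rate),
                     window = c(12, 50))
}

#' Load a fertility schedule from CSV
#'
#' Expects a header `age,rate` and one row per single year of age, e.g. a
#' EUROSTAT single-year-of-age extract.
#'
#' @param path CSV file path.
#' @inheritParams fertility_schedule
#' @return A [fertility_schedule()].
#' @export
read_fertility_csv <- function(path, window = c(12, 50)) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_double(), rate = readr::col_double()
  ))
  fertility_schedule(tab, window = window)
}

#' Packaged synthetic fertility schedule
#'
#' The default schedule used throughout: `make_synthetic_schedule(30, 6)`.
#' A CSV copy ships in `inst/extdata/fertility_synthetic.csv`.
#'
#' @return A [fertility_schedule()].
#' @export
default_schedule <- function() make_synthetic_schedule(30, 6)

#' Cumulative normalized fertility fraction
#'
#' Fraction of the normalized fertility area accumulated from the window
#' start up to `age`. Piecewise-quadratic (exact integral of the linearly
#' interpolated rates); 0 at the window start, 1 at the window end; ages
#' outside the window clamp. Monotone non-decreasing in `age`. Vectorized
#' over `age`.
#'
#' @param s A [fertility_schedule()].
#' @param age Age(s), years.
#' @return Fractions in `[0, 1]`.
#' @export
cumulative_fraction <- function(s, age) {
  stopifnot(inherits(s, "fertility_schedule"))
  kx <- s$knot_age
  a <- pmin(pmax(as.numeric(age), kx[1]), kx[length(kx)])
  i <- findInterval(a, kx, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(kx) - 1L)
  dx <- a - kx[i]
  h <- kx[i + 1L] - kx[i]
  slope <- (s$knot_rate[i + 1L] - s$knot_rate[i]) / h
  area <- s$knot_cum[i] + s$knot_rate[i] * dx + slope * dx^2 / 2
  frac <- area / s$total_area
  out <- pmin(pmax(frac, 0), 1)
  out[age <= s$window[1]] <- 0
  out[age >= s$window[2]] <- 1
  out
}

#' Anticipation coefficient
#'
#' Maps a carrier's age at onset (AO) to the fraction of reproductive output
#' the lineage retains in that generation: 0 when onset precedes the fertile
#' window (no reproduction), 1 when onset follows it (reproduction
#' unaffected), and in between the cumulative normalized fertility fraction
#' up to the AO plus the fraction of children observed to be born after
#' parental onset, clamped to 1.
#'
#' This additive-then-clamp form is a documented reconstruction of the
#' coefficient: it follows directly from the area-normalization definition
#' of the fertility contribution and the stated post-onset birth fractions
#' (8% for ATXN2, 8.3% for ATXN3), but the original closed-form expression
#' was published only in supplementary material not reproduced here.
#' Monotone non-decreasing in `ao`. Vectorized over `ao`.
#'
#' @param s A [fertility_schedule()].
#' @param ao Age(s) at onset, years.
#' @param post_onset_birth_fraction Fraction in `[0, 1]` added to the
#'   cumulative fertility fraction before clamping.
#' @return Coefficients in `[0, 1]`.
#' @export
#' @examples
#' s <- make_synthetic_schedule(30, 6)
#' anticipation_coefficient(s, 12, 0.08) # exactly 0
#' anticipation_coefficient(s, 50, 0.08) # exactly 1
anticipation_coefficient <- function(s, ao, post_onset_birth_fraction = 0) {
  stopifnot(inherits(s, "fertility_schedule"))
  f <- post_onset_birth_fraction
  if (!is.finite(f) || f < 0 || f > 1) {
    stop("post_onset_birth_fraction must be in [0, 1]; got ", f,
         call. = FALSE)
  }
  out <- pmin(1, cumulative_fraction(s, ao) + f)
  out[ao <= s$window[1]] <- 0
  out[ao >= s$window[2]] <- 1
  out
}

#' @export
print.fertility_schedule <- function(x, ...) {
  cat(sprintf("<fertility_schedule: %d tabulated ages %g-%g, window %g-%g, area normalized to 1>\n",
              length(x$ages), min(x$ages), max(x$ages),
              x$window[1], x$window[2]))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.fertility_schedule <- function(x, ...) {
  tibble::tibble(age = x$ages, rate = x$rates)
}

#' Plot a fertility schedule
#'
#' @param object A [fertility_schedule()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fertility_schedule <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$window, linetype = "dashed") +
    ggplot2::labs(x = "Age (years)", y = "Fertility rate (births/woman/year)")
}
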