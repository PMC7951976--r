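#' Piecewise-linear gene trend
#'
#' A continuous piecewise-linear mean program for one gene over a time course:
#' an expression level at day 0, ordered breakpoints, and one slope per
#' segment (normalized-expression units per day). Negative values are clamped
#' at zero when the trend is evaluated.
#'
#' @param baseline Expression at day 0 (>= 0).
#' @param breakpoints Strictly increasing day values inside \code{t_range}.
#' @param slopes One slope per segment (\code{length(breakpoints) + 1}).
#' @param t_range Time span covered, default \code{c(0, 42)}.
#' @return An object of class \code{trend_spec}.
#' @export
trend_spec <- function(baseline, breakpoints = numeric(0), slopes = 0,
                       t_range = c(0, 42)) {
  breakpoints <- as.numeric(breakpoints)
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing")
  if (length(breakpoints) &&
      (min(breakpoints) <= t_range[1] || max(breakpoints) >= t_range[2]))
    stop("breakpoints must lie strictly inside t_range")
  if (length(slopes) != length(breakpoints) + 1)
    stop("need one slope per segment")
  if (baseline < 0) stop("baseline must be >= 0")
  structure(list(baseline = baseline, breakpoints = breakpoints,
                 slopes = as.numeric(slopes), t_range = as.numeric(t_range)),
            class = "trend_spec")
}

#' Evaluate a piecewise-linear trend
#'
#' @param spec A [trend_spec()].
#' @param times Day values (extended linearly beyond \code{t_range}).
#' @return Numeric vector of mean expression values, clamped at 0.
#' @export
trend_values <- function(spec, times) {
  knots <- c(spec$t_range[1], spec$breakpoints)
  # value at the start of each segment
  seg_len <- diff(c(knots, Inf))
  starts <- spec$baseline +
    cumsum(c(0, spec$slopes[-length(spec$slopes)] * diff(knots)))
  idx <- findInterval(times, knots, all.inside = FALSE)
  idx[idx < 1] <- 1L
  pmax(0, starts[idx] + spec$slopes[idx] * (times - knots[idx]))
}

#' Time-warp function
#'
#' A piecewise-constant tempo factor a(t) > 0 over test time, with warp map
#' w(t) = integral of a from 0 to t. The warped condition expresses at test
#' time t what the reference expresses at time w(t): a factor above 1 means
#' the test condition runs ahead of the reference.
#'
#' @param rates Positive tempo factors, one per interval.
#' @param breaks Increasing interval boundaries (length \code{length(rates)-1});
#'   the last rate extends to infinity.
#' @return An object of class \code{warp_function}.
#' @examples
#' w <- warp_function(c(1.7, 1), 16)  # 1.7x tempo for the first 16 days
#' warp_map(w, c(10, 20))
#' @export
warp_function <- function(rates, breaks = numeric(0)) {
  rates <- as.numeric(rates); breaks <- as.numeric(breaks)
  if (any(rates <= 0)) stop("tempo factors must be > 0")
  if (length(breaks) != length(rates) - 1)
    stop("need length(rates) - 1 break positions")
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0))
    stop("breaks must be positive and strictly increasing")
  # cumulative integral of a at each break
  cum <- c(0, cumsum(rates[-length(rates)] * diff(c(0, breaks))))
  structure(list(rates = rates, breaks = breaks, cum = cum),
            class = "warp_function")
}

#' @rdname warp_function
#' @param warp A [warp_function()].
#' @param t Test-time day values.
#' @return \code{warp_map}: reference-time values w(t).
#' @export
warp_map <- function(warp, t) {
  knots <- c(0, warp$breaks)
  idx <- findInterval(t, knots)
  idx[idx < 1] <- 1L
  warp$cum[idx] + warp$rates[idx] * (t - knots[idx])
}

#' @rdname warp_function
#' @param tau Reference-time day values.
#' @return \code{warp_inverse}: test-time values t with w(t) = tau.
#' @export
warp_inverse <- function(warp, tau) {
  knots <- c(0, warp$breaks)
  idx <- findInterval(tau, warp$cum)
  idx[idx < 1] <- 1L
  knots[idx] + (tau - warp$cum[idx]) / warp$rates[idx]
}

#' Apply a time warp to a trend
#'
#' Returns the trend the warped condition follows: mu_test(t) =
#' mu_ref(w(t)). Breakpoints map through the inverse warp and slopes scale by
#' the local tempo factor; tempo-change points themselves become breakpoints
#' of the warped trend.
#'
#' @param spec A [trend_spec()].
#' @param warp A [warp_function()].
#' @return A new [trend_spec()] on the same \code{t_range}.
#' @export
warp_trend <- function(spec, warp) {
  t0 <- spec$t_range[1]; t1 <- spec$t_range[2]
  bp <- sort(unique(c(warp_inverse(warp, spec$breakpoints), warp$breaks)))
  bp <- bp[bp > t0 & bp < t1]
  knots <- c(t0, bp, t1)
  vals <- trend_values(spec, warp_map(warp, knots))
  slopes <- diff(vals) / diff(knots)
  # slope beyond the last knot continues the local warped rate
  trend_spec(baseline = vals[1], breakpoints = bp, slopes = slopes,
             t_range = spec$t_range)
}

#' Evaluate a set of trends on a grid
#'
#' Convenience for noise-free analyses: the genes x times matrix of trend
#' means.
#'
#' @param specs List of [trend_spec()] (names become rownames).
#' @param times Day values (columns).
#' @return Numeric matrix, genes x times.
#' @export
trend_matrix <- function(specs, times) {
  out <- t(vapply(specs, trend_values, numeric(length(times)), times = times))
  colnames(out) <- as.character(times)
  out
}
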