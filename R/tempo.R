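#' Trend events of a segmented fit
#'
#' Extracts the two event times the tempo analysis relies on: the start of
#' the first increasing segment not preceded by a decreasing segment (the
#' up-trend start), and the first peak, defined as the breakpoint between an
#' increasing segment and a following flat-or-decreasing segment. If several
#' qualifying structures exist only the first is considered.
#'
#' @param fit A [fit_segmented()] result.
#' @return List of class \code{trend_events}: \code{gene_id},
#'   \code{up_start}, \code{up_slope}, \code{up_duration}, \code{peak_time}
#'   (each \code{NA} when absent), \code{max_fitted}, \code{t_min}.
#' @export
extract_events <- function(fit) {
  stopifnot(inherits(fit, "segfit"))
  dir <- fit$directions
  starts <- c(fit$t_range[1], fit$breakpoints)
  ends <- c(fit$breakpoints, fit$t_range[2])
  up_start <- up_slope <- up_duration <- NA_real_
  up_idx <- which(dir == "up")
  if (length(up_idx)) {
    first_down <- if (any(dir == "down")) which(dir == "down")[1] else Inf
    ok <- up_idx[up_idx < first_down]
    if (length(ok)) {
      i <- ok[1]
      up_start <- starts[i]; up_slope <- fit$slopes[i]
      up_duration <- ends[i] - starts[i]
    }
  }
  peak_time <- NA_real_
  if (length(dir) > 1) {
    for (i in seq_len(length(dir) - 1)) {
      if (dir[i] == "up" && dir[i + 1] %in% c("flat", "down")) {
        peak_time <- ends[i]
        break
      }
    }
  }
  structure(list(gene_id = fit$gene_id, up_start = up_start,
                 up_slope = up_slope, up_duration = up_duration,
                 peak_time = peak_time, max_fitted = max(fit$fitted.values),
                 t_min = fit$t_range[1]),
            class = "trend_events")
}

#' @export
print.trend_events <- function(x, ...) {
  cat("trend_events", if (!is.null(x$gene_id)) paste0("[", x$gene_id, "]"),
      ": up_start =", x$up_start, ", peak =", x$peak_time,
      ", max fitted =", signif(x$max_fitted, 4), "\n")
  invisible(x)
}

#' Event table for a list of fits
#'
#' @param fits Named list of [fit_segmented()] results.
#' @return Data frame with one row per gene: \code{gene_id}, \code{up_start},
#'   \code{up_slope}, \code{up_duration}, \code{peak_time},
#'   \code{max_fitted}.
#' @export
events_table <- function(fits) {
  ev <- lapply(fits, extract_events)
  data.frame(gene_id = vapply(ev, function(e)
               if (is.null(e$gene_id)) NA_character_ else e$gene_id,
               character(1)),
             up_start = vapply(ev, `[[`, numeric(1), "up_start"),
             up_slope = vapply(ev, `[[`, numeric(1), "up_slope"),
             up_duration = vapply(ev, `[[`, numeric(1), "up_duration"),
             peak_time = vapply(ev, `[[`, numeric(1), "peak_time"),
             max_fitted = vapply(ev, `[[`, numeric(1), "max_fitted"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Early/Late-Up classification of one gene
#'
#' A test gene is called early when its qualifying up-trend starts at least
#' \code{min_lead} days before the reference gene's, and its up-slope is at
#' least \code{slope_ratio} times the slope of the reference segment
#' containing the test start time (guarding against reference segments that
#' are labeled flat but fitted with an appreciable positive slope). Late is
#' the role-reversed rule. Genes up-trending from day 0 in both conditions
#' are excluded from the early/late tabulation (returned as "n/a").
#'
#' @param test_events,ref_events [extract_events()] results.
#' @param test_fit,ref_fit The corresponding [fit_segmented()] objects.
#' @param min_lead Required lead in days.
#' @param slope_ratio Required slope multiple over the containing reference
#'   segment.
#' @return One of "early", "late", "unchanged", "n/a".
#' @export
classify_early_up <- function(test_events, ref_events, test_fit, ref_fit,
                              min_lead = 2, slope_ratio = 5) {
  te <- test_events; re <- ref_events
  if (is.na(te$up_start) || is.na(re$up_start)) return("n/a")
  if (te$up_start == 0 && re$up_start == 0) return("n/a")
  if (re$up_start - te$up_start >= min_lead) {
    ref_seg_slope <- ref_fit$slopes[segment_at(ref_fit, te$up_start)]
    if (te$up_slope >= slope_ratio * ref_seg_slope) return("early")
  }
  if (te$up_start - re$up_start >= min_lead) {
    test_seg_slope <- test_fit$slopes[segment_at(test_fit, re$up_start)]
    if (re$up_slope >= slope_ratio * test_seg_slope) return("late")
  }
  "unchanged"
}

#' Early/Late-Peak classification of one gene
#'
#' Early when the test peak precedes the reference peak by at least
#' \code{min_lead} days; late via role reversal; "n/a" when either peak is
#' absent.
#'
#' @inheritParams classify_early_up
#' @return One of "early", "late", "unchanged", "n/a".
#' @export
classify_early_peak <- function(test_events, ref_events, min_lead = 2) {
  if (is.na(test_events$peak_time) || is.na(ref_events$peak_time))
    return("n/a")
  d <- ref_events$peak_time - test_events$peak_time
  if (d >= min_lead) "early" else if (-d >= min_lead) "late" else "unchanged"
}

#' Differential-expression classification of one gene
#'
#' DE-up when the maximum fitted value of the test gene plus \code{bias} is
#' at least \code{fold} times the maximum fitted value of the reference gene
#' plus \code{bias}; DE-down via role reversal. The bias keeps very lowly
#' expressed genes from appearing DE through multiplicatively large but
#' absolutely small differences.
#'
#' @param test_max,ref_max Maximum fitted values (or [extract_events()]
#'   results, from which they are taken).
#' @param fold Required fold change.
#' @param bias Additive stabilizer.
#' @return One of "up", "down", "none".
#' @export
classify_de <- function(test_max, ref_max, fold = 3, bias = 1) {
  if (inherits(test_max, "trend_events")) test_max <- test_max$max_fitted
  if (inherits(ref_max, "trend_events")) ref_max <- ref_max$max_fitted
  if (test_max + bias >= fold * (ref_max + bias)) "up"
  else if (ref_max + bias >= fold * (test_max + bias)) "down"
  else "none"
}

#' Classify all shared genes of two fitted conditions
#'
#' @param test_fits,ref_fits Named lists of [fit_segmented()] results; genes
#'   are matched by name.
#' @param min_lead,slope_ratio See [classify_early_up()].
#' @param fold,bias See [classify_de()].
#' @return Data frame with per-gene \code{up_call}, \code{peak_call},
#'   \code{de_call} and supporting numbers (leads, max fitted values).
#' @export
classify_tempo <- function(test_fits, ref_fits, min_lead = 2, slope_ratio = 5,
                           fold = 3, bias = 1) {
  genes <- intersect(names(test_fits), names(ref_fits))
  rows <- lapply(genes, function(g) {
    te <- extract_events(test_fits[[g]]); re <- extract_events(ref_fits[[g]])
    data.frame(gene_id = g,
               up_call = classify_early_up(te, re, test_fits[[g]],
                                           ref_fits[[g]], min_lead,
                                           slope_ratio),
               peak_call = classify_early_peak(te, re, min_lead),
               de_call = classify_de(te, re, fold, bias),
               up_lead = re$up_start - te$up_start,
               peak_lead = re$peak_time - te$peak_time,
               test_max = te$max_fitted, ref_max = re$max_fitted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Acceleration-factor point estimates from shared events
#'
#' For each gene with peaks in both conditions, the estimate is the ratio of
#' the reference peak time to the test peak time (the peak is preferred as
#' the more accurate marker of regulatory change). Genes without shared
#' peaks contribute the ratio of up-trend start times, excluding genes that
#' start up-trending at day 0 in either condition. A ratio of 2 means the
#' gene runs twice as fast in the test condition.
#'
#' @param test_events,ref_events [events_table()] data frames.
#' @return Data frame: \code{gene_id}, \code{test_time} (event time in the
#'   test condition), \code{ratio}, \code{source} ("peak" or "up_start").
#' @export
acceleration_points <- function(test_events, ref_events) {
  m <- merge(test_events, ref_events, by = "gene_id",
             suffixes = c(".test", ".ref"))
  peak_ok <- !is.na(m$peak_time.test) & !is.na(m$peak_time.ref) &
    m$peak_time.test > 0
  up_ok <- !peak_ok & !is.na(m$up_start.test) & !is.na(m$up_start.ref) &
    m$up_start.test > 0 & m$up_start.ref > 0
  out <- rbind(
    data.frame(gene_id = m$gene_id[peak_ok],
               test_time = m$peak_time.test[peak_ok],
               ratio = m$peak_time.ref[peak_ok] / m$peak_time.test[peak_ok],
               source = rep("peak", sum(peak_ok)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = m$gene_id[up_ok],
               test_time = m$up_start.test[up_ok],
               ratio = m$up_start.ref[up_ok] / m$up_start.test[up_ok],
               source = rep("up_start", sum(up_ok)),
               stringsAsFactors = FALSE))
  if (!nrow(out))
    stop("no genes with shared events; a larger gene panel is needed")
  out[order(out$test_time), , drop = FALSE]
}

#' Smooth acceleration point estimates into a continuous curve
#'
#' Least-squares basis-spline regression of the event-time ratios against
#' event time in the test condition. Ratios are winsorized at the 1st/99th
#' percentiles before smoothing since ratio estimators explode for events
#' near day 0. The summary statistic is the median of the smoothed curve
#' evaluated on a uniform grid over the first \code{window} days.
#'
#' @param points [acceleration_points()] result.
#' @param df Spline degrees of freedom.
#' @param window Test-event-time window (days) for the median, default
#'   \code{c(0, 16)}.
#' @param winsor Quantile pair for winsorizing ratios; \code{NULL} disables.
#' @return Object of class \code{accel_curve}: \code{points}, \code{curve}
#'   (data frame \code{test_time}, \code{a}), \code{window_median},
#'   \code{window}.
#' @export
smooth_acceleration <- function(points, df = 4, window = c(0, 16),
                                winsor = c(0.01, 0.99)) {
  stopifnot(nrow(points) >= 1)
  r <- points$ratio; tt <- points$test_time
  if (!is.null(winsor) && length(r) > 2) {
    q <- stats::quantile(r, winsor, type = 7, names = FALSE)
    r <- pmin(pmax(r, q[1]), q[2])
  }
  span <- diff(range(tt))
  degenerate <- nrow(points) < 10 || span < 5
  if (degenerate) {
    warning("degenerate point set; constant acceleration fit")
    fitfun <- function(x) rep(mean(r), length(x))
  } else {
    fit <- stats::lm(r ~ splines::bs(tt, df = df))
    fitfun <- function(x) unname(stats::predict(fit, data.frame(tt = x)))
  }
  grid <- seq(min(tt), max(tt), length.out = 512)
  curve <- data.frame(test_time = grid, a = fitfun(grid))
  win <- grid >= window[1] & grid <= window[2]
  window_median <- if (any(win)) stats::median(curve$a[win]) else NA_real_
  structure(list(points = points, curve = curve,
                 window_median = window_median, window = window, df = df),
            class = "accel_curve")
}

#' @export
print.accel_curve <- function(x, ...) {
  cat("accel_curve:", nrow(x$points), "point estimates\n")
  cat(sprintf("  median acceleration over days %g-%g: %.3f\n",
              x$window[1], x$window[2], x$window_median))
  invisible(x)
}

#' @export
plot.accel_curve <- function(x, ...) {
  graphics::plot(x$points$test_time, x$points$ratio, xlab = "test event day",
                 ylab = "acceleration factor", col = "grey50", ...)
  graphics::lines(x$curve$test_time, x$curve$a, col = 2, lwd = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
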