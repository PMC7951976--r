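#' Most dynamic genes by coefficient of variation of fitted trends
#'
#' Per gene and mixture, the CV (sd/mean) of the fitted trend values
#' measures temporal dynamics; the highest CV across mixtures is each
#' gene's score, and the top \code{n} genes are retained. Genes with
#' non-positive mean fitted values in a mixture are skipped for that
#' mixture.
#'
#' @param fits_by_mixture Named list (mixture -> named list of
#'   [fit_segmented()] results), or a single fit list.
#' @param n Panel size.
#' @return Character vector of gene ids (length <= n), highest score first.
#' @export
dynamic_genes <- function(fits_by_mixture, n = 2000) {
  if (length(fits_by_mixture) && inherits(fits_by_mixture[[1]], "segfit"))
    fits_by_mixture <- list(fits_by_mixture)
  scores <- list()
  for (fits in fits_by_mixture) {
    cv <- vapply(fits, function(f) {
      fv <- f$fitted.values
      m <- mean(fv)
      if (!is.finite(m) || m <= 0) return(NA_real_)
      stats::sd(fv) / m
    }, numeric(1))
    scores[[length(scores) + 1L]] <- cv
  }
  genes <- unique(unlist(lapply(scores, names)))
  best <- vapply(genes, function(g) {
    v <- unlist(lapply(scores, function(s) s[g]))
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
  best <- best[!is.na(best)]
  names(utils::head(sort(best, decreasing = TRUE), n))
}

avg_by_day <- function(counts, days) {
  ud <- sort(unique(days))
  out <- vapply(ud, function(d)
    rowMeans(counts[, days == d, drop = FALSE]), numeric(nrow(counts)))
  colnames(out) <- as.character(ud)
  out
}

#' Day-pair Spearman correlation map between two conditions
#'
#' Within-day biological replicates are averaged to one profile per day;
#' Spearman correlations over the gene panel are computed for every
#' (reference day, test day) pair. Raw expected counts are appropriate
#' input since rank correlation makes normalization unnecessary.
#'
#' @param ref,test [species_matrix()] objects (or lists with \code{counts}
#'   and \code{samples}).
#' @param panel Gene ids to correlate over (present in both).
#' @return Object of class \code{corr_map}: \code{map} (reference days x
#'   test days; NA where a day profile is constant), \code{ref_days},
#'   \code{test_days}, \code{panel}.
#' @export
correlation_map <- function(ref, test, panel) {
  panel <- intersect(panel, intersect(rownames(ref$counts),
                                      rownames(test$counts)))
  if (!length(panel)) stop("empty gene panel after intersection")
  ar <- avg_by_day(ref$counts[panel, , drop = FALSE], ref$samples$day)
  at <- avg_by_day(test$counts[panel, , drop = FALSE], test$samples$day)
  map <- suppressWarnings(stats::cor(ar, at, method = "spearman"))
  structure(list(map = map,
                 ref_days = as.numeric(colnames(ar)),
                 test_days = as.numeric(colnames(at)),
                 panel = panel),
            class = "corr_map")
}

#' @export
print.corr_map <- function(x, ...) {
  cat("corr_map:", length(x$ref_days), "reference days x",
      length(x$test_days), "test days over", length(x$panel), "genes\n")
  invisible(x)
}

# squared perpendicular distance from points (x, y) to the two-piece line
# through the origin with slopes th over the x-axis break at b
perp_dist2 <- function(x, y, th, b) {
  p1 <- c(b, b * th[1])
  # segment (0,0)-(p1)
  d1 <- c(b, b * th[1]); l1 <- sum(d1^2)
  tt <- pmin(pmax((x * d1[1] + y * d1[2]) / l1, 0), 1)
  dist1 <- (x - tt * d1[1])^2 + (y - tt * d1[2])^2
  # ray from p1 with direction (1, th2)
  d2 <- c(1, th[2]); l2 <- sum(d2^2)
  uu <- pmax(((x - p1[1]) * d2[1] + (y - p1[2]) * d2[2]) / l2, 0)
  dist2 <- (x - p1[1] - uu * d2[1])^2 + (y - p1[2] - uu * d2[2])^2
  pmin(dist1, dist2)
}

#' Correlation-weighted segmented acceleration fit
#'
#' Estimates acceleration from a day-pair correlation map by weighted
#' total-least-squares segmented regression: minimize the sum over day
#' pairs of squared correlation times squared perpendicular distance from
#' the pair (test day, reference day) to a two-piece line through (0, 0)
#' with a fixed breakpoint (default test day 16). Slopes are
#' box-constrained to \code{bounds} and found by L-BFGS-B from initial
#' slopes 1. The first-segment slope, in reference days per test day, is
#' the acceleration factor over the early course. Standard errors come
#' from bootstrapping panel genes with replacement and recomputing map and
#' fit.
#'
#' @param map A [correlation_map()] result.
#' @param breakpoint Fixed breakpoint on the test-day axis.
#' @param bounds Slope box constraints, default \code{c(1/10, 10)}.
#' @param n_boot Bootstrap replicates (0 to skip); requires \code{ref},
#'   \code{test}.
#' @param ref,test The matrices the map was computed from (for the
#'   bootstrap).
#' @param seed Seed for the bootstrap.
#' @param censor_saturated Drop day pairs whose correlation ridge saturates
#'   at the map boundary before fitting (default TRUE). When one condition's
#'   program has run past the span the other condition covers, its days
#'   correlate best with the boundary day of the other axis; those pairs
#'   carry no tempo information and only flatten the fit. A test day whose
#'   best-correlated reference day is the final reference day is censored
#'   (and symmetrically for reference days).
#' @return Object of class \code{corr_accel}: \code{slopes}, \code{se},
#'   \code{objective}, \code{convergence}, \code{at_bound},
#'   \code{breakpoint}, \code{bounds}.
#' @export
fit_correlation_acceleration <- function(map, breakpoint = 16,
                                         bounds = c(1 / 10, 10),
                                         n_boot = 0, ref = NULL, test = NULL,
                                         seed = 1, censor_saturated = TRUE) {
  stopifnot(inherits(map, "corr_map"))
  if (length(map$ref_days) < 5 || length(map$test_days) < 5)
    stop("need at least 5 days per axis")
  fit_one <- function(M) {
    pts <- expand.grid(ti = map$ref_days, tj = map$test_days)
    w <- as.vector(M)^2
    ok <- is.finite(w)
    if (censor_saturated) {
      am_col <- apply(M, 2, function(v)
        if (all(is.na(v))) NA_integer_ else which.max(v))
      am_row <- apply(M, 1, function(v)
        if (all(is.na(v))) NA_integer_ else which.max(v))
      keep_col <- !is.na(am_col) & am_col < nrow(M)
      keep_row <- !is.na(am_row) & am_row < ncol(M)
      ok <- ok & rep(keep_col, each = nrow(M)) & rep(keep_row, ncol(M))
    }
    x <- pts$tj[ok]; y <- pts$ti[ok]; w <- w[ok]
    obj <- function(th) sum(w * perp_dist2(x, y, th, breakpoint))
    o <- stats::optim(c(1, 1), obj, method = "L-BFGS-B",
                      lower = bounds[1], upper = bounds[2])
    o
  }
  o <- fit_one(map$map)
  if (o$convergence != 0)
    warning("optimizer did not converge; reporting best iterate")
  se <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (is.null(ref) || is.null(test)) {
      warning("bootstrap requires ref and test data; skipping")
    } else {
      set.seed(seed)
      ar <- avg_by_day(ref$counts[map$panel, , drop = FALSE],
                       ref$samples$day)
      at <- avg_by_day(test$counts[map$panel, , drop = FALSE],
                       test$samples$day)
      sl <- matrix(NA_real_, n_boot, 2)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(length(map$panel), replace = TRUE)
        M <- suppressWarnings(stats::cor(ar[idx, , drop = FALSE],
                                         at[idx, , drop = FALSE],
                                         method = "spearman"))
        sl[b, ] <- fit_one(M)$par
      }
      se <- apply(sl, 2, stats::sd)
    }
  }
  at_bound <- o$par <= bounds[1] + 1e-6 | o$par >= bounds[2] - 1e-6
  structure(list(slopes = o$par, se = se, objective = o$value,
                 convergence = o$convergence, at_bound = at_bound,
                 breakpoint = breakpoint, bounds = bounds, n_boot = n_boot),
            class = "corr_accel")
}

#' @export
print.corr_accel <- function(x, ...) {
  cat(sprintf(
    "corr_accel: slope %.3f (days 0-%g), %.3f after; SE %.3g / %.3g\n",
    x$slopes[1], x$breakpoint, x$slopes[2], x$se[1], x$se[2]))
  if (any(x$at_bound)) cat("  note: slope pinned at a box constraint\n")
  invisible(x)
}
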