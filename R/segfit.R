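#' Continuous piecewise-linear (segmented) trend regression
#'
#' Fits gene expression against time with a connected piecewise-linear curve.
#' Breakpoint candidates are restricted to observed days; for each breakpoint
#' count k = 0..max_segments-1 the least-squares fit is found (exhaustively
#' for k <= 2, by greedy insertion with local refinement above), subject to
#' every segment containing at least \code{min_points} observations
#' (replicates at a day count individually; observations at a breakpoint
#' count for both adjacent segments). The breakpoint count is selected by
#' BIC with 2 + 2k parameters, ties resolved toward fewer segments. Each
#' segment is labeled up/down when a t-test on its slope rejects at
#' \code{alpha}, flat otherwise.
#'
#' @param y Numeric expression values (normalized expected counts).
#' @param times Day of each observation (same length as \code{y}).
#' @param max_segments Maximum number of segments (default 5, i.e. up to 4
#'   breakpoints).
#' @param min_points Minimum observations per segment (default 5; the sorted
#'   sample preset uses 2).
#' @param alpha Significance threshold for the slope direction test.
#' @param gene_id Optional label carried in the result.
#' @return An object of class \code{segfit} with elements \code{breakpoints},
#'   \code{slopes}, \code{directions}, \code{slope_p}, \code{coefficients},
#'   \code{fitted.values}, \code{residuals}, \code{rss}, \code{bic}
#'   (one value per candidate breakpoint count), \code{k}, \code{times},
#'   \code{y}.
#' @seealso [fit_all()] for fitting many genes at once.
#' @examples
#' t <- rep(0:21, each = 3)
#' y <- pmax(0, t - 8) * 2 + rnorm(length(t), sd = 0.1)
#' fit <- fit_segmented(y, t)
#' fit$breakpoints
#' @export
fit_segmented <- function(y, times, max_segments = 5, min_points = 5,
                          alpha = 0.1, gene_id = NULL) {
  Y <- matrix(as.numeric(y), ncol = 1)
  colnames(Y) <- if (is.null(gene_id)) "gene" else gene_id
  fit_engine(Y, times, max_segments, min_points, alpha)[[1]]
}

#' Fit segmented trends to all genes of a matrix
#'
#' Independent per-gene fits sharing the time grid; deterministic given
#' inputs. Genes whose fit fails are skipped with a message.
#'
#' @param values Genes x samples matrix of normalized expression, or a
#'   \code{normalized_matrix}.
#' @param days Day of each sample (taken from the object when omitted).
#' @inheritParams fit_segmented
#' @return Named list of [fit_segmented()] results.
#' @export
fit_all <- function(values, days = NULL, max_segments = 5, min_points = 5,
                    alpha = 0.1) {
  if (inherits(values, "normalized_matrix")) {
    if (is.null(days)) days <- values$samples$day
    values <- values$values
  }
  if (is.null(days)) stop("days required")
  fit_engine(t(values), days, max_segments, min_points, alpha)
}

#' Genes eligible for trend fitting
#'
#' A gene is fitted when the 0.8 quantile of its normalized expression is
#' strictly above a threshold (default 20) in at least one mixture.
#'
#' @param norm_list Named list (one entry per mixture) of genes x samples
#'   matrices or \code{normalized_matrix} objects sharing a gene axis.
#' @param quantile Quantile level (linear-interpolation convention).
#' @param threshold Expression the quantile must exceed (strict).
#' @return Character vector of gene ids.
#' @export
trendy_gene_filter <- function(norm_list, quantile = 0.8, threshold = 20) {
  if (!is.list(norm_list) || inherits(norm_list, "normalized_matrix"))
    norm_list <- list(norm_list)
  keep <- NULL
  for (nm in norm_list) {
    v <- if (inherits(nm, "normalized_matrix")) nm$values else as.matrix(nm)
    q <- apply(v, 1, stats::quantile, probs = quantile, type = 7,
               names = FALSE)
    ok <- rownames(v)[q > threshold]
    keep <- union(keep, ok)
  }
  keep
}

# ---- engine ----------------------------------------------------------------

# observations per segment, breakpoints inclusive on both sides
seg_counts <- function(times_sorted, bp, t0, t1) {
  lo <- c(t0, bp); hi <- c(bp, t1)
  vapply(seq_along(lo), function(j)
    sum(times_sorted >= lo[j] & times_sorted <= hi[j]), integer(1))
}

seg_design <- function(t, bp, hinges = NULL, cand = NULL) {
  if (!is.null(hinges)) {
    idx <- match(bp, cand)
    cbind(1, t, hinges[, idx, drop = FALSE])
  } else {
    X <- cbind(1, t)
    for (b in bp) X <- cbind(X, pmax(t - b, 0))
    X
  }
}

# Y: samples x genes. Returns list of segfit, one per column of Y.
fit_engine <- function(Y, times, max_segments = 5, min_points = 5,
                       alpha = 0.1) {
  stopifnot(max_segments >= 1, min_points >= 1, nrow(Y) == length(times))
  ord <- order(times)
  t_s <- times[ord]; Ys <- Y[ord, , drop = FALSE]
  n <- length(t_s); G <- ncol(Ys)
  if (n < min_points) stop("need at least min_points observations")
  ut <- unique(t_s)
  t0 <- ut[1]; t1 <- ut[length(ut)]
  cand <- if (length(ut) > 2) ut[-c(1, length(ut))] else numeric(0)
  kmax <- max_segments - 1L
  hinges <- if (length(cand))
    vapply(cand, function(b) pmax(t_s - b, 0), numeric(n)) else NULL
  yss <- colSums(Ys^2)

  rss_q <- function(X) {
    Q <- qr.Q(qr(X))
    pmax(yss - colSums(crossprod(Q, Ys)^2), 0)
  }
  valid <- function(bp) all(seg_counts(t_s, bp, t0, t1) >= min_points)

  # best[[k+1]]: list(rss = G-vector, bp = list of breakpoint vectors per gene)
  best <- vector("list", kmax + 1L)
  best[[1]] <- list(rss = rss_q(cbind(1, t_s)),
                    bp = rep(list(numeric(0)), G))

  exhaustive_k <- min(kmax, 2L)
  for (k in seq_len(exhaustive_k)) {
    if (length(cand) < k) break
    sets <- utils::combn(length(cand), k)
    bres <- rep(Inf, G); bcfg <- rep(NA_integer_, G)
    cfgs <- list(); ci <- 0L
    for (j in seq_len(ncol(sets))) {
      bp <- cand[sets[, j]]
      if (!valid(bp)) next
      ci <- ci + 1L; cfgs[[ci]] <- bp
      r <- rss_q(seg_design(t_s, bp, hinges, cand))
      upd <- r < bres - 1e-12
      bres[upd] <- r[upd]; bcfg[upd] <- ci
    }
    if (ci == 0L) break
    best[[k + 1L]] <- list(rss = bres,
                           bp = lapply(bcfg, function(i)
                             if (is.na(i)) NULL else cfgs[[i]]))
  }

  # greedy insertion + one pass of neighbor refinement for larger k
  if (kmax > exhaustive_k) {
    gene_rss <- function(bp, g) {
      X <- seg_design(t_s, bp, hinges, cand)
      f <- stats::.lm.fit(X, Ys[, g])
      sum(f$residuals^2)
    }
    for (k in seq.int(exhaustive_k + 1L, kmax)) {
      if (is.null(best[[k]])) break
      bres <- rep(Inf, G); bbp <- vector("list", G)
      for (g in seq_len(G)) {
        base <- best[[k]]$bp[[g]]
        if (is.null(base)) next
        cur_bp <- NULL; cur <- Inf
        for (b in setdiff(cand, base)) {
          bp <- sort(c(base, b))
          if (!valid(bp)) next
          r <- gene_rss(bp, g)
          if (r < cur - 1e-12) { cur <- r; cur_bp <- bp }
        }
        if (is.null(cur_bp)) next
        # local refinement: slide each breakpoint to a neighboring day
        for (j in seq_along(cur_bp)) {
          ii <- match(cur_bp[j], cand)
          for (d in c(-1L, 1L)) {
            jj <- ii + d
            if (jj < 1L || jj > length(cand)) next
            bp <- sort(unique(replace(cur_bp, j, cand[jj])))
            if (length(bp) != length(cur_bp) || !valid(bp)) next
            r <- gene_rss(bp, g)
            if (r < cur - 1e-12) { cur <- r; cur_bp <- bp }
          }
        }
        bres[g] <- cur; bbp[[g]] <- cur_bp
      }
      if (all(!is.finite(bres))) break
      best[[k + 1L]] <- list(rss = bres, bp = bbp)
    }
  }

  # BIC selection, ties toward fewer segments
  ks <- which(!vapply(best, is.null, logical(1))) - 1L
  bic_tab <- matrix(NA_real_, G, kmax + 1L,
                    dimnames = list(colnames(Ys), paste0("k", 0:kmax)))
  for (k in ks) {
    r <- best[[k + 1L]]$rss
    ok <- is.finite(r)
    bic_tab[ok, k + 1L] <- n * log(pmax(r[ok], 1e-10) / n) +
      (2 + 2 * k) * log(n)
  }
  out <- vector("list", G)
  names(out) <- colnames(Ys)
  for (g in seq_len(G)) {
    bg <- bic_tab[g, ]
    kg <- unname(which.min(bg)) - 1L  # first minimum = smallest k on ties
    bp <- best[[kg + 1L]]$bp[[g]]
    out[[g]] <- segfit_finalize(Ys[, g], t_s, ord, bp, bg, kg, alpha,
                                min_points, colnames(Ys)[g])
  }
  out
}

segfit_finalize <- function(y_s, t_s, ord, bp, bic, k, alpha, min_points,
                            gene_id) {
  n <- length(y_s)
  X <- seg_design(t_s, bp)
  p <- ncol(X)
  qx <- qr(X)
  beta <- qr.coef(qx, y_s)
  fitted_s <- drop(X %*% beta)
  res_s <- y_s - fitted_s
  rss <- sum(res_s^2)
  df <- n - p
  sigma2 <- if (df > 0) rss / df else NA_real_
  XtXi <- chol2inv(qr.R(qx))
  nseg <- k + 1L
  # slope of segment j = beta[2] + sum of hinge coefficients up to j-1
  L <- matrix(0, nseg, p)
  L[, 2] <- 1
  if (k > 0) for (j in 2:nseg) L[j, 3:(j + 1)] <- 1
  slopes <- drop(L %*% beta)
  se <- sqrt(pmax(rowSums((L %*% XtXi) * L) * sigma2, 0))
  # numerically perfect fits make the slope t-test meaningless: slopes
  # below numerical noise are genuinely flat, others certain
  eps <- 1e-8 * (max(abs(y_s)) / max(diff(range(t_s)), 1) + 1e-12)
  exact <- rss <= 1e-10 * max(sum(y_s^2), 1e-300) | se == 0
  tval <- ifelse(exact, ifelse(abs(slopes) <= eps, 0, Inf),
                 slopes / se)
  pval <- if (df > 0) 2 * stats::pt(-abs(tval), df) else rep(1, nseg)
  dir <- ifelse(pval <= alpha & slopes > 0, "up",
                ifelse(pval <= alpha & slopes < 0, "down", "flat"))
  # restore original observation order
  inv <- order(ord)
  structure(list(gene_id = gene_id, breakpoints = bp, k = k,
                 coefficients = beta, slopes = slopes, slope_se = se,
                 slope_p = pval, directions = dir,
                 fitted.values = fitted_s[inv], residuals = res_s[inv],
                 rss = rss, bic = bic, n = n, alpha = alpha,
                 min_points = min_points,
                 times = t_s[inv], y = y_s[inv],
                 t_range = c(t_s[1], t_s[n])),
            class = "segfit")
}

# fitted slope of the segment containing time t; when t equals a breakpoint
# the segment ending there is used
segment_at <- function(fit, t) {
  starts <- c(fit$t_range[1], fit$breakpoints)
  i <- sum(starts < t)
  max(i, 1L)
}

#' @export
print.segfit <- function(x, ...) {
  cat("segfit", if (!is.null(x$gene_id)) paste0("[", x$gene_id, "]"),
      ": ", x$k + 1, " segment(s)\n", sep = "")
  if (x$k > 0)
    cat("  breakpoints:", paste(signif(x$breakpoints, 4), collapse = ", "),
        "\n")
  cat("  directions: ", paste(x$directions, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.segfit <- function(object, ...) {
  starts <- c(object$t_range[1], object$breakpoints)
  ends <- c(object$breakpoints, object$t_range[2])
  tab <- data.frame(start = starts, end = ends, slope = object$slopes,
                    se = object$slope_se, p = object$slope_p,
                    direction = object$directions,
                    stringsAsFactors = FALSE)
  structure(list(gene_id = object$gene_id, segments = tab, bic = object$bic,
                 k = object$k, rss = object$rss, n = object$n),
            class = "summary.segfit")
}

#' @export
print.summary.segfit <- function(x, ...) {
  cat("Segmented trend fit", if (!is.null(x$gene_id))
    paste0("for ", x$gene_id), "\n")
  cat(sprintf("n = %d, RSS = %.4g, chosen breakpoints = %d\n",
              x$n, x$rss, x$k))
  print(x$segments, digits = 4)
  cat("BIC by breakpoint count:\n")
  print(round(x$bic, 2))
  invisible(x)
}

#' @export
coef.segfit <- function(object, ...) {
  out <- c(object$coefficients[1], object$slopes)
  names(out) <- c("intercept", paste0("slope", seq_along(object$slopes)))
  out
}

#' @export
predict.segfit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) return(object$fitted.values)
  drop(seg_design(newtimes, object$breakpoints) %*% object$coefficients)
}

#' @export
fitted.segfit <- function(object, ...) object$fitted.values

#' @export
residuals.segfit <- function(object, ...) object$residuals

#' @export
plot.segfit <- function(x, ...) {
  graphics::plot(x$times, x$y, xlab = "day", ylab = "expression",
                 main = x$gene_id, ...)
  o <- order(x$times)
  graphics::lines(x$times[o], x$fitted.values[o], col = 2, lwd = 2)
  if (x$k > 0) graphics::abline(v = x$breakpoints, lty = 3, col = "grey40")
  invisible(x)
}
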