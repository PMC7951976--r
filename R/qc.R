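#' Sequencing-depth outlier filter
#'
#' Removes samples with unusually low sequencing depth: the threshold is the
#' median of the log10 total expected counts minus 1.5 times their IQR
#' (linear-interpolation quantiles), computed across all samples of the
#' cohort; samples strictly below are removed. Low depth was found to be the
#' main predictor of cross-species misalignment, so this filter doubles as
#' the misalignment guard. Zero-depth samples count as below threshold.
#'
#' @param m A [chimeric_matrix()], [species_matrix()], or counts matrix.
#' @return Object of class \code{qc_report} with a per-sample table
#'   (\code{sample_id}, \code{log10_depth}, \code{verdict}) and the
#'   threshold used.
#' @export
depth_filter <- function(m) {
  counts <- if (is.list(m)) m$counts else as.matrix(m)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  ids <- colnames(counts)
  depth <- colSums(counts)
  ld <- ifelse(depth > 0, log10(depth), -Inf)
  fin <- ld[is.finite(ld)]
  med <- stats::median(fin)
  iqr <- diff(stats::quantile(fin, c(0.25, 0.75), type = 7, names = FALSE))
  thr <- med - 1.5 * iqr
  verdict <- ifelse(ld < thr, "removed-depth", "kept")
  structure(list(samples = data.frame(sample_id = ids, log10_depth = ld,
                                      verdict = verdict, row.names = NULL,
                                      stringsAsFactors = FALSE),
                 threshold = thr, type = "depth"),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report [", x$type, "]: ",
      sum(x$samples$verdict == "kept"), "/", nrow(x$samples),
      " samples kept\n", sep = "")
  if (!is.null(x$threshold))
    cat("  threshold:", signif(x$threshold, 5), "\n")
  invisible(x)
}

#' Samples a QC report keeps
#'
#' @param report A \code{qc_report}.
#' @return Character vector of retained sample ids (protected singletons are
#'   retained).
#' @export
qc_kept <- function(report) {
  v <- report$samples$verdict
  report$samples$sample_id[v %in% c("kept", "protected-singleton")]
}

# principal-component spline outlier p-values for one mixture's samples.
# Returns BH-adjusted p per sample (named). Expression enters on the log
# scale so that component loadings are homoscedastic in time.
pc_outlier_pvals <- function(values, day, n_top = 1000, n_comp = 10,
                             spline_degree = 4, log_transform = TRUE) {
  if (log_transform) values <- log2(values + 1)
  n <- ncol(values)
  n_comp_eff <- min(n_comp, n - 1, nrow(values))
  if (n_comp_eff < n_comp)
    message("reducing principal components to ", n_comp_eff,
            " (only ", n, " samples)")
  v <- rowMeans(values^2) - rowMeans(values)^2
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(values)))]
  pc <- stats::prcomp(t(values[top, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  scores <- pc$x[, seq_len(n_comp_eff), drop = FALSE]
  basis <- splines::bs(day, degree = spline_degree)
  rs <- apply(scores, 2, function(s) {
    fit <- stats::lm(s ~ basis)
    stats::rstudent(fit)
  })
  stat <- apply(abs(rs), 1, max)
  df <- n - (spline_degree + 1) - 1
  p <- 2 * stats::pt(-stat, df = max(df, 1))
  p <- pmin(p, 1)
  stats::setNames(stats::p.adjust(p, "BH"), colnames(values))
}

#' Replicate-outlier elimination on principal-component loadings
#'
#' Identifies samples whose expression profiles disagree with biological
#' replicates and temporally neighboring samples. Per mixture: the top
#' \code{n_top} highest-variance genes are reduced to \code{n_comp}
#' principal components (centered, unscaled); each component's loadings are
#' regressed on day with a degree-\code{spline_degree} polynomial spline;
#' the per-sample statistic is the maximum absolute studentized residual
#' over the components, referred to a t distribution and BH-adjusted across
#' samples. Backward elimination repeatedly removes the sample with the
#' smallest adjusted p below \code{p_threshold} (never a time point's last
#' remaining sample), refitting each round; forward selection then re-adds
#' removed samples in removal order, retaining any whose adjusted p rises
#' above the threshold. The surviving set should be re-normalized before
#' analysis.
#'
#' @param norm A \code{normalized_matrix} (any number of mixtures; the
#'   procedure runs per mixture), or a genes x samples matrix with
#'   \code{samples} supplied.
#' @param samples Sample metadata when \code{norm} is a bare matrix.
#' @param p_threshold Adjusted p-value threshold (default 1e-05).
#' @param n_top Highest-variance genes used.
#' @param n_comp Principal components used (reduced with a message when
#'   fewer samples are available).
#' @param spline_degree Degree of the polynomial spline in day.
#' @param log_transform Rank gene variance and run the PCA on
#'   \code{log2(x + 1)} expression (default), keeping component loadings
#'   homoscedastic across the course.
#' @return A \code{qc_report}: per-sample \code{verdict} (kept /
#'   removed-replicate / protected-singleton), final adjusted p, removal
#'   order, and the parameters used.
#' @export
replicate_outlier_filter <- function(norm, samples = NULL,
                                     p_threshold = 1e-05, n_top = 1000,
                                     n_comp = 10, spline_degree = 4,
                                     log_transform = TRUE) {
  if (inherits(norm, "normalized_matrix")) {
    values <- norm$values; samples <- norm$samples
  } else {
    values <- as.matrix(norm)
    if (is.null(samples)) stop("samples metadata required")
  }
  ids <- colnames(values)
  verdict <- stats::setNames(rep("kept", length(ids)), ids)
  adj_final <- stats::setNames(rep(NA_real_, length(ids)), ids)
  removal_order <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  ord_counter <- 0L
  for (mx in unique(samples$mixture)) {
    in_mx <- samples$mixture == mx
    v <- values[, in_mx, drop = FALSE]
    day_all <- stats::setNames(samples$day[in_mx], ids[in_mx])
    keep <- colnames(v)
    removed <- character(0)
    protected <- character(0)
    pvals <- function(set) pc_outlier_pvals(v[, set, drop = FALSE],
                                            day_all[set], n_top, n_comp,
                                            spline_degree, log_transform)
    # backward elimination
    repeat {
      adj <- pvals(keep)
      last_of_day <- vapply(keep, function(s)
        sum(day_all[keep] == day_all[s]) == 1, logical(1))
      low <- adj < p_threshold
      protected <- union(protected, keep[low & last_of_day])
      elig <- keep[low & !last_of_day]
      if (!length(elig)) break
      victim <- elig[which.min(adj[elig])]
      keep <- setdiff(keep, victim)
      removed <- c(removed, victim)
      ord_counter <- ord_counter + 1L
      removal_order[victim] <- ord_counter
    }
    # forward selection, in removal order
    for (s in removed) {
      trial <- c(keep, s)
      adj <- pvals(trial)
      if (adj[s] > p_threshold) {
        keep <- trial
        removed <- setdiff(removed, s)
      }
    }
    verdict[removed] <- "removed-replicate"
    verdict[intersect(protected, keep)] <- "protected-singleton"
    adj_final[keep] <- pvals(keep)[keep]
  }
  structure(list(samples = data.frame(sample_id = ids,
                                      verdict = unname(verdict[ids]),
                                      adj_p = unname(adj_final[ids]),
                                      removal_order =
                                        unname(removal_order[ids]),
                                      row.names = NULL,
                                      stringsAsFactors = FALSE),
                 threshold = p_threshold,
                 params = list(n_top = n_top, n_comp = n_comp,
                               spline_degree = spline_degree,
                               log_transform = log_transform,
                               pca = "centered, unscaled"),
                 type = "replicate"),
            class = "qc_report")
}
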