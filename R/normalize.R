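#' Size factors for expected-count samples
#'
#' Per-sample positive scale factors, rescaled to mean 1, computed with the
#' pooled-deconvolution estimator (scran's \code{calculateSumFactors}; for
#' cohorts too small to pool, scran itself degrades to robust library-size
#' factors, which keeps triplicate groups immune to single corrupted
#' members). Should scran fail outright, a median-of-ratios estimate
#' against a geometric-mean pseudo-reference is used instead. All-zero
#' genes are excluded from estimation.
#'
#' @param counts Genes x samples matrix of expected counts (>= 2 samples).
#' @return Positive numeric vector (one per sample), mean 1; attribute
#'   \code{method} records the estimator used.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  use <- rowSums(counts) > 0
  cm <- counts[use, , drop = FALSE]
  if (!nrow(cm)) stop("no expressed genes")
  method <- "scran-pooled"
  sf <- tryCatch(suppressWarnings(scran::calculateSumFactors(cm)),
                 error = function(e) NULL)
  if (is.null(sf) || !all(is.finite(sf)) || !all(sf > 0)) {
    sf <- median_of_ratios(cm)
    method <- "median-of-ratios"
  }
  sf <- sf / mean(sf)
  names(sf) <- colnames(counts)
  attr(sf, "method") <- method
  sf
}

median_of_ratios <- function(cm) {
  pos <- rowSums(cm > 0) == ncol(cm)
  if (!any(pos))
    stop("no genes expressed in every sample; cannot form a pseudo-reference")
  ref <- exp(rowMeans(log(cm[pos, , drop = FALSE])))
  sf <- apply(cm[pos, , drop = FALSE], 2, function(y)
    stats::median(y / ref))
  bad <- which(!is.finite(sf) | sf <= 0)
  if (length(bad))
    stop("sample(s) share no expressed genes with the reference: ",
         paste(colnames(cm)[bad], collapse = ", "))
  sf
}

#' Two-stage size-factor normalization
#'
#' Human and mouse counts are normalized separately; this operates on one
#' species. Stage 1 normalizes biological replicates within each
#' (mixture, day) group (singleton groups keep factor 1). Stage 2 averages
#' the stage-1 normalized replicate profiles per group and estimates factors
#' across all group averages -- all days and mixtures of the species --
#' which are then applied to every sample of the corresponding group.
#'
#' @param m A [species_matrix()], or a genes x samples matrix with
#'   \code{samples} supplied.
#' @param samples Sample metadata when \code{m} is a bare matrix.
#' @return Object of class \code{normalized_matrix}: \code{values} (genes x
#'   samples), \code{samples}, \code{stage1_factors}, \code{stage2_factors}
#'   (per sample), \code{group} (per-sample "mixture.day" label),
#'   \code{averages} (stage-2 input profiles), \code{species}.
#' @export
two_stage_normalize <- function(m, samples = NULL) {
  if (inherits(m, "species_matrix")) {
    counts <- m$counts; samples <- m$samples; species <- m$species
  } else {
    counts <- as.matrix(m); species <- NA_character_
    if (is.null(samples)) stop("samples metadata required")
  }
  group <- paste(samples$mixture, samples$day, sep = ".")
  sf1 <- rep(1, ncol(counts)); names(sf1) <- colnames(counts)
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) >= 2)
      sf1[idx] <- size_factors(counts[, idx, drop = FALSE])
    # singleton groups skip stage 1 (factor 1)
  }
  norm1 <- sweep(counts, 2, sf1, "/")
  groups <- unique(group)
  averages <- vapply(groups, function(g)
    rowMeans(norm1[, group == g, drop = FALSE]), numeric(nrow(counts)))
  colnames(averages) <- groups
  sf2g <- if (length(groups) >= 2) size_factors(averages)
          else stats::setNames(1, groups)
  sf2 <- sf2g[match(group, groups)]
  names(sf2) <- colnames(counts)
  values <- sweep(norm1, 2, sf2, "/")
  structure(list(values = values, samples = samples,
                 stage1_factors = sf1, stage2_factors = sf2,
                 group = group, averages = averages, species = species),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", length(unique(x$group)), " replicate groups)\n", sep = "")
  invisible(x)
}
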