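#' Gene set for comparing in vitro courses with a reference panel
#'
#' The union of the top \code{n} most dynamic in vitro genes (highest CV of
#' fitted trend values across mixtures, see [dynamic_genes()]) and the top
#' \code{n} reference genes by CV across reference samples. Errors when
#' fewer than half the union is present in both identifier spaces, the
#' signature of an identifier-mapping failure.
#'
#' @param invitro_fits Named list (mixture -> fit list) as for
#'   [dynamic_genes()].
#' @param panel Reference expression matrix (genes x reference samples).
#' @param n Top-list size per side.
#' @return Character vector of gene ids.
#' @export
reference_gene_union <- function(invitro_fits, panel, n = 1500) {
  iv <- dynamic_genes(invitro_fits, n)
  m <- rowMeans(panel); s <- apply(panel, 1, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  rv <- names(utils::head(sort(cv[!is.na(cv)], decreasing = TRUE), n))
  u <- union(iv, rv)
  invitro_genes <- unique(unlist(lapply(invitro_fits, names)))
  if (length(invitro_fits) && inherits(invitro_fits[[1]], "segfit"))
    invitro_genes <- names(invitro_fits)
  frac <- mean(u %in% rownames(panel) & u %in% invitro_genes)
  if (frac < 0.5)
    stop("only ", round(100 * frac), "% of the union maps to both datasets; ",
         "check gene identifiers")
  u
}

#' Correlation of in vitro days against reference samples
#'
#' Replicate-averaged in vitro day profiles are Spearman-correlated with
#' each reference sample over the supplied gene set.
#'
#' @param invitro A [species_matrix()] (or list with \code{counts},
#'   \code{samples}).
#' @param panel Reference matrix (genes x reference samples).
#' @param genes Gene set to correlate over.
#' @return Matrix, in vitro days x reference samples.
#' @export
reference_correlation <- function(invitro, panel, genes) {
  genes <- intersect(genes, intersect(rownames(invitro$counts),
                                      rownames(panel)))
  if (!length(genes)) stop("no shared genes")
  av <- avg_by_day(invitro$counts[genes, , drop = FALSE],
                   invitro$samples$day)
  suppressWarnings(stats::cor(av, panel[genes, , drop = FALSE],
                              method = "spearman"))
}

# moment estimate of per-gene NB dispersion on normalized counts
moment_dispersion <- function(z) {
  m <- rowMeans(z)
  v <- rowMeans(z^2) - m^2
  phi <- (v - m) / m^2
  phi[!is.finite(phi) | phi < 1e-8] <- 1e-8
  pmin(phi, 10)
}

nb_deviance_residuals <- function(z, mu, phi) {
  t1 <- ifelse(z > 0, z * log(z / mu), 0)
  t2 <- (z + 1 / phi) * log((1 + phi * z) / (1 + phi * mu))
  sign(z - mu) * sqrt(2 * pmax(t1 - t2, 0))
}

#' Count-model dimension reduction
#'
#' Reduces a joint count matrix (in vitro profiles plus reference samples)
#' to \code{k} components under a negative-binomial count model. The
#' default path computes NB deviance residuals on size-factor-normalized
#' counts (per-gene moment dispersions) and takes their principal
#' components; normalizing before forming residuals makes the coordinates
#' exactly invariant to depth changes matched by the size factors. The
#' \code{"glmpca"} path fits a generalized PCA under the NB likelihood by
#' Fisher-scoring alternation with a ridge penalty and a minimum iteration
#' floor, falling back to the residual path on failure.
#'
#' @param counts Genes x samples non-negative matrix.
#' @param k Components to keep.
#' @param size_factors Per-sample factors (default: depth scaled to mean 1).
#' @param method "deviance" (default) or "glmpca".
#' @param penalty Ridge penalty for the glmpca path.
#' @param min_iter Minimum iterations for the glmpca path.
#' @return Object of class \code{count_reduction}: \code{coords} (samples x
#'   k), \code{method}, \code{k}, \code{size_factors}, \code{sdev}.
#' @export
reduce_counts <- function(counts, k = 6, size_factors = NULL,
                          method = c("deviance", "glmpca"), penalty = 10,
                          min_iter = 400) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(size_factors)) {
    size_factors <- colSums(counts)
    size_factors <- size_factors / mean(size_factors)
  }
  keep <- rowSums(counts) > 0
  z <- sweep(counts[keep, , drop = FALSE], 2, size_factors, "/")
  k_eff <- min(k, ncol(z) - 1, nrow(z))
  coords <- NULL; used <- method; sdev <- NULL
  if (method == "glmpca") {
    fit <- tryCatch(nb_glmpca(z, k_eff, penalty, min_iter),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("glmpca path failed to converge; falling back to deviance ",
              "residual PCA")
      used <- "deviance"
    } else {
      coords <- fit$V
      sdev <- apply(fit$V, 2, stats::sd)
    }
  }
  if (is.null(coords)) {
    used <- "deviance"
    mu <- rowMeans(z)
    phi <- moment_dispersion(z)
    r <- nb_deviance_residuals(z, matrix(mu, nrow(z), ncol(z)),
                               matrix(phi, nrow(z), ncol(z)))
    pc <- stats::prcomp(t(r), center = TRUE, scale. = FALSE)
    coords <- pc$x[, seq_len(k_eff), drop = FALSE]
    sdev <- pc$sdev[seq_len(k_eff)]
  }
  rownames(coords) <- colnames(counts)
  structure(list(coords = coords, method = used, k = k_eff,
                 size_factors = size_factors, sdev = sdev,
                 penalty = if (used == "glmpca") penalty else NA_real_),
            class = "count_reduction")
}

# compact NB generalized PCA: log mu = a_g + U_g V_s', alternating ridge-
# penalized Fisher scoring with fixed moment dispersions; counts are
# pre-normalized so no offset term is needed
nb_glmpca <- function(z, k, penalty = 10, min_iter = 400, max_iter = 1000,
                      tol = 1e-6) {
  G <- nrow(z); S <- ncol(z)
  phi <- moment_dispersion(z)
  a <- log(pmax(rowMeans(z), 1e-8))
  mu0 <- rowMeans(z)
  r0 <- nb_deviance_residuals(z, matrix(mu0, G, S), matrix(phi, G, S))
  sv <- svd(r0, nu = k, nv = k)
  U <- sv$u %*% diag(sqrt(sv$d[seq_len(k)]), k) * 0.01
  V <- sv$v %*% diag(sqrt(sv$d[seq_len(k)]), k) * 0.01
  dev_prev <- Inf
  for (it in seq_len(max_iter)) {
    eta <- a + U %*% t(V)
    mu <- exp(pmin(eta, 30))
    W <- mu / (1 + phi * mu)            # Fisher weights, G x S
    E <- (z - mu) / mu                  # working residuals (score / weight)
    # update V: per sample ridge-weighted regression on U
    for (s in seq_len(S)) {
      ws <- W[, s]
      A <- crossprod(U, U * ws) + diag(penalty, k)
      b <- crossprod(U, ws * E[, s] + (U %*% V[s, ]) * ws)
      V[s, ] <- solve(A, b)
    }
    eta <- a + U %*% t(V)
    mu <- exp(pmin(eta, 30))
    W <- mu / (1 + phi * mu)
    E <- (z - mu) / mu
    # update U and a: per gene
    Xg <- cbind(1, V)
    for (g in seq_len(G)) {
      wg <- W[g, ]
      A <- crossprod(Xg, Xg * wg) + diag(c(0, rep(penalty, k)), k + 1)
      b <- crossprod(Xg, wg * (E[g, ] + drop(Xg %*% c(a[g], U[g, ]))))
      cf <- solve(A, b)
      a[g] <- cf[1]; U[g, ] <- cf[-1]
    }
    mu <- exp(pmin(a + U %*% t(V), 30))
    dev <- sum(nb_deviance_residuals(z, mu, matrix(phi, G, S))^2)
    if (it >= min_iter && abs(dev_prev - dev) < tol * (abs(dev) + 1)) break
    dev_prev <- dev
  }
  list(U = U, V = V, a = a, deviance = dev, iterations = it)
}

#' Dissimilarity of in vitro days to reference samples
#'
#' Euclidean distances in the reduced space between in vitro day profiles
#' and reference samples, smoothed per (mixture, reference) with a basis
#' spline in day; the minimizing day of the smoothed curve stages the
#' culture against the reference.
#'
#' @param reduction A [reduce_counts()] result on the joint matrix.
#' @param meta Data frame describing the reduction's samples (rows of
#'   \code{coords}): columns \code{id}, \code{type} ("invitro" or
#'   "reference"), \code{mixture}, \code{day}.
#' @param df Spline degrees of freedom for smoothing.
#' @return Object of class \code{dissimilarity_curve}: \code{distances}
#'   (long data frame), \code{smooth} (per mixture/reference curves),
#'   \code{min_day} (data frame mixture, reference, day).
#' @export
dissimilarity_curve <- function(reduction, meta, df = 4) {
  co <- reduction$coords
  stopifnot(nrow(co) == nrow(meta))
  iv <- which(meta$type == "invitro")
  rf <- which(meta$type == "reference")
  if (!length(rf)) stop("no reference samples in meta")
  rows <- list()
  for (i in iv) for (j in rf)
    rows[[length(rows) + 1L]] <- data.frame(
      mixture = meta$mixture[i], day = meta$day[i],
      reference = meta$id[j],
      dist = sqrt(sum((co[i, ] - co[j, ])^2)),
      stringsAsFactors = FALSE)
  d <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  smooth <- list(); mins <- list()
  for (mx in unique(d$mixture)) for (rr in unique(d$reference)) {
    dd <- d[d$mixture == mx & d$reference == rr, ]
    if (nrow(dd) < 2 || length(unique(dd$day)) < 2) {
      mins[[paste(mx, rr)]] <- data.frame(mixture = mx, reference = rr,
                                          day = dd$day[1],
                                          stringsAsFactors = FALSE)
      next
    }
    dfe <- min(df, length(unique(dd$day)) - 1)
    fit <- stats::lm(dist ~ splines::bs(day, df = dfe), data = dd)
    grid <- seq(min(dd$day), max(dd$day), length.out = 512)
    pr <- stats::predict(fit, data.frame(day = grid))
    smooth[[paste(mx, rr)]] <- data.frame(mixture = mx, reference = rr,
                                          day = grid, dist = pr,
                                          stringsAsFactors = FALSE)
    mins[[paste(mx, rr)]] <- data.frame(mixture = mx, reference = rr,
                                        day = grid[which.min(pr)],
                                        stringsAsFactors = FALSE)
  }
  structure(list(distances = d,
                 smooth = do.call(rbind, c(unname(smooth),
                                           list(make.row.names = FALSE))),
                 min_day = do.call(rbind, c(unname(mins),
                                            list(make.row.names = FALSE)))),
            class = "dissimilarity_curve")
}

#' @export
print.dissimilarity_curve <- function(x, ...) {
  cat("dissimilarity_curve: minimizing days\n")
  print(x$min_day)
  invisible(x)
}
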