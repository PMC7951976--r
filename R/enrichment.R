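#' Read a GMT gene-set collection
#'
#' Symbols are uppercase-normalized; empty sets are dropped.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(s) unique(toupper(s)))
  sets[lengths(sets) >= 1]
}

#' Over-representation analysis
#'
#' One-sided hypergeometric test of each gene set's overlap with a hit list
#' against a background (the set of all genes on which segmented regression
#' was run), with Benjamini-Hochberg correction across sets. Sets disjoint
#' from the background are skipped.
#'
#' @param hits Character vector of hit genes (subset of \code{background}).
#' @param background Character vector of background genes.
#' @param sets Named list of gene sets.
#' @return Data frame: \code{set}, \code{size} (in background),
#'   \code{overlap}, \code{p}, \code{q}.
#' @export
ora <- function(hits, background, sets) {
  background <- unique(background)
  hits <- unique(hits)
  extra <- setdiff(hits, background)
  if (length(extra)) {
    warning("dropping ", length(extra), " hits absent from the background")
    hits <- intersect(hits, background)
  }
  N <- length(background); K <- length(hits)
  rows <- list()
  for (nm in names(sets)) {
    m <- length(intersect(sets[[nm]], background))
    if (m == 0) {
      message("set ", nm, " disjoint from background; skipped")
      next
    }
    k <- length(intersect(sets[[nm]], hits))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, m, N - m, K, lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, size = m, overlap = k, p = p,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(set = character(0), size = integer(0),
                      overlap = integer(0), p = numeric(0), q = numeric(0)))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- stats::p.adjust(out$p, "BH")
  out
}

#' Per-gene timing-difference statistic
#'
#' The signed difference in days between reference and test event times
#' (positive: the test condition runs ahead). Peaks are preferred; absent
#' shared peaks, up-trend starts are used; genes without either shared
#' event carry 0.
#'
#' @param test_events,ref_events [events_table()] data frames.
#' @param genes Background gene ids (default: union of the two tables).
#' @return Data frame: \code{gene_id}, \code{statistic}, \code{source}
#'   ("peak", "up_start", or "none").
#' @export
timing_statistic <- function(test_events, ref_events, genes = NULL) {
  if (is.null(genes))
    genes <- union(test_events$gene_id, ref_events$gene_id)
  ti <- match(genes, test_events$gene_id)
  ri <- match(genes, ref_events$gene_id)
  tp <- test_events$peak_time[ti]; rp <- ref_events$peak_time[ri]
  tu <- test_events$up_start[ti]; ru <- ref_events$up_start[ri]
  stat <- numeric(length(genes))
  src <- rep("none", length(genes))
  use_peak <- !is.na(tp) & !is.na(rp)
  stat[use_peak] <- rp[use_peak] - tp[use_peak]
  src[use_peak] <- "peak"
  use_up <- !use_peak & !is.na(tu) & !is.na(ru)
  stat[use_up] <- ru[use_up] - tu[use_up]
  src[use_up] <- "up_start"
  data.frame(gene_id = genes, statistic = stat, source = src,
             stringsAsFactors = FALSE)
}

#' Permutation enrichment on a continuous timing statistic
#'
#' Each set scores the mean statistic of its member genes; the null is the
#' score of size-matched random gene draws (without replacement) from the
#' background. Two directional p-values are reported per set: acceleration
#' (observed mean at least as positive as the null) and deceleration, each
#' BH-adjusted across sets. Mirrored draws make negating every statistic
#' swap the two directions exactly.
#'
#' @param stat Named numeric vector of per-gene statistics, or a
#'   [timing_statistic()] data frame.
#' @param sets Named list of gene sets.
#' @param n_perm Permutations (default 1e5; the full-scale analysis uses
#'   4e6).
#' @param min_size,max_size Set-size bounds after intersection with the
#'   background.
#' @param seed Seed for the permutation draws.
#' @return Data frame: \code{set}, \code{size}, \code{score},
#'   \code{p_accel}, \code{q_accel}, \code{p_decel}, \code{q_decel}.
#' @export
gsea_continuous <- function(stat, sets, n_perm = 1e5, min_size = 1,
                            max_size = 250, seed = 1) {
  if (is.data.frame(stat))
    stat <- stats::setNames(stat$statistic, stat$gene_id)
  if (n_perm < 1000)
    warning("fewer than 1000 permutations gives poor p-value resolution")
  genes <- names(stat)
  members <- lapply(sets, function(s) intersect(s, genes))
  sz <- lengths(members)
  keep <- sz >= min_size & sz <= max_size
  members <- members[keep]; sz <- sz[keep]
  if (!length(members))
    return(data.frame(set = character(0), size = integer(0),
                      score = numeric(0), p_accel = numeric(0),
                      q_accel = numeric(0), p_decel = numeric(0),
                      q_decel = numeric(0)))
  n <- length(stat)
  set.seed(seed)
  null_by_size <- list()
  for (s in sort(unique(sz))) {
    null_by_size[[as.character(s)]] <- vapply(seq_len(n_perm), function(i)
      sum(stat[sample.int(n, s)]), numeric(1)) / s
  }
  score <- vapply(members, function(mm) mean(stat[mm]), numeric(1))
  p_accel <- p_decel <- numeric(length(members))
  for (i in seq_along(members)) {
    null <- null_by_size[[as.character(sz[i])]]
    p_accel[i] <- (1 + sum(null >= score[i])) / (n_perm + 1)
    p_decel[i] <- (1 + sum(null <= score[i])) / (n_perm + 1)
  }
  data.frame(set = names(members), size = sz, score = score,
             p_accel = p_accel, q_accel = stats::p.adjust(p_accel, "BH"),
             p_decel = p_decel, q_decel = stats::p.adjust(p_decel, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
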