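test_that("ORA matches exact hypergeometric enumeration", {
  background <- paste0("g", 1:40)
  hits <- paste0("g", 1:20)
  sets <- list(exact = paste0("g", 1:20),
               half = paste0("g", 11:30),
               off = paste0("g", 21:40))
  res <- ora(hits, background, sets)
  # independent combinatorial oracle: tail of the hypergeometric pmf
  tail_p <- function(k, m, N, K) {
    kk <- k:min(m, K)
    sum(choose(m, kk) * choose(N - m, K - kk)) / choose(N, K)
  }
  expect_equal(res$p[res$set == "exact"], tail_p(20, 20, 40, 20))
  expect_equal(res$p[res$set == "half"], tail_p(10, 20, 40, 20))
  expect_equal(res$p[res$set == "off"], tail_p(0, 20, 40, 20))
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))

  # a set disjoint from the background is skipped
  expect_message(res2 <- ora(hits, background, list(alien = c("zz1", "zz2"))),
                 "disjoint")
  expect_equal(nrow(res2), 0)
  # p-values are invariant to gene order
  res3 <- ora(sample(hits), sample(background), sets)
  expect_equal(res3$p[order(res3$set)], res$p[order(res$set)])
})

test_that("ORA p-values are calibrated against the exact null", {
  set.seed(30)
  background <- paste0("g", 1:2000)
  set1 <- list(s = paste0("g", 1:200))
  # random hits: overlap is exactly hypergeometric; compare the observed
  # overlap distribution with its exact law (goodness of fit), and check
  # super-uniformity of the p-values at several levels
  ov <- replicate(500, ora(sample(background, 300), background,
                           set1)$overlap)
  ks <- 0:100
  pk <- stats::dhyper(ks, 200, 1800, 300)
  bins <- c(-Inf, 22, 26, 30, 34, 38, Inf)
  obs <- table(cut(ov, bins))
  expected <- vapply(seq_len(length(bins) - 1), function(i)
    sum(pk[ks > bins[i] & ks <= bins[i + 1]]), numeric(1))
  gof <- suppressWarnings(stats::chisq.test(obs, p = expected))
  expect_gt(gof$p.value, 0.01)
  ps <- stats::phyper(ov - 1, 200, 1800, 300, lower.tail = FALSE)
  for (alpha in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 500))
})

test_that("timing statistic prefers peaks and defaults to zero", {
  ev <- function(gene, up, peak) data.frame(gene_id = gene, up_start = up,
                                            up_slope = 1, up_duration = 2,
                                            peak_time = peak,
                                            max_fitted = 5)
  test <- rbind(ev("a", 3, 6), ev("b", 8, NA), ev("c", NA, NA))
  ref <- rbind(ev("a", 5, 10), ev("b", 14, NA), ev("c", 4, NA))
  ts <- timing_statistic(test, ref)
  expect_equal(ts$statistic[ts$gene_id == "a"], 4)    # peaks: 10 - 6
  expect_equal(ts$source[ts$gene_id == "a"], "peak")
  expect_equal(ts$statistic[ts$gene_id == "b"], 6)    # up starts: 14 - 8
  expect_equal(ts$statistic[ts$gene_id == "c"], 0)    # no shared event
  expect_equal(ts$source[ts$gene_id == "c"], "none")
})

test_that("continuous enrichment is calibrated on an exhaustive null", {
  # 10-gene background: compare permutation p with exact enumeration of
  # all C(10, 3) set scores
  set.seed(8)
  stat <- stats::setNames(c(5, 4, 3, 2, 1, 0, -1, -2, -3, -4),
                          paste0("g", 1:10))
  members <- c("g1", "g2", "g4")
  score <- mean(stat[members])
  combos <- utils::combn(10, 3)
  exact <- mean(apply(combos, 2, function(i) mean(stat[i])) >= score)
  res <- gsea_continuous(stat, list(s = members), n_perm = 2e4)
  expect_lt(abs(res$p_accel - exact), 0.005)

  # a set built from the largest statistics achieves the resolution floor
  stat2 <- stats::setNames(stats::rnorm(1000), paste0("g", 1:1000))
  top <- names(sort(stat2, decreasing = TRUE))[1:20]
  res2 <- gsea_continuous(stat2, list(top = top), n_perm = 5000)
  expect_equal(res2$p_accel, 1 / 5001)

  # all-zero statistics cannot look enriched
  stat0 <- stats::setNames(rep(0, 200), paste0("g", 1:200))
  res0 <- gsea_continuous(stat0, list(s = paste0("g", 1:15)),
                          n_perm = 2000)
  expect_gte(res0$p_accel, 0.5)
})

test_that("negating the statistic swaps the directional p-values exactly", {
  set.seed(9)
  stat <- stats::setNames(stats::rnorm(300), paste0("g", 1:300))
  sets <- list(a = paste0("g", 1:12), b = paste0("g", 50:70),
               c = paste0("g", 200:230))
  r1 <- gsea_continuous(stat, sets, n_perm = 3000, seed = 4)
  r2 <- gsea_continuous(-stat, sets, n_perm = 3000, seed = 4)
  expect_equal(r1$p_accel, r2$p_decel)
  expect_equal(r1$p_decel, r2$p_accel)

  # set-size bounds filter sets before testing
  r3 <- gsea_continuous(stat, c(sets, list(huge = paste0("g", 1:299))),
                        n_perm = 1500, max_size = 250)
  expect_false("huge" %in% r3$set)
  expect_warning(gsea_continuous(stat, sets, n_perm = 500), "resolution")
})

test_that("GMT parsing normalizes symbols", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tTp53\tsox2", "setB\tdesc\tGENE1"), p)
  sets <- read_gmt(p)
  expect_equal(sets$setA, c("TP53", "SOX2"))
  expect_equal(sets$setB, "GENE1")
})
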