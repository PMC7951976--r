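test_that("trend evaluation is piecewise linear with clamping", {
  s <- trend_spec(10, c(5, 15), c(0, 2, -3), c(0, 42))
  expect_equal(trend_values(s, c(0, 5)), c(10, 10))
  expect_equal(trend_values(s, 10), 20)
  expect_equal(trend_values(s, 15), 30)
  expect_equal(trend_values(s, 20), 15)
  expect_equal(trend_values(s, 42), 0)  # clamped at zero
  expect_error(trend_spec(10, c(15, 5), c(0, 1, 1)), "increasing")
})

test_that("warp map, inverse, and trend warping are consistent", {
  w <- warp_function(c(2, 1), 16)
  expect_equal(warp_map(w, c(0, 10, 16, 20)), c(0, 20, 32, 36))
  # inverse agrees with a bisection oracle on w
  for (tau in c(3, 20, 35, 40)) {
    t_bis <- stats::uniroot(function(t) warp_map(w, t) - tau, c(0, 60),
                            tol = 1e-10)$root
    expect_equal(warp_inverse(w, tau), t_bis, tolerance = 1e-7)
  }
  # identity warp leaves a trend unchanged
  s <- trend_spec(5, c(10, 20), c(0, 1.5, 0), c(0, 42))
  s1 <- warp_trend(s, warp_function(1))
  expect_equal(s1$breakpoints, s$breakpoints)
  expect_equal(s1$slopes, s$slopes)
  expect_equal(s1$baseline, s$baseline)
  # a = 2 on [0,16]: breakpoint at day 10 maps to day 5, slope doubles
  s2 <- warp_trend(trend_spec(5, 10, c(0, 1), c(0, 42)), w)
  expect_equal(s2$breakpoints[1], 5)
  expect_equal(s2$slopes[2], 2)
  # breakpoint at day 20 maps through the numeric inverse (= day 10 here)
  s3 <- warp_trend(trend_spec(5, 20, c(0, 1), c(0, 42)), w)
  expect_true(any(abs(s3$breakpoints - 10) < 1e-8))
  # warped trend equals mu_ref(w(t)) everywhere
  tt <- seq(0, 42, 0.25)
  expect_equal(trend_values(s3, tt),
               trend_values(trend_spec(5, 20, c(0, 1), c(0, 42)),
                            warp_map(w, tt)))
})

test_that("simulation is deterministic and respects composition", {
  cfg <- simulation_config(n_genes = 100, days = seq(0, 20, 2),
                           replicates = 2, seed = 42)
  s1 <- simulate_timecourse(cfg)
  s2 <- simulate_timecourse(cfg)
  expect_identical(s1$matrix$counts, s2$matrix$counts)

  # species count fractions track the truth composition; per-sample error
  # reflects gene-level negative-binomial noise on the species totals plus
  # the 0.5% bleed-through
  sp <- heterochron:::species_of(rownames(s1$matrix$counts),
                                 c("hg19", "mm10"))
  hfrac <- colSums(s1$matrix$counts[sp == "hg19", ]) /
    colSums(s1$matrix$counts)
  tr <- s1$truth$samples
  mixed <- tr$sample_id[startsWith(tr$sample_id, "H10_")]
  idx <- match(mixed, colnames(s1$matrix$counts))
  dev <- abs(hfrac[idx] - tr$human_frac[match(mixed, tr$sample_id)])
  expect_lt(stats::median(dev), 0.02)
  expect_lt(max(dev), 0.08)
})

test_that("noise-free mode produces exact means with proportional bleed", {
  cfg <- simulation_config(n_genes = 25, days = seq(0, 10, 2),
                           replicates = 1, noise = "none",
                           bleed_rate = 0.004,
                           mixtures = list(list(label = "H100",
                                                human_frac = 1)),
                           seed = 3)
  sim <- simulate_timecourse(cfg)
  r <- misalignment_rate(sim$matrix, "hg19")
  expect_equal(r$rate, rep(0.004, nrow(r)), tolerance = 1e-12)
})

test_that("injected outliers have the advertised signatures", {
  cfg <- simulation_config(n_genes = 60, days = 0:14, replicates = 3,
                           mixtures = list(list(label = "H100",
                                                human_frac = 1)),
                           seed = 8)
  sim <- simulate_timecourse(cfg)
  victim <- "H100_d07_r2"
  out <- inject_outliers(sim,
                         low_depth = list(sample_ids = victim,
                                          factor = 1e-3))
  # the rescaled sample falls below the depth-filter threshold
  ld <- log10(colSums(out$matrix$counts))
  thr <- stats::median(ld) - 1.5 * stats::IQR(ld, type = 7)
  expect_lt(ld[victim], thr)
  expect_equal(out$truth$samples$outlier[
    out$truth$samples$sample_id == victim], "low_depth")

  # zero outlier spec leaves the matrix untouched
  same <- inject_outliers(sim)
  expect_identical(same$matrix$counts, sim$matrix$counts)

  # a scrambled replicate decorrelates from its siblings
  out2 <- inject_outliers(sim, scramble = list(sample_ids = victim))
  lc <- log2(out2$matrix$counts + 1)
  sibs <- c("H100_d07_r1", "H100_d07_r3")
  scr_cor <- max(stats::cor(lc[, victim], lc[, sibs]))
  clean_cor <- stats::cor(lc[, sibs[1]], lc[, sibs[2]])
  expect_lt(scr_cor, clean_cor - 0.2)
})

test_that("noise-free warped cohorts place events at the inverse warp", {
  set.seed(11)
  days <- c(0:14, seq(16, 42, 2)); times <- rep(days, each = 3)
  w <- warp_function(c(1.7, 1), 16)
  specs <- replicate(15, random_trend_spec_grid("peak", 42, grid = NULL),
                     simplify = FALSE)
  names(specs) <- paste0("G", seq_along(specs))
  warped <- lapply(specs, warp_trend, warp = w)
  fr <- fit_all(trend_matrix(specs, times), times)
  ft <- fit_all(trend_matrix(warped, times), times)
  er <- events_table(fr); et <- events_table(ft)
  ok <- !is.na(er$peak_time) & !is.na(et$peak_time)
  expect_gt(sum(ok), 5)
  expect_lt(max(abs(et$peak_time[ok] -
                      warp_inverse(w, er$peak_time[ok]))), 2.1)
})
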