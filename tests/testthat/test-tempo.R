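test_that("event extraction follows the first-qualifying rules", {
  # flat then up from day 8: up start at 8, no peak
  f1 <- synth_fit(8, c(0, 2))
  e1 <- extract_events(f1)
  expect_equal(e1$up_start, 8)
  expect_equal(e1$up_slope, 2)
  expect_true(is.na(e1$peak_time))

  # up from 0 to 10 then down: up start 0, peak at 10
  f2 <- synth_fit(10, c(2, -1), baseline = 0)
  e2 <- extract_events(f2)
  expect_equal(e2$up_start, 0)
  expect_equal(e2$peak_time, 10)

  # down then up: the rise is preceded by a fall, so no qualifying up start
  f3 <- synth_fit(12, c(-1, 2), baseline = 30)
  e3 <- extract_events(f3)
  expect_true(is.na(e3$up_start))

  # up -> flat counts as a peak
  f4 <- synth_fit(c(5, 15), c(0, 3, 0))
  expect_equal(extract_events(f4)$peak_time, 15)
})

test_that("early-up calls respect lead and the slope-ratio guard", {
  ref <- synth_fit(14, c(0.2, 5), directions = c("flat", "up"))
  test_ok <- synth_fit(8, c(0, 5))
  e_ref <- extract_events(ref)
  # lead 6 >= 2 and slope 5 >= 5 * 0.2: early
  expect_equal(classify_early_up(extract_events(test_ok), e_ref,
                                 test_ok, ref), "early")
  # lead of 1 day only: not early
  test_lead1 <- synth_fit(13, c(0, 5))
  expect_equal(classify_early_up(extract_events(test_lead1), e_ref,
                                 test_lead1, ref), "unchanged")
  # lead 6 but slope 0.9 < 5 * 0.2: the guard fires
  test_slow <- synth_fit(8, c(0, 0.9))
  expect_equal(classify_early_up(extract_events(test_slow), e_ref,
                                 test_slow, ref), "unchanged")
  # missing event on either side
  flat <- synth_fit(numeric(0), 0, baseline = 5)
  expect_equal(classify_early_up(extract_events(flat), e_ref, flat, ref),
               "n/a")
  # both up-trending from day 0: excluded from tabulation
  z1 <- synth_fit(numeric(0), 2, baseline = 0)
  z2 <- synth_fit(numeric(0), 3, baseline = 0)
  expect_equal(classify_early_up(extract_events(z1), extract_events(z2),
                                 z1, z2), "n/a")
})

test_that("reference segment at a breakpoint is the one ending there", {
  # reference is flat (fitted slope 0.1) until its breakpoint at day 14;
  # a test up start falling exactly on a reference breakpoint must be
  # compared against the segment that ends there
  ref <- synth_fit(14, c(0.1, 4), directions = c("flat", "up"))
  expect_equal(heterochron:::segment_at(ref, 14), 1)
  expect_equal(heterochron:::segment_at(ref, 14.5), 2)
  expect_equal(heterochron:::segment_at(ref, 0), 1)
  test <- synth_fit(c(8, 20), c(0, 3, 0))
  expect_equal(classify_early_up(extract_events(test),
                                 extract_events(ref), test, ref),
               "early")
})

test_that("peak and DE calls cover the truth table boundaries", {
  p5 <- synth_fit(c(2, 5), c(0, 3, -1))
  p10 <- synth_fit(c(3, 10), c(0, 3, -1))
  e5 <- extract_events(p5); e10 <- extract_events(p10)
  expect_equal(classify_early_peak(e5, e10), "early")
  expect_equal(classify_early_peak(e10, e5), "late")
  expect_equal(classify_early_peak(e5, e5), "unchanged")
  flat <- extract_events(synth_fit(numeric(0), 0, baseline = 5))
  expect_equal(classify_early_peak(flat, e5), "n/a")

  expect_equal(classify_de(29, 9), "up")      # 30 >= 3 * 10, boundary
  expect_equal(classify_de(0, 0), "none")     # 1 < 3
  expect_equal(classify_de(9, 29), "down")
})

test_that("classification and point estimates are antisymmetric", {
  set.seed(77)
  n_checked <- 0
  for (i in 1:1000) {
    a <- random_synth_fit("g")
    b <- random_synth_fit("g")
    ea <- extract_events(a); eb <- extract_events(b)
    up_ab <- classify_early_up(ea, eb, a, b)
    up_ba <- classify_early_up(eb, ea, b, a)
    swap <- c(early = "late", late = "early", unchanged = "unchanged",
              "n/a" = "n/a")
    expect_identical(up_ba, unname(swap[up_ab]))
    pk_ab <- classify_early_peak(ea, eb)
    pk_ba <- classify_early_peak(eb, ea)
    expect_identical(pk_ba, unname(swap[pk_ab]))
    de_swap <- c(up = "down", down = "up", none = "none")
    expect_identical(classify_de(eb, ea),
                     unname(de_swap[classify_de(ea, eb)]))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1000)
})

test_that("acceleration points prefer peaks and invert under swap", {
  ev <- function(gene, up, peak) data.frame(gene_id = gene, up_start = up,
                                            up_slope = 1, up_duration = 5,
                                            peak_time = peak,
                                            max_fitted = 10)
  test <- rbind(ev("a", 4, 5), ev("b", 8, NA), ev("c", 0, NA),
                ev("d", NA, 6))
  ref <- rbind(ev("a", 6, 10), ev("b", 12, NA), ev("c", 5, NA),
               ev("d", NA, 12))
  pts <- acceleration_points(test, ref)
  # gene a: both peaks -> 10/5 = 2 (up-start ratio 1.5 ignored)
  expect_equal(pts$ratio[pts$gene_id == "a"], 2)
  expect_equal(pts$source[pts$gene_id == "a"], "peak")
  # gene b: shared up-trends -> 12/8
  expect_equal(pts$ratio[pts$gene_id == "b"], 1.5)
  # gene c: test up-start at day 0 -> discarded
  expect_false("c" %in% pts$gene_id)
  # swap inverts ratios
  pts_swap <- acceleration_points(ref, test)
  m <- merge(pts, pts_swap, by = "gene_id")
  expect_equal(m$ratio.x, 1 / m$ratio.y)
})

test_that("smoothing reproduces constant factors and the identity null", {
  pts <- data.frame(gene_id = paste0("g", 1:20),
                    test_time = seq(1, 20, 1), ratio = 1.7,
                    source = "peak")
  ac <- smooth_acceleration(pts)
  expect_equal(ac$window_median, 1.7, tolerance = 1e-8)
  expect_equal(range(ac$curve$a), c(1.7, 1.7), tolerance = 1e-8)

  pts1 <- pts; pts1$ratio <- 1
  expect_equal(smooth_acceleration(pts1)$window_median, 1,
               tolerance = 1e-6)

  # degenerate span falls back to a constant fit with a warning
  few <- pts[1:3, ]
  expect_warning(ac2 <- smooth_acceleration(few), "degenerate")
  expect_equal(ac2$window_median, 1.7, tolerance = 1e-8)
})

test_that("early-up calls are sensitive to real warps and specific without them", {
  # sensitivity: flat-then-rise genes observed with bulk-like NB noise in a
  # reference and a 1.7x-warped condition, with true leads of at least 4
  # days (comfortably beyond the sampling-grid resolution, which bounds any
  # estimator's lead precision)
  set.seed(99)
  days <- c(0:14, seq(16, 42, 2)); times <- rep(days, each = 3)
  w <- warp_function(c(1.7, 1), 16)
  scale <- 50
  hits <- 0; n <- 120
  for (i in seq_len(n)) {
    b1 <- runif(1, 10, 26)
    spec <- trend_spec(runif(1, 2, 20), b1, c(0, runif(1, 1, 5)), c(0, 42))
    wspec <- warp_trend(spec, w)
    yr <- rnbinom(length(times), mu = scale * trend_values(spec, times),
                  size = 50)
    yt <- rnbinom(length(times), mu = scale * trend_values(wspec, times),
                  size = 50)
    fr <- fit_segmented(yr, times); ft <- fit_segmented(yt, times)
    hits <- hits + (classify_early_up(extract_events(ft),
                                      extract_events(fr), ft, fr) ==
                      "early")
  }
  expect_gte(hits / n, 0.9)

  # specificity: two independent cohorts of the same unwarped condition;
  # early calls across all genes stay at or below 5%
  tot <- 0; early <- 0
  for (seed in 1:6) {
    sp <- sim_fit_pair(seed, n_genes = 200, warp_rate = NULL,
                       test_label = "H100b", human_frac = 1)
    cl <- classify_tempo(sp$test_fits, sp$ref_fits)
    tot <- tot + nrow(cl)
    early <- early + sum(cl$up_call == "early")
  }
  expect_lte(early / tot, 0.05)
})

test_that("identical conditions give ratio 1 and no calls", {
  set.seed(5)
  days <- c(0:14, seq(16, 42, 2)); t <- rep(days, each = 3)
  specs <- replicate(12, random_trend_spec_grid(
    sample(c("rise", "rise_flat", "peak"), 1), 42, grid = NULL),
    simplify = FALSE)
  names(specs) <- paste0("G", seq_along(specs))
  fits <- fit_all(trend_matrix(specs, t), t)
  cl <- classify_tempo(fits, fits)
  expect_true(all(cl$up_call %in% c("unchanged", "n/a")))
  expect_true(all(cl$peak_call %in% c("unchanged", "n/a")))
  expect_true(all(cl$de_call == "none"))
  ev <- events_table(fits)
  pts <- acceleration_points(ev, ev)
  expect_true(all(pts$ratio == 1))
})
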