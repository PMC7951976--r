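test_that("dynamic gene ranking recomputes the CV oracle", {
  t <- rep(0:10, each = 2)
  fits <- list(
    constant = fit_segmented(rep(20, length(t)), t, gene_id = "constant"),
    mild = fit_segmented(20 + t, t, gene_id = "mild"),
    steep = fit_segmented(5 + 4 * t, t, gene_id = "steep"))
  got <- dynamic_genes(list(mix = fits), n = 2)
  cv <- vapply(fits, function(f)
    stats::sd(fitted(f)) / mean(fitted(f)), numeric(1))
  expect_equal(got, names(sort(cv, decreasing = TRUE))[1:2])
  expect_false("constant" %in% dynamic_genes(list(mix = fits), n = 2))
  expect_equal(dynamic_genes(list(mix = fits), n = 1), "steep")
})

test_that("self-correlation maps are symmetric with unit diagonal", {
  set.seed(6)
  days <- seq(0, 20, 2)
  counts <- matrix(rnbinom(40 * length(days) * 2, mu = 60, size = 5),
                   40)
  rownames(counts) <- paste0("g", 1:40)
  samples <- data.frame(sample_id = paste0("s", seq_len(ncol(counts))),
                        mixture = "H100",
                        day = rep(days, each = 2), replicate = 1:2)
  colnames(counts) <- samples$sample_id
  sm <- species_matrix(counts, "hg19", samples)
  map <- correlation_map(sm, sm, rownames(counts))
  expect_equal(unname(diag(map$map)), rep(1, length(days)))
  expect_equal(map$map, t(map$map))
  expect_true(all(map$map >= -1 & map$map <= 1))
})

test_that("the correlation ridge tracks a two-fold warp", {
  set.seed(9)
  days <- c(0:14, seq(16, 42, 2)); t <- days
  specs <- replicate(60, random_trend_spec_grid(
    sample(c("rise", "rise_flat", "peak", "fall"), 1), 42, NULL),
    simplify = FALSE)
  names(specs) <- paste0("G", seq_along(specs))
  w <- warp_function(c(2, 1), 16)
  warped <- lapply(specs, warp_trend, warp = w)
  samples <- data.frame(sample_id = paste0("d", days), mixture = "X",
                        day = days, replicate = 1)
  mk <- function(sp) {
    cm <- trend_matrix(sp, t); colnames(cm) <- samples$sample_id
    species_matrix(cm, "hg19", samples)
  }
  map <- correlation_map(mk(specs), mk(warped), names(specs))
  # for reference days within the warped span, the best test day is ~ t/2
  for (ti in c(8, 12, 16, 20)) {
    i <- which(map$ref_days == ti)
    best <- map$test_days[which.max(map$map[i, ])]
    expect_lte(abs(best - warp_inverse(w, ti)), 2)
  }
})

test_that("segmented correlation fit recovers identity and bounds", {
  set.seed(10)
  days <- c(0:14, seq(16, 42, 2))
  specs <- replicate(60, random_trend_spec_grid(
    sample(c("rise", "rise_flat", "peak", "fall"), 1), 42, NULL),
    simplify = FALSE)
  names(specs) <- paste0("G", seq_along(specs))
  samples <- data.frame(sample_id = paste0("d", days), mixture = "X",
                        day = days, replicate = 1)
  mk <- function(sp) {
    cm <- trend_matrix(sp, days) +
      matrix(abs(rnorm(length(sp) * length(days), sd = 0.5)),
             length(sp))
    colnames(cm) <- samples$sample_id
    species_matrix(cm, "hg19", samples)
  }
  ref <- mk(specs)
  fit_id <- fit_correlation_acceleration(correlation_map(ref, ref,
                                                         names(specs)))
  expect_equal(fit_id$slopes[1], 1, tolerance = 0.05)

  # warp 2: first-segment slope near 2
  warped <- lapply(specs, warp_trend, warp = warp_function(c(2, 1), 16))
  fit2 <- fit_correlation_acceleration(
    correlation_map(ref, mk(warped), names(specs)))
  expect_equal(fit2$slopes[1], 2, tolerance = 0.2)

  # a ridge far outside the box pins the slope at the bound, flagged
  rd <- seq(0, 42, 2); td <- seq(0, 2, 0.25)
  ridge <- outer(rd, td, function(y, x) exp(-(y - 20 * x)^2 / 50))
  map20 <- structure(list(map = ridge, ref_days = rd, test_days = td,
                          panel = "synthetic"), class = "corr_map")
  fit20 <- fit_correlation_acceleration(map20)
  expect_equal(fit20$slopes[1], 10, tolerance = 1e-4)
  expect_true(any(fit20$at_bound))

  # reciprocity: transposing the map inverts the slope (within the
  # bootstrap-scale uncertainty of the weighted total-least-squares fit)
  map12 <- correlation_map(ref, mk(warped), names(specs))
  map21 <- structure(list(map = t(map12$map), ref_days = map12$test_days,
                          test_days = map12$ref_days,
                          panel = map12$panel), class = "corr_map")
  finv <- fit_correlation_acceleration(map21)
  expect_equal(finv$slopes[1] * fit2$slopes[1], 1, tolerance = 0.3)
})

test_that("off-trajectory weights do not drive the minimizer", {
  set.seed(12)
  days <- c(0:14, seq(16, 42, 2))
  specs <- replicate(50, random_trend_spec_grid(
    sample(c("rise", "rise_flat", "peak"), 1), 42, NULL),
    simplify = FALSE)
  names(specs) <- paste0("G", seq_along(specs))
  samples <- data.frame(sample_id = paste0("d", days), mixture = "X",
                        day = days, replicate = 1)
  mk <- function(M) {
    colnames(M) <- samples$sample_id
    species_matrix(M, "hg19", samples)
  }
  ref <- mk(trend_matrix(specs, days))
  warped <- lapply(specs, warp_trend, warp = warp_function(c(1.5, 1), 16))
  test <- mk(trend_matrix(warped, days))
  map <- correlation_map(ref, test, names(specs))
  f1 <- fit_correlation_acceleration(map)
  # zero the weights of day pairs far from the fitted trajectory
  d2 <- heterochron:::perp_dist2(
    rep(map$test_days, each = length(map$ref_days)),
    rep(map$ref_days, length(map$test_days)),
    f1$slopes, 16)
  map2 <- map
  map2$map[matrix(d2 > 36, length(map$ref_days))] <- 0
  f2 <- fit_correlation_acceleration(map2)
  expect_lt(abs(f2$slopes[1] - f1$slopes[1]), 0.05)
})
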