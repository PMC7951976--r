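# shared fixture builders; everything is generated in code at test time

# small hand-built chimeric matrix
make_chimeric <- function(counts = NULL, n_h = 2, n_m = 2, n_samp = 2) {
  if (is.null(counts)) {
    counts <- matrix(seq_len((n_h + n_m) * n_samp) * 1.5,
                     n_h + n_m, n_samp)
    rownames(counts) <- c(paste0("hg19_GENE", seq_len(n_h)),
                          paste0("mm10_Gene", seq_len(n_m)))
    colnames(counts) <- paste0("s", seq_len(n_samp))
  }
  samples <- data.frame(sample_id = colnames(counts), mixture = "H100",
                        day = seq_len(ncol(counts)) - 1, replicate = 1,
                        stringsAsFactors = FALSE)
  chimeric_matrix(counts, samples)
}

# build a segfit-structured object directly from a trend description,
# without running the regression (for classification truth tables)
synth_fit <- function(breakpoints, slopes, baseline = 10,
                      directions = NULL, t_range = c(0, 42),
                      gene_id = "g") {
  spec <- trend_spec(baseline, breakpoints, slopes, t_range)
  times <- seq(t_range[1], t_range[2], length.out = 43)
  fv <- trend_values(spec, times)
  if (is.null(directions))
    directions <- ifelse(slopes > 0, "up", ifelse(slopes < 0, "down", "flat"))
  structure(list(gene_id = gene_id, breakpoints = breakpoints,
                 k = length(breakpoints),
                 coefficients = c(baseline, slopes[1], diff(slopes)),
                 slopes = slopes, slope_se = rep(0, length(slopes)),
                 slope_p = ifelse(directions == "flat", 1, 0),
                 directions = directions, fitted.values = fv,
                 residuals = rep(0, length(times)), rss = 0,
                 bic = NA, n = length(times), alpha = 0.1, min_points = 5,
                 times = times, y = fv, t_range = t_range),
            class = "segfit")
}

# random synthetic segfit for property tests (direction labels consistent
# with slopes)
random_synth_fit <- function(gene_id = "g", t_range = c(0, 42)) {
  arch <- sample(c("flat", "rise", "rise_flat", "peak", "fall"), 1)
  spec <- random_trend_spec_grid(arch, t_max = t_range[2], grid = NULL)
  synth_fit(spec$breakpoints, spec$slopes, spec$baseline,
            t_range = t_range, gene_id = gene_id)
}

# archetype trends with optional grid-aligned breakpoints
random_trend_spec_grid <- function(archetype, t_max = 42, grid = NULL) {
  pick <- function(lo, hi) {
    if (is.null(grid)) stats::runif(1, lo, hi)
    else sample(grid[grid >= lo & grid <= hi], 1)
  }
  switch(archetype,
    flat = trend_spec(stats::runif(1, 5, 50), t_range = c(0, t_max)),
    rise = trend_spec(stats::runif(1, 2, 20), pick(4, t_max - 14),
                      c(0, stats::runif(1, 1, 5)), c(0, t_max)),
    rise_flat = {
      b1 <- pick(4, t_max - 22); b2 <- b1 + pick(6, 14)
      trend_spec(stats::runif(1, 2, 20), c(b1, b2),
                 c(0, stats::runif(1, 1, 5), 0), c(0, t_max))
    },
    peak = {
      b1 <- pick(4, t_max - 24); b2 <- b1 + pick(6, 12)
      base <- stats::runif(1, 2, 20); up <- stats::runif(1, 1, 5)
      height <- base + up * (b2 - b1)
      down <- -min(stats::runif(1, 0.3, 1) * up,
                   0.95 * height / (t_max - b2))
      trend_spec(base, c(b1, b2), c(0, up, down), c(0, t_max))
    },
    fall = {
      b1 <- pick(4, t_max - 17); base <- stats::runif(1, 20, 60)
      down <- -min(stats::runif(1, 0.3, 2), 0.95 * base / (t_max - b1))
      trend_spec(base, b1, c(0, down), c(0, t_max))
    })
}

# simulate one human cohort pair and return fits + events for both mixtures
sim_fit_pair <- function(seed, n_genes = 150, warp_rate = 1.7,
                         warp_until = 16, test_label = "H10",
                         human_frac = 0.1) {
  mixtures <- list(list(label = "H100", human_frac = 1))
  mixtures[[2]] <- if (is.null(warp_rate))
    list(label = test_label, human_frac = human_frac)
  else
    list(label = test_label, human_frac = human_frac,
         warp_rate = warp_rate, warp_until = warp_until)
  cfg <- simulation_config(n_genes = n_genes, seed = seed,
                           mixtures = mixtures)
  sim <- simulate_timecourse(cfg)
  h <- split_by_species(sim$matrix)$hg19
  sel <- function(mx) {
    i <- h$samples$mixture == mx
    species_matrix(h$counts[, i, drop = FALSE], "hg19", h$samples[i, ])
  }
  nr <- two_stage_normalize(sel("H100"))
  nt <- two_stage_normalize(sel(test_label))
  genes <- trendy_gene_filter(list(nr, nt))
  fr <- fit_all(nr$values[genes, , drop = FALSE], nr$samples$day)
  ft <- fit_all(nt$values[genes, , drop = FALSE], nt$samples$day)
  list(sim = sim, ref_sm = sel("H100"), test_sm = sel(test_label),
       ref_norm = nr, test_norm = nt, ref_fits = fr, test_fits = ft,
       ref_events = events_table(fr), test_events = events_table(ft))
}

# independent brute-force segmented least squares (enumeration oracle)
brute_force_rss <- function(y, t, k, min_points = 5) {
  ut <- sort(unique(t))
  cand <- ut[-c(1, length(ut))]
  cfgs <- if (k == 0) list(numeric(0))
          else utils::combn(cand, k, simplify = FALSE)
  best <- Inf
  for (bp in cfgs) {
    cnt <- vapply(seq_len(k + 1), function(j) {
      lo <- c(min(ut), bp)[j]; hi <- c(bp, max(ut))[j]
      sum(t >= lo & t <= hi)
    }, integer(1))
    if (any(cnt < min_points)) next
    X <- cbind(1, t)
    for (b in bp) X <- cbind(X, pmax(t - b, 0))
    r <- sum(stats::.lm.fit(X, y)$residuals^2)
    if (r < best) best <- r
  }
  best
}
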