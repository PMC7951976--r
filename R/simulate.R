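#' Configuration for the chimeric time-course generator
#'
#' Defaults mirror the study design the package targets: triplicate bulk
#' RNA-seq sampling, daily over the first two weeks and every second day
#' thereafter to day 42; negative-binomial expected counts at bulk-like
#' dispersion; log-normal sequencing depth; a small cross-species
#' bleed-through standing in for read misalignment; and a pure-human
#' reference condition (H100) alongside a 10%-human chimeric condition (H10)
#' whose human genes run at a 1.7x tempo over the first 16 days.
#'
#' @param n_genes Genes per species.
#' @param days Sampling grid (days since differentiation start).
#' @param replicates Biological replicates per (mixture, day).
#' @param mixtures List of mixture descriptions; each a list with
#'   \code{label}, \code{human_frac} (day-0 human fraction), and optional
#'   \code{warp_rate}/\code{warp_until} (human-gene tempo factor and the day
#'   it reverts to 1) and \code{mouse_warp_rate}/\code{mouse_warp_until}.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param depth_mean,depth_cv Mean and CV of per-sample sequencing depth
#'   (total expected counts).
#' @param bleed_rate Fraction of each species' counts reassigned to the other
#'   species' genes.
#' @param accelerated_fraction Share of genes that follow the mixture warp;
#'   the rest keep the reference tempo.
#' @param drift_rate Logit-scale drift of the human fraction per day in mixed
#'   cultures (positive: the human share rises, reaching ~50% by day 12 when
#'   seeded at 10%).
#' @param archetype_probs Sampling weights for the trend archetypes
#'   flat / rise / rise_flat / peak / fall.
#' @param noise "nb" for stochastic counts, "none" for exact means
#'   (deterministic depth, proportional bleed).
#' @param n_mito Mitochondrial decoy genes per species (flat trends, symbols
#'   beginning MT-).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genes = 200,
                              days = c(0:14, seq(16, 42, by = 2)),
                              replicates = 3,
                              mixtures = list(
                                list(label = "H100", human_frac = 1),
                                list(label = "H10", human_frac = 0.1,
                                     warp_rate = 1.7, warp_until = 16)),
                              nb_dispersion = 0.02,
                              depth_mean = 1e6, depth_cv = 0.3,
                              bleed_rate = 0.005,
                              accelerated_fraction = 1,
                              drift_rate = 0.183,
                              archetype_probs = c(flat = 0.45, rise = 0.15,
                                                  rise_flat = 0.15,
                                                  peak = 0.15, fall = 0.1),
                              noise = c("nb", "none"),
                              n_mito = 0,
                              seed = 1) {
  noise <- match.arg(noise)
  stopifnot(n_genes >= 1, replicates >= 1, nb_dispersion > 0,
            depth_mean > 0, depth_cv >= 0,
            bleed_rate >= 0, bleed_rate <= 1,
            accelerated_fraction >= 0, accelerated_fraction <= 1)
  for (mx in mixtures) {
    if (is.null(mx$label) || is.null(mx$human_frac))
      stop("each mixture needs label and human_frac")
    if (mx$human_frac < 0 || mx$human_frac > 1)
      stop("human_frac must be in [0, 1]")
  }
  structure(list(n_genes = n_genes, days = sort(unique(days)),
                 replicates = replicates, mixtures = mixtures,
                 nb_dispersion = nb_dispersion, depth_mean = depth_mean,
                 depth_cv = depth_cv, bleed_rate = bleed_rate,
                 accelerated_fraction = accelerated_fraction,
                 drift_rate = drift_rate,
                 archetype_probs = archetype_probs, noise = noise,
                 n_mito = n_mito, seed = seed),
            class = "simulation_config")
}

# draw one trend from the archetype library; breakpoint ranges scale with
# the course length (at the default 42-day course they stay >= 5 days apart
# and clear of the boundaries so segments remain identifiable)
random_trend_spec <- function(archetype, t_max = 42) {
  u <- function(lo, hi) stats::runif(1, lo * t_max / 42, hi * t_max / 42)
  switch(archetype,
    flat = trend_spec(stats::runif(1, 5, 50), t_range = c(0, t_max)),
    rise = {
      b1 <- u(4, 28)
      trend_spec(stats::runif(1, 2, 20), b1,
                 c(0, stats::runif(1, 1, 5)), c(0, t_max))
    },
    rise_flat = {
      b1 <- u(4, 20); b2 <- b1 + u(6, 14)
      trend_spec(stats::runif(1, 2, 20), c(b1, b2),
                 c(0, stats::runif(1, 1, 5), 0), c(0, t_max))
    },
    peak = {
      b1 <- u(4, 18); b2 <- b1 + u(6, 12)
      base <- stats::runif(1, 2, 20); up <- stats::runif(1, 1, 5)
      height <- base + up * (b2 - b1)
      down <- -min(stats::runif(1, 0.3, 1) * up,
                   0.95 * height / (t_max - b2))
      trend_spec(base, c(b1, b2), c(0, up, down), c(0, t_max))
    },
    fall = {
      b1 <- u(4, 25); base <- stats::runif(1, 20, 60)
      down <- -min(stats::runif(1, 0.3, 2), 0.95 * base / (t_max - b1))
      trend_spec(base, b1, c(0, down), c(0, t_max))
    },
    stop("unknown archetype: ", archetype))
}

mixture_warp <- function(mx, field = "warp") {
  rate <- mx[[paste0(field, "_rate")]]
  until <- mx[[paste0(field, "_until")]]
  if (is.null(rate) || rate == 1) return(NULL)
  if (is.null(until)) until <- 16
  warp_function(c(rate, 1), until)
}

human_fraction <- function(f0, days, drift_rate) {
  if (f0 <= 0 || f0 >= 1) return(rep(f0, length(days)))
  stats::plogis(stats::qlogis(f0) + drift_rate * days)
}

#' Simulate a chimeric dual-species time course
#'
#' Generates species-tagged expected-count matrices under known piecewise-
#' linear gene programs, a known time warp between conditions, logistic
#' composition drift, log-normal depth, negative-binomial counts, and
#' cross-species bleed-through. The returned truth object is sufficient to
#' recompute every downstream expected value.
#'
#' @param config A [simulation_config()].
#' @return List with elements \code{matrix} (a [chimeric_matrix()]) and
#'   \code{truth} (trend specs per species, warp per mixture, per-sample
#'   composition/depth, accelerated flags, outlier labels).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  arch <- names(config$archetype_probs)
  draw_specs <- function(prefix) {
    a <- sample(arch, ng, replace = TRUE, prob = config$archetype_probs)
    sp <- lapply(a, random_trend_spec, t_max = max(config$days))
    names(sp) <- paste0(prefix, seq_len(ng))
    sp
  }
  human <- draw_specs("HG")
  mouse <- draw_specs("Mg")
  if (config$n_mito > 0) {
    mito <- function(prefix) {
      sp <- replicate(config$n_mito, random_trend_spec("flat", max(config$days)),
                      simplify = FALSE)
      names(sp) <- paste0("MT-", prefix, seq_len(config$n_mito))
      sp
    }
    human <- c(human, mito("H"))
    mouse <- c(mouse, mito("M"))
  }
  accelerated <- stats::runif(length(human)) < config$accelerated_fraction
  names(accelerated) <- names(human)

  days_rep <- rep(config$days, each = config$replicates)
  reps <- rep(seq_len(config$replicates), length(config$days))
  blocks <- list(); meta <- list(); truth_samples <- list()
  warps <- list()
  for (mx in config$mixtures) {
    hw <- mixture_warp(mx, "warp")
    mw <- mixture_warp(mx, "mouse_warp")
    warps[[mx$label]] <- list(human = hw, mouse = mw)
    f_day <- human_fraction(mx$human_frac, days_rep, config$drift_rate)
    # per-gene means on the sampling grid (genes x samples of this mixture)
    mu_at <- function(specs, warp, flags) {
      t(vapply(seq_along(specs), function(i) {
        tt <- if (!is.null(warp) && flags[i]) warp_map(warp, days_rep)
              else days_rep
        trend_values(specs[[i]], tt)
      }, numeric(length(days_rep))))
    }
    mu_h <- mu_at(human, hw, accelerated)
    mu_m <- mu_at(mouse, mw, accelerated)
    n_s <- length(days_rep)
    depth <- if (config$noise == "nb") {
      # log-normal truncated at +/- 2 sd: pooled libraries are depth-
      # balanced, so routine variation stays within a band; extreme
      # depths are the failure mode modeled by injected outliers
      sdlog <- sqrt(log(1 + config$depth_cv^2))
      z <- stats::qnorm(stats::runif(n_s, stats::pnorm(-2), stats::pnorm(2)))
      exp(log(config$depth_mean) - sdlog^2 / 2 + sdlog * z)
    } else rep(config$depth_mean, n_s)
    counts <- matrix(0, length(human) + length(mouse), n_s)
    rownames(counts) <- c(paste0("hg19_", names(human)),
                          paste0("mm10_", names(mouse)))
    hi <- seq_along(human); mi <- length(human) + seq_along(mouse)
    for (s in seq_len(n_s)) {
      tot_h <- depth[s] * f_day[s]; tot_m <- depth[s] * (1 - f_day[s])
      mh <- mu_h[, s]; mm <- mu_m[, s]
      eh <- if (sum(mh) > 0) tot_h * mh / sum(mh) else mh * 0
      em <- if (sum(mm) > 0) tot_m * mm / sum(mm) else mm * 0
      if (config$noise == "nb") {
        yh <- stats::rnbinom(length(eh), mu = eh, size = 1 / config$nb_dispersion)
        ym <- stats::rnbinom(length(em), mu = em, size = 1 / config$nb_dispersion)
        if (config$bleed_rate > 0) {
          bh <- stats::rbinom(length(yh), yh, config$bleed_rate)
          bm <- stats::rbinom(length(ym), ym, config$bleed_rate)
          yh <- yh - bh; ym <- ym - bm
          ph <- if (sum(mh) > 0) mh else rep(1, length(mh))
          pm <- if (sum(mm) > 0) mm else rep(1, length(mm))
          if (sum(bh) > 0) ym <- ym + stats::rmultinom(1, sum(bh), pm)[, 1]
          if (sum(bm) > 0) yh <- yh + stats::rmultinom(1, sum(bm), ph)[, 1]
        }
      } else {
        # deterministic: expected counts with proportional bleed
        br <- config$bleed_rate
        yh <- eh * (1 - br); ym <- em * (1 - br)
        ph <- if (sum(mh) > 0) mh / sum(mh) else rep(1 / length(mh), length(mh))
        pm <- if (sum(mm) > 0) mm / sum(mm) else rep(1 / length(mm), length(mm))
        ym <- ym + sum(eh) * br * pm
        yh <- yh + sum(em) * br * ph
      }
      counts[hi, s] <- yh; counts[mi, s] <- ym
    }
    ids <- sprintf("%s_d%02g_r%d", mx$label, days_rep, reps)
    colnames(counts) <- ids
    blocks[[mx$label]] <- counts
    meta[[mx$label]] <- data.frame(sample_id = ids, mixture = mx$label,
                                   day = days_rep, replicate = reps,
                                   stringsAsFactors = FALSE)
    truth_samples[[mx$label]] <- data.frame(sample_id = ids,
                                            human_frac = f_day, depth = depth,
                                            outlier = "none",
                                            stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  samples <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  truth <- list(human_specs = human, mouse_specs = mouse, warps = warps,
                accelerated = accelerated,
                samples = do.call(rbind, c(truth_samples,
                                           list(make.row.names = FALSE))),
                bleed_rate = config$bleed_rate, config = config)
  list(matrix = chimeric_matrix(counts, samples), truth = truth)
}

#' Inject quality-control failures into a simulated cohort
#'
#' Low-depth outliers rescale a sample's counts by a small factor; scrambled
#' outliers permute a sample's counts across genes (destroying its agreement
#' with replicate and neighboring samples while preserving its depth).
#' Injected labels are recorded in the truth object.
#'
#' @param sim Result of [simulate_timecourse()].
#' @param low_depth Optional list: \code{sample_ids}, \code{factor}
#'   (default 1e-3).
#' @param scramble Optional list: \code{sample_ids}.
#' @param seed Seed for the scramble permutation.
#' @return The modified \code{sim} list.
#' @export
inject_outliers <- function(sim, low_depth = NULL, scramble = NULL, seed = 1) {
  m <- sim$matrix; truth <- sim$truth
  set.seed(seed)
  if (!is.null(low_depth)) {
    fac <- if (is.null(low_depth$factor)) 1e-3 else low_depth$factor
    idx <- match(low_depth$sample_ids, colnames(m$counts))
    if (anyNA(idx)) stop("unknown sample ids in low_depth")
    m$counts[, idx] <- m$counts[, idx, drop = FALSE] * fac
    truth$samples$outlier[match(low_depth$sample_ids,
                                truth$samples$sample_id)] <- "low_depth"
  }
  if (!is.null(scramble)) {
    idx <- match(scramble$sample_ids, colnames(m$counts))
    if (anyNA(idx)) stop("unknown sample ids in scramble")
    for (s in idx) m$counts[, s] <- m$counts[sample.int(nrow(m$counts)), s]
    truth$samples$outlier[match(scramble$sample_ids,
                                truth$samples$sample_id)] <- "scrambled"
  }
  list(matrix = m, truth = truth)
}
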