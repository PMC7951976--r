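#' Pipeline configuration
#'
#' Assembles the parameters of every analysis stage with the package's
#' defaults (minimum lead 2 days, slope-ratio guard 5, DE fold 3 with bias
#' 1, up to 5 segments with 5 points each at alpha 0.1, activity quantile
#' 0.8 over 20, dynamic panels of 2000/1500 genes, correlation breakpoint
#' at day 16 with slope bounds [1/10, 10], reduction to 6 components with
#' penalty 10 and 400 minimum iterations). The \code{"sorted"} preset
#' switches only the segmented-regression parameters (minimum 2 points per
#' segment, for the sparser sorted-sample series).
#'
#' @param ... Overrides for any default (nested lists are merged).
#' @param preset "default" or "sorted".
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(..., preset = c("default", "sorted")) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = 1,
    simulate = TRUE,
    simulation = list(),            # overrides for simulation_config()
    counts = NULL, meta = NULL,     # used when simulate = FALSE
    species = "hg19",
    reference_mixture = "H100",
    pure_mixtures = list(H100 = "hg19", M100 = "mm10"),
    qc = list(p_threshold = 1e-05, n_top = 1000, n_comp = 10,
              spline_degree = 4),
    fit = list(max_segments = 5, min_points = 5, alpha = 0.1),
    activity = list(quantile = 0.8, threshold = 20),
    classify = list(min_lead = 2, slope_ratio = 5, fold = 3, bias = 1),
    accel = list(df = 4, window = c(0, 16)),
    correlate = list(n_dynamic = 2000, breakpoint = 16,
                     bounds = c(1 / 10, 10), n_boot = 200),
    reference = list(n_union = 1500, k = 6, penalty = 10, min_iter = 400),
    enrich = list(n_perm = 1e5, min_size = 1, max_size = 250),
    gmt = NULL,
    preset = preset)
  if (preset == "sorted") cfg$fit$min_points <- 2
  cfg <- modify_list_deep(cfg, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
        !is.null(names(new[[nm]])))
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    else base[[nm]] <- new[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; its keys override [pipeline_config()] defaults.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- if (!is.null(y$preset)) y$preset else "default"
  y$preset <- NULL
  do.call(pipeline_config, c(y, list(preset = preset)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end tempo analysis
#'
#' Simulate (or read) a chimeric time course, apply depth and replicate QC,
#' split and normalize per species, fit segmented trends per mixture,
#' classify tempo and differential expression against the reference
#' mixture, estimate event-based and correlation-based acceleration, and
#' (when gene sets are supplied) run enrichment on the timing statistic.
#' Every stage writes its outputs under \code{out_dir} and the manifest
#' records all parameters, the seed, and content digests; reruns with the
#' same configuration reproduce the digests.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param out_dir Output directory (created; default a temporary one).
#' @return Invisibly, a list with the stage objects and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("heterochron-run-")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "heterochron",
                   version = as.character(utils::packageVersion("heterochron")),
                   seed = config$seed,
                   preset = config$preset,
                   parameters = config[setdiff(names(config),
                                               c("counts", "meta"))],
                   outputs = list(), failure = NULL)
  res <- list()
  ok <- TRUE
  stage <- function(name, expr) {
    if (!ok) return(invisible(NULL))
    r <- tryCatch(expr, error = function(e) e)
    if (inherits(r, "error")) {
      manifest$failure <<- list(stage = name, message = conditionMessage(r))
      ok <<- FALSE
      return(invisible(NULL))
    }
    r
  }

  res$data <- stage("data", {
    if (isTRUE(config$simulate)) {
      sim_cfg <- do.call(simulation_config,
                         modify_list_deep(list(seed = config$seed),
                                          config$simulation))
      sim <- simulate_timecourse(sim_cfg)
      write_counts(sim$matrix, file.path(out_dir, "counts.tsv"),
                   file.path(out_dir, "samples.csv"))
      sim
    } else {
      list(matrix = read_counts(config$counts, config$meta), truth = NULL)
    }
  })

  res$qc_depth <- stage("qc_depth", {
    rep_ <- depth_filter(res$data$matrix)
    write_tsv(rep_$samples, file.path(out_dir, "qc_depth.tsv"))
    rep_
  })
  res$filtered <- stage("qc_depth_apply", {
    keep <- qc_kept(res$qc_depth)
    m <- res$data$matrix
    chimeric_matrix(m$counts[, keep, drop = FALSE],
                    m$samples[match(keep, m$samples$sample_id), ],
                    m$species_tags, m$sep)
  })

  res$misalignment <- stage("misalignment", {
    out <- list()
    for (mx in names(config$pure_mixtures)) {
      sel <- res$filtered$samples$mixture == mx
      if (!any(sel)) next
      sub <- chimeric_matrix(res$filtered$counts[, sel, drop = FALSE],
                             res$filtered$samples[sel, ],
                             res$filtered$species_tags, res$filtered$sep)
      out[[mx]] <- misalignment_rate(sub, config$pure_mixtures[[mx]])
    }
    if (length(out)) {
      tab <- do.call(rbind, c(out, list(make.row.names = FALSE)))
      write_tsv(tab, file.path(out_dir, "misalignment.tsv"))
    }
    out
  })

  res$species <- stage("split", {
    sp <- split_by_species(res$filtered, drop_mito = TRUE)
    for (tag in names(sp))
      if (nrow(sp[[tag]]$counts))
        write_counts(sp[[tag]], file.path(out_dir,
                                          paste0("counts_", tag, ".tsv")))
    sp
  })

  res$qc_replicate <- stage("qc_replicate", {
    sm <- res$species[[config$species]]
    norm0 <- two_stage_normalize(sm)
    rep_ <- replicate_outlier_filter(norm0,
                                     p_threshold = config$qc$p_threshold,
                                     n_top = config$qc$n_top,
                                     n_comp = config$qc$n_comp,
                                     spline_degree = config$qc$spline_degree)
    write_tsv(rep_$samples, file.path(out_dir, "qc_replicate.tsv"))
    rep_
  })

  res$norm <- stage("normalize", {
    sm <- res$species[[config$species]]
    keep <- qc_kept(res$qc_replicate)
    sm2 <- species_matrix(sm$counts[, keep, drop = FALSE],
                          sm$species,
                          sm$samples[match(keep, sm$samples$sample_id), ])
    norm <- two_stage_normalize(sm2)
    write_tsv(data.frame(sample_id = colnames(norm$values),
                         stage1 = norm$stage1_factors,
                         stage2 = norm$stage2_factors),
              file.path(out_dir, "size_factors.tsv"))
    norm
  })

  res$fits <- stage("fit", {
    norm <- res$norm
    by_mix <- split(seq_len(ncol(norm$values)), norm$samples$mixture)
    values_by_mix <- lapply(by_mix, function(i)
      norm$values[, i, drop = FALSE])
    genes <- trendy_gene_filter(values_by_mix,
                                quantile = config$activity$quantile,
                                threshold = config$activity$threshold)
    fits <- lapply(names(by_mix), function(mx) {
      i <- by_mix[[mx]]
      fit_all(norm$values[genes, i, drop = FALSE], norm$samples$day[i],
              max_segments = config$fit$max_segments,
              min_points = config$fit$min_points,
              alpha = config$fit$alpha)
    })
    names(fits) <- names(by_mix)
    summ <- do.call(rbind, lapply(names(fits), function(mx)
      data.frame(mixture = mx, gene_id = names(fits[[mx]]),
                 k = vapply(fits[[mx]], `[[`, integer(1), "k"),
                 breakpoints = vapply(fits[[mx]], function(f)
                   paste(signif(f$breakpoints, 6), collapse = ","),
                   character(1)),
                 directions = vapply(fits[[mx]], function(f)
                   paste(f$directions, collapse = ","), character(1)),
                 stringsAsFactors = FALSE)))
    write_tsv(summ, file.path(out_dir, "fits.tsv"))
    fits
  })

  res$classification <- stage("classify", {
    ref <- config$reference_mixture
    if (!ref %in% names(res$fits)) stop("reference mixture not fitted")
    out <- list()
    for (mx in setdiff(names(res$fits), ref)) {
      cl <- classify_tempo(res$fits[[mx]], res$fits[[ref]],
                           min_lead = config$classify$min_lead,
                           slope_ratio = config$classify$slope_ratio,
                           fold = config$classify$fold,
                           bias = config$classify$bias)
      cl <- cbind(mixture = mx, cl)
      out[[mx]] <- cl
    }
    if (length(out))
      write_tsv(do.call(rbind, c(out, list(make.row.names = FALSE))),
                file.path(out_dir, "classification.tsv"))
    out
  })

  res$acceleration <- stage("accelerate", {
    ref <- config$reference_mixture
    ev_ref <- events_table(res$fits[[ref]])
    out <- list()
    for (mx in setdiff(names(res$fits), ref)) {
      ev <- events_table(res$fits[[mx]])
      pts <- acceleration_points(ev, ev_ref)
      ac <- smooth_acceleration(pts, df = config$accel$df,
                                window = config$accel$window)
      write_tsv(pts, file.path(out_dir, paste0("accel_points_", mx, ".tsv")))
      write_tsv(ac$curve, file.path(out_dir,
                                    paste0("accel_curve_", mx, ".tsv")))
      out[[mx]] <- ac
    }
    jsonlite::write_json(lapply(out, `[[`, "window_median"),
                         file.path(out_dir, "acceleration.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  res$correlation <- stage("correlate", {
    ref <- config$reference_mixture
    panel <- dynamic_genes(res$fits, n = config$correlate$n_dynamic)
    sm <- res$species[[config$species]]
    subm <- function(mx) {
      sel <- sm$samples$mixture == mx &
        sm$samples$sample_id %in% colnames(res$norm$values)
      species_matrix(sm$counts[, sel, drop = FALSE], sm$species,
                     sm$samples[sel, ])
    }
    out <- list()
    for (mx in setdiff(names(res$fits), ref)) {
      map <- correlation_map(subm(ref), subm(mx), panel)
      fit <- fit_correlation_acceleration(
        map, breakpoint = config$correlate$breakpoint,
        bounds = config$correlate$bounds,
        n_boot = config$correlate$n_boot,
        ref = subm(ref), test = subm(mx), seed = config$seed)
      utils::write.table(map$map,
                         file.path(out_dir, paste0("corr_map_", mx, ".tsv")),
                         sep = "\t", quote = FALSE)
      out[[mx]] <- fit
    }
    jsonlite::write_json(
      lapply(out, function(f) list(slopes = f$slopes, se = f$se,
                                   objective = f$objective)),
      file.path(out_dir, "correlation_acceleration.json"),
      auto_unbox = TRUE, digits = NA)
    out
  })

  res$enrichment <- stage("enrich", {
    if (is.null(config$gmt)) NULL else {
      sets <- if (is.character(config$gmt)) read_gmt(config$gmt)
              else config$gmt
      ref <- config$reference_mixture
      ev_ref <- events_table(res$fits[[ref]])
      out <- list()
      for (mx in setdiff(names(res$fits), ref)) {
        ev <- events_table(res$fits[[mx]])
        ts <- timing_statistic(ev, ev_ref)
        gs <- gsea_continuous(ts, sets, n_perm = config$enrich$n_perm,
                              min_size = config$enrich$min_size,
                              max_size = config$enrich$max_size,
                              seed = config$seed)
        write_tsv(gs, file.path(out_dir, paste0("enrichment_", mx, ".tsv")))
        out[[mx]] <- gs
      }
      out
    }
  })

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$outputs <- as.list(tools::md5sum(files))
  names(manifest$outputs) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
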