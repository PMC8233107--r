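#' Region bookkeeping for a parcellation with excluded parcels
#'
#' Drops the given 0-indexed region numbers from a parcellation, the
#' convention used when some atlas parcels carry no signal for part of the
#' cohort. The default excluded set is the five 333-parcel atlas regions
#' without coverage (0-indexed 133, 296, 299, 302, 304), leaving 328
#' analysis regions.
#'
#' @param n_regions total atlas regions (default 333).
#' @param excluded 0-indexed region numbers to drop.
#' @return integer vector of retained 0-indexed region numbers.
#' @export
analysis_regions <- function(n_regions = 333L,
                             excluded = default_excluded_regions()) {
  all <- seq_len(n_regions) - 1L
  if (any(!excluded %in% all)) stop("excluded indices outside the atlas")
  setdiff(all, excluded)
}

#' @rdname analysis_regions
#' @export
default_excluded_regions <- function() c(133L, 296L, 299L, 302L, 304L)

#' Read and write parcellated series as TSV
#'
#' The signal file is time x regions with a header row of region labels;
#' the events file is BIDS-style (`onset`, `duration`, `trial_type`,
#' optional `performance`). Numeric parsing and writing are
#' locale-independent; a write/read round trip preserves values to better
#' than 1e-12.
#'
#' @param path signal TSV path.
#' @param events_path events TSV path.
#' @param tr repetition time in seconds.
#' @param volunteer_id label for the series.
#' @return a `parcel_series`.
#' @export
read_parcel_series <- function(path, events_path, tr, volunteer_id = path) {
  fields <- utils::count.fields(path, sep = "\t")
  if (length(unique(fields)) != 1)
    stop(sprintf("ragged rows in %s (lines: %s)", path,
                 paste(which(fields != fields[1]), collapse = ", ")))
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "numeric")
  ev <- utils::read.delim(events_path)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("events file lacks columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  parcel_series(volunteer_id, t(as.matrix(tab)), tr, names(tab), ev)
}

#' @rdname read_parcel_series
#' @param series a `parcel_series` to write.
#' @export
write_parcel_series <- function(series, path, events_path) {
  tab <- as.data.frame(t(series$signal))
  names(tab) <- series$region_labels
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(series$events, events_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration defaults
#'
#' All method constants in one place: the Morlet filterbank (15 scales,
#' 0.007-0.15 Hz, omega0 = 6), trimming (120 time points, 2 scales), the
#' 20-slice sliced-Wasserstein distance, the 256-pixel Gaussian grid with
#' bandwidth factor 0.08, 300 permutations, 256 bootstraps and alpha =
#' 0.05, plus the synthetic-study defaults. Any entry can be overridden
#' via `...` or a YAML/JSON file.
#'
#' @param ... overrides.
#' @param file optional YAML or JSON file of overrides.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(
    seed = 1L, n_volunteers = 6L, n_regions = 60L, tr = 1.5,
    coupling_strength = 3, idiosyncrasy_strength = 1,
    performance_effect = 1, ar1_phi = 0.4, noise_sd = 1,
    f_min = 0.007, f_max = 0.15, n_scales = 15L, omega0 = 6,
    trim_time = 120L, trim_scales = 2L, scale_width = 3L,
    metrics = metric_names, n_slices = 20L,
    n_neighbors = 15L, min_dist = 0.1, n_epochs = 150L,
    grid = 256L, bandwidth_factor = 0.08,
    n_perm = 300L, n_boot = 256L, alpha = 0.05,
    n_train = 100L, eval_subsample = NULL, mode = "normal")
  if (!is.null(file)) {
    ov <- if (grepl("[.]json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
          else yaml::read_yaml(file)
    cfg[names(ov)] <- ov
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full state-space comparison pipeline
#'
#' Executes the four stages in order -- TVFC computation, the six metric
#' spaces, embedding + watershed segmentation, and the permutation
#' statistics -- on either a synthetic study generated from the
#' configuration or user-provided series, writing per-metric distance
#' matrices, the bootstrap summary, and a reproducible run manifest.
#'
#' @param config a [pipeline_config()] list.
#' @param out_dir output directory (created if missing).
#' @param series optional list of `parcel_series` (otherwise a synthetic
#'   study is generated from `config`).
#' @return a run manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run"),
                         series = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_line <- function(...) message(sprintf(...))
  log_line("parameters: omega0=%g, %d scales %g-%g Hz, trim %d/%d, %d slices, grid %d, bandwidth %.3g, %d permutations, %d bootstraps, alpha=%.3g",
           config$omega0, config$n_scales, config$f_min, config$f_max,
           config$trim_time, config$trim_scales, config$n_slices,
           config$grid, config$bandwidth_factor, config$n_perm,
           config$n_boot, config$alpha)
  stage <- "simulate"
  manifest <- list(seed = config$seed, stages = list(), outputs = character(0))
  result <- tryCatch({
    if (is.null(series)) {
      sc <- study_config(
        n_volunteers = config$n_volunteers, n_regions = config$n_regions,
        tr = config$tr, coupling_strength = config$coupling_strength,
        idiosyncrasy_strength = config$idiosyncrasy_strength,
        performance_effect = config$performance_effect,
        ar1_phi = config$ar1_phi, noise_sd = config$noise_sd,
        seed = config$seed)
      series <- generate_study(sc)
    }
    manifest$stages$simulate <- list(n_volunteers = length(series))

    stage <- "tvfc"
    fb <- build_filterbank(config$f_min, config$f_max, config$n_scales,
                           config$omega0, config$tr)
    tvfc <- lapply(series, compute_tvfc, fb = fb,
                   trim_time = config$trim_time,
                   trim_scales = config$trim_scales,
                   scale_width = config$scale_width)
    manifest$stages$tvfc <- list(
      n_points = sum(vapply(tvfc, function(t) dim(t$graphs)[1], 0)),
      retained_scales = length(tvfc[[1]]$retained_scales))

    stage <- "distances"
    points_by_vol <- lapply(tvfc, state_points)
    # one pairwise matrix per metric over a compact point subsample, for
    # inspection; the bootstrap recomputes per-split matrices itself
    probe_idx <- lapply(points_by_vol, function(p)
      unique(pmin(floor(seq(1, length(p), length.out = 20L)), length(p))))
    probe <- do.call(c, mapply(function(p, i) p[i], points_by_vol, probe_idx,
                               SIMPLIFY = FALSE))
    for (m in config$metrics) {
      Dm <- pairwise_distances(probe, m, config$n_slices)
      f <- file.path(out_dir, sprintf("distances_%s.csv", m))
      utils::write.csv(Dm$D, f, row.names = FALSE)
      manifest$outputs <- c(manifest$outputs, f)
    }

    stage <- "statistics"
    boot <- bootstrap_driver(points_by_vol, metrics = config$metrics,
                             n_boot = config$n_boot,
                             n_train = config$n_train,
                             eval_subsample = config$eval_subsample,
                             n_neighbors = config$n_neighbors,
                             min_dist = config$min_dist,
                             n_epochs = config$n_epochs, grid = config$grid,
                             bandwidth_factor = config$bandwidth_factor,
                             alpha = config$alpha, n_perm = config$n_perm,
                             mode = config$mode, n_slices = config$n_slices,
                             seed = config$seed)
    f <- file.path(out_dir, "bootstrap_summary.csv")
    utils::write.csv(boot$summary, f, row.names = FALSE)
    manifest$outputs <- c(manifest$outputs, f)
    list(tvfc = tvfc, bootstrap = boot)
  }, error = function(e)
    stop(sprintf("pipeline stage '%s' failed (seed %d): %s", stage,
                 config$seed, conditionMessage(e)), call. = FALSE))

  cfg_file <- file.path(out_dir, "config.json")
  ser <- config
  ser$metrics <- as.list(ser$metrics)
  jsonlite::write_json(ser, cfg_file, auto_unbox = TRUE, null = "null",
                       digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  manifest$outputs <- c(manifest$outputs, cfg_file)
  manifest$wall_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  mf <- manifest
  mf$wall_seconds <- NULL  # reruns with the same config hash identically
  jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$result <- result
  invisible(manifest)
}
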