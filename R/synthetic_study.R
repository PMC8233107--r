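#' Study configuration for the synthetic block-design generator
#'
#' Describes a multi-volunteer block-design scanning session with
#' condition-specific inter-regional coupling. Defaults emulate a
#' desk-scale version of a continuous 25.6-minute session at TR = 1.5 s:
#' eight blocks (rest, video, math and memory, each presented twice), each
#' a 12-s instruction segment followed by a 3-min task segment, giving
#' 1024 samples. Coupled activity is band-limited to the low-frequency
#' BOLD band 0.009-0.08 Hz.
#'
#' @param n_volunteers number of volunteers (divisible by 3 for the
#'   three-group split).
#' @param n_regions number of parcellated regions (>= 4).
#' @param tr repetition time in seconds.
#' @param block_layout data.frame with columns `condition`, `duration`
#'   (task seconds), `instruction` (instruction seconds), `performance`
#'   (fraction correct in \[0,1\], NA for rest). Default: the eight-block
#'   session described above with fixed per-block performance levels.
#' @param band numeric length-2, coupling passband in Hz.
#' @param coupling_strength nonnegative scalar; amplitude of the shared
#'   community signal relative to unit-variance noise.
#' @param idiosyncrasy_strength nonnegative scalar; size of the
#'   volunteer-specific mixing perturbation applied to the coupled
#'   component.
#' @param performance_effect scalar; coupling is scaled by
#'   `1 + performance_effect * (performance - 0.5)` within each block.
#' @param ar1_phi lag-1 autocorrelation of the additive noise, in (-1, 1).
#' @param noise_sd marginal standard deviation of the additive AR1 noise.
#' @param communities named integer vector: number of coupled communities
#'   per condition. Conditions absent from the map (and instruction
#'   segments) are uncoupled. The default gives each task a distinct
#'   network configuration -- video 2, math 4, memory 8 communities --
#'   with rest uncoupled, so condition contrasts are structural, not just
#'   a relabeling of regions.
#' @param seed integer seed; required, the study is a pure function of the
#'   configuration.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_volunteers = 6L, n_regions = 60L, tr = 1.5,
                         block_layout = default_block_layout(),
                         band = c(0.009, 0.08),
                         coupling_strength = 3, idiosyncrasy_strength = 1,
                         performance_effect = 1, ar1_phi = 0.4, noise_sd = 1,
                         communities = c(video = 2L, math = 4L, memory = 8L),
                         seed = NULL) {
  if (is.null(seed)) stop("`seed` is required: the study must be reproducible")
  if (n_regions < 4L) stop("n_regions must be >= 4")
  stopifnot(is.data.frame(block_layout),
            all(c("condition", "duration", "instruction", "performance") %in%
                  names(block_layout)))
  if (any(block_layout$duration <= 0))
    stop("zero- or negative-duration blocks are not invertible")
  perf <- block_layout$performance
  if (any(!is.na(perf) & (perf < 0 | perf > 1)))
    stop("block performance must lie in [0, 1]")
  nyq <- 1 / (2 * tr)
  if (!(band[1] < band[2] && band[2] < nyq))
    stop(sprintf("band must satisfy f_lo < f_hi < Nyquist = %.4f Hz", nyq))
  if (abs(ar1_phi) >= 1) stop("ar1_phi must lie in (-1, 1)")
  if (coupling_strength < 0 || idiosyncrasy_strength < 0)
    stop("strengths must be nonnegative")
  structure(list(
    n_volunteers = as.integer(n_volunteers), n_regions = as.integer(n_regions),
    tr = tr, block_layout = block_layout, band = band,
    coupling_strength = coupling_strength,
    idiosyncrasy_strength = idiosyncrasy_strength,
    performance_effect = performance_effect, ar1_phi = ar1_phi,
    noise_sd = noise_sd, communities = communities,
    seed = as.integer(seed)), class = "study_config")
}

#' Default eight-block session layout
#'
#' Rest, video, math and memory each presented twice; every presentation is
#' a 12-s instruction segment followed by a 180-s task segment (1536 s in
#' total). The session opens with rest and closes with video, so the
#' temporal trim of the coherence analysis removes most of one rest and one
#' video presentation. Task blocks carry fixed percent-correct performance
#' levels; rest has none.
#'
#' @return data.frame with columns condition, duration, instruction,
#'   performance.
#' @export
default_block_layout <- function() {
  data.frame(
    condition   = c("rest", "video", "math", "memory",
                    "rest", "math", "memory", "video"),
    duration    = rep(180, 8),
    instruction = rep(12, 8),
    performance = c(NA, 0.80, 0.90, 0.85, NA, 0.60, 0.55, 0.70),
    stringsAsFactors = FALSE)
}

#' Construct a parcellated series object
#'
#' @param volunteer_id label.
#' @param signal regions x time numeric matrix.
#' @param tr repetition time (seconds).
#' @param region_labels character vector, one per row of `signal`.
#' @param events data.frame with columns onset, duration, trial_type and
#'   optionally performance (seconds-based, within the scan).
#' @return object of class `parcel_series`.
#' @export
parcel_series <- function(volunteer_id, signal, tr, region_labels,
                          events) {
  signal <- as.matrix(signal)
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("signal contains missing or non-finite values")
  if (nrow(signal) != length(region_labels))
    stop("region count does not match region_labels")
  scan_end <- ncol(signal) * tr
  if (any(events$onset < 0) || any(events$onset + events$duration > scan_end + 1e-9))
    stop("events lie outside the scan")
  if (is.null(events$performance)) events$performance <- NA_real_
  structure(list(volunteer_id = volunteer_id, signal = signal, tr = tr,
                 region_labels = region_labels, events = events),
            class = "parcel_series")
}

#' @export
print.parcel_series <- function(x, ...) {
  cat(sprintf("<parcel_series> volunteer %s: %d regions x %d samples (TR %.2fs), %d events\n",
              x$volunteer_id, nrow(x$signal), ncol(x$signal), x$tr,
              nrow(x$events)))
  invisible(x)
}

# random-phase Fourier noise restricted to [f_lo, f_hi], unit variance
band_limited_noise <- function(n, tr, band) {
  freqs <- seq(0, 1 / tr, length.out = n + 1)[seq_len(n)]
  freqs <- pmin(freqs, 1 / tr - freqs)  # two-sided
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) stop("band contains no Fourier frequencies at this length")
  spec <- complex(modulus = as.numeric(keep),
                  argument = stats::runif(n, -pi, pi))
  x <- Re(stats::fft(spec, inverse = TRUE))
  as.numeric(scale(x))
}

# unit-marginal-variance AR1 noise
ar1_noise <- function(n, phi) {
  innov <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# events table (onset/duration/trial_type/performance) from a block layout
layout_events <- function(layout) {
  onset <- 0
  rows <- vector("list", nrow(layout) * 2L)
  for (b in seq_len(nrow(layout))) {
    rows[[2 * b - 1]] <- data.frame(onset = onset,
                                    duration = layout$instruction[b],
                                    trial_type = "instruction",
                                    performance = NA_real_)
    onset <- onset + layout$instruction[b]
    rows[[2 * b]] <- data.frame(onset = onset, duration = layout$duration[b],
                                trial_type = layout$condition[b],
                                performance = layout$performance[b])
    onset <- onset + layout$duration[b]
  }
  do.call(rbind, rows)
}

#' Generate a synthetic multi-volunteer study
#'
#' Produces one `parcel_series` per volunteer. Each coupled condition owns
#' a fixed random partition of the regions into its configured number of
#' communities (shared across volunteers). Within a task block, regions of
#' a community share a band-limited random-phase latent oscillation with
#' gain `g = coupling_strength * (1 + performance_effect * (performance -
#' 0.5))`; instruction segments are uncoupled. The coupled component is
#' passed through a volunteer-specific mixing perturbation
#' `I + idiosyncrasy_strength * E` (E standard normal / sqrt(R)), AR1
#' noise is added region-wise, and each region is rescaled within the
#' block so its marginal sd is `noise_sd` in every condition: coupling
#' changes inter-regional correlation (within-community correlation
#' `g^2 / (1 + g^2)` for an unperturbed mixing), not signal power, as in
#' amplitude-normalized BOLD. Deterministic given `config$seed`.
#'
#' @param config a [study_config()].
#' @return list of `parcel_series`, one per volunteer.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  R <- config$n_regions
  tr <- config$tr
  layout <- config$block_layout
  events <- layout_events(layout)
  total_sec <- sum(layout$duration + layout$instruction)
  n_time <- ceiling(total_sec / tr - 1e-9)
  conditions <- unique(layout$condition)

  # fixed per-condition community partitions, shared by all volunteers
  partitions <- lapply(conditions, function(cond) {
    ncomm <- config$communities[cond]
    if (is.na(ncomm) || ncomm < 1) return(NULL)  # uncoupled condition
    sample(rep_len(seq_len(ncomm), R))
  })
  names(partitions) <- conditions

  # per-sample block index / condition / performance
  sample_onset <- (seq_len(n_time) - 1) * tr
  ev_idx <- findInterval(sample_onset + 1e-9, events$onset)

  volunteers <- vector("list", config$n_volunteers)
  for (v in seq_len(config$n_volunteers)) {
    mix <- diag(R) + config$idiosyncrasy_strength *
      matrix(stats::rnorm(R * R, sd = 1 / sqrt(R)), R, R)
    noise <- t(vapply(seq_len(R), function(r)
      ar1_noise(n_time, config$ar1_phi), numeric(n_time)))
    sig <- noise
    for (b in seq_len(nrow(events))) {
      cond <- events$trial_type[b]
      cols <- which(ev_idx == b)
      if (cond == "instruction" || !length(cols)) next
      part <- partitions[[cond]]
      if (is.null(part)) next
      perf <- events$performance[b]
      gain <- config$coupling_strength *
        (1 + config$performance_effect * (ifelse(is.na(perf), 0.5, perf) - 0.5))
      coupled <- matrix(0, R, length(cols))
      for (cm in seq_len(max(part))) {
        members <- which(part == cm)
        latent <- band_limited_noise(length(cols), tr, config$band)
        coupled[members, ] <- coupled[members, ] +
          matrix(gain * latent, length(members), length(cols), byrow = TRUE)
      }
      coupled <- mix %*% coupled
      # exact per-region variance of the mixed coupled component, so the
      # block can be rescaled to constant marginal power
      comm_gain <- vapply(seq_len(max(part)), function(cm)
        rowSums(mix[, which(part == cm), drop = FALSE]), numeric(R))
      vr <- gain^2 * rowSums(matrix(comm_gain, R)^2)
      sig[, cols] <- (coupled + noise[, cols]) / sqrt(1 + vr)
    }
    volunteers[[v]] <- parcel_series(
      volunteer_id = sprintf("vol%02d", v), signal = config$noise_sd * sig,
      tr = tr, region_labels = sprintf("R%03d", seq_len(R)), events = events)
  }
  volunteers
}

#' AR1 surrogate of a parcellated series
#'
#' Per region, fits the lag-1 autocorrelation and innovation variance by
#' the method of moments and emits an independent AR1 realization matched
#' in length, mean, and variance. Used to calibrate coherence-distance
#' significance against temporally autocorrelated but uncoupled data.
#'
#' @param series a `parcel_series`.
#' @param seed integer seed for the surrogate draw.
#' @return a `parcel_series` with surrogate signal and the same metadata.
#' @export
ar1_surrogate <- function(series, seed) {
  stopifnot(inherits(series, "parcel_series"))
  n <- ncol(series$signal)
  if (n < 3) stop("series too short to fit an AR1 model")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- series$signal
  for (r in seq_len(nrow(out))) {
    x <- series$signal[r, ]
    s <- stats::sd(x)
    if (s == 0)
      stop(sprintf("region %s has constant signal; AR1 fit undefined",
                   series$region_labels[r]))
    xc <- x - mean(x)
    phi <- sum(xc[-1] * xc[-n]) / sum(xc^2)
    phi <- max(min(phi, 0.99), -0.99)
    y <- ar1_noise(n, phi)
    out[r, ] <- mean(x) + s * (y - mean(y)) / stats::sd(y)
  }
  parcel_series(series$volunteer_id, out, series$tr, series$region_labels,
                series$events)
}

#' Condition and performance labels for given time samples
#'
#' @param series a `parcel_series`.
#' @param time_index integer sample indices (1-based).
#' @return data.frame with columns time_index, condition, performance.
#' @export
sample_conditions <- function(series, time_index) {
  onset <- (time_index - 1) * series$tr
  ev <- findInterval(onset + 1e-9, series$events$onset)
  ev[ev < 1] <- 1L
  data.frame(time_index = time_index,
             condition = series$events$trial_type[ev],
             performance = series$events$performance[ev])
}
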