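#' Morlet wavelet filterbank
#'
#' Center frequencies are log-spaced between `f_min` and `f_max`
#' (inclusive of both endpoints); scales follow the Morlet approximate
#' center-frequency relation `f = omega0 / (2 * pi * s)`, so scale is
#' strictly decreasing in frequency.
#'
#' @param f_min,f_max passband endpoints in Hz, `0 < f_min < f_max`.
#' @param n_scales number of scales (>= 2; >= 5 recommended).
#' @param omega0 Morlet base frequency (dimensionless, >= 6 so the
#'   kernel's nonzero mean is below machine precision).
#' @param tr sampling interval in seconds, used to check `f_max` against
#'   the Nyquist frequency.
#' @return object of class `filterbank`.
#' @export
build_filterbank <- function(f_min = 0.007, f_max = 0.15, n_scales = 15L,
                             omega0 = 6, tr = 1.5) {
  if (!(f_min > 0 && f_min < f_max)) stop("need 0 < f_min < f_max")
  nyq <- 1 / (2 * tr)
  if (f_max >= nyq)
    stop(sprintf("f_max = %g Hz is at or above Nyquist (%g Hz) for TR = %g s",
                 f_max, nyq, tr))
  if (n_scales < 2) stop("n_scales must be >= 2")
  if (omega0 < 6) stop("omega0 must be >= 6")
  center_freqs <- exp(seq(log(f_max), log(f_min), length.out = n_scales))
  scales <- omega0 / (2 * pi * center_freqs)
  structure(list(omega0 = omega0, scales = scales,
                 center_freqs = center_freqs, f_min = f_min, f_max = f_max,
                 n_scales = as.integer(n_scales), tr = tr),
            class = "filterbank")
}

#' @export
print.filterbank <- function(x, ...) {
  cat(sprintf("<filterbank> %d Morlet scales, %.4g-%.4g Hz, omega0 = %g\n",
              x$n_scales, x$f_min, x$f_max, x$omega0))
  invisible(x)
}

#' Retained scale indices after spectral trimming
#'
#' @param fb a [build_filterbank()].
#' @param trim_scales scales dropped at each spectral edge.
#' @return integer indices into the filterbank's scales.
#' @export
retained_scale_index <- function(fb, trim_scales = 2L) {
  keep <- seq_len(fb$n_scales)
  if (trim_scales > 0)
    keep <- keep[-c(seq_len(trim_scales),
                    fb$n_scales + 1 - seq_len(trim_scales))]
  if (length(keep) < 1) stop("no scales retained after trimming")
  keep
}

# discretized Morlet kernel at scale s (seconds), support +/- 4s; reversed
# in the convolution below so that conv equals the correlation
# sum_t f(t) psi*((t - u)/s) dt / sqrt(s).
morlet_kernel <- function(s, omega0, tr) {
  m <- ceiling(4 * s / tr)
  x <- ((-m:m) * tr) / s
  (tr / sqrt(s)) * exp(1i * omega0 * x) * exp(-x^2 / 2)
}

#' Continuous wavelet transform of a parcellated series
#'
#' Computes `W[r, s, u] = sum_t f_r(t) (1/sqrt(s)) psi*((t - u)/s) dt`
#' with the complex Morlet kernel `psi(x) = exp(i omega0 x) exp(-x^2/2)`
#' discretized on a +/- 4s support and `dt = TR`. Signals are zero-padded
#' for the convolution; the temporal trim downstream absorbs the resulting
#' edge artifacts.
#'
#' @param series a `parcel_series`, or a plain regions x time matrix (then
#'   `tr` is taken from `fb`).
#' @param fb a [build_filterbank()].
#' @return object of class `spectrogram` with complex `coeffs`
#'   (regions x scales x time).
#' @export
cwt <- function(series, fb) {
  sig <- if (inherits(series, "parcel_series")) series$signal else as.matrix(series)
  tr <- if (inherits(series, "parcel_series")) series$tr else fb$tr
  R <- nrow(sig); Tn <- ncol(sig)
  max_support <- 2 * ceiling(4 * max(fb$scales) / tr) + 1
  if (Tn < max_support)
    stop(sprintf(paste0("series length %d is shorter than the support of the",
                        " largest wavelet (%d samples); complete overlap",
                        " between signal and kernel is required"),
                 Tn, max_support))
  N <- stats::nextn(Tn + max_support, 2)
  F_sig <- stats::mvfft(rbind(t(sig), matrix(0, N - Tn, R)))
  coeffs <- array(0i, dim = c(R, fb$n_scales, Tn))
  for (si in seq_len(fb$n_scales)) {
    k <- morlet_kernel(fb$scales[si], fb$omega0, tr)
    m <- (length(k) - 1L) / 2L
    kpad <- complex(real = numeric(N))
    kpad[seq_along(k)] <- k
    F_k <- stats::fft(kpad)
    conv <- stats::mvfft(F_sig * F_k, inverse = TRUE) / N
    # conv[u + m] = sum_j f(u + j) psi(-j dt / s) = W(u) for real f
    coeffs[, si, ] <- t(conv[(m + 1):(m + Tn), , drop = FALSE])
  }
  structure(list(coeffs = coeffs, filterbank = fb, tr = tr),
            class = "spectrogram")
}

# Gaussian time smoothing, sd = s seconds at each scale, applied along the
# rows of a scales x time matrix (numeric or complex); zero padding, full
# windows everywhere in the interior.
smooth_time <- function(x, scales, tr) {
  out <- x
  Tn <- ncol(x)
  for (si in seq_len(nrow(x))) {
    sd_samp <- scales[si] / tr
    m <- ceiling(4 * sd_samp)
    k <- stats::dnorm(-m:m, sd = sd_samp)
    k <- k / sum(k)
    row <- x[si, ]
    if (is.complex(row)) {
      re <- stats::filter(c(rep(0, m), Re(row), rep(0, m)), k, sides = 2)
      im <- stats::filter(c(rep(0, m), Im(row), rep(0, m)), k, sides = 2)
      out[si, ] <- complex(real = re[(m + 1):(m + Tn)],
                           imaginary = im[(m + 1):(m + Tn)])
    } else {
      f <- stats::filter(c(rep(0, m), row, rep(0, m)), k, sides = 2)
      out[si, ] <- f[(m + 1):(m + Tn)]
    }
  }
  out
}

# boxcar across scales (edge scales average over the available window)
smooth_scales <- function(x, width = 3L) {
  S <- nrow(x)
  if (S == 1L || width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  out <- x
  for (si in seq_len(S)) {
    lo <- max(1L, si - half); hi <- min(S, si + half)
    out[si, ] <- colMeans(x[lo:hi, , drop = FALSE])
  }
  out
}

# FFT-based Gaussian time smoothing of a time x columns matrix (complex ok)
smooth_time_cols <- function(x, sd_samp) {
  Tn <- nrow(x)
  m <- ceiling(4 * sd_samp)
  k <- stats::dnorm(-m:m, sd = sd_samp)
  k <- k / sum(k)
  N <- stats::nextn(Tn + length(k), 2)
  Fk <- stats::fft(c(k, rep(0, N - length(k))))
  pad <- matrix(if (is.complex(x)) 0i else 0, N - Tn, ncol(x))
  conv <- stats::mvfft(stats::mvfft(rbind(x, pad)) * Fk, inverse = TRUE) / N
  conv[(m + 1):(m + Tn), , drop = FALSE]
}

#' Wavelet squared coherence between two spectrogram slices
#'
#' `R2_t(s) = |<s^-1 W^XY>|^2 / (<s^-1 |W^X|^2> <s^-1 |W^Y|^2>)` where
#' `W^XY = W^X conj(W^Y)` is the cross-wavelet spectrum and `<.>` smooths
#' in time (Gaussian, sd = s at each scale) and in scale (boxcar of
#' `scale_width` scales). Values are clipped to \[0, 1\]; coordinates with
#' zero smoothed power are defined as 0.
#'
#' @param Wx,Wy complex scales x time matrices (rows ordered as the
#'   filterbank scales).
#' @param fb the [build_filterbank()] that produced them.
#' @param scale_width boxcar width of the scale smoothing.
#' @return list with `R2` (scales x time, in \[0,1\]) and `crosspower`
#'   (`|W^XY|`, unsmoothed).
#' @export
wavelet_coherence_pair <- function(Wx, Wy, fb, scale_width = 3L) {
  stopifnot(all(dim(Wx) == dim(Wy)), nrow(Wx) == fb$n_scales)
  inv_s <- 1 / fb$scales
  cross <- Wx * Conj(Wy)
  num <- smooth_scales(smooth_time(cross * inv_s, fb$scales, fb$tr), scale_width)
  px <- smooth_scales(smooth_time(Mod(Wx)^2 * inv_s, fb$scales, fb$tr), scale_width)
  py <- smooth_scales(smooth_time(Mod(Wy)^2 * inv_s, fb$scales, fb$tr), scale_width)
  den <- px * py
  R2 <- Mod(num)^2 / den
  R2[den <= 0 | !is.finite(R2)] <- 0
  list(R2 = pmin(pmax(R2, 0), 1), crosspower = Mod(cross))
}

#' Broadband power-weighted coherence
#'
#' Collapses multispectral squared coherence to one value per time point:
#' the weighted mean of `R2_t(s)` with weights `w_s(t) = |W^XY_t(s)|`,
#' normalized by the sum of weights so the result stays in \[0, 1\]. The
#' coherence-distance graph edge is `1 - C_t`. All-zero weights at a time
#' point give `C_t = 0`.
#'
#' @param R2 scales x time squared-coherence field.
#' @param crosspower scales x time nonnegative cross-wavelet power field.
#' @return numeric vector `C_t` of length `ncol(R2)`, in \[0, 1\].
#' @export
power_weighted_tvfc <- function(R2, crosspower) {
  stopifnot(all(dim(R2) == dim(crosspower)))
  wsum <- colSums(crosspower)
  ct <- colSums(R2 * crosspower) / wsum
  ct[wsum <= 0] <- 0
  pmin(pmax(ct, 0), 1)
}

#' Time-varying functional connectivity graphs
#'
#' Applies [wavelet_coherence_pair()] and [power_weighted_tvfc()] to every
#' region pair, using only the retained scales (the outer `trim_scales`
#' scales at each spectral edge are dropped) and retained times (the outer
#' `trim_time` samples at each temporal edge are dropped). Edges are
#' coherence distances `1 - C_t`; every graph is symmetric with a zero
#' diagonal. The per-pair computation is vectorized across pairs but is
#' numerically identical to the two scalar operations above.
#'
#' @param series a `parcel_series`.
#' @param fb a [build_filterbank()].
#' @param trim_time samples dropped at each temporal edge (cone of
#'   influence; default 120).
#' @param trim_scales scales dropped at each spectral edge (default 2).
#' @param scale_width scale-smoothing boxcar width.
#' @return object of class `tvfc_series`: `graphs` (time x R x R array of
#'   distances), `node_amp` (time x (R * retained scales) matrix of `|W|`
#'   node topographies, region-major), `retained_time_index`,
#'   `retained_scales` (Hz), `point_meta` (volunteer, time_index,
#'   condition, performance), `region_labels`, `tr`.
#' @export
compute_tvfc <- function(series, fb, trim_time = 120L, trim_scales = 2L,
                         scale_width = 3L) {
  stopifnot(inherits(series, "parcel_series"))
  R <- nrow(series$signal); Tn <- ncol(series$signal)
  keep_s <- retained_scale_index(fb, trim_scales)
  if (Tn <= 2 * trim_time) stop("no time points retained after trimming")
  keep_t <- (trim_time + 1L):(Tn - trim_time)

  W <- cwt(series, fb)$coeffs
  inv_s <- 1 / fb$scales
  S <- fb$n_scales
  Tk <- length(keep_t)
  half <- (scale_width - 1L) %/% 2L

  # smoothed auto-power: regions x scales x time (scale boxcar included)
  auto <- array(0, dim = c(R, S, Tn))
  for (r in seq_len(R))
    auto[r, , ] <- smooth_scales(
      smooth_time(Mod(W[r, , , drop = FALSE])[1, , , drop = TRUE]^2 * inv_s,
                  fb$scales, fb$tr), scale_width)

  pairs <- utils::combn(R, 2)
  P <- ncol(pairs)
  num_acc <- matrix(0, Tk, P)
  den_acc <- matrix(0, Tk, P)

  # lazily computed, freed when the scale window moves on
  sm_cross <- vector("list", S)  # time-smoothed s^-1 cross spectrum, T x P
  raw_mod <- vector("list", S)   # |cross| at retained times, Tk x P
  compute_scale <- function(si) {
    Ws <- t(W[, si, ])                                   # T x R complex
    cr <- Ws[, pairs[1, ], drop = FALSE] *
      Conj(Ws[, pairs[2, ], drop = FALSE])               # T x P
    raw_mod[[si]] <<- Mod(cr[keep_t, , drop = FALSE])
    sm_cross[[si]] <<- smooth_time_cols(cr * inv_s[si], fb$scales[si] / fb$tr)
    invisible(NULL)
  }

  for (si in keep_s) {
    lo <- max(1L, si - half); hi <- min(S, si + half)
    for (w in lo:hi) if (is.null(sm_cross[[w]])) compute_scale(w)
    acc <- sm_cross[[lo]]
    if (hi > lo) for (w in (lo + 1):hi) acc <- acc + sm_cross[[w]]
    num <- acc[keep_t, , drop = FALSE] / (hi - lo + 1)
    ax <- auto[pairs[1, ], si, keep_t, drop = FALSE]     # P x 1 x Tk
    ay <- auto[pairs[2, ], si, keep_t, drop = FALSE]
    den <- t(matrix(ax * ay, P, Tk))                     # Tk x P
    R2 <- Mod(num)^2 / den
    R2[!is.finite(R2) | den <= 0] <- 0
    R2 <- pmin(pmax(R2, 0), 1)
    num_acc <- num_acc + R2 * raw_mod[[si]]
    den_acc <- den_acc + raw_mod[[si]]
    if (lo > 1) for (w in seq_len(lo - 1)) {
      sm_cross[w] <- list(NULL)
      raw_mod[w] <- list(NULL)
    }
  }
  ct <- num_acc / den_acc
  ct[den_acc <= 0] <- 0
  ct <- pmin(pmax(ct, 0), 1)

  graphs <- array(0, dim = c(Tk, R, R))
  for (p in seq_len(P)) {
    graphs[, pairs[1, p], pairs[2, p]] <- 1 - ct[, p]
    graphs[, pairs[2, p], pairs[1, p]] <- 1 - ct[, p]
  }

  Sk <- length(keep_s)
  node_amp <- matrix(0, Tk, R * Sk)
  for (r in seq_len(R))
    node_amp[, ((r - 1) * Sk + 1):(r * Sk)] <-
      t(Mod(W[r, keep_s, keep_t, drop = FALSE])[1, , , drop = TRUE])

  meta <- sample_conditions(series, keep_t)
  meta <- data.frame(volunteer = series$volunteer_id, meta)
  structure(list(graphs = graphs, node_amp = node_amp,
                 retained_time_index = keep_t,
                 retained_scales = fb$center_freqs[keep_s],
                 point_meta = meta, region_labels = series$region_labels,
                 tr = series$tr),
            class = "tvfc_series")
}

#' @export
print.tvfc_series <- function(x, ...) {
  cat(sprintf("<tvfc_series> %s: %d graphs on %d regions, %d retained scales (%.4g-%.4g Hz)\n",
              x$point_meta$volunteer[1], dim(x$graphs)[1], dim(x$graphs)[2],
              length(x$retained_scales), min(x$retained_scales),
              max(x$retained_scales)))
  invisible(x)
}

#' Significance threshold for coherence distances from AR1 surrogates
#'
#' Simulates `n_surrogates` independent pairs of AR1 signals matched to
#' the study's noise model, computes their broadband coherence distances
#' through the same filterbank and trimming, and returns the requested
#' lower quantile of the pooled distance distribution. Distances below the
#' threshold are unlikely under temporally autocorrelated but uncoupled
#' signals, i.e. significantly coherent.
#'
#' @param config a [study_config()] supplying TR, AR1 coefficient, noise
#'   sd and the scan length.
#' @param fb a [build_filterbank()].
#' @param n_surrogates number of independent pairs (>= 50).
#' @param quantile lower quantile of the surrogate distance distribution.
#' @param trim_time,trim_scales as in [compute_tvfc()].
#' @param scale_width scale-smoothing boxcar width.
#' @return scalar distance threshold in \[0, 1\].
#' @export
coherence_significance_threshold <- function(config, fb, n_surrogates = 50L,
                                             quantile = 0.05,
                                             trim_time = 120L,
                                             trim_scales = 2L,
                                             scale_width = 3L) {
  if (n_surrogates < 50) stop("n_surrogates must be >= 50")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  layout <- config$block_layout
  n_time <- ceiling(sum(layout$duration + layout$instruction) / config$tr - 1e-9)
  events <- layout_events(layout)
  dists <- numeric(0)
  for (i in seq_len(n_surrogates)) {
    sig <- rbind(config$noise_sd * ar1_noise(n_time, config$ar1_phi),
                 config$noise_sd * ar1_noise(n_time, config$ar1_phi))
    if (any(apply(sig, 1, stats::sd) == 0)) stop("degenerate surrogate draw")
    ps <- parcel_series("surr", sig, config$tr, c("A", "B"), events)
    tv <- compute_tvfc(ps, fb, trim_time, trim_scales, scale_width)
    dists <- c(dists, tv$graphs[, 1, 2])
  }
  stats::quantile(dists, probs = quantile, names = FALSE)
}
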