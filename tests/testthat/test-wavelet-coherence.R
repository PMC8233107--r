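test_that("filterbank endpoints, spacing and validation", {
  fb <- build_filterbank(0.007, 0.15, 15L, 6, tr = 1.5)
  expect_equal(fb$n_scales, 15L)
  expect_equal(max(fb$center_freqs), 0.15)
  expect_equal(min(fb$center_freqs), 0.007)
  expect_true(all(diff(fb$scales) > 0) || all(diff(fb$scales) < 0))
  r <- fb$center_freqs[-1] / fb$center_freqs[-15]
  expect_lt(max(abs(r - r[1])), 1e-12)
  fb2 <- build_filterbank(0.007, 0.15, 2L, 6, tr = 1.5)
  expect_equal(sort(fb2$center_freqs), c(0.007, 0.15))
  expect_error(build_filterbank(0.01, 0.4, 15L, 6, tr = 1.5), "Nyquist")
  expect_error(build_filterbank(0.01, 0.1, 15L, 4, tr = 1.5), "omega0")
  expect_equal(length(retained_scale_index(fb, 2L)), 11L)
})

test_that("CWT is linear, localizes sinusoids and validates length", {
  fb <- tiny_fb()
  Tn <- 360; tr <- 1.5; tt <- (0:(Tn - 1)) * tr
  ev <- data.frame(onset = 0, duration = Tn * tr, trial_type = "rest",
                   performance = NA)
  f0 <- fb$center_freqs[4]
  sig <- rbind(sin(2 * pi * f0 * tt), rnorm(Tn))
  ps <- parcel_series("a", sig, tr, c("x", "y"), ev)
  W <- cwt(ps, fb)$coeffs
  expect_equal(dim(W), c(2L, 8L, Tn))
  expect_equal(which.max(Mod(W[1, , Tn / 2])), 4L)
  # zero signal -> zero coefficients
  z <- cwt(parcel_series("z", matrix(0, 1, Tn), tr, "x", ev), fb)$coeffs
  expect_equal(max(Mod(z)), 0)
  # linearity to high precision
  g <- rbind(rnorm(Tn), rnorm(Tn))
  Wg <- cwt(parcel_series("g", g, tr, c("x", "y"), ev), fb)$coeffs
  Wmix <- cwt(parcel_series("m", 2 * sig + 3 * g, tr, c("x", "y"), ev),
              fb)$coeffs
  expect_lt(max(Mod(Wmix - 2 * W - 3 * Wg)), 1e-10)
  expect_error(cwt(parcel_series("s", matrix(rnorm(40), 1, 40), tr, "x",
                                 data.frame(onset = 0, duration = 60,
                                            trial_type = "rest",
                                            performance = NA)), fb),
               "support")
})

test_that("squared coherence is 1 for self and sign-flipped pairs", {
  fb <- tiny_fb()
  Tn <- 360; tr <- 1.5
  ev <- data.frame(onset = 0, duration = Tn * tr, trial_type = "rest",
                   performance = NA)
  set.seed(8)
  ps <- parcel_series("a", rbind(rnorm(Tn)), tr, "x", ev)
  W <- cwt(ps, fb)$coeffs
  self <- wavelet_coherence_pair(W[1, , ], W[1, , ], fb)
  inner <- self$R2[, 100:260]
  expect_lt(max(abs(inner - 1)), 1e-9)
  flip <- wavelet_coherence_pair(W[1, , ], -W[1, , ], fb)
  expect_lt(max(abs(flip$R2[, 100:260] - 1)), 1e-9)
})

test_that("independent white noise keeps mean mid-scale coherence modest", {
  fb <- build_filterbank(0.02, 0.15, 8L, 6, tr = 1.5)
  Tn <- 4096; tr <- 1.5
  ev <- data.frame(onset = 0, duration = Tn * tr, trial_type = "rest",
                   performance = NA)
  set.seed(12)
  ps <- parcel_series("a", rbind(rnorm(Tn), rnorm(Tn)), tr, c("x", "y"), ev)
  W <- cwt(ps, fb)$coeffs
  wc <- wavelet_coherence_pair(W[1, , ], W[2, , ], fb)
  mid <- wc$R2[3:6, 300:3800]
  expect_lt(mean(mid), 0.35)
})

test_that("power weighting is a bounded weighted mean", {
  R2 <- matrix(c(1, 0), 2, 1)
  w <- matrix(c(1, 1), 2, 1)
  expect_equal(power_weighted_tvfc(R2, w), 0.5)
  expect_equal(power_weighted_tvfc(matrix(c(0.8, 0.3), 2, 1),
                                   matrix(c(2, 0), 2, 1)), 0.8)
  ones <- matrix(1, 5, 4)
  expect_equal(power_weighted_tvfc(ones, matrix(runif(20) + 0.1, 5, 4)),
               rep(1, 4))
  expect_equal(power_weighted_tvfc(ones, matrix(0, 5, 4)), rep(0, 4))
})

test_that("TVFC graphs are symmetric, bounded, trimmed and track coupling", {
  cfg <- tiny_study(n_volunteers = 3L, n_regions = 6L, seed = 3L)
  st <- generate_study(cfg)
  tv <- tiny_tvfc(st[[1]])
  Tn <- ncol(st[[1]]$signal)
  expect_equal(dim(tv$graphs)[1], Tn - 80L)
  expect_equal(length(tv$retained_scales), 8L - 4L)
  expect_true(all(tv$graphs >= 0 & tv$graphs <= 1))
  for (i in c(1, 50, 100)) {
    g <- tv$graphs[i, , ]
    expect_equal(g, t(g))
    expect_equal(diag(g), rep(0, 6))
  }
  # matches the scalar per-pair route exactly
  W <- cwt(st[[1]], tiny_fb())$coeffs
  wc <- wavelet_coherence_pair(W[2, , ], W[5, , ], tiny_fb())
  keep_s <- retained_scale_index(tiny_fb(), 2L)
  keep_t <- 41:(Tn - 40)
  ct <- power_weighted_tvfc(wc$R2[keep_s, keep_t],
                            wc$crosspower[keep_s, keep_t])
  expect_equal(tv$graphs[, 2, 5], 1 - ct, tolerance = 1e-12)
})

test_that("a region is at TVFC distance ~0 from its duplicate", {
  cfg <- tiny_study(n_volunteers = 3L, n_regions = 4L, seed = 5L)
  st <- generate_study(cfg)
  sig <- rbind(st[[1]]$signal, st[[1]]$signal[1, ])
  ps <- parcel_series("dup", sig, st[[1]]$tr, c(st[[1]]$region_labels, "dup"),
                      st[[1]]$events)
  tv <- tiny_tvfc(ps)
  expect_lt(max(tv$graphs[, 1, 5]), 1e-6)
})

test_that("two latent-sharing regions are closer than an independent one", {
  set.seed(31)
  Tn <- 360; tr <- 1.5
  lat <- stats::filter(rnorm(Tn), 0.9, method = "recursive")
  sig <- rbind(lat + 0.3 * rnorm(Tn), lat + 0.3 * rnorm(Tn), rnorm(Tn))
  ev <- data.frame(onset = 0, duration = Tn * tr, trial_type = "rest",
                   performance = NA)
  tv <- tiny_tvfc(parcel_series("t", sig, tr, c("a", "b", "c"), ev))
  expect_lt(median(tv$graphs[, 1, 2]),
            min(median(tv$graphs[, 1, 3]), median(tv$graphs[, 2, 3])))
})

test_that("broadband coherence approaches 1 as added noise vanishes", {
  set.seed(17)
  Tn <- 360; tr <- 1.5
  ev <- data.frame(onset = 0, duration = Tn * tr, trial_type = "rest",
                   performance = NA)
  base <- stats::filter(rnorm(Tn), 0.95, method = "recursive")
  med <- vapply(c(2, 1, 0.5, 0.2, 0.05), function(sdv) {
    sig <- rbind(base, 3 * base + sdv * rnorm(Tn))
    tv <- tiny_tvfc(parcel_series("p", sig, tr, c("a", "b"), ev))
    median(1 - tv$graphs[, 1, 2])
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  expect_gt(med[5], 0.97)
})

test_that("AR1 surrogate threshold is an order statistic of distances", {
  cfg <- tiny_study(n_volunteers = 3L, n_regions = 4L, seed = 13L)
  fb <- tiny_fb()
  th0 <- coherence_significance_threshold(cfg, fb, 50L, quantile = 0,
                                          trim_time = 40L)
  th5 <- coherence_significance_threshold(cfg, fb, 50L, quantile = 0.05,
                                          trim_time = 40L)
  th1 <- coherence_significance_threshold(cfg, fb, 50L, quantile = 1,
                                          trim_time = 40L)
  expect_lte(th0, th5)
  expect_lte(th5, th1)
  expect_true(th0 >= 0 && th1 <= 1)
  expect_error(coherence_significance_threshold(cfg, fb, 10L), ">= 50")
})
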