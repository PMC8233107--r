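test_that("study generation is deterministic and shape-correct", {
  cfg <- tiny_study(seed = 5L)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg)
  expect_length(st1, 3L)
  expect_identical(st1, st2)
  expect_equal(dim(st1[[1]]$signal), c(12L, 352L))
  expect_false(identical(st1[[1]]$signal, st1[[2]]$signal))
  expect_error(generate_study(tiny_study(seed = NULL)), "seed")
})

test_that("configuration invariants are enforced", {
  expect_error(study_config(n_regions = 3, seed = 1), "n_regions")
  bad <- tiny_layout(); bad$duration[2] <- 0
  expect_error(study_config(block_layout = bad, seed = 1), "duration")
  bad2 <- tiny_layout(); bad2$performance[2] <- 1.4
  expect_error(study_config(block_layout = bad2, seed = 1), "performance")
  expect_error(study_config(band = c(0.01, 0.5), tr = 1.5, seed = 1),
               "Nyquist")
  expect_error(study_config(ar1_phi = 1, seed = 1), "ar1_phi")
})

test_that("zero coupling leaves inter-regional correlations at zero", {
  long <- data.frame(condition = "math", duration = 3000, instruction = 6,
                     performance = 0.8)
  cfg <- study_config(n_volunteers = 3L, n_regions = 6L, tr = 1.5,
                      block_layout = long, coupling_strength = 0, seed = 2,
                      communities = c(math = 2L))
  st <- generate_study(cfg)
  cm <- cor(t(st[[1]]$signal))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.06)
  expect_lt(abs(mean(cm[upper.tri(cm)])), 0.05)
})

test_that("block correlation matrices cluster by condition (ARI > 0.8)", {
  # two conditions with distinct 2-community partitions, 10 blocks each
  layout <- data.frame(
    condition = rep(c("math", "memory"), 10),
    duration = 90, instruction = 0.01, performance = 0.8)
  cfg <- study_config(n_volunteers = 3L, n_regions = 12L, tr = 1.5,
                      block_layout = layout, coupling_strength = 3,
                      noise_sd = 1, seed = 9,
                      communities = c(math = 2L, memory = 2L))
  st <- generate_study(cfg)
  sig <- st[[1]]$signal
  ev <- st[[1]]$events
  task <- ev[ev$trial_type != "instruction", ]
  feats <- t(vapply(seq_len(nrow(task)), function(b) {
    cols <- floor(task$onset[b] / 1.5):(floor((task$onset[b] +
                                                task$duration[b]) / 1.5) - 1)
    cm <- cor(t(sig[, cols + 1]))
    cm[upper.tri(cm)]
  }, numeric(66)))
  cl <- cutree(hclust(dist(feats), method = "average"), k = 2)
  expect_gt(adjusted_rand(cl, task$trial_type), 0.8)
})

test_that("coupling strength monotonically raises within-community coherence", {
  layout <- data.frame(condition = "math", duration = 400, instruction = 0.01,
                       performance = 0.5)
  mean_r <- vapply(c(0.5, 1.5, 4), function(cs) {
    rs <- vapply(1:10, function(s) {
      cfg <- study_config(n_volunteers = 3L, n_regions = 6L, tr = 1.5,
                          block_layout = layout, coupling_strength = cs,
                          seed = s, communities = c(math = 1L))
      st <- generate_study(cfg)
      cm <- cor(t(st[[1]]$signal))
      mean(cm[upper.tri(cm)])
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("marginal signal power is flat across conditions", {
  cfg <- tiny_study(n_regions = 8L, seed = 21L, coupling_strength = 3)
  st <- generate_study(cfg)
  ev <- st[[1]]$events
  task <- ev[ev$trial_type %in% c("math", "rest"), ]
  sds <- vapply(seq_len(nrow(task)), function(b) {
    cols <- floor(task$onset[b] / 1.5):(floor((task$onset[b] +
                                                task$duration[b]) / 1.5) - 1)
    mean(apply(st[[1]]$signal[, cols + 1], 1, sd))
  }, numeric(1))
  expect_lt(max(sds) / min(sds), 1.35)
})

test_that("AR1 surrogates recover the lag-1 structure and moments", {
  set.seed(6)
  Tn <- 5000
  ev <- data.frame(onset = 0, duration = Tn * 1.5, trial_type = "rest",
                   performance = NA)
  phi_hat <- function(x) {
    xc <- x - mean(x)
    sum(xc[-1] * xc[-Tn]) / sum(xc^2)
  }
  # white-noise input -> phi near 0
  wn <- parcel_series("w", rbind(rnorm(Tn)), 1.5, "x", ev)
  sw <- ar1_surrogate(wn, seed = 2)
  expect_lt(abs(phi_hat(sw$signal[1, ])), 0.1)
  # AR1(0.7) input -> phi recovered
  ar <- parcel_series("a", rbind(5 + 2 * stats::filter(rnorm(Tn), 0.7,
                                 method = "recursive")), 1.5, "x", ev)
  sa <- ar1_surrogate(ar, seed = 3)
  expect_gt(phi_hat(sa$signal[1, ]), 0.6)
  expect_lt(phi_hat(sa$signal[1, ]), 0.8)
  expect_equal(mean(sa$signal[1, ]), mean(ar$signal[1, ]), tolerance = 1e-9)
  expect_equal(sd(sa$signal[1, ]), sd(ar$signal[1, ]), tolerance = 1e-9)
  expect_equal(dim(sa$signal), dim(ar$signal))
  # constant region errors with its label
  cc <- parcel_series("c", rbind(rep(1, 10)), 1.5, "flatline",
                      data.frame(onset = 0, duration = 15,
                                 trial_type = "rest", performance = NA))
  expect_error(ar1_surrogate(cc, seed = 1), "flatline")
})

test_that("events land inside the scan and map to sample conditions", {
  cfg <- tiny_study(seed = 30L)
  st <- generate_study(cfg)
  ev <- st[[1]]$events
  expect_true(all(ev$onset >= 0))
  expect_lte(max(ev$onset + ev$duration), ncol(st[[1]]$signal) * 1.5 + 1e-9)
  sc <- sample_conditions(st[[1]], c(1L, 10L, 60L))
  expect_equal(names(sc), c("time_index", "condition", "performance"))
  expect_equal(sc$condition[1], "instruction")
})
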