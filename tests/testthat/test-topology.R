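test_that("forced small configurations give the expected diagrams", {
  # two points at distance d
  d <- matrix(c(0, 0.7, 0.7, 0), 2)
  pd <- vr_persistence(d, max_dim = 1)
  expect_equal(unname(pd[[1]]$pairs), cbind(0, 0.7), ignore_attr = TRUE)
  expect_equal(pd[[1]]$essential_count, 1L)
  expect_equal(nrow(pd[[2]]$pairs), 0L)

  # unit square: one H1 class born at the side, dying at the diagonal
  sq <- as.matrix(dist(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  pd <- vr_persistence(sq, max_dim = 2)
  expect_equal(nrow(pd[[1]]$pairs), 3L)
  expect_equal(unname(pd[[1]]$pairs[, 2]), rep(1, 3))
  expect_equal(unname(pd[[2]]$pairs), cbind(1, sqrt(2)), ignore_attr = TRUE)
  expect_equal(nrow(pd[[3]]$pairs), 0L)

  # n equidistant points: all H0 deaths at d, H1 empty after fill-in
  n <- 5
  eq <- matrix(0.4, n, n); diag(eq) <- 0
  pd <- vr_persistence(eq, max_dim = 2)
  expect_equal(unname(pd[[1]]$pairs[, 2]), rep(0.4, n - 1))
  expect_equal(nrow(pd[[2]]$pairs), 0L)
})

test_that("vr_persistence matches the brute-force reduction oracle", {
  for (seed in 1:30) {
    n <- sample(3:8, 1)
    d <- random_metric_space(n, seed)
    pd <- vr_persistence(d, max_dim = 2)
    oracle <- oracle_vr_persistence(d, max_dim = 2)
    for (k in 1:3) expect_diagram_equal(pd[[k]], oracle[[k]])
  }
})

test_that("H0 equals single-linkage merge heights and births are zero", {
  # hand-checked chain
  ch <- matrix(c(0, 0.2, 0.9, 0.2, 0, 0.3, 0.9, 0.3, 0), 3)
  expect_equal(h0_single_linkage(ch), c(0.2, 0.3))
  # equidistant triple
  tri <- matrix(0.5, 3, 3); diag(tri) <- 0
  expect_equal(h0_single_linkage(tri), c(0.5, 0.5))
  # cross-oracle on random spaces
  for (seed in 1:15) {
    d <- random_metric_space(12, seed + 100)
    h <- h0_single_linkage(d)
    v <- sort(vr_persistence(d, max_dim = 0)[[1]]$pairs[, 2])
    expect_lt(max(abs(h - v)), 1e-9)
    pd0 <- vr_persistence(d, max_dim = 0)[[1]]
    expect_equal(unname(pd0$pairs[, 1]), rep(0, nrow(d) - 1))
    expect_equal(pd0$essential_count, 1L)
  }
})

test_that("H0 deaths are Lipschitz under uniform distance perturbation", {
  set.seed(7)
  for (rep in 1:10) {
    d <- random_metric_space(10, rep)
    eps <- 0.01
    pert <- matrix(runif(100, -eps, eps), 10)
    pert <- (pert + t(pert)) / 2; diag(pert) <- 0
    d2 <- pmax(d + pert, 0); diag(d2) <- 0
    expect_lt(max(abs(h0_single_linkage(d) - h0_single_linkage(d2))), eps)
  }
})

test_that("sliced-Wasserstein identity, symmetry and a worked example", {
  set.seed(3)
  mk <- function(n, dim = 1) {
    b <- runif(n)
    persistence_diagram(dim, cbind(b, b + runif(n)))
  }
  d1 <- mk(4); d2 <- mk(6)
  expect_equal(sliced_wasserstein(d1, d1), 0)
  expect_equal(sliced_wasserstein(d1, d2), sliced_wasserstein(d2, d1))
  expect_error(sliced_wasserstein(d1, mk(3, dim = 2)), "dimension")

  # single point vs empty: mean projected distance to the diagonal
  one <- persistence_diagram(0, cbind(0, 1))
  none <- persistence_diagram(0, matrix(0, 0, 2))
  th <- -pi / 2 + pi * (0:19) / 20
  brute <- mean(abs(0 * cos(th) + 1 * sin(th) - 0.5 * (cos(th) + sin(th))))
  expect_equal(sliced_wasserstein(one, none), brute, tolerance = 1e-12)
})

test_that("sliced-Wasserstein behaves as a pseudo-metric on random triples", {
  set.seed(11)
  mk <- function() {
    n <- sample(0:6, 1)
    b <- runif(n)
    persistence_diagram(1, cbind(b, b + runif(n)))
  }
  for (i in 1:80) {
    a <- mk(); b <- mk(); c <- mk()
    dab <- sliced_wasserstein(a, b)
    dbc <- sliced_wasserstein(b, c)
    dac <- sliced_wasserstein(a, c)
    expect_gte(dab, 0)
    expect_equal(dab, sliced_wasserstein(b, a), tolerance = 1e-12)
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("diagram distance matrix matches scalar calls and is equivariant", {
  set.seed(5)
  mk <- function(n) {
    b <- runif(n)
    persistence_diagram(1, cbind(b, b + runif(n)))
  }
  ds <- lapply(c(3, 5, 2, 4), mk)
  M <- diagram_distance_matrix(ds, 1L)
  expect_s3_class(M, "state_dist")
  expect_equal(diag(M$D), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(M$D[i, j], sliced_wasserstein(ds[[i]], ds[[j]]),
                 tolerance = 1e-12)
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  M2 <- diagram_distance_matrix(ds[perm], 1L)
  expect_equal(M2$D, M$D[perm, perm], tolerance = 1e-12)
  # identical diagrams -> zero matrix
  M3 <- diagram_distance_matrix(rep(ds[1], 3), 1L)
  expect_equal(max(abs(M3$D)), 0)
  expect_error(diagram_distance_matrix(list(ds[[1]], mk(2)), 2L), "H2")
})

test_that("diagram CSV round trip is lossless", {
  set.seed(9)
  ds <- list(persistence_diagram(0, cbind(0, runif(5) + 0.1), 1L),
             persistence_diagram(1, cbind(runif(3), runif(3) + 1), 0L))
  f <- tempfile(fileext = ".csv")
  write_diagrams(ds, f)
  back <- read_diagrams(f)
  for (i in 1:2) {
    expect_equal(back[[i]]$dimension, ds[[i]]$dimension)
    expect_equal(back[[i]]$pairs, ds[[i]]$pairs, tolerance = 1e-12)
    expect_equal(back[[i]]$essential_count, ds[[i]]$essential_count)
  }
})

test_that("invalid filtrations and the blow-up guard are rejected", {
  bad <- matrix(c(0, NA, NA, 0), 2)
  expect_error(vr_persistence(bad), "NaN|non-finite")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(vr_persistence(neg), "negative")
  big <- matrix(0.5, 401, 401); diag(big) <- 0
  expect_error(vr_persistence(big, max_dim = 2), "force")
})
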