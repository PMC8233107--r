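# Brute-force persistent-homology oracle: dense Z/2 boundary-matrix
# reduction over the full simplex list in one left-to-right pass.
# Deliberately naive and independent of the package's reduction.

oracle_vr_persistence <- function(d, max_dim = 2) {
  n <- nrow(d)
  dmax <- min(max_dim + 1, n - 1)
  verts <- list(); vals <- numeric(0); dims <- integer(0)
  for (k in 0:dmax) {
    cmb <- utils::combn(n, k + 1)
    for (ci in seq_len(ncol(cmb))) {
      vs <- cmb[, ci]
      verts[[length(verts) + 1]] <- vs
      vals <- c(vals, if (k == 0) 0 else max(d[vs, vs]))
      dims <- c(dims, k)
    }
  }
  m <- length(verts)
  lex <- vapply(verts, function(v)
    paste(sprintf("%05d", c(v, rep(0, 4 - length(v)))), collapse = ""), "")
  ord <- order(vals, dims, lex)
  verts <- verts[ord]; vals <- vals[ord]; dims <- dims[ord]
  key <- vapply(verts, function(v) paste(v, collapse = "-"), "")
  pos <- stats::setNames(seq_len(m), key)

  # dense boundary matrix
  B <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    if (dims[j] == 0) next
    vs <- verts[[j]]
    for (drop in seq_along(vs))
      B[pos[[paste(vs[-drop], collapse = "-")]], j] <- TRUE
  }
  low <- function(col) { w <- which(col); if (length(w)) max(w) else 0L }
  low_of <- integer(m)      # column index owning each pivot row
  pair_birth <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    repeat {
      l <- low(B[, j])
      if (l == 0L || low_of[l] == 0L) break
      B[, j] <- xor(B[, j], B[, low_of[l]])
    }
    l <- low(B[, j])
    if (l > 0L) { low_of[l] <- j; pair_birth[j] <- l }
  }
  out <- list()
  for (k in 0:max_dim) {
    killers <- which(!is.na(pair_birth) & dims == k + 1)
    births <- pair_birth[killers]
    keep <- vals[killers] > vals[births]
    pairs <- cbind(birth = vals[births][keep], death = vals[killers][keep])
    creators <- sum(dims == k & vapply(seq_len(m), function(j)
      dims[j] == k && low(B[, j]) == 0L, TRUE))
    essential <- creators - length(killers)
    out[[k + 1]] <- list(dimension = k,
                         pairs = pairs[order(pairs[, 1], pairs[, 2]), ,
                                       drop = FALSE],
                         essential_count = essential)
  }
  out
}

sort_pairs <- function(p) {
  p <- matrix(as.numeric(p), ncol = 2)
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

expect_diagram_equal <- function(pd, oracle, tol = 1e-12) {
  expect_equal(nrow(pd$pairs), nrow(oracle$pairs))
  if (nrow(pd$pairs))
    expect_equal(sort_pairs(pd$pairs), sort_pairs(oracle$pairs),
                 tolerance = tol, ignore_attr = TRUE)
  expect_equal(pd$essential_count, oracle$essential_count)
}

random_metric_space <- function(n, seed) {
  set.seed(seed)
  as.matrix(stats::dist(matrix(stats::rnorm(n * 3), n)))
}
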