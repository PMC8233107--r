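#' Two-dimensional neighbor embedding of a state distance matrix
#'
#' Deterministic manifold embedding in the three-step style of
#' neighbor-graph methods: (1) the k-nearest neighbors of every point are
#' found in the precomputed distance matrix; (2) each neighborhood is
#' promoted to a fuzzy simplicial set with local connectivity calibration
#' (per-point bandwidth solved so the effective neighbor count is
#' `log2(k)`), and the directed weights are symmetrized by probabilistic
#' union; (3) a two-dimensional layout is sought that preserves the fuzzy
#' graph, initialized from the spectral embedding of the symmetrized graph
#' Laplacian and refined by attraction along graph edges and sampled
#' repulsion, with the attraction kernel `1/(1 + a d^(2b))` fitted from
#' `min_dist`. All randomness is driven by `seed`.
#'
#' @param D a `state_dist` or plain symmetric distance matrix.
#' @param n_neighbors neighborhood size (default 15).
#' @param min_dist minimum spacing in the embedding (default 0.1).
#' @param seed integer seed.
#' @param n_epochs refinement epochs (default 150).
#' @return object of class `embedding2d` with `coords` (n x 2), `model`
#'   (training state for out-of-sample projection), `seed` and `params`.
#' @export
fit_embedding <- function(D, n_neighbors = 15L, min_dist = 0.1, seed = 1L,
                          n_epochs = 150L) {
  Dm <- if (inherits(D, "state_dist")) D$D else as.matrix(D)
  if (nrow(Dm) != ncol(Dm) || !isSymmetric(unname(Dm), tol = 1e-8))
    stop("distance matrix must be square and symmetric")
  n <- nrow(Dm)
  if (n < n_neighbors + 1) stop("need at least n_neighbors + 1 points")
  k <- min(n_neighbors, n - 1L)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  # zero-distance points are the same state: embed unique representatives
  # and copy coordinates onto their duplicates
  rep_of <- seq_len(n)
  for (i in seq_len(n)) {
    z <- which(Dm[i, seq_len(i - 1)] == 0)
    if (i > 1 && length(z)) rep_of[i] <- rep_of[z[1]]
  }
  reps <- which(rep_of == seq_len(n))
  if (length(reps) < 3) stop("need at least 3 distinct points to embed")
  Du <- Dm[reps, reps, drop = FALSE]
  ku <- min(k, length(reps) - 1L)

  fuzzy <- fuzzy_weights(Du, ku)
  W <- fuzzy$W
  B <- W + t(W) - W * t(W)  # fuzzy union

  ucoords <- spectral_init(B)
  ab <- find_ab_params(min_dist)
  ucoords <- refine_layout(ucoords, B, ab$a, ab$b, n_epochs)
  coords <- ucoords[match(rep_of, reps), , drop = FALSE]

  structure(list(
    coords = coords,
    model = list(train_coords = coords, n_train = n, k = k, ab = ab),
    seed = as.integer(seed),
    params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                  metric_mode = "precomputed", n_epochs = n_epochs)),
    class = "embedding2d")
}

# per-row fuzzy neighbor weights: rho_i = nearest distance, sigma_i solved
# so sum_j exp(-(d_ij - rho_i)/sigma_i) = log2(k)
fuzzy_weights <- function(Dm, k, rows = seq_len(nrow(Dm)),
                          self_cols = TRUE) {
  n_cols <- ncol(Dm)
  target <- log2(k)
  W <- matrix(0, length(rows), n_cols)
  for (ii in seq_along(rows)) {
    i <- rows[ii]
    d <- Dm[i, ]
    if (self_cols) d[i] <- Inf  # exclude self
    nb <- order(d)[seq_len(k)]
    dn <- d[nb]
    rho <- dn[1]
    f <- function(s) sum(exp(-pmax(dn - rho, 0) / s)) - target
    lo <- 1e-6; hi <- max(dn[k] - rho, 1e-6) * 10 + 1
    sig <- tryCatch(stats::uniroot(f, c(lo, hi), extendInt = "downX")$root,
                    error = function(e) hi)
    W[ii, nb] <- exp(-pmax(dn - rho, 0) / sig)
  }
  list(W = W)
}

# spectral layout: eigenvectors 2:3 of the symmetric-normalized adjacency
spectral_init <- function(B) {
  n <- nrow(B)
  deg <- pmax(rowSums(B), 1e-12)
  L <- B / sqrt(outer(deg, deg))
  e <- eigen(L, symmetric = TRUE)
  coords <- e$vectors[, 2:3, drop = FALSE]
  # deterministic sign convention
  for (j in 1:2) {
    m <- which.max(abs(coords[, j]))
    if (coords[m, j] < 0) coords[, j] <- -coords[, j]
  }
  scale_factor <- 10 / max(apply(coords, 2, function(x) diff(range(x)) + 1e-12))
  coords * scale_factor
}

# least-squares fit of 1/(1 + a x^(2b)) to the min_dist offset-exponential
find_ab_params <- function(min_dist, spread = 1) {
  x <- seq(1e-3, 3 * spread, length.out = 300)
  y <- ifelse(x <= min_dist, 1, exp(-(x - min_dist) / spread))
  obj <- function(p) sum((1 / (1 + exp(p[1]) * x^(2 * exp(p[2]))) - y)^2)
  p <- stats::optim(c(log(1.5), log(1)), obj)$par
  list(a = exp(p[1]), b = exp(p[2]))
}

# batch attraction along edges + sampled repulsion, decaying step size
refine_layout <- function(coords, B, a, b, n_epochs) {
  n <- nrow(coords)
  idx <- which(B > 0.05, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  if (!nrow(idx) || n_epochs < 1) return(coords)
  w <- B[idx]
  i <- idx[, 1]; j <- idx[, 2]
  for (ep in seq_len(n_epochs)) {
    lr <- 1 - (ep - 1) / n_epochs
    diff <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    d2 <- pmax(rowSums(diff^2), 1e-10)
    # attraction gradient of the pair cross-entropy
    ga <- (-2 * a * b * d2^(b - 1)) / (1 + a * d2^b)
    push <- lr * 0.1 * w * ga * diff
    # each endpoint moves at most 40% of the gap: no overshoot oscillation
    push <- push * pmin(1, 0.4 * sqrt(d2) / pmax(sqrt(rowSums(push^2)), 1e-12))
    upd <- rowsum(rbind(push, -push), c(i, j))
    rows <- as.integer(rownames(upd))
    coords[rows, ] <- coords[rows, ] + upd
    # sampled repulsion
    r <- sample.int(n, length(i), replace = TRUE)
    diff <- coords[i, , drop = FALSE] - coords[r, , drop = FALSE]
    d2 <- pmax(rowSums(diff^2), 1e-3)
    gr <- (2 * b) / (d2 * (1 + a * d2^b))
    push <- lr * 0.1 * pmin(gr, 4) * diff
    upd <- rowsum(push, i)
    rows <- as.integer(rownames(upd))
    coords[rows, ] <- coords[rows, ] + upd
  }
  coords
}

#' Project new points into a fitted embedding
#'
#' Out-of-sample placement: each new point is located at the weighted mean
#' of the embedding coordinates of its `k` nearest training points, with
#' inverse-distance weights sharp enough that a point identical to a
#' training point lands on its twin.
#'
#' @param model an `embedding2d` from [fit_embedding()].
#' @param D_new rectangular distances, new points x training points
#'   (columns in training order).
#' @param power inverse-distance weight exponent.
#' @return m x 2 coordinate matrix.
#' @export
project_embedding <- function(model, D_new, power = 4) {
  stopifnot(inherits(model, "embedding2d"))
  D_new <- as.matrix(D_new)
  if (ncol(D_new) != model$model$n_train)
    stop("column count does not match the training set")
  k <- model$model$k
  Y <- model$model$train_coords
  out <- matrix(0, nrow(D_new), 2)
  for (i in seq_len(nrow(D_new))) {
    d <- D_new[i, ]
    nb <- order(d)[seq_len(k)]
    dn <- d[nb]
    w <- 1 / (dn + 1e-9 * max(dn[k], 1e-12))^power
    w <- w / sum(w)
    out[i, ] <- colSums(Y[nb, , drop = FALSE] * w)
  }
  out
}

#' Gaussian density grid and watershed segmentation of a 2-D embedding
#'
#' A Gaussian kernel density is evaluated on a grid of at most
#' `grid` x `grid` pixels; the dimension with the smaller coordinate range
#' is trimmed so pixels stay square. Per-axis bandwidths are
#' `bandwidth_factor` times the axis coordinate range (equivalently, the
#' kernel sd is that fraction of the grid extent in pixels). The watershed
#' labels every pixel by steepest ascent: each pixel points to its
#' highest-density 8-neighbor (plateau ties to the lower linear index);
#' chains terminate in local maxima, which seed the clusters. Pixels with
#' density below `floor_frac` times the maximum stay unlabeled (0).
#'
#' @param coords n x 2 coordinate matrix (n >= 2, not all identical).
#' @param grid grid size along the larger axis (default 256).
#' @param bandwidth_factor KDE bandwidth multiplier (default 0.08).
#' @param floor_frac relative density floor for labeling.
#' @return object of class `watershed_seg`: `density` and `labels` grids,
#'   grid axes `x`/`y`, `assignments` (per-point cluster id), and
#'   `n_clusters`.
#' @export
density_and_watershed <- function(coords, grid = 256L,
                                  bandwidth_factor = 0.08,
                                  floor_frac = 1e-6) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 points")
  sx <- stats::sd(coords[, 1]); sy <- stats::sd(coords[, 2])
  if (sx == 0 && sy == 0) {
    warning("all points identical; single cluster")
    return(structure(list(density = matrix(1, 1, 1),
                          labels = matrix(1L, 1, 1),
                          x = coords[1, 1], y = coords[1, 2],
                          bandwidth_factor = bandwidth_factor,
                          assignments = rep(1L, nrow(coords)),
                          n_clusters = 1L),
                     class = "watershed_seg"))
  }
  rx <- diff(range(coords[, 1])); ry <- diff(range(coords[, 2]))
  hx <- max(bandwidth_factor * max(rx, ry * 1e-3), 1e-9)
  hy <- max(bandwidth_factor * max(ry, rx * 1e-3), 1e-9)
  pad <- 3
  xr <- range(coords[, 1]) + c(-pad * hx, pad * hx)
  yr <- range(coords[, 2]) + c(-pad * hy, pad * hy)
  # square pixels: full grid on the larger range, trim the other
  if (diff(xr) >= diff(yr)) {
    nx <- as.integer(grid)
    px <- diff(xr) / (nx - 1)
    ny <- max(2L, as.integer(round(diff(yr) / px)) + 1L)
    yr[2] <- yr[1] + (ny - 1) * px  # exactly square pixels
  } else {
    ny <- as.integer(grid)
    px <- diff(yr) / (ny - 1)
    nx <- max(2L, as.integer(round(diff(xr) / px)) + 1L)
    xr[2] <- xr[1] + (nx - 1) * px
  }
  gx <- seq(xr[1], xr[2], length.out = nx)
  gy <- seq(yr[1], yr[2], length.out = ny)
  Kx <- stats::dnorm(outer(gx, coords[, 1], "-") / hx) / hx
  Ky <- stats::dnorm(outer(gy, coords[, 2], "-") / hy) / hy
  dens <- Kx %*% t(Ky) / nrow(coords)  # nx x ny

  labels <- watershed_labels(dens, floor_frac)
  ix <- pmin(pmax(round((coords[, 1] - gx[1]) / (gx[2] - gx[1])) + 1, 1), nx)
  iy <- pmin(pmax(round((coords[, 2] - gy[1]) / (gy[2] - gy[1])) + 1, 1), ny)
  assignments <- labels[cbind(ix, iy)]
  structure(list(density = dens, labels = labels, x = gx, y = gy,
                 bandwidth_factor = bandwidth_factor,
                 assignments = as.integer(assignments),
                 n_clusters = max(labels)),
            class = "watershed_seg")
}

# steepest-ascent watershed by pointer jumping; deterministic
watershed_labels <- function(dens, floor_frac = 1e-6) {
  nx <- nrow(dens); ny <- ncol(dens)
  npix <- nx * ny
  lin <- seq_len(npix)
  # best (highest-density) 8-neighbor of each pixel; ties to lower index
  best_val <- rep(-Inf, npix)
  best_idx <- lin
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0), ]
  ix <- (lin - 1) %% nx + 1
  iy <- (lin - 1) %/% nx + 1
  for (s in seq_len(nrow(shifts))) {
    jx <- ix + shifts$dx[s]
    jy <- iy + shifts$dy[s]
    ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
    nb <- (jy - 1) * nx + jx
    v <- rep(-Inf, npix)
    v[ok] <- dens[nb[ok]]
    better <- v > best_val | (v == best_val & ok & nb < best_idx)
    best_val[better] <- v[better]
    best_idx[better] <- nb[better]
  }
  d <- as.numeric(dens)
  # ascend if the neighbor is strictly denser, or equally dense with a
  # lower linear index (plateau policy); otherwise the pixel is a root
  parent <- ifelse(best_val > d | (best_val == d & best_idx < lin),
                   best_idx, lin)
  repeat {
    pp <- parent[parent]
    if (identical(pp, parent)) break
    parent <- pp
  }
  roots <- sort(unique(parent))
  # order cluster ids by decreasing peak density for stable labeling
  roots <- roots[order(-d[roots], roots)]
  lab <- match(parent, roots)
  lab[d < floor_frac * max(d)] <- 0L
  matrix(as.integer(lab), nx, ny)
}

#' @export
print.watershed_seg <- function(x, ...) {
  cat(sprintf("<watershed_seg> %d x %d grid, %d clusters, %d points\n",
              nrow(x$density), ncol(x$density), x$n_clusters,
              length(x$assignments)))
  invisible(x)
}

#' @export
plot.watershed_seg <- function(x, ...) {
  graphics::image(x$x, x$y, x$density, col = grDevices::hcl.colors(64),
                  xlab = "embedding 1", ylab = "embedding 2", ...)
  graphics::contour(x$x, x$y, matrix(as.numeric(x$labels), nrow(x$labels)),
                    add = TRUE, drawlabels = FALSE,
                    levels = seq(0.5, x$n_clusters + 0.5))
  invisible(x)
}
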