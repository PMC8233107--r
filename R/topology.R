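#' Persistence diagram object
#'
#' @param dimension homological dimension k (0, 1 or 2).
#' @param pairs two-column matrix of finite (birth, death) pairs with
#'   death > birth.
#' @param essential_count number of classes that never die (stored but
#'   excluded from `pairs`).
#' @return object of class `persistence_diagram`.
#' @export
persistence_diagram <- function(dimension, pairs, essential_count = 0L) {
  pairs <- matrix(as.numeric(pairs), ncol = 2,
                  dimnames = list(NULL, c("birth", "death")))
  if (nrow(pairs) && any(pairs[, 2] <= pairs[, 1]))
    stop("every death must exceed its birth")
  structure(list(dimension = as.integer(dimension), pairs = pairs,
                 essential_count = as.integer(essential_count)),
            class = "persistence_diagram")
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> H%d: %d finite pairs, %d essential\n",
              x$dimension, nrow(x$pairs), x$essential_count))
  invisible(x)
}

check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d) || any(!is.finite(d))) stop("distance matrix has NaN or non-finite entries")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be square and symmetric")
  d
}

#' Vietoris-Rips persistent homology of a finite metric space
#'
#' Computes persistence diagrams of the Vietoris-Rips filtration
#' `K_r = Rips(G(E < r))` for homological dimensions 0..`max_dim` by
#' boundary-matrix reduction over Z/2 (top-down with clearing). Simplices
#' enter at their diameter; ties in filtration value are broken by
#' dimension then lexicographic vertex order, so an edge at exactly `r`
#' enters after every simplex below `r`. Zero-persistence pairs are
#' dropped; essential classes are counted, not listed.
#'
#' @param distance_matrix symmetric nonnegative zero-diagonal matrix.
#' @param max_dim largest homological dimension (<= 2).
#' @param max_radius truncate the filtration at this diameter
#'   (default `Inf`: the full filtration).
#' @param force allow more than 400 points at `max_dim = 2` (combinatorial
#'   blow-up guard).
#' @return list of `persistence_diagram`s, dimensions `0:max_dim`.
#' @export
vr_persistence <- function(distance_matrix, max_dim = 2L, max_radius = Inf,
                           force = FALSE) {
  d <- check_distance_matrix(distance_matrix)
  if (max_dim > 2) stop("max_dim must be <= 2")
  if (nrow(d) > 400 && max_dim >= 2 && !force)
    stop("refusing > 400 nodes at max_dim = 2; pass force = TRUE to override")
  raw <- .vr_persistence_cpp(d, as.integer(max_dim),
                             if (is.finite(max_radius)) max_radius else .Machine$double.xmax)
  lapply(raw, function(x)
    persistence_diagram(x$dimension, x$pairs, x$essential_count))
}

#' Single-linkage merge heights (zeroth persistent homology)
#'
#' The `n - 1` dendrogram merge heights of agglomerative single-linkage
#' clustering, ascending; these equal the death times of the finite H0
#' classes of the Vietoris-Rips filtration.
#'
#' @param distance_matrix symmetric nonnegative zero-diagonal matrix.
#' @return ascending numeric vector of length `n - 1`.
#' @export
h0_single_linkage <- function(distance_matrix) {
  d <- check_distance_matrix(distance_matrix)
  if (nrow(d) < 2) return(numeric(0))
  sort(stats::hclust(stats::as.dist(d), method = "single")$height)
}

#' Fast H0 persistence diagram of a distance matrix
#'
#' All H0 classes are born at zero distance; the finite deaths are the
#' single-linkage merge heights, and a single essential component remains.
#' Merges at exactly zero height (duplicate points) would be
#' zero-persistence pairs and are dropped.
#'
#' @param distance_matrix symmetric nonnegative zero-diagonal matrix.
#' @return a `persistence_diagram` of dimension 0.
#' @export
h0_diagram <- function(distance_matrix) {
  h <- h0_single_linkage(distance_matrix)
  persistence_diagram(0L, cbind(rep(0, sum(h > 0)), h[h > 0]),
                      essential_count = 1L)
}

#' Persistence diagram of one state point's TVFC graph
#'
#' @param point a `state_point` (must carry its coherence-distance graph).
#' @param dimension homological dimension 0, 1 or 2.
#' @return a `persistence_diagram` with the point's metadata attached.
#' @export
state_diagram <- function(point, dimension) {
  g <- point$graph
  if (is.null(g)) stop("state_point carries no graph")
  d <- if (dimension == 0) h0_diagram(g)
       else vr_persistence(g, max_dim = dimension)[[dimension + 1]]
  d$volunteer <- point$volunteer
  d$time_index <- point$time_index
  d$condition <- point$condition
  d$performance <- point$performance
  d
}

#' Sliced-Wasserstein distance between persistence diagrams
#'
#' Each diagram is augmented with the diagonal projections of the other's
#' points; for each of `n_slices` fixed directions evenly spaced in
#' `[-pi/2, pi/2)` the augmented diagrams are projected, sorted, and
#' matched in order with an l1 cost; the distance is the mean cost over
#' slices. Essential classes are excluded (they are not in `pairs`).
#'
#' @param d1,d2 `persistence_diagram`s of the same dimension.
#' @param n_slices number of projection directions (default 20).
#' @return nonnegative distance.
#' @export
sliced_wasserstein <- function(d1, d2, n_slices = 20L) {
  if (d1$dimension != d2$dimension)
    stop("diagrams have different dimensions")
  theta <- -pi / 2 + pi * (seq_len(n_slices) - 1) / n_slices
  a <- d1$pairs; b <- d2$pairs
  proj <- function(m, th) m[, 1] * cos(th) + m[, 2] * sin(th)
  dproj <- function(m, th) (m[, 1] + m[, 2]) / 2 * (cos(th) + sin(th))
  costs <- vapply(theta, function(th) {
    u <- sort(c(proj(a, th), dproj(b, th)))
    v <- sort(c(proj(b, th), dproj(a, th)))
    sum(abs(u - v))
  }, numeric(1))
  mean(costs)
}

#' Pairwise sliced-Wasserstein distance matrix over diagrams
#'
#' @param diagrams list of `persistence_diagram`s, all of dimension
#'   `dimension`.
#' @param dimension homological dimension (checked against each diagram).
#' @param n_slices number of projection directions.
#' @return object of class `state_dist` labeled `H<dimension>`.
#' @export
diagram_distance_matrix <- function(diagrams, dimension, n_slices = 20L) {
  dims <- vapply(diagrams, function(d) d$dimension, 0L)
  if (any(dims != dimension))
    stop("mixed diagram dimensions; expected all H", dimension)
  D <- .sw_cross_cpp(lapply(diagrams, `[[`, "pairs"), list(), n_slices, TRUE)
  structure(list(metric = paste0("H", dimension), D = D,
                 points = state_meta(diagrams)),
            class = "state_dist")
}

#' Write / read persistence diagrams as CSV
#'
#' One row per finite pair (`dimension`, `birth`, `death`); essential
#' counts per dimension are carried in commented header lines. Round-trips
#' are lossless to better than 1e-12.
#'
#' @param diagrams list of `persistence_diagram`s.
#' @param path file path.
#' @return `read_diagrams` returns a list of `persistence_diagram`s.
#' @export
write_diagrams <- function(diagrams, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (d in diagrams)
    writeLines(sprintf("# H%d essential %d", d$dimension, d$essential_count),
               con)
  writeLines("dimension,birth,death", con)
  for (d in diagrams)
    if (nrow(d$pairs))
      writeLines(sprintf("%d,%.17g,%.17g", d$dimension, d$pairs[, 1],
                         d$pairs[, 2]), con)
  invisible(path)
}

#' @rdname write_diagrams
#' @export
read_diagrams <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# H", lines, value = TRUE)
  ess <- utils::read.table(text = sub("^# H(\\d+) essential (\\d+)$", "\\1 \\2", hdr),
                           col.names = c("dimension", "essential"))
  body <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  lapply(seq_len(nrow(ess)), function(i) {
    k <- ess$dimension[i]
    p <- body[body$dimension == k, c("birth", "death"), drop = FALSE]
    persistence_diagram(k, as.matrix(p), ess$essential[i])
  })
}
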