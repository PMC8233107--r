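#' Weighted Jaccard distance between nonnegative weight vectors
#'
#' `1 - sum(min(w1, w2)) / sum(max(w1, w2))`; two all-zero vectors are at
#' distance 0 (identical emptiness).
#'
#' @param w1,w2 equal-length nonnegative numeric vectors.
#' @return distance in \[0, 1\].
#' @export
weighted_jaccard <- function(w1, w2) {
  if (length(w1) != length(w2)) stop("length mismatch")
  if (any(w1 < 0) || any(w2 < 0)) stop("negative entries are not allowed")
  smax <- sum(pmax(w1, w2))
  if (smax == 0) return(0)
  1 - sum(pmin(w1, w2)) / smax
}

#' Euclidean distance between node topographies
#'
#' @param p1,p2 `state_point` objects or plain numeric vectors.
#' @return nonnegative distance.
#' @export
node_distance <- function(p1, p2) {
  v1 <- if (inherits(p1, "state_point")) p1$node_vector else p1
  v2 <- if (inherits(p2, "state_point")) p2$node_vector else p2
  if (length(v1) != length(v2)) stop("length mismatch")
  sqrt(sum((v1 - v2)^2))
}

#' Node-wise weighted degree (strength) of a TVFC graph
#'
#' @param graph symmetric zero-diagonal regions x regions matrix.
#' @return per-region strength vector `strength_r = sum_q weight(r, q)`.
#' @export
strength_vector <- function(graph) {
  graph <- as.matrix(graph)
  if (!isSymmetric(unname(graph), tol = 1e-8)) stop("graph must be symmetric")
  diag(graph) <- 0
  rowSums(graph)
}

#' Extract simplicial state points from TVFC series
#'
#' Each retained time point becomes a `state_point` carrying the three
#' simplicial feature vectors: the node topography (`|W|` over regions and
#' retained scales, region-major), the upper-triangle edge weights, and
#' the per-region strengths. The Jaccard-based metrics operate on
#' coherence weights (`1 - distance`) by default; set
#' `edge_weights = "distance"` to use coherence distances directly.
#'
#' @param tvfc a `tvfc_series` or list of them (concatenated in order).
#' @param edge_weights `"coherence"` (default) or `"distance"`.
#' @return list of `state_point` objects.
#' @export
state_points <- function(tvfc, edge_weights = c("coherence", "distance")) {
  edge_weights <- match.arg(edge_weights)
  if (inherits(tvfc, "tvfc_series")) tvfc <- list(tvfc)
  out <- list()
  for (tv in tvfc) {
    R <- dim(tv$graphs)[2]
    ut <- upper.tri(matrix(0, R, R))
    for (i in seq_len(dim(tv$graphs)[1])) {
      g <- tv$graphs[i, , ]
      w <- if (edge_weights == "coherence") 1 - g else g
      diag(w) <- 0
      out[[length(out) + 1L]] <- structure(list(
        volunteer = tv$point_meta$volunteer[i],
        time_index = tv$point_meta$time_index[i],
        condition = tv$point_meta$condition[i],
        performance = tv$point_meta$performance[i],
        node_vector = tv$node_amp[i, ],
        edge_vector = w[ut],
        strength_vector = rowSums(w),
        graph = g), class = "state_point")
    }
  }
  out
}

metric_names <- c("node", "edge", "strength", "H0", "H1", "H2")

#' Pairwise state distance matrix under one of the six metrics
#'
#' Simplicial metrics (`node`, `edge`, `strength`) operate on
#' `state_point` feature vectors; homological metrics (`H0`, `H1`, `H2`)
#' accept a list of `persistence_diagram`s (or `state_point`s, in which
#' case diagrams of the requested dimension are computed from their
#' graphs) and delegate to [sliced_wasserstein()].
#'
#' @param points list of `state_point`s or `persistence_diagram`s.
#' @param metric_name one of `"node"`, `"edge"`, `"strength"`, `"H0"`,
#'   `"H1"`, `"H2"`.
#' @param n_slices slices for the sliced-Wasserstein metrics.
#' @return object of class `state_dist`: `metric`, symmetric zero-diagonal
#'   `D`, and `points` metadata (row order = input order).
#' @export
pairwise_distances <- function(points, metric_name, n_slices = 20L) {
  if (!metric_name %in% metric_names)
    stop("unknown metric; must be one of: ", paste(metric_names, collapse = ", "))
  n <- length(points)
  meta <- state_meta(points)
  if (metric_name %in% c("H0", "H1", "H2")) {
    k <- as.integer(substring(metric_name, 2))
    diags <- lapply(points, function(p) {
      if (inherits(p, "persistence_diagram")) p else state_diagram(p, k)
    })
    if (any(vapply(diags, function(d) d$dimension, 0L) != k))
      stop("diagram dimension mismatch for metric ", metric_name)
    D <- diagram_distance_matrix(diags, k, n_slices)$D
  } else {
    field <- switch(metric_name, node = "node_vector", edge = "edge_vector",
                    strength = "strength_vector")
    X <- do.call(rbind, lapply(points, `[[`, field))
    D <- if (metric_name == "node") as.matrix(stats::dist(X))
         else .jaccard_cross_cpp(X, X, TRUE)
  }
  dimnames(D) <- NULL
  structure(list(metric = metric_name, D = D, points = meta),
            class = "state_dist")
}

#' Rectangular cross-distances between two state point sets
#'
#' Same metrics as [pairwise_distances()], for out-of-sample projection:
#' rows are `new_points`, columns the training `points`.
#'
#' @inheritParams pairwise_distances
#' @param new_points list of `state_point`s / `persistence_diagram`s.
#' @return plain numeric matrix, `length(new_points)` x `length(points)`.
#' @export
cross_distances <- function(new_points, points, metric_name, n_slices = 20L) {
  if (!metric_name %in% metric_names)
    stop("unknown metric; must be one of: ", paste(metric_names, collapse = ", "))
  if (metric_name %in% c("H0", "H1", "H2")) {
    k <- as.integer(substring(metric_name, 2))
    da <- lapply(new_points, function(p)
      if (inherits(p, "persistence_diagram")) p else state_diagram(p, k))
    db <- lapply(points, function(p)
      if (inherits(p, "persistence_diagram")) p else state_diagram(p, k))
    return(.sw_cross_cpp(lapply(da, `[[`, "pairs"),
                         lapply(db, `[[`, "pairs"), n_slices, FALSE))
  }
  field <- switch(metric_name, node = "node_vector", edge = "edge_vector",
                  strength = "strength_vector")
  X <- do.call(rbind, lapply(new_points, `[[`, field))
  Y <- do.call(rbind, lapply(points, `[[`, field))
  if (metric_name == "node") {
    x2 <- rowSums(X^2); y2 <- rowSums(Y^2)
    sqrt(pmax(outer(x2, y2, "+") - 2 * X %*% t(Y), 0))
  } else {
    .jaccard_cross_cpp(X, Y, FALSE)
  }
}

state_meta <- function(points) {
  get_field <- function(p, f, default) {
    v <- p[[f]]
    if (is.null(v)) default else v
  }
  data.frame(
    volunteer = vapply(points, get_field, "", f = "volunteer", default = NA_character_),
    time_index = vapply(points, get_field, 0, f = "time_index", default = NA_real_),
    condition = vapply(points, get_field, "", f = "condition", default = NA_character_),
    performance = vapply(points, get_field, 0, f = "performance", default = NA_real_),
    stringsAsFactors = FALSE)
}

#' @export
print.state_dist <- function(x, ...) {
  cat(sprintf("<state_dist> metric %s: %d x %d\n", x$metric, nrow(x$D),
              ncol(x$D)))
  invisible(x)
}
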