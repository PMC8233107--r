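#' Mean performance graph from a set of TVFC state points
#'
#' Element-wise mean of the coherence-distance graphs of the listed
#' points. Components are pooled across bootstrap reinitializations: a
#' time point contributes once per draw in which it qualifies, so
#' duplicates are allowed.
#'
#' @param points list of `state_point`s carrying their graphs.
#' @param task task label for bookkeeping.
#' @param valence `"high"` or `"low"` performance valence.
#' @return object of class `mean_graph` with the averaged graph and
#'   component metadata.
#' @export
build_mean_graph <- function(points, task = NA_character_,
                             valence = NA_character_) {
  if (!length(points)) stop("empty component list")
  g <- Reduce(`+`, lapply(points, `[[`, "graph")) / length(points)
  structure(list(task = task, valence = valence, graph = g,
                 component_ids = state_meta(points)),
            class = "mean_graph")
}

#' @export
print.mean_graph <- function(x, ...) {
  cat(sprintf("<mean_graph> task %s / %s valence: %d regions, %d components\n",
              x$task, x$valence, nrow(x$graph), nrow(x$component_ids)))
  invisible(x)
}

mean_graph_edge_weights <- function(mg, edge_weights = "coherence") {
  g <- mg$graph
  w <- if (edge_weights == "coherence") 1 - g else g
  diag(w) <- 0
  w[upper.tri(w)]
}

#' Distances between mean performance graphs
#'
#' All-pairs distance matrices between mean graphs under the weighted
#' Jaccard distance over edges and the sliced-Wasserstein distance over H0
#' persistence diagrams, reusing the package's metric operations. Entries
#' crossing performance valence within the same task are flagged.
#'
#' @param means list of `mean_graph`s (>= 2).
#' @param edge_weights Jaccard weight convention, as in [state_points()].
#' @param n_slices sliced-Wasserstein slices.
#' @return list: `edge_jaccard` and `sw_h0` matrices, plus the logical
#'   `cross_valence` flag matrix.
#' @export
cross_valence_distances <- function(means, edge_weights = "coherence",
                                    n_slices = 20L) {
  n <- length(means)
  if (n < 2) stop("need at least 2 mean graphs")
  ej <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      d <- weighted_jaccard(mean_graph_edge_weights(means[[i]], edge_weights),
                            mean_graph_edge_weights(means[[j]], edge_weights))
      ej[i, j] <- d; ej[j, i] <- d
    }
  diags <- lapply(means, function(m) h0_diagram(m$graph))
  sw <- diagram_distance_matrix(diags, 0L, n_slices)$D
  tasks <- vapply(means, `[[`, "", "task")
  val <- vapply(means, `[[`, "", "valence")
  cross <- outer(tasks, tasks, "==") & outer(val, val, "!=")
  nm <- paste(tasks, val, sep = ".")
  dimnames(ej) <- dimnames(sw) <- dimnames(cross) <- list(nm, nm)
  list(edge_jaccard = ej, sw_h0 = sw, cross_valence = cross)
}

#' RMS and SD of distances from a mean graph to its components
#'
#' @param mean_graph a `mean_graph`.
#' @param components the `state_point` list the mean was drawn from
#'   (>= 2).
#' @param metric `"edge"` (weighted Jaccard) or `"H0"`
#'   (sliced-Wasserstein).
#' @param edge_weights Jaccard weight convention.
#' @param n_slices sliced-Wasserstein slices.
#' @return named numeric vector `c(rms, sd)`.
#' @export
rms_to_components <- function(mean_graph, components, metric = "edge",
                              edge_weights = "coherence", n_slices = 20L) {
  if (length(components) < 2) stop("need at least 2 components")
  dists <- switch(metric,
    edge = {
      mw <- mean_graph_edge_weights(mean_graph, edge_weights)
      vapply(components, function(p) {
        g <- p$graph
        w <- if (edge_weights == "coherence") 1 - g else g
        diag(w) <- 0
        weighted_jaccard(mw, w[upper.tri(w)])
      }, numeric(1))
    },
    H0 = {
      md <- h0_diagram(mean_graph$graph)
      vapply(components, function(p)
        sliced_wasserstein(md, h0_diagram(p$graph), n_slices), numeric(1))
    },
    stop("unknown metric '", metric, "'; use \"edge\" or \"H0\""))
  c(rms = sqrt(mean(dists^2)), sd = stats::sd(dists))
}
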