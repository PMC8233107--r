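#' Volunteer tripartition and condition-balanced subsampling plan
#'
#' Splits volunteers at random into three equal groups (embedding
#' training, watershed clustering, testing). Per volunteer, one randomly
#' chosen presentation each of the repeated math and memory tasks is
#' removed to balance conditions, and `n_train` training indices are
#' drawn from the remaining points as an evenly spaced lattice with random
#' phase (maximal temporal separation).
#'
#' @param meta_list list with one per-volunteer data.frame of retained
#'   point metadata, ordered in time, containing a `condition` column
#'   (e.g. `lapply(tvfc_list, function(tv) tv$point_meta)`).
#' @param seed integer seed.
#' @param n_train training points per volunteer (default 100).
#' @param balance_conditions conditions with one presentation removed.
#' @return object of class `split_plan`: volunteer index vectors
#'   `embed_group`, `cluster_group`, `test_group`; `retained` (per
#'   volunteer, indices into the point list after balancing);
#'   `train_subsample` (per volunteer, `n_train` indices, a subset of
#'   `retained`); `seed`.
#' @export
make_split <- function(meta_list, seed, n_train = 100L,
                       balance_conditions = c("math", "memory")) {
  V <- length(meta_list)
  if (V < 3 || V %% 3 != 0)
    stop("the number of volunteers must be a positive multiple of 3")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(V)
  g <- V / 3
  retained <- vector("list", V)
  train <- vector("list", V)
  for (v in seq_len(V)) {
    cond <- meta_list[[v]]$condition
    keep <- rep(TRUE, length(cond))
    runs <- rle(cond)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1
    for (bc in balance_conditions) {
      hits <- which(runs$values == bc)
      if (length(hits) < 2)
        stop(sprintf("volunteer %d lacks repeated '%s' presentations", v, bc))
      drop <- sample(hits, 1)
      keep[run_start[drop]:run_end[drop]] <- FALSE
    }
    retained[[v]] <- which(keep)
    n <- length(retained[[v]])
    if (n < n_train)
      stop("fewer retained points than requested training subsample")
    step <- n / n_train
    phase <- stats::runif(1) * step
    lattice <- unique(pmin(floor(phase + (seq_len(n_train) - 1) * step) + 1, n))
    # numerically guaranteed distinct for step > 1, but guard anyway
    while (length(lattice) < n_train)
      lattice <- union(lattice, sample.int(n, 1))
    train[[v]] <- retained[[v]][sort(lattice)]
  }
  structure(list(embed_group = sort(perm[seq_len(g)]),
                 cluster_group = sort(perm[g + seq_len(g)]),
                 test_group = sort(perm[2 * g + seq_len(g)]),
                 retained = retained, train_subsample = train,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Permutation null for per-cluster label counts
#'
#' Randomly permutes point labels `n_perm` times and records the mean and
#' standard deviation of the per-(cluster, label) count, the normal
#' summary used for the permutation p-values.
#'
#' @param assignments integer cluster id per point (0 = unassigned,
#'   excluded).
#' @param labels label per point (volunteer, condition, ...).
#' @param n_perm number of permutations (default 300).
#' @param seed integer seed.
#' @param blocks optional block id per point. When given, labels (which
#'   must be constant within a block) are permuted across whole blocks
#'   rather than across points: the exchangeable unit of a block design
#'   with temporally autocorrelated points is the presentation, and
#'   point-level permutation is anticonservative there.
#' @return list with `observed`, `null_mean`, `null_sd` (cluster x label
#'   matrices), `clusters`, `labels`, and the permuted count array.
#' @export
permutation_null <- function(assignments, labels, n_perm = 300L, seed = 1L,
                             blocks = NULL) {
  stopifnot(length(assignments) == length(labels))
  keep <- assignments > 0
  a <- factor(assignments[keep])
  l <- factor(labels[keep])
  if (nlevels(a) == 1 && nlevels(l) == 1)
    warning("single cluster and single label: degenerate null")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  obs <- unclass(table(a, l))
  perms <- array(0, dim = c(nlevels(a), nlevels(l), n_perm))
  if (is.null(blocks)) {
    for (p in seq_len(n_perm))
      perms[, , p] <- unclass(table(a, sample(l)))
  } else {
    stopifnot(length(blocks) == length(labels))
    b <- factor(blocks[keep])
    block_lab <- tapply(as.character(l), b, function(x) x[1])
    if (any(tapply(as.character(l), b, function(x) length(unique(x))) > 1))
      stop("labels are not constant within blocks")
    M <- unclass(table(a, b))                 # cluster x block point counts
    nb <- nlevels(b)
    for (p in seq_len(n_perm)) {
      permlab <- factor(block_lab[sample.int(nb)], levels = levels(l))
      ind <- stats::model.matrix(~ permlab - 1)  # block x label indicator
      perms[, , p] <- M %*% ind
    }
  }
  list(observed = obs,
       null_mean = apply(perms, 1:2, mean),
       null_sd = apply(perms, 1:2, stats::sd),
       clusters = as.integer(levels(a)), labels = levels(l),
       perms = perms)
}

#' Infer block (presentation) ids from point metadata
#'
#' A new block starts whenever the volunteer or the condition changes
#' along the time-ordered point sequence; with instruction segments
#' interleaving task presentations this recovers the presentations.
#'
#' @param meta data.frame with `volunteer` and `condition`, time-ordered
#'   within volunteer.
#' @return integer block id per row.
#' @export
infer_blocks <- function(meta) {
  v <- as.character(meta$volunteer)
  cond <- as.character(meta$condition)
  n <- length(v)
  if (!n) return(integer(0))
  new_block <- c(TRUE, v[-1] != v[-n] | cond[-1] != cond[-n])
  cumsum(new_block)
}

# p-values from a permutation null; "normal" uses the (mean, sd) summary,
# "empirical" the permutation rank
null_pvalues <- function(obs, null, tail = c("right", "left", "two"),
                         mode = c("normal", "empirical")) {
  tail <- match.arg(tail)
  mode <- match.arg(mode)
  if (mode == "normal") {
    z <- (obs - null$null_mean) / null$null_sd
    z[null$null_sd == 0] <- 0
    switch(tail,
           right = stats::pnorm(z, lower.tail = FALSE),
           left = stats::pnorm(z),
           two = 2 * stats::pnorm(-abs(z)))
  } else {
    n_perm <- dim(null$perms)[3]
    ge <- apply(sweep(null$perms, 1:2, obs, ">="), 1:2, sum)
    le <- apply(sweep(null$perms, 1:2, obs, "<="), 1:2, sum)
    switch(tail,
           right = (1 + ge) / (1 + n_perm),
           left = (1 + le) / (1 + n_perm),
           two = pmin(1, 2 * pmin((1 + ge) / (1 + n_perm),
                                  (1 + le) / (1 + n_perm))))
  }
}

#' Volunteer generalizability of watershed clusters
#'
#' A volunteer is "represented" in a cluster unless the left-tail
#' permutation test flags significant under-representation at the
#' Bonferroni-corrected level `alpha / (V * C)`. Returns, for each bin
#' `k`, the percentage of assigned test points lying in clusters with
#' exactly `k` represented volunteers.
#'
#' @param assignments cluster id per test point (0 excluded).
#' @param volunteers volunteer label per test point.
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations for the null (default 300).
#' @param seed integer seed.
#' @param mode p-value mode, `"normal"` (default) or `"empirical"`.
#' @return list: `bin_percent` (named vector over 0..V, summing to 100),
#'   `represented` (cluster x volunteer logical), `p` (matrix),
#'   `n_tests` (Bonferroni m).
#' @export
volunteer_generalizability <- function(assignments, volunteers, alpha = 0.05,
                                       n_perm = 300L, seed = 1L,
                                       mode = "normal") {
  null <- permutation_null(assignments, volunteers, n_perm, seed)
  p <- null_pvalues(null$observed, null, "left", mode)
  V <- length(null$labels)
  C <- length(null$clusters)
  m <- V * C
  represented <- !(p < alpha / m)
  n_rep <- rowSums(represented)
  keep <- assignments > 0
  cl <- factor(assignments[keep], levels = null$clusters)
  pts_per_cluster <- as.integer(table(cl))
  bins <- setNames(numeric(V + 1), 0:V)
  for (k in 0:V)
    bins[as.character(k)] <-
      100 * sum(pts_per_cluster[n_rep == k]) / sum(pts_per_cluster)
  list(bin_percent = bins, represented = represented, p = p, n_tests = m)
}

#' Stimulus enrichment of watershed clusters
#'
#' Right-tail permutation test for clusters containing significantly many
#' points of each condition, Bonferroni-corrected over
#' `n_conditions * n_clusters` tests. The colocalization percentage of a
#' condition is the share of that condition's points residing in clusters
#' significantly enriched for it.
#'
#' @inheritParams volunteer_generalizability
#' @param conditions condition label per test point.
#' @param all_conditions optional complete condition set (absent
#'   conditions reported as 0% with a warning).
#' @param blocks optional block id per point; labels are then permuted
#'   across presentations (see [permutation_null()]). Recommended for
#'   block designs; `NULL` permutes points, the literal convention.
#' @return list: `colocalization` (named percentage per condition),
#'   `significant` (cluster x condition logical), `p`, `n_tests`, `null`.
#' @export
stimulus_enrichment <- function(assignments, conditions, alpha = 0.05,
                                n_perm = 300L, seed = 1L, mode = "normal",
                                all_conditions = NULL, blocks = NULL) {
  null <- permutation_null(assignments, conditions, n_perm, seed,
                           blocks = blocks)
  p <- null_pvalues(null$observed, null, "right", mode)
  C <- length(null$clusters)
  L <- length(null$labels)
  m <- C * ifelse(is.null(all_conditions), L, length(all_conditions))
  sig <- p < alpha / m
  keep <- assignments > 0
  cl <- factor(assignments[keep], levels = null$clusters)
  cond <- factor(conditions[keep], levels = null$labels)
  counts <- unclass(table(cl, cond))
  coloc <- vapply(seq_len(L), function(j) {
    tot <- sum(counts[, j])
    if (tot == 0) return(NA_real_)
    100 * sum(counts[sig[, j], j]) / tot
  }, numeric(1))
  names(coloc) <- null$labels
  if (!is.null(all_conditions)) {
    missing <- setdiff(all_conditions, null$labels)
    if (length(missing)) {
      warning("conditions absent from the test set: ",
              paste(missing, collapse = ", "))
      coloc[missing] <- 0
    }
    coloc <- coloc[all_conditions]
  }
  list(colocalization = coloc, significant = sig, p = p, n_tests = m,
       null = null)
}

#' Effect sizes and null colocalization for stimulus enrichment
#'
#' Two permuted references for observed colocalization percentages:
#' the restricted null permutes point labels but keeps the pre-identified
#' significant clusters fixed (expected colocalization by cluster size
#' alone); the full null permutes labels and reruns the entire enrichment
#' test (false-positive colocalization). Cohen's d (pooled SD) is
#' computed between the observed and restricted-null distributions.
#'
#' @param real_pcts numeric matrix (draws x conditions) or vector of
#'   observed colocalization percentages.
#' @param assignments,conditions as in [stimulus_enrichment()].
#' @param significant cluster x condition logical from the real analysis
#'   (rows ordered as the cluster levels of `assignments`).
#' @param n_draws permuted draws for each null (default 20).
#' @param alpha,n_perm,mode forwarded to the full-null reruns.
#' @param seed integer seed.
#' @param blocks optional block id per point; permutations then move
#'   whole presentations (see [permutation_null()]).
#' @return list: `cohens_d` per condition (`Inf` sentinel when both
#'   distributions are degenerate), `restricted_null` and `full_null`
#'   (draws x conditions matrices).
#' @export
enrichment_effect_size <- function(real_pcts, assignments, conditions,
                                   significant, n_draws = 20L, alpha = 0.05,
                                   n_perm = 300L, mode = "normal",
                                   seed = 1L, blocks = NULL) {
  real_pcts <- rbind(real_pcts)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  keep <- assignments > 0
  a <- factor(assignments[keep])
  cond_levels <- sort(unique(conditions[keep]))
  bl <- if (is.null(blocks)) NULL else blocks[keep]
  permute_labels <- function(lab) {
    if (is.null(bl)) return(sample(lab))
    b <- factor(bl)
    block_lab <- tapply(lab, b, function(x) x[1])
    unname(block_lab[sample.int(nlevels(b))][as.integer(b)])
  }
  yellow <- matrix(NA_real_, n_draws, length(cond_levels),
                   dimnames = list(NULL, cond_levels))
  black <- yellow
  for (dd in seq_len(n_draws)) {
    perm <- permute_labels(conditions[keep])
    counts <- unclass(table(a, factor(perm, levels = cond_levels)))
    for (j in seq_along(cond_levels)) {
      tot <- sum(counts[, j])
      yellow[dd, j] <- if (tot == 0) 0 else
        100 * sum(counts[significant[, j, drop = TRUE], j]) / tot
    }
    full <- stimulus_enrichment(assignments[keep], perm, alpha, n_perm,
                                seed = seed + dd, mode = mode, blocks = bl)
    black[dd, cond_levels] <- full$colocalization[cond_levels]
  }
  d <- vapply(seq_along(cond_levels), function(j) {
    x <- real_pcts[, min(j, ncol(real_pcts))]
    if (!is.null(colnames(real_pcts)) &&
        cond_levels[j] %in% colnames(real_pcts))
      x <- real_pcts[, cond_levels[j]]
    y <- yellow[, j]
    sp <- sqrt((stats::var(x) * (length(x) - 1) +
                  stats::var(y) * (length(y) - 1)) /
                 (length(x) + length(y) - 2))
    if (!is.finite(sp) || sp == 0) {
      if (mean(x) == mean(y)) return(0)
      warning("zero-variance distributions; Cohen's d reported as Inf")
      return(Inf * sign(mean(x) - mean(y)))
    }
    (mean(x) - mean(y)) / sp
  }, numeric(1))
  names(d) <- cond_levels
  list(cohens_d = d, restricted_null = yellow, full_null = black)
}

#' Performance-valenced clusters within a task
#'
#' Restricted to clusters already significantly enriched for `task`, tests
#' whether the task points inside each cluster show more or fewer correct
#' responses than expected (two-tailed permutation test of the
#' within-cluster mean block performance; Bonferroni over the number of
#' candidate clusters). Valence is `high` when the observed mean reaches
#' the task mean (ties high), else `low`.
#'
#' @param assignments cluster id per test point.
#' @param conditions condition label per test point.
#' @param performance block performance per test point.
#' @param task task condition to analyse.
#' @param task_clusters integer ids of clusters significant for `task`.
#' @param alpha,n_perm,seed,mode as elsewhere.
#' @param blocks optional block id per point; the null then permutes
#'   block-level performance across presentations rather than point-wise.
#' @return data.frame (cluster, n, observed_mean, null_mean, null_sd, p,
#'   valence, significant); zero rows when no candidate clusters exist.
#' @export
performance_test <- function(assignments, conditions, performance, task,
                             task_clusters, alpha = 0.05, n_perm = 300L,
                             seed = 1L, mode = "normal", blocks = NULL) {
  sel <- conditions == task & assignments > 0 & !is.na(performance)
  if (!length(task_clusters) || !any(sel)) {
    message("no significant clusters for task ", task)
    return(data.frame(cluster = integer(0), n = integer(0),
                      observed_mean = numeric(0), null_mean = numeric(0),
                      null_sd = numeric(0), p = numeric(0),
                      valence = character(0), significant = logical(0)))
  }
  a <- assignments[sel]
  perf <- performance[sel]
  task_mean <- mean(perf)
  bl <- if (is.null(blocks)) NULL else factor(blocks[sel])
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- lapply(task_clusters, function(cid) {
    inside <- a == cid
    n <- sum(inside)
    if (n == 0)
      return(data.frame(cluster = cid, n = 0L, observed_mean = NA_real_,
                        null_mean = NA_real_, null_sd = NA_real_,
                        p = NA_real_, valence = NA_character_,
                        significant = FALSE))
    obs <- mean(perf[inside])
    nulls <- if (is.null(bl)) {
      vapply(seq_len(n_perm), function(i) mean(sample(perf, n)), numeric(1))
    } else {
      # permute block performances; cluster keeps its per-block weights
      w <- tapply(inside, bl, sum)
      bperf <- tapply(perf, bl, function(x) x[1])
      vapply(seq_len(n_perm), function(i) {
        sum(w * bperf[sample.int(length(bperf))]) / sum(w)
      }, numeric(1))
    }
    mu <- mean(nulls); sdv <- stats::sd(nulls)
    p <- if (mode == "normal") {
      z <- if (sdv == 0) 0 else (obs - mu) / sdv
      2 * stats::pnorm(-abs(z))
    } else {
      2 * min((1 + sum(nulls >= obs)) / (1 + n_perm),
              (1 + sum(nulls <= obs)) / (1 + n_perm))
    }
    data.frame(cluster = cid, n = n, observed_mean = obs, null_mean = mu,
               null_sd = sdv, p = p,
               valence = if (obs >= task_mean) "high" else "low",
               significant = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha / length(task_clusters)
  out
}

#' Map coordinates into a watershed segmentation
#'
#' @param seg a `watershed_seg`.
#' @param coords m x 2 coordinates.
#' @return integer cluster ids (0 = unassigned / off-grid low density).
#' @export
assign_to_segmentation <- function(seg, coords) {
  coords <- as.matrix(coords)
  if (length(seg$x) < 2)
    return(rep(1L, nrow(coords)))
  ix <- round((coords[, 1] - seg$x[1]) / (seg$x[2] - seg$x[1])) + 1
  iy <- round((coords[, 2] - seg$y[1]) / (seg$y[2] - seg$y[1])) + 1
  ix <- pmin(pmax(ix, 1), length(seg$x))
  iy <- pmin(pmax(iy, 1), length(seg$y))
  as.integer(seg$labels[cbind(ix, iy)])
}

#' Bootstrap driver: repeated split / embed / segment / test
#'
#' Repeats the volunteer split, embedding, watershed segmentation, and the
#' statistical tests with fresh seeds, and aggregates the per-draw results
#' (mean and 95% CI). Simplicial metrics use precomputed state points;
#' homological metrics use precomputed persistence diagrams.
#'
#' @param points_by_volunteer list (one entry per volunteer) of
#'   `state_point` lists, in time order.
#' @param metrics character subset of the six metric names.
#' @param n_boot number of reinitializations (default 256).
#' @param n_train training points per volunteer (default 100).
#' @param eval_subsample optional cap on cluster-/test-group points per
#'   volunteer (evenly spaced subsample; NULL = use all balanced points).
#' @param n_neighbors,min_dist,n_epochs embedding parameters.
#' @param grid,bandwidth_factor segmentation parameters.
#' @param alpha,n_perm,mode test parameters.
#' @param perm_unit `"block"` (default) permutes condition labels across
#'   presentations in the enrichment test -- the exchangeable unit for
#'   temporally autocorrelated block designs; `"point"` permutes points,
#'   the literal convention.
#' @param n_slices sliced-Wasserstein slices.
#' @param seed integer seed; draw `i` uses `seed + i`.
#' @return object of class `bootstrap_result`: `draws` (per metric, list
#'   of per-draw lists), `summary` (tidy data.frame of colocalization
#'   percentages), `generalizability` (per metric, draws x bins matrix).
#' @export
bootstrap_driver <- function(points_by_volunteer, metrics = metric_names,
                             n_boot = 256L, n_train = 100L,
                             eval_subsample = NULL, n_neighbors = 15L,
                             min_dist = 0.1, n_epochs = 150L, grid = 256L,
                             bandwidth_factor = 0.08, alpha = 0.05,
                             n_perm = 300L, mode = "normal",
                             perm_unit = c("block", "point"),
                             n_slices = 20L, seed = 1L) {
  perm_unit <- match.arg(perm_unit)
  stopifnot(all(metrics %in% metric_names))
  V <- length(points_by_volunteer)
  meta_list <- lapply(points_by_volunteer, state_meta)
  # precompute diagrams once per requested homological dimension
  diag_cache <- list()
  for (m in intersect(metrics, c("H0", "H1", "H2"))) {
    k <- as.integer(substring(m, 2))
    diag_cache[[m]] <- lapply(points_by_volunteer, function(pts)
      lapply(pts, state_diagram, dimension = k))
  }
  pick <- function(metric, vol, idx) {
    if (metric %in% names(diag_cache)) diag_cache[[metric]][[vol]][idx]
    else points_by_volunteer[[vol]][idx]
  }
  draws <- lapply(metrics, function(m) vector("list", n_boot))
  names(draws) <- metrics
  for (b in seq_len(n_boot)) {
    plan <- make_split(meta_list, seed = seed + b, n_train = n_train)
    sub_idx <- function(v) {
      idx <- plan$retained[[v]]
      if (!is.null(eval_subsample) && length(idx) > eval_subsample)
        idx <- idx[unique(pmin(floor(seq(1, length(idx),
                                         length.out = eval_subsample)), length(idx)))]
      idx
    }
    for (m in metrics) {
      train_items <- do.call(c, lapply(plan$embed_group, function(v)
        pick(m, v, plan$train_subsample[[v]])))
      clus_items <- do.call(c, lapply(plan$cluster_group, function(v)
        pick(m, v, sub_idx(v))))
      test_items <- do.call(c, lapply(plan$test_group, function(v)
        pick(m, v, sub_idx(v))))
      Dtr <- pairwise_distances(train_items, m, n_slices)
      emb <- fit_embedding(Dtr, n_neighbors, min_dist, seed = seed + b,
                           n_epochs = n_epochs)
      clus_coords <- project_embedding(emb,
        cross_distances(clus_items, train_items, m, n_slices))
      seg <- density_and_watershed(clus_coords, grid, bandwidth_factor)
      test_coords <- project_embedding(emb,
        cross_distances(test_items, train_items, m, n_slices))
      assignments <- assign_to_segmentation(seg, test_coords)
      tmeta <- state_meta(test_items)
      gen <- volunteer_generalizability(assignments, tmeta$volunteer,
                                        alpha, n_perm, seed = seed + b,
                                        mode = mode)
      enr <- stimulus_enrichment(assignments, tmeta$condition, alpha,
                                 n_perm, seed = seed + b, mode = mode,
                                 blocks = if (perm_unit == "block")
                                   infer_blocks(tmeta) else NULL)
      draws[[m]][[b]] <- list(plan = plan, segmentation = seg,
                              assignments = assignments, meta = tmeta,
                              generalizability = gen, enrichment = enr)
    }
  }
  rows <- list()
  genmats <- list()
  for (m in metrics) {
    coloc <- do.call(rbind, lapply(draws[[m]], function(d)
      d$enrichment$colocalization))
    for (cond in colnames(coloc)) {
      x <- coloc[, cond]
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, condition = cond, mean = mean(x, na.rm = TRUE),
        ci_lo = stats::quantile(x, 0.025, na.rm = TRUE, names = FALSE),
        ci_hi = stats::quantile(x, 0.975, na.rm = TRUE, names = FALSE),
        n_boot = n_boot)
    }
    genmats[[m]] <- do.call(rbind, lapply(draws[[m]], function(d)
      d$generalizability$bin_percent))
  }
  structure(list(draws = draws, summary = do.call(rbind, rows),
                 generalizability = genmats, n_boot = n_boot, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d draws\n", x$n_boot))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
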