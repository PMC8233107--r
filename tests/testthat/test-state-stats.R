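# per-volunteer metadata with the full-scale retained-point layout:
# 777 points, math and memory presented twice (120 points each)
full_scale_meta <- function() {
  cond <- c(rep("rest", 57), rep("video", 120), rep("math", 120),
            rep("memory", 120), rep("rest", 120), rep("math", 120),
            rep("memory", 120))
  data.frame(condition = cond, stringsAsFactors = FALSE)
}

test_that("condition balancing yields 537 points and a spaced lattice", {
  meta <- replicate(6, full_scale_meta(), simplify = FALSE)
  plan <- make_split(meta, seed = 11L)
  for (v in 1:6) {
    expect_length(plan$retained[[v]], 537L)
    expect_length(plan$train_subsample[[v]], 100L)
    expect_gte(min(diff(plan$train_subsample[[v]])), floor(537 / 100) - 1)
    expect_true(all(plan$train_subsample[[v]] %in% plan$retained[[v]]))
  }
  # groups partition the volunteers equally
  expect_setequal(c(plan$embed_group, plan$cluster_group, plan$test_group),
                  1:6)
  expect_length(plan$embed_group, 2L)
  expect_identical(plan, make_split(meta, seed = 11L))
  expect_false(identical(plan$retained,
                         make_split(meta, seed = 12L)$retained))
  expect_error(make_split(meta[1:4], seed = 1L), "multiple of 3")
  nomem <- meta
  nomem[[2]]$condition[nomem[[2]]$condition == "memory"] <- "rest"
  expect_error(make_split(nomem, seed = 1L), "memory")
})

test_that("permutation null matches the hypergeometric expectation", {
  set.seed(1)
  a <- rep(1:2, each = 200)
  l <- sample(rep(c("x", "y"), 200))
  null <- permutation_null(a, l, n_perm = 300L, seed = 2L)
  expect_equal(dim(null$observed), c(2L, 2L))
  # each cluster holds 200 points, half of each label expected
  expect_equal(unname(null$null_mean), matrix(100, 2, 2), tolerance = 0.05)
  expect_identical(null, permutation_null(a, l, n_perm = 300L, seed = 2L))
  # identical labels -> degenerate null
  n2 <- permutation_null(a, rep("x", 400), n_perm = 50L, seed = 1L)
  expect_equal(unname(n2$null_sd), matrix(0, 2, 1))
  expect_equal(n2$observed, n2$null_mean, ignore_attr = TRUE)
})

test_that("volunteer representation bins sum to 100 and track mixing", {
  set.seed(4)
  a <- rep(1:3, each = 120)
  mixed <- sample(rep(sprintf("v%d", 1:4), 90))
  gen <- volunteer_generalizability(a, mixed, seed = 5L)
  expect_equal(sum(gen$bin_percent), 100)
  expect_equal(unname(gen$bin_percent["4"]), 100)
  # clusters owned by single volunteers concentrate mass in bin 1
  owned <- sprintf("v%d", rep(1:3, each = 120))
  gen2 <- volunteer_generalizability(a, owned, seed = 5L)
  expect_gt(unname(gen2$bin_percent["1"]), 99)
})

test_that("stimulus enrichment flags constructed pure clusters", {
  a <- rep(1:3, each = 100)
  cond <- rep(c("A", "B", "C"), each = 100)
  enr <- stimulus_enrichment(a, cond, seed = 3L)
  expect_equal(unname(enr$colocalization), c(100, 100, 100))
  expect_true(all(diag(enr$significant)))
  expect_true(all(enr$colocalization >= 0 & enr$colocalization <= 100))
  # missing condition warns and reports 0
  expect_warning(
    enr2 <- stimulus_enrichment(a, cond, seed = 3L,
                                all_conditions = c("A", "B", "C", "D")),
    "absent")
  expect_equal(unname(enr2$colocalization["D"]), 0)
})

test_that("randomized labels rarely reach Bonferroni significance", {
  set.seed(8)
  flagged <- 0; total <- 0
  for (rep in 1:12) {
    a <- sample(1:6, 360, replace = TRUE)
    cond <- sample(c("A", "B", "C"), 360, replace = TRUE)
    enr <- stimulus_enrichment(a, cond, seed = rep)
    flagged <- flagged + sum(enr$significant)
    total <- total + length(enr$significant)
  }
  expect_lte(flagged / total, 0.05)
})

test_that("effect sizes separate real structure from permuted labels", {
  set.seed(10)
  a <- rep(1:3, each = 100)
  cond <- rep(c("A", "B", "C"), each = 100)
  enr <- stimulus_enrichment(a, cond, seed = 2L)
  real <- rbind(enr$colocalization, enr$colocalization + 1)
  es <- enrichment_effect_size(real, a, cond, enr$significant,
                               n_draws = 8L, n_perm = 100L, seed = 6L)
  expect_true(all(es$cohens_d > 0))
  expect_equal(dim(es$restricted_null), c(8L, 3L))
  # permuted labels spread across clusters: restricted null well below 100
  expect_lt(mean(es$restricted_null), 60)
  # real identical to null -> d = 0
  es0 <- enrichment_effect_size(es$restricted_null, a, cond,
                                enr$significant, n_draws = 8L,
                                n_perm = 100L, seed = 6L)
  expect_lt(max(abs(es0$cohens_d)), 0.8)
})

test_that("performance valence flags only genuinely shifted clusters", {
  set.seed(12)
  a <- rep(1:4, each = 80)
  cond <- rep("math", 320)
  # cluster 1 low performance, cluster 4 high, 2-3 at the mean
  perf <- c(rep(0.55, 80), rep(0.75, 160), rep(0.95, 80))
  res <- performance_test(a, cond, perf, "math", task_clusters = 1:4,
                          seed = 3L)
  expect_equal(res$valence[res$cluster == 1], "low")
  expect_equal(res$valence[res$cluster == 4], "high")
  expect_true(all(res$significant[res$cluster %in% c(1, 4)]))
  expect_false(any(res$significant[res$cluster %in% c(2, 3)]))
  # a cluster is never both: valence is a deterministic mean split
  expect_true(all(table(res$cluster) == 1))
  # uniform performance -> nothing valenced
  resu <- performance_test(a, cond, rep(0.8, 320), "math",
                           task_clusters = 1:4, seed = 3L)
  expect_false(any(resu$significant))
  # no candidate clusters -> empty, message
  expect_message(
    res0 <- performance_test(a, cond, perf, "math", integer(0), seed = 1L),
    "no significant")
  expect_equal(nrow(res0), 0L)
})

test_that("the bootstrap driver aggregates draws reproducibly", {
  cfg <- tiny_study(n_volunteers = 3L, n_regions = 8L, seed = 17L)
  st <- generate_study(cfg)
  tvfc <- lapply(st, tiny_tvfc)
  pts <- lapply(tvfc, state_points)
  b1 <- bootstrap_driver(pts, metrics = c("strength"), n_boot = 1L,
                         n_train = 40L, eval_subsample = 60L,
                         n_neighbors = 10L, n_epochs = 30L, n_perm = 60L,
                         seed = 2L)
  expect_length(b1$draws$strength, 1L)
  expect_true(all(c("metric", "condition", "mean", "ci_lo", "ci_hi") %in%
                    names(b1$summary)))
  b2 <- bootstrap_driver(pts, metrics = c("strength"), n_boot = 1L,
                         n_train = 40L, eval_subsample = 60L,
                         n_neighbors = 10L, n_epochs = 30L, n_perm = 60L,
                         seed = 2L)
  expect_equal(b1$summary, b2$summary)
  # constant statistic aggregates to itself: CI collapses onto the mean
  one <- b1$summary
  expect_true(all(one$ci_lo <= one$mean & one$mean <= one$ci_hi))
})

test_that("test statistics never use embed- or cluster-group points", {
  cfg <- tiny_study(n_volunteers = 3L, n_regions = 8L, seed = 23L)
  st <- generate_study(cfg)
  tvfc <- lapply(st, tiny_tvfc)
  pts <- lapply(tvfc, state_points)
  b <- bootstrap_driver(pts, metrics = "node", n_boot = 2L, n_train = 40L,
                        eval_subsample = 50L, n_neighbors = 10L,
                        n_epochs = 30L, n_perm = 60L, seed = 4L)
  vols <- vapply(st, function(s) s$volunteer_id, "")
  for (d in b$draws$node) {
    test_vols <- vols[d$plan$test_group]
    expect_setequal(unique(d$meta$volunteer), test_vols)
  }
})
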