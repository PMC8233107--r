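# Desk-scale fixtures: a short block layout and a fast filterbank so unit
# tests stay quick; acceptance tests use the full-length defaults.

tiny_layout <- function() {
  data.frame(
    condition   = c("rest", "video", "math", "memory",
                    "rest", "math", "memory", "video"),
    duration    = rep(60, 8),
    instruction = rep(6, 8),
    performance = c(NA, 0.8, 0.9, 0.85, NA, 0.6, 0.55, 0.7),
    stringsAsFactors = FALSE)
}

tiny_fb <- function() build_filterbank(0.02, 0.15, 8L, 6, tr = 1.5)

tiny_study <- function(n_volunteers = 3L, n_regions = 12L, seed = 1L, ...) {
  study_config(n_volunteers = n_volunteers, n_regions = n_regions,
               tr = 1.5, block_layout = tiny_layout(), seed = seed, ...)
}

tiny_tvfc <- function(series, trim_time = 40L, trim_scales = 2L) {
  compute_tvfc(series, tiny_fb(), trim_time = trim_time,
               trim_scales = trim_scales)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  stot <- comb2(sum(tab))
  exp_idx <- si * sj / stot
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
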