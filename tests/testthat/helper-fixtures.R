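# shared fixtures, built in code

# one valid random model per kind, under a local RNG stream
random_model <- function(kind) {
  a <- 10^runif(1, -4, 0.5)
  b <- if (kind %in% c("VPL", "PL")) runif(1, 0.05, 0.9) else 10^runif(1, -3, 0.3)
  k <- if (kind %in% c("VEX", "VPL")) 10^runif(1, -8, -2) else 0
  rate_model(kind, alpha = a, beta = b, k = k)
}

ALL_KINDS <- c("VEX", "EX", "VPL", "PL")

# noiseless fv-like dataset + one assembled set (exact t and s)
noiseless_fixture <- function(seed = 1) {
  sc <- synthetic_scenario(s_noise_cv = 0, calib_halfwidth_frac = 0, seed = seed)
  gen <- generate_dataset(sc)
  rs <- assemble_rate_sets(gen$dataset, 1, seed = seed)
  list(gen = gen, points = rs$sets[[1]], truth = gen$truth)
}

# tiny two-level dated dataset for calibration-simulation tests
two_node_dataset <- function(parent_median = 100, parent_sd_frac = 0.02,
                             child_median = 10, child_sd_frac = 0.196) {
  pw <- parent_median * parent_sd_frac * 1.96
  cw <- child_median * child_sd_frac * 1.96 / child_median  # fraction
  sc <- NULL # not used; build by hand
  tree <- ape::read.tree(text = sprintf(
    "((A:0.1,B:0.1)C:0.2,D:0.3)P:0;"))
  nodes <- data.frame(
    node_id = c("C", "P"),
    parent_id = c("P", NA),
    t_median_myr = c(child_median, parent_median),
    t_lower95_myr = c(child_median - child_sd_frac * 1.96 * child_median,
                      parent_median - pw),
    t_upper95_myr = c(child_median + child_sd_frac * 1.96 * child_median,
                      parent_median + pw),
    stringsAsFactors = FALSE)
  s_draws <- list(C = rep(0.1, 50), P = rep(0.3, 50))
  cospeciation_dataset(tree, nodes, s_draws = s_draws)
}

# whole-row rejection sampler: the brute-force oracle for the top-down
# truncated sampler (child < parent, all draws plain normal)
rejection_sample_times <- function(medians, sds, parent_of, n_sets,
                                   max_tries = 1e5) {
  ids <- names(medians)
  out <- matrix(NA_real_, n_sets, length(ids), dimnames = list(NULL, ids))
  for (i in seq_len(n_sets)) {
    for (try in seq_len(max_tries)) {
      d <- rnorm(length(ids), medians, sds)
      names(d) <- ids
      ok <- all(d > 0) &&
        all(vapply(ids, function(id) {
          p <- parent_of[[id]]
          is.null(p) || is.na(p) || d[[id]] < d[[p]]
        }, logical(1)))
      if (ok) { out[i, ] <- d; break }
    }
  }
  out
}
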