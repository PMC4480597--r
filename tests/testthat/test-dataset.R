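test_that("sigma_from_interval implements the wider-half-width rule", {
  expect_equal(sigma_from_interval(10, 6.08, 11.96), 2.0)
  expect_equal(sigma_from_interval(5, 3.04, 6.96), 1.0)
  expect_equal(sigma_from_interval(43.47, 43.47, 43.47), 0.0)
  expect_error(sigma_from_interval(5, 6, 7), "ordering")
})

test_that("node heights are node-to-tip path lengths, ultrametricity enforced", {
  tr <- ape::read.tree(text = "(A:0.3,B:0.3)R:0;")
  h <- node_heights(tr)
  expect_equal(unname(h), 0.3)
  expect_identical(names(h), "R")

  # ladder tree with unit branches: heights checked against explicit path sums
  tr2 <- ape::read.tree(text = "(((A:1,B:1)N1:1,C:2)N2:1,D:3)N3:0;")
  h2 <- node_heights(tr2)
  expect_equal(unname(h2[c("N1", "N2", "N3")]), c(1, 2, 3))

  tr3 <- ape::read.tree(text = "(A:0.4,B:0.3)R:0;")
  expect_error(node_heights(tr3), "ultrametric")
})

test_that("dataset constructor validates ordering invariants", {
  ds <- two_node_dataset()
  expect_s3_class(ds, "cospeciation_dataset")
  expect_equal(sum(ds$nodes$dated), 2L)
  # child calibration above parent -> error
  expect_error(two_node_dataset(parent_median = 5, child_median = 50),
               "below its dated ancestor")
  # s medians decreasing towards the root -> error
  tree <- ape::read.tree(text = "((A:0.1,B:0.1)C:0.2,D:0.3)P:0;")
  nodes <- data.frame(node_id = c("C", "P"), parent_id = c("P", NA),
                      t_median_myr = c(10, 100),
                      t_lower95_myr = c(8, 90), t_upper95_myr = c(12, 110))
  expect_error(
    cospeciation_dataset(tree, nodes,
                         s_draws = list(C = rep(0.5, 5), P = rep(0.3, 5))),
    "exceeds its parent")
})

test_that("calibration-time simulation honours priors and ordering", {
  ds <- two_node_dataset(parent_median = 100, child_median = 10)
  d <- simulate_calibration_times(ds, 10000, seed = 31)
  expect_equal(dim(d), c(10000L, 2L))
  # ordering holds in every row
  expect_true(all(d[, "C"] < d[, "P"]))
  # marginal means within 3 standard errors (constraints inactive here)
  for (id in c("C", "P")) {
    mu <- ds$nodes$t_median_myr[ds$nodes$node_id == id]
    sig <- ds$nodes$t_sd_myr[ds$nodes$node_id == id]
    expect_lt(abs(mean(d[, id]) - mu), 3 * sig / sqrt(10000))
    expect_equal(sd(d[, id]), sig, tolerance = 0.05)
  }
  # infeasible ordering errors
  ds_bad <- tryCatch(two_node_dataset(parent_median = 5, child_median = 50),
                     error = function(e) NULL)
  expect_null(ds_bad)  # already rejected at construction

  # degenerate prior: all draws equal the median
  ds0 <- two_node_dataset(parent_sd_frac = 0, child_sd_frac = 0)
  d0 <- simulate_calibration_times(ds0, 20, seed = 1)
  expect_true(all(d0[, "P"] == 100))
  expect_true(all(d0[, "C"] == 10))
})

test_that("top-down truncated sampler matches a whole-row rejection oracle", {
  # moderately interacting pair so truncation actually binds
  ds <- two_node_dataset(parent_median = 30, parent_sd_frac = 0.1,
                         child_median = 22, child_sd_frac = 0.2)
  set.seed(77)
  d <- simulate_calibration_times(ds, 4000)
  o <- rejection_sample_times(
    medians = c(C = 22, P = 30),
    sds = c(C = ds$nodes$t_sd_myr[ds$nodes$node_id == "C"],
            P = ds$nodes$t_sd_myr[ds$nodes$node_id == "P"]),
    parent_of = list(C = "P", P = NA), n_sets = 4000)
  # the two samplers target different factorisations of the constrained joint;
  # their child marginals must agree closely where truncation binds
  expect_true(all(d[, "C"] < d[, "P"]))
  expect_lt(abs(mean(d[, "C"]) - mean(o[, "C"])), 0.4)
  expect_lt(abs(sd(d[, "C"]) - sd(o[, "C"])), 0.4)
})

test_that("rate-set assembly pairs draws, converts units, conserves nodes", {
  fx <- noiseless_fixture()
  ds <- fx$gen$dataset
  rs <- assemble_rate_sets(ds, 7, seed = 5)
  expect_s3_class(rs, "rate_sample_sets")
  expect_length(rs$sets, 7L)
  dated_ids <- ds$nodes$node_id[ds$nodes$dated]
  for (p in rs$sets) {
    expect_setequal(p$node_id, dated_ids)
    # rbar * t * 1e6 = s exactly
    expect_identical(p$rbar * (p$t_myr * 1e6), p$s)
  }
  # co-sampled undated draws follow replicate indexing
  expect_equal(dim(rs$undated_s), c(7L, 2L))
  expect_setequal(colnames(rs$undated_s), c("I", "II"))

  # zero-variance s and t: all sets identical
  p1 <- rs$sets[[1]]; p2 <- rs$sets[[5]]
  expect_equal(p1$t_myr, p2$t_myr)
  expect_equal(p1$s, p2$s)

  expect_error(assemble_rate_sets(ds, 0), "positive count")
})

test_that("assembly is bitwise reproducible under a seed", {
  sc <- synthetic_scenario(seed = 12)
  ds <- generate_dataset(sc)$dataset
  a <- assemble_rate_sets(ds, 4, seed = 99)
  b <- assemble_rate_sets(ds, 4, seed = 99)
  expect_identical(a$sets, b$sets)
  expect_identical(a$undated_s, b$undated_s)
})
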