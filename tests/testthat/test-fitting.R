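test_that("adjusted R-squared formula and preconditions", {
  expect_equal(adjusted_r_squared(1.0, 11, 2), 1.0)
  expect_equal(adjusted_r_squared(0.9, 11, 2), 0.875)
  expect_error(adjusted_r_squared(0.9, 4, 3), "n_points > n_params")
})

test_that("noiseless power-law data are recovered exactly under both criteria", {
  fx <- noiseless_fixture()
  truth <- fx$truth$model
  for (fitter in list(fit_average_rate_model, fit_time_model)) {
    f <- fitter(fx$points, "PL")
    expect_equal(f$params$alpha, truth$alpha, tolerance = 1e-4)
    expect_equal(f$params$beta, truth$beta, tolerance = 1e-4)
    expect_equal(f$adj_r2, 1, tolerance = 1e-10)
    expect_true(f$converged)
  }
  ft <- fit_time_model(fx$points, "PL")
  expect_lte(ft$sse, 1e-12 * sum(fx$points$t_myr^2))
})

test_that("nested vertically-translated fit collapses onto the simple truth", {
  fx <- noiseless_fixture()
  f <- fit_average_rate_model(fx$points, "VPL")
  min_rbar_myr <- min(fx$points$s / fx$points$t_myr)
  expect_lte(f$params$k, 1e-3 * min_rbar_myr)
  expect_equal(f$params$beta, fx$truth$model$beta, tolerance = 1e-3)
})

test_that("insufficient points are rejected; 3-point fits need the override", {
  pts <- data.frame(node_id = c("a", "b", "c"),
                    t_myr = c(1, 10, 50), s = c(0.1, 0.3, 0.5))
  expect_error(fit_average_rate_model(pts, "VEX"), "at least")
  expect_error(fit_time_model(pts, "VPL"), "at least")
  # 2-parameter kind on 3 points is allowed, with adj R2 suppressed
  f <- fit_time_model(pts, "PL")
  expect_true(is.na(f$adj_r2))
})

test_that("EX saturation is penalised, not fatal", {
  # deep s values exceed what a tight exponential can accumulate
  pts <- data.frame(node_id = letters[1:8],
                    t_myr = c(1, 2, 5, 10, 20, 40, 70, 100),
                    s = c(0.05, 0.09, 0.17, 0.25, 0.35, 0.45, 0.55, 0.95))
  f <- fit_time_model(pts, "EX")
  expect_true(is.finite(f$sse))
  expect_gt(f$params$alpha / f$params$beta, 0)
})

test_that("analytic jacobians agree with central differences", {
  fx <- noiseless_fixture()
  t <- fx$points$t_myr; s <- fx$points$s; y <- s / t
  for (kind in ALL_KINDS) {
    th <- tdrp:::fit_starts(kind, t, s, "LSE_t", 1)[[1]]
    for (crit in c("rbar", "time")) {
      fn <- if (crit == "rbar") function(x) tdrp:::resid_rbar(x, kind, t, y)
            else function(x) tdrp:::resid_time(x, kind, t, s)
      ja <- if (crit == "rbar") tdrp:::jac_rbar(th, kind, t, y)
            else tdrp:::jac_time(th, kind, t, s)
      jn <- sapply(seq_along(th), function(j) {
        h <- 1e-6 * max(abs(th[j]), 1)
        e1 <- th; e1[j] <- e1[j] + h
        e2 <- th; e2[j] <- e2[j] - h
        (fn(e1) - fn(e2)) / (2 * h)
      })
      expect_equal(ja, jn, tolerance = 1e-5, ignore_attr = TRUE)
    }
  }
})

test_that("extra parameters never worsen the optimum (nesting)", {
  set.seed(33)
  sc <- synthetic_scenario(seed = 17)
  ds <- generate_dataset(sc)$dataset
  pts <- assemble_rate_sets(ds, 1, seed = 18)$sets[[1]]
  for (crit in c("LSE_rbar", "LSE_t")) {
    sv <- tdrp:::fit_decay_model(pts, "VEX", crit)$sse
    se <- tdrp:::fit_decay_model(pts, "EX", crit)$sse
    expect_lte(sv, se + 1e-9 + 1e-6 * se)
    svp <- tdrp:::fit_decay_model(pts, "VPL", crit)$sse
    sp <- tdrp:::fit_decay_model(pts, "PL", crit)$sse
    expect_lte(svp, sp + 1e-9 + 1e-6 * sp)
  }
})

test_that("fitting is unit-equivariant between Myr and years", {
  fx <- noiseless_fixture()
  f_myr <- fit_average_rate_model(fx$points, "PL")
  # refit with t expressed in years and rates per year
  pts_y <- data.frame(node_id = fx$points$node_id,
                      t_myr = fx$points$t_myr,  # container stays Myr-named
                      s = fx$points$s)
  m_y <- convert_time_unit(f_myr$params, "year")
  # converted parameters must reproduce the year-scale curve exactly
  expect_equal(average_rate(m_y, fx$points$t_myr * 1e6),
               average_rate(f_myr$params, fx$points$t_myr) / 1e6,
               tolerance = 1e-6)
})

test_that("ensemble fitting summarises parameters across replicate sets", {
  fx <- noiseless_fixture()
  sets <- rep(list(fx$points), 5)
  ens <- fit_ensemble(sets, "PL", "LSE_rbar", n_starts = 3)
  expect_equal(nrow(ens$per_set), 5L)
  # identical sets: identical fits, zero-width intervals
  bsum <- ens$summary[ens$summary$quantity == "beta", ]
  expect_equal(bsum$lower95, bsum$upper95)
  expect_equal(bsum$median, 0.6, tolerance = 1e-4)
  expect_equal(ens$n_failed, 0L)
})

test_that("returned optimum is never above the multi-start initial objectives", {
  sc <- synthetic_scenario(seed = 23)
  ds <- generate_dataset(sc)$dataset
  pts <- assemble_rate_sets(ds, 1, seed = 24)$sets[[1]]
  for (kind in c("EX", "PL")) {
    f <- tdrp:::fit_decay_model(pts, kind, "LSE_t", n_starts = 5)
    starts <- tdrp:::fit_starts(kind, pts$t_myr, pts$s, "LSE_t", 5)
    sse0 <- vapply(starts, function(th)
      sum(tdrp:::resid_time(th, kind, pts$t_myr, pts$s)^2), numeric(1))
    expect_lte(f$sse, min(sse0) + 1e-9)
  }
})
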