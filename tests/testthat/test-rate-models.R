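test_that("closed forms reproduce hand-computed values", {
  expect_equal(instantaneous_rate(rate_model("PL", 2, 0.5), 4), 1.0)
  expect_equal(instantaneous_rate(rate_model("VEX", 1, 0.1, k = 0.5), 0), 1.5)
  expect_lt(instantaneous_rate(rate_model("EX", 3, 0.2), 1e6), 1e-12)

  expect_equal(cumulative_substitutions(rate_model("EX", 1, 1), 1),
               1 - exp(-1))
  expect_equal(cumulative_substitutions(rate_model("PL", 0.4, 0.5), 6.25), 2.0)
  for (kind in ALL_KINDS) {
    m <- rate_model(kind, 0.3, 0.4, k = if (kind %in% c("VEX", "VPL")) 0.01 else 0)
    expect_identical(cumulative_substitutions(m, 0), 0)
  }

  expect_equal(average_rate(rate_model("PL", 1.5e-4, 0.6, time_unit = "year"), 10),
               1.5e-4 * 10^(-0.6) / 0.4)
  expect_equal(round(average_rate(rate_model("PL", 1.5e-4, 0.6,
                                             time_unit = "year"), 10), 9),
               9.4196e-5, tolerance = 1e-4)
})

test_that("parameter validation rejects invalid models and domains", {
  expect_error(rate_model("PL", alpha = -1, beta = 0.5), "alpha")
  expect_error(rate_model("PL", alpha = 1, beta = 1.2), "beta < 1")
  expect_error(rate_model("VPL", alpha = 1, beta = 1), "beta < 1")
  expect_error(rate_model("VEX", alpha = 1, beta = Inf), "finite")
  expect_error(rate_model("VEX", alpha = 1, beta = 0.1, k = -0.1), "k")
  # EX/PL carry no k
  expect_identical(rate_model("EX", 1, 1, k = 5)$k, 0)

  m <- rate_model("PL", 1, 0.5)
  expect_error(instantaneous_rate(m, 0), "singular")
  expect_error(average_rate(m, 0), "> 0")
  expect_error(invert_time(m, -1), ">= 0")
  mex <- rate_model("EX", 1, 1)
  expect_error(invert_time(mex, 1.0), "unreachable|saturates")
})

test_that("cumulative substitutions match adaptive quadrature of the rate", {
  set.seed(42)
  for (kind in ALL_KINDS) {
    for (i in 1:25) {
      m <- random_model(kind)
      t1 <- 10^runif(1, -1, 2)
      q <- integrate(function(x) instantaneous_rate(m, x), 0, t1,
                     rel.tol = 1e-10, abs.tol = 0)$value
      expect_equal(cumulative_substitutions(m, t1), q, tolerance = 1e-8)
    }
  }
})

test_that("derivative of cumulative curve is the instantaneous rate", {
  set.seed(7)
  grid <- c(0.5, 1, 5, 20, 80)
  h <- 1e-5
  for (kind in ALL_KINDS) {
    m <- random_model(kind)
    num <- (cumulative_substitutions(m, grid + h) -
              cumulative_substitutions(m, grid - h)) / (2 * h)
    expect_equal(num, instantaneous_rate(m, grid), tolerance = 1e-6)
  }
})

test_that("monotonicity and rate ordering hold on positive grids", {
  set.seed(11)
  grid <- sort(10^runif(40, -2, 2))
  for (kind in ALL_KINDS) {
    m <- random_model(kind)
    r <- instantaneous_rate(m, grid)
    s <- cumulative_substitutions(m, grid)
    rb <- average_rate(m, grid)
    expect_true(all(diff(r) < 0))
    expect_true(all(diff(s) > 0))
    expect_true(all(diff(rb) < 0))
    # current rate never exceeds the mean of the past
    expect_true(all(r <= rb + 1e-15))
    expect_true(all(r >= m$k))
  }
})

test_that("inversion round-trips across kinds, with closed-form anchors", {
  expect_equal(invert_time(rate_model("PL", 0.4, 0.5), 2), 6.25)
  expect_equal(invert_time(rate_model("EX", 1, 1), 1 - exp(-1)), 1,
               tolerance = 1e-9)
  set.seed(99)
  for (kind in ALL_KINDS) {
    m <- random_model(kind)
    expect_identical(invert_time(m, 0), 0)
    tt <- 10^runif(100, -2, 2)
    s <- cumulative_substitutions(m, tt)
    t2 <- invert_time(m, s)
    expect_true(all(abs(t2 - tt) <= 1e-8 * pmax(tt, 1)))
  }
})

test_that("numeric inversion agrees with an independent bisection oracle", {
  bisect <- function(m, s, lo = 0, hi = 1) {
    while (cumulative_substitutions(m, hi) < s) hi <- hi * 2
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (cumulative_substitutions(m, mid) < s) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  set.seed(5)
  for (kind in c("VEX", "VPL")) {
    m <- random_model(kind)
    for (tt in 10^runif(10, -1, 2)) {
      s <- cumulative_substitutions(m, tt)
      expect_equal(invert_time(m, s), bisect(m, s),
                   tolerance = 1e-8)
    }
  }
})

test_that("power-law average rate is log-affine with slope -beta; VPL tends to k", {
  m <- rate_model("PL", 3e-2, 0.55)
  tt <- 10^seq(-1, 2, length.out = 20)
  lr <- log10(average_rate(m, tt))
  slopes <- diff(lr) / diff(log10(tt))
  expect_equal(slopes, rep(-0.55, 19), tolerance = 1e-12)

  mv <- rate_model("VPL", 3e-2, 0.55, k = 1e-3)
  expect_equal(average_rate(mv, 1e9), 1e-3, tolerance = 1e-3)
  mvex <- rate_model("VEX", 1, 0.5, k = 2e-3)
  expect_equal(average_rate(mvex, 1e8), 2e-3, tolerance = 1e-3)
})

test_that("unit conversion is exact and invertible", {
  for (kind in ALL_KINDS) {
    set.seed(3)
    m <- random_model(kind)  # Myr units
    my <- convert_time_unit(m, "year")
    t_myr <- c(0.5, 3, 50)
    expect_equal(average_rate(my, t_myr * 1e6),
                 average_rate(m, t_myr) / 1e6, tolerance = 1e-12)
    back <- convert_time_unit(my, "Myr")
    expect_equal(back$alpha, m$alpha, tolerance = 1e-12)
    expect_equal(back$beta, m$beta, tolerance = 1e-12)
    expect_equal(back$k, m$k, tolerance = 1e-12)
  }
})

test_that("JSON serialisation round-trips value-exactly", {
  m <- rate_model("VPL", alpha = 1 / 3, beta = 2 / 7, k = 1e-9,
                  time_unit = "year")
  m2 <- model_from_json(model_to_json(m))
  expect_identical(m2$kind, "VPL")
  expect_identical(m2$alpha, m$alpha)
  expect_identical(m2$beta, m$beta)
  expect_identical(m2$k, m$k)
  expect_identical(m2$time_unit, "year")
  p <- tempfile(fileext = ".json")
  model_to_json(m, path = p)
  expect_identical(model_from_json(p)$alpha, m$alpha)
  unlink(p)
})
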