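# LC quadratures: trapezoid weights, extrapolation to zero, classical
# rules, and estimation.

test_that("trapezoid weights follow the closed formula and telescope", {
  expect_equal(trapezoid_weights(c(0, 6, 12, 24)), c(3, 6, 9, 6))
  expect_equal(trapezoid_weights(c(0, 24)), c(12, 12))
  for (i in 1:20) {
    knots <- sort(stats::runif(sample(2:9, 1), 0, 24))
    if (any(diff(knots) == 0)) next
    w <- trapezoid_weights(knots)
    expect_equal(sum(w), max(knots) - min(knots), tolerance = 1e-12)
  }
  expect_error(trapezoid_weights(5), "two knots")
  expect_error(trapezoid_weights(c(3, 2)), "increasing")
})

test_that("trapezoid rule is exact for piecewise-linear integrands", {
  knots <- c(0, 3, 7, 15, 24)
  vals <- c(10, 4, 6, 1, 0.5)
  exact <- sum(diff(knots) * (utils::head(vals, -1) + vals[-1]) / 2)
  q <- trapezoid_quadrature(knots)
  expect_equal(estimate(q, vals), exact, tolerance = 1e-12)
})

test_that("extrapolation to zero stays within the LC class", {
  # hand-derived: knots (1, 2) get combined weights (2, 0)
  w <- trapezoid_weights(c(1, 2)) + extrapolate_to_zero_adjustment(c(1, 2))
  expect_equal(w, c(2, 0))
  # applied to C(t) = t the estimate is the full integral over [0, 2]
  expect_equal(sum(w * c(1, 2)), 2)
  # formula value at knots (2, 4, ..., 24)
  d <- extrapolate_to_zero_adjustment(seq(2, 24, by = 2))
  expect_equal(d[1:2], c(3, -1))
  expect_true(all(d[-(1:2)] == 0))
  # no-op when the first knot is at zero
  expect_equal(extrapolate_to_zero_adjustment(c(0, 5, 10)), c(0, 0, 0))
  # oracle: explicitly extrapolate then integrate, for random linear and
  # exponential concentration curves
  set.seed(42)
  for (i in 1:100) {
    knots <- sort(stats::runif(4, 0.5, 24))
    if (any(diff(knots) < 1e-3)) next
    f <- if (i %% 2) {
      a <- stats::runif(1, 1, 10); b <- stats::runif(1, -0.3, 0.3)
      function(t) a + b * t
    } else {
      a <- stats::runif(1, 5, 20); k <- stats::runif(1, 0.05, 0.3)
      function(t) a * exp(-k * t)
    }
    vals <- f(knots)
    # extrapolate-then-trapezoid oracle
    slope <- (vals[2] - vals[1]) / (knots[2] - knots[1])
    c0 <- vals[1] - slope * knots[1]
    full <- sum(trapezoid_weights(c(0, knots)) * c(c0, vals))
    w <- trapezoid_weights(knots) + extrapolate_to_zero_adjustment(knots)
    expect_equal(sum(w * vals), full, tolerance = 1e-10)
  }
})

test_that("Gauss-Legendre nodes, weights and exactness degree 2n-1", {
  g1 <- gauss_legendre(1)
  expect_equal(g1$knots, 12)
  expect_equal(g1$weights, 24)
  g2 <- gauss_legendre(2)
  expect_equal(g2$knots, c(12 - 12 / sqrt(3), 12 + 12 / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(g2$weights, c(12, 12), tolerance = 1e-12)
  for (n in 1:8) {
    g <- gauss_legendre(n)
    expect_equal(sum(g$weights), 24, tolerance = 1e-10)
    for (k in 0:(2 * n - 1)) {
      exact <- 24^(k + 1) / (k + 1)
      expect_equal(sum(g$weights * g$knots^k) / exact, 1,
                   tolerance = 1e-12,
                   label = sprintf("GL-%d monomial t^%d", n, k))
    }
  }
})

test_that("Clenshaw-Curtis nodes, weights and exactness degree n-1", {
  cc3 <- clenshaw_curtis(3)
  expect_equal(cc3$knots, c(0, 12, 24), tolerance = 1e-12)
  expect_equal(cc3$weights, c(4, 16, 4), tolerance = 1e-12)
  for (n in 2:8) {
    cc <- clenshaw_curtis(n)
    expect_equal(sum(cc$weights), 24, tolerance = 1e-10)
    expect_equal(cc$knots[1], 0)
    expect_equal(cc$knots[n], 24)
    for (k in 0:(n - 1)) {
      exact <- 24^(k + 1) / (k + 1)
      expect_equal(sum(cc$weights * cc$knots^k) / exact, 1,
                   tolerance = 1e-10,
                   label = sprintf("CC-%d monomial t^%d", n, k))
    }
  }
  expect_error(clenshaw_curtis(1), "n >= 2")
})

test_that("estimate is the weight-concentration dot product", {
  q <- quadrature(c(0, 6, 12, 24), c(3, 6, 9, 6), kind = "trapezoid")
  expect_equal(estimate(q, c(10, 5, 2, 1)), 84)
  expect_equal(estimate(q, rep(0, 4)), 0)
  expect_equal(estimate(q, rbind(c(10, 5, 2, 1), c(0, 0, 0, 0))), c(84, 0))
  expect_error(estimate(q, 1:3), "per knot")
})

test_that("quadrature construction enforces its invariants", {
  expect_error(quadrature(c(1, 1, 2), rep(1, 3)), "increasing")
  expect_error(quadrature(c(1, 2), 1), "one entry per knot")
  expect_error(quadrature(c(1, 25), c(1, 1)), "inside the interval")
  expect_error(quadrature(c(0, 12), c(6, 6), kind = "trapezoid"),
               "last knot")
})

test_that("design files round-trip at full precision", {
  q <- quadrature(c(0.810477123456789, 4.06657, 9.13651, 23.1896),
                  c(1.67152712345678901, 5.33966, 1.27416, 18.4662),
                  kind = "optimal_lc")
  path <- tempfile(fileext = ".json")
  write_design(q, path, model_id = 1L, cv = 0)
  rec <- read_design(path)
  expect_identical(rec$quadrature$knots, q$knots)
  expect_identical(rec$quadrature$weights, q$weights)
  expect_identical(rec$quadrature$kind, "optimal_lc")
  expect_equal(rec$model, 1L)
})
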