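# Inner maximization, envelope gradients, and the outer design searches.

test_that("max_risk on a point box returns the risk at that point", {
  m1 <- pk_model(1)
  th <- interior_theta(1)
  pt <- parameter_box(th, th)
  q <- gauss_legendre(4)
  mr <- max_risk(q, m1, pt, cv = 0.05,
                 optimizer_settings(inner_starts = 1, grid_points = 0))
  expect_equal(mr$objective, relative_risk(q, m1, th, 0.05)$value,
               tolerance = 1e-12)
  expect_equal(unname(mr$theta_star), unname(th), tolerance = 1e-9)
})

test_that("inner maximization agrees with a dense grid oracle", {
  m1 <- pk_model(1)
  box <- default_box(m1)
  q <- gauss_legendre(6)
  mr <- max_risk(q, m1, box, cv = 0)
  # brute-force oracle on the reparameterized feasible region
  sp <- aucdesign:::.param_space(box)
  axes <- lapply(1:2, function(j)
    seq(sp$lower[[j]], sp$upper[[j]], length.out = 200))
  Theta <- sp$to_theta_mat(as.matrix(expand.grid(axes)))
  grid_max <- max(aucdesign:::.risk_profile(q, m1, Theta, 0))
  expect_gte(mr$objective, grid_max - 1e-8)
  expect_equal(mr$objective, grid_max, tolerance = 1e-6)
  # objective consistency invariant
  expect_equal(mr$objective,
               relative_risk(q, m1, mr$theta_star, cv = 0)$value,
               tolerance = 1e-10)
  expect_true(box_contains(box, mr$theta_star, tol = 1e-9))
})

test_that("worst-case risk is monotone in the noise level", {
  m1 <- pk_model(1)
  box <- default_box(m1)
  q <- gauss_legendre(6)
  s <- optimizer_settings(inner_starts = 4)
  objs <- vapply(c(0, 0.05, 0.10), function(cv)
    max_risk(q, m1, box, cv, s)$objective, numeric(1))
  expect_true(all(diff(objs) > 0))
})

test_that("envelope gradient matches finite differences in the design", {
  m1 <- pk_model(1)
  th <- interior_theta(1)
  q <- quadrature(c(1, 5, 11, 19), c(3, 5.5, 7, 8))
  cv <- 0.06
  og <- outer_gradient(q, m1, th, cv)
  # closed-form weight partial
  C <- concentration(m1, th, q$knots)
  A <- auc(m1, th)
  b <- A - sum(q$weights * C)
  expect_equal(og$weights,
               (2 * cv^2 * q$weights * C^2 - 2 * b * C) / A^2,
               tolerance = 1e-12)
  # FD over the full design vector (theta held fixed)
  fd_w <- fd_gradient(function(w)
    relative_risk(quadrature(q$knots, w), m1, th, cv)$value, q$weights)
  expect_lt(rel_err(og$weights, fd_w), 1e-6)
  fd_t <- fd_gradient(function(kt)
    relative_risk(quadrature(kt, q$weights), m1, th, cv)$value, q$knots)
  expect_lt(rel_err(og$knots, fd_t), 1e-5)
})

test_that("optimal trapezoid satisfies its constraints and dominates the
           equispaced schedule", {
  m2 <- pk_model(2)
  box <- default_box(2)
  s <- cheap_settings()
  tr <- optimize_trapezoid(m2, box, cv = 0.05, n = 4, settings = s)
  kn <- tr$quadrature$knots
  expect_true(all(diff(kn) > 0))
  expect_equal(kn[4], 24, tolerance = 1e-9)
  eq <- trapezoid_quadrature(c(6, 12, 18, 24), extrapolate = TRUE)
  eq_obj <- max_risk(eq, m2, box, 0.05, s)$objective
  expect_lte(tr$objective, eq_obj + 1e-12)
  # invariant: stored objective reproduces under re-maximization
  re <- max_risk(tr$quadrature, m2, box, 0.05, s,
                 extra_starts = list(tr$theta_star))
  expect_equal(re$objective, tr$objective, tolerance = 1e-9)
})

test_that("optimal LC dominates trapezoid and classical baselines", {
  m1 <- pk_model(1)
  box <- default_box(m1)
  s <- cheap_settings()
  cv <- 0.05; n <- 4
  tr <- optimize_trapezoid(m1, box, cv, n, settings = s)
  lc <- optimize_lc(m1, box, cv, n, settings = s, trapezoid = tr)
  gl_obj <- max_risk(gauss_legendre(n), m1, box, cv, s)$objective
  cc_obj <- max_risk(clenshaw_curtis(n), m1, box, cv, s)$objective
  expect_lte(lc$objective, min(tr$objective, gl_obj, cc_obj) + 1e-12)
  expect_identical(lc$quadrature$kind, "optimal_lc")
  expect_true(all(diff(lc$quadrature$knots) > 0))
})

test_that("optimal LC objective is non-increasing in the sample size", {
  m1 <- pk_model(1)
  box <- default_box(m1)
  s <- cheap_settings(exchange_rounds = 1, nm_iterations = 200)
  objs <- vapply(c(2, 4, 6), function(n)
    optimize_lc(m1, box, cv = 0.10, n = n, settings = s)$objective,
    numeric(1))
  expect_true(all(diff(objs) < 1e-10))
})

test_that("identical settings give bit-identical results", {
  m1 <- pk_model(1)
  box <- default_box(m1)
  s <- cheap_settings(exchange_rounds = 1, nm_iterations = 100)
  a <- optimize_lc(m1, box, cv = 0.05, n = 3, settings = s)
  b <- optimize_lc(m1, box, cv = 0.05, n = 3, settings = s)
  expect_identical(a$quadrature, b$quadrature)
  expect_identical(a$objective, b$objective)
  expect_identical(a$theta_star, b$theta_star)
})
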