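# Concentration-time models: values, AUC identities, sensitivities,
# AUC ranges.

test_that("model construction validates inputs", {
  expect_error(pk_model(0), "between 1 and 5")
  expect_error(pk_model(6), "between 1 and 5")
  expect_error(pk_model(1, constants = list(Zz = 3)), "Unknown constant")
  m <- pk_model(1)
  expect_error(concentration(m, c(ka = -1, ke = 0.1), 1), "positive")
  expect_error(concentration(m, c(ka = 1, ke = 0.1), 30), "interval")
  expect_error(concentration(m, c(foo = 1, bar = 0.1), 1), "names")
  # unnamed vectors are taken in declared parameter order
  expect_identical(concentration(m, c(1, 0.1), 3),
                   concentration(m, c(ka = 1, ke = 0.1), 3))
})

test_that("concentrations match reference values and oracles", {
  expect_equal(concentration(pk_model(1), c(ka = 0.9, ke = 0.2), 0), 0)
  expect_equal(concentration(pk_model(3),
                             c(k1 = 1, k2 = 0.1, alpha = 1.25), 0), 22.5)
  # model 4 against an independent bisection solve of the implicit relation
  th <- c(KM = 20, Vm = 0.2)
  expect_equal(concentration(pk_model(4), th, 24),
               mm_bisect(20, 0.2, 10, 24), tolerance = 1e-9)
  expect_equal(concentration(pk_model(4), th, 24), 8.4852,
               tolerance = 1e-4)
  # model 5 starts at zero and stays non-negative
  C5 <- concentration(pk_model(5), interior_theta(5), seq(0, 24, by = 2))
  expect_equal(C5[1], 0, tolerance = 1e-10)
  expect_true(all(C5 >= -1e-10))
})

test_that("closed-form AUC agrees with numerical integration", {
  for (id in 1:3) {
    m <- pk_model(id)
    th <- interior_theta(id)
    num <- stats::integrate(function(t) concentration(m, th, t), 0, 24,
                            rel.tol = 1e-12)$value
    expect_equal(auc(m, th), num, tolerance = 1e-10,
                 label = paste("model", id, "AUC"))
  }
  # steady-state telescoping: AUC over one dosing interval = A(1/ke - 1/ka)
  th <- c(ka = 3 * log(2), ke = log(2) / 12)
  expect_equal(auc(pk_model(2), th), 20 * (1 / th[["ke"]] - 1 / th[["ka"]]),
               tolerance = 1e-12)
  expect_equal(auc(pk_model(2), th), 336.6288, tolerance = 1e-6)
  expect_equal(auc(pk_model(1), th), 250.0671, tolerance = 1e-6)
})

test_that("model 4 integral identity agrees with direct ODE integration", {
  m4 <- pk_model(4)
  # independent oracle: integrate dC/dt = -Vm C/(KM + C) with an integral
  # state and compare to the closed-form identity used by auc()
  ode_auc <- function(KM, Vm) {
    rhs <- function(t, y, p) list(c(-p$Vm * y[1] / (p$KM + y[1]), y[1]))
    sol <- deSolve::lsoda(c(10, 0), c(0, 24), rhs,
                          list(KM = KM, Vm = Vm),
                          rtol = 1e-11, atol = 1e-12)
    unname(sol[2, 3])
  }
  for (KM in seq(2, 20, length.out = 10))
    for (Vm in seq(0.2, 1, length.out = 10))
      expect_equal(auc(m4, c(KM = KM, Vm = Vm)), ode_auc(KM, Vm),
                   tolerance = 1e-6)
})

test_that("model 4 approaches linear bolus kinetics for large KM", {
  k <- log(2) / 12
  KM <- 1e4  # 10^3 * C0
  lin <- 10 * (1 - exp(-24 * k)) / k
  expect_equal(auc(pk_model(4), c(KM = KM, Vm = k * KM)), lin,
               tolerance = 0.01)
})

test_that("analytic gradients match central finite differences", {
  knots <- c(1, 5, 12, 20)
  for (id in 1:5) {
    m <- pk_model(id)
    th <- interior_theta(id)
    rel <- if (id == 5) 1e-4 else 1e-6  # FD step; ODE noise needs larger h
    s <- sensitivities(m, th, knots, hessians = FALSE)
    g_auc <- fd_gradient(function(x) auc(m, x), th, rel = rel)
    expect_lt(rel_err(s$auc_gradient, g_auc, floor = 1e-6), 1e-5)
    g_C <- fd_gradient(function(x) concentration(m, x, knots), th,
                       rel = rel)
    expect_lt(rel_err(s$conc_gradient, g_C,
                      floor = 1e-4 * max(abs(s$concentration))), 1e-4)
  }
})

test_that("Hessians match finite differences of the gradients", {
  knots <- c(2, 8, 16)
  for (id in c(1, 2, 3, 4)) {
    m <- pk_model(id)
    th <- interior_theta(id)
    s <- sensitivities(m, th, knots, hessians = TRUE)
    H_fd <- sapply(seq_along(th), function(j) {
      h <- 1e-5 * th[j]
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      (sensitivities(m, tp, knots, hessians = FALSE)$auc_gradient -
         sensitivities(m, tm, knots, hessians = FALSE)$auc_gradient) /
        (2 * h)
    })
    expect_lt(rel_err(s$auc_hessian, H_fd,
                      floor = 1e-6 * max(abs(H_fd))), 1e-4)
  }
})

test_that("auc_range handles degenerate boxes and matches Table anchors", {
  m1 <- pk_model(1)
  th <- c(ka = 1.2, ke = 0.12)
  pt <- parameter_box(th, th)
  r <- auc_range(m1, pt, grid_points = 2)
  expect_equal(r$min, auc(m1, th), tolerance = 1e-10)
  expect_equal(r$max, auc(m1, th), tolerance = 1e-10)
  # printed ranges [58, 337] and [70, 221]
  r2 <- auc_range(pk_model(2))
  expect_equal(r2$min, 57.708, tolerance = 1e-4)
  expect_equal(r2$max, 336.629, tolerance = 1e-4)
  r4 <- auc_range(pk_model(4))
  expect_equal(r4$min, 69.98, tolerance = 1e-3)
  expect_equal(r4$max, 221.48, tolerance = 1e-3)
})

test_that("parameter boxes validate and parse constraints", {
  expect_error(parameter_box(c(a = 1), c(a = 0)), "lower <= upper")
  b <- parameter_box(c(ka = 0.2, ke = 0.06), c(ka = 2, ke = 0.17),
                     constraints = list("ka >= 2*ke"))
  expect_true(box_contains(b, c(ka = 0.5, ke = 0.1)))
  expect_false(box_contains(b, c(ka = 0.2, ke = 0.17)))
  expect_error(parameter_box(c(ka = 0.1, ke = 1), c(ka = 0.2, ke = 2),
                             constraints = list("ka >= 2*ke")),
               "not satisfiable")
})
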