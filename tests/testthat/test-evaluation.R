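# Monte-Carlo profile simulation, performance statistics, consistency
# inequalities.

test_that("simulation is noiseless at cv = 0 and reproducible by seed", {
  m1 <- pk_model(1)
  box <- default_box(m1)
  times <- c(2, 8, 16, 24)
  s1 <- simulate_profiles(m1, box, times, 200, cv = 0, seed = 11)
  expect_identical(s1$observed, s1$conc)
  s2 <- simulate_profiles(m1, box, times, 200, cv = 0.1, seed = 11)
  s3 <- simulate_profiles(m1, box, times, 200, cv = 0.1, seed = 11)
  expect_identical(s2$observed, s3$observed)
  s4 <- simulate_profiles(m1, box, times, 200, cv = 0.1, seed = 12)
  expect_false(identical(s2$observed, s4$observed))
  # constraint respected in every draw
  expect_true(all(s1$theta[, "ka"] >= 2 * s1$theta[, "ke"]))
})

test_that("empirical noise CV matches the nominal cv", {
  m1 <- pk_model(1)
  th <- interior_theta(1)
  pt <- parameter_box(th, th)
  times <- c(4, 12)
  sim <- simulate_profiles(m1, pt, times, 1e5, cv = 0.1, seed = 5)
  emp <- apply(sim$observed, 2, stats::sd) / concentration(m1, th, times)
  expect_equal(unname(emp), c(0.1, 0.1), tolerance = 0.01)
})

test_that("uniform draws cover the box uniformly", {
  m4 <- pk_model(4)
  box <- default_box(4)  # rectangular, no constraint
  sim <- simulate_profiles(m4, box, 24, 1e5, cv = 0, seed = 9)
  for (j in 1:2) {
    u <- (sim$theta[, j] - box$lower[j]) / (box$upper[j] - box$lower[j])
    d <- suppressWarnings(stats::ks.test(u, "punif")$statistic)
    expect_lt(unname(d), 0.01)
  }
})

test_that("an exact design on a point box yields all-zero statistics", {
  m1 <- pk_model(1)
  th <- interior_theta(1)
  pt <- parameter_box(th, th)
  w <- auc(m1, th) / concentration(m1, th, 6)
  q <- quadrature(6, w)
  st <- evaluate_method(q, m1, pt, cv = 0, n_profiles = 50, seed = 3)
  expect_equal(st$bias, 0, tolerance = 1e-12)
  expect_equal(st$rmsre, 0, tolerance = 1e-12)
  expect_equal(st$max_abs_deviance, 0, tolerance = 1e-10)
})

test_that("single-profile statistics equal that profile's errors", {
  m1 <- pk_model(1)
  box <- default_box(m1)
  q <- gauss_legendre(4)
  st <- evaluate_method(q, m1, box, cv = 0.1, n_profiles = 1, seed = 21,
                        return_profiles = TRUE)
  err <- st$profiles$estimate - st$profiles$true_auc
  expect_equal(st$bias, err)
  expect_equal(st$rmsre, abs(err / st$profiles$true_auc))
  expect_equal(st$max_abs_deviance, err)
})

test_that("RMSRE^2 converges to the box-average of the relative risk", {
  m4 <- pk_model(4)
  box <- default_box(4)
  q <- gauss_legendre(4)
  cv <- 0.05
  st <- evaluate_method(q, m4, box, cv, n_profiles = 2e4, seed = 17,
                        return_profiles = TRUE)
  rel2 <- ((st$profiles$estimate - st$profiles$true_auc) /
             st$profiles$true_auc)^2
  se <- stats::sd(rel2) / sqrt(length(rel2))
  # numerical box average of R_r on a fine grid
  g <- 150
  Theta <- as.matrix(expand.grid(
    KM = seq(box$lower[["KM"]], box$upper[["KM"]], length.out = g),
    Vm = seq(box$lower[["Vm"]], box$upper[["Vm"]], length.out = g)))
  avg <- mean(aucdesign:::.risk_profile(q, m4, Theta, cv))
  expect_lt(abs(st$rmsre^2 - avg), 3 * se)
})

test_that("extreme deviances can only grow when samples are pooled", {
  m1 <- pk_model(1)
  box <- default_box(m1)
  q <- gauss_legendre(4)
  a <- evaluate_method(q, m1, box, 0.1, n_profiles = 500, seed = 1,
                       return_profiles = TRUE)
  b <- evaluate_method(q, m1, box, 0.1, n_profiles = 500, seed = 2,
                       return_profiles = TRUE)
  rel <- function(s) (s$profiles$estimate - s$profiles$true_auc) /
    s$profiles$true_auc
  pooled <- max(abs(c(rel(a), rel(b))))
  expect_gte(pooled, max(abs(rel(a))))
  expect_gte(pooled, abs(a$max_rel_deviance))
})

test_that("consistency checks issue the expected verdicts", {
  # values on the scale of a successful noise-free optimization
  stats0 <- structure(list(rmsre = 1.12e-4, max_rel_deviance = 2.0e-4,
                           cv = 0, model_id = 1L),
                      class = "simulation_stats")
  res0 <- list(objective = (2.03e-4)^2, cv = 0, model_id = 1L)
  ck <- consistency_checks(stats0, res0)
  expect_true(all(ck$passed))
  # the RMSRE bound is strict: equality fails
  stats_eq <- structure(list(rmsre = 2.03e-4, max_rel_deviance = 1e-5,
                             cv = 0, model_id = 1L),
                        class = "simulation_stats")
  ck2 <- consistency_checks(stats_eq, res0)
  expect_false(ck2$passed[1])
  # with noise the deviance bound is not applicable
  stats1 <- structure(list(rmsre = 0.04, max_rel_deviance = 0.2,
                           cv = 0.05, model_id = 1L),
                      class = "simulation_stats")
  res1 <- list(objective = 0.05^2, cv = 0.05, model_id = 1L)
  ck3 <- consistency_checks(stats1, res1)
  expect_false(ck3$applicable[2])
  expect_true(is.na(ck3$passed[2]))
  # mismatched inputs are rejected
  expect_error(consistency_checks(stats1, res0), "noise levels")
})
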