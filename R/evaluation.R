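# Monte-Carlo evaluation of a quadrature against a model and parameter box:
# uniform parameter draws, constant-CV Gaussian measurement noise, and the
# summary statistics used to benchmark designs (bias, RMSRE, extreme
# deviances), together with the consistency inequalities linking them to
# the minimax objective.

#' Simulate noisy concentration profiles
#'
#' Draws parameter vectors uniformly from the feasible region of a box
#' (rejection sampling under any linear constraint), evaluates the model
#' concentrations at the requested times, and applies independent Gaussian
#' noise with a constant coefficient of variation:
#' \eqn{\hat C = C (1 + c_v \varepsilon)}, \eqn{\varepsilon \sim N(0,1)}.
#' Negative simulated concentrations are kept as drawn; truncation would
#' break the zero-mean noise assumption underlying the risk formulas.
#'
#' @param model a \code{\link{pk_model}}.
#' @param box a \code{\link{parameter_box}}.
#' @param times sampling times inside the model interval.
#' @param n_profiles number of simulated profiles.
#' @param cv noise coefficient of variation (>= 0).
#' @param seed integer seed; same seed, same stream.
#' @param rtol ODE relative tolerance (model 5).
#' @return list with \code{theta} (n_profiles x p matrix), \code{auc}
#'   (true AUC per profile), \code{conc} (noise-free concentrations,
#'   n_profiles x length(times)) and \code{observed} (noisy counterpart).
#' @export
simulate_profiles <- function(model, box, times, n_profiles, cv,
                              seed = NULL, rtol = 1e-8) {
  stopifnot(n_profiles >= 1, cv >= 0)
  if (any(times < model$interval[1]) || any(times > model$interval[2]))
    stop("Requested times fall outside the model interval.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- length(box$lower)
  draw <- function(m) {
    Th <- matrix(stats::runif(m * p), m, p)
    Th <- sweep(sweep(Th, 2, box$upper - box$lower, `*`), 2, box$lower, `+`)
    colnames(Th) <- names(box$lower)
    Th
  }
  Theta <- draw(n_profiles)
  if (length(box$constraints)) {
    keep <- rep(TRUE, nrow(Theta))
    for (cn in box$constraints)
      keep <- keep & (drop(Theta %*% cn$coef) >= cn$rhs)
    Theta <- Theta[keep, , drop = FALSE]
    guard <- 0L
    while (nrow(Theta) < n_profiles) {
      Th2 <- draw(2L * (n_profiles - nrow(Theta)) + 16L)
      keep <- rep(TRUE, nrow(Th2))
      for (cn in box$constraints)
        keep <- keep & (drop(Th2 %*% cn$coef) >= cn$rhs)
      Theta <- rbind(Theta, Th2[keep, , drop = FALSE])
      guard <- guard + 1L
      if (guard > 1000L)
        stop("Feasible region appears empty: rejection sampling failed.",
             call. = FALSE)
    }
    Theta <- Theta[seq_len(n_profiles), , drop = FALSE]
  }
  mb <- .model_batch(model, Theta, times, rtol = rtol)
  eps <- matrix(stats::rnorm(n_profiles * length(times)),
                n_profiles, length(times))
  C <- unname(mb$C)
  list(theta = Theta, auc = unname(mb$auc), conc = C,
       observed = C * (1 + cv * eps))
}

#' Monte-Carlo performance statistics of a quadrature
#'
#' Simulates noisy profiles over a parameter box, applies the LC estimate
#' \eqn{\hat Q = \sum_i w_i \hat C(t_i)} to each, and summarizes the
#' estimation errors \eqn{\hat Q - AUC}:
#' \itemize{
#'   \item \code{bias}: mean error (conc x h);
#'   \item \code{rmsre}: root mean squared relative error;
#'   \item \code{max_abs_deviance} / \code{max_rel_deviance}: the signed
#'     error (absolute / relative) of largest magnitude;
#'   \item \code{min_deviance}, \code{max_deviance} and relative
#'     counterparts: the most negative and most positive signed errors.
#' }
#'
#' @inheritParams simulate_profiles
#' @param quad a \code{\link{quadrature}} whose knots are the sampling
#'   times.
#' @param n_profiles number of profiles (20,000 reproduces the reference
#'   evaluation scale).
#' @param return_profiles logical; also return the per-profile
#'   \code{(true_auc, estimate)} pairs.
#' @return an object of class \code{"simulation_stats"}.
#' @export
evaluate_method <- function(quad, model, box, cv, n_profiles = 20000,
                            seed = NULL, return_profiles = FALSE,
                            rtol = 1e-8) {
  sim <- simulate_profiles(model, box, quad$knots, n_profiles, cv,
                           seed = seed, rtol = rtol)
  qhat <- drop(sim$observed %*% quad$weights)
  err <- qhat - sim$auc
  rel <- err / sim$auc
  pick_extreme <- function(x) x[which.max(abs(x))]
  out <- structure(list(
    bias = mean(err),
    rmsre = sqrt(mean(rel^2)),
    max_abs_deviance = pick_extreme(err),
    max_rel_deviance = pick_extreme(rel),
    min_deviance = min(err), max_deviance = max(err),
    min_rel_deviance = min(rel), max_rel_deviance_signed = max(rel),
    n_profiles = n_profiles, cv = cv, seed = seed,
    model_id = model$model_id, kind = quad$kind, n = quad$n),
    class = "simulation_stats")
  if (return_profiles)
    out$profiles <- data.frame(true_auc = sim$auc, estimate = qhat)
  out
}

#' @export
print.simulation_stats <- function(x, ...) {
  cat("Monte-Carlo evaluation (", x$n_profiles, " profiles, cv = ",
      x$cv, ")\n", sep = "")
  cat(sprintf("  bias: %.4g   RMSRE: %.4g\n", x$bias, x$rmsre))
  cat(sprintf("  extreme deviance: %.4g (absolute), %.4g (relative)\n",
              x$max_abs_deviance, x$max_rel_deviance))
  invisible(x)
}

#' Consistency checks between simulation statistics and the objective
#'
#' For any design, the root mean squared relative error over profiles
#' drawn from inside the box must stay strictly below the square root of
#' the worst-case risk (the objective).  Without random noise
#' (\eqn{c_v = 0}) the magnitude of every relative deviance -- in
#' particular the extreme one -- is likewise bounded by the square root of
#' the objective; failure of that bound indicates a failed inner
#' maximization.  With noise the deviance bound no longer applies (single
#' draws can exceed the root risk) and is reported as not applicable.
#'
#' @param stats a \code{\link{evaluate_method}} result.
#' @param result a \code{"minimax_result"} (or any list with
#'   \code{objective}, \code{cv}, \code{model_id}) for the same design,
#'   model and noise level.
#' @return a data frame with one row per inequality: \code{check},
#'   \code{applicable}, \code{passed}, \code{lhs}, \code{rhs}.
#' @export
consistency_checks <- function(stats, result) {
  if (!is.null(stats$model_id) && !is.null(result$model_id) &&
      !identical(stats$model_id, result$model_id))
    stop("`stats` and `result` refer to different models.", call. = FALSE)
  if (!is.null(stats$cv) && !is.null(result$cv) &&
      abs(stats$cv - result$cv) > 1e-12)
    stop("`stats` and `result` refer to different noise levels.",
         call. = FALSE)
  sobj <- sqrt(result$objective)
  cv0 <- isTRUE(abs(result$cv) < .Machine$double.eps)
  data.frame(
    check = c("rmsre < sqrt(objective)",
              "max |relative deviance| <= sqrt(objective) [cv = 0 only]"),
    applicable = c(TRUE, cv0),
    passed = c(stats$rmsre < sobj,
               if (cv0) abs(stats$max_rel_deviance) <= sobj else NA),
    lhs = c(stats$rmsre, abs(stats$max_rel_deviance)),
    rhs = c(sobj, sobj))
}
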