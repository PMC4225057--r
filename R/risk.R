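# Estimator risk under constant-CV noise.  With measurements
# Chat_i = C(t_i, theta) (1 + cv * eps_i), eps_i zero-mean unit-variance and
# independent, the LC estimate Qhat = sum(w_i Chat_i) has
#   E(Qhat) = sum(w_i C_i),   V(Qhat) = cv^2 sum(w_i^2 C_i^2),
# and the relative risk
#   R_r(theta) = {cv^2 sum(w_i^2 C_i^2) + [AUC - sum(w_i C_i)]^2} / AUC^2.
# Only the first two moments of the noise enter; its full distribution is
# irrelevant.

#' Expectation of the LC estimator
#'
#' \eqn{E(\hat Q) = \sum_i w_i C(t_i, \theta)} under zero-mean measurement
#' noise.
#'
#' @param quad a \code{\link{quadrature}}.
#' @param model a \code{\link{pk_model}}.
#' @param theta positive parameter vector.
#' @param rtol ODE relative tolerance (model 5).
#' @return expected estimate (conc x h).
#' @export
expected_estimate <- function(quad, model, theta, rtol = 1e-10) {
  sum(quad$weights * concentration(model, theta, quad$knots, rtol = rtol))
}

#' Variance of the LC estimator under constant-CV noise
#'
#' \eqn{V(\hat Q) = \sum_i w_i^2 \sigma_i^2} with
#' \eqn{\sigma_i = c_v C(t_i, \theta)}.
#'
#' @inheritParams expected_estimate
#' @param cv coefficient of variation of the measurement noise (>= 0).
#' @return variance (conc^2 x h^2).
#' @export
estimator_variance <- function(quad, model, theta, cv, rtol = 1e-10) {
  stopifnot(cv >= 0)
  C <- concentration(model, theta, quad$knots, rtol = rtol)
  cv^2 * sum(quad$weights^2 * C^2)
}

# Core: risk value and, on request, its theta-gradient and Hessian assembled
# from the model sensitivities by the chain rule.
.risk_eval <- function(quad, model, theta, cv, deriv = 0, relative = TRUE,
                       rtol = 1e-10) {
  stopifnot(cv >= 0)
  e <- .model_eval(model, theta, quad$knots, deriv = deriv, rtol = rtol,
                   atol = rtol * 1e-2)
  w <- quad$weights
  C <- e$C; A <- e$auc
  if (relative && A <= 0)
    stop("Relative risk requires AUC(theta) > 0.", call. = FALSE)
  S <- sum(w^2 * C^2)            # sum w_i^2 C_i^2
  b <- A - sum(w * C)            # bias of Qhat (AUC - E(Qhat))
  Vterm <- cv^2 * S
  Nval <- Vterm + b^2
  denom <- if (relative) A^2 else 1
  out <- list(value = Nval / denom,
              variance_term = Vterm / denom,
              bias_term = b^2 / denom,
              expected = sum(w * C), auc = A,
              cv = cv, relative = relative)
  if (deriv >= 1) {
    dC <- e$dC                                  # nt x p
    dA <- e$dauc                                # p
    dS <- drop(2 * crossprod(dC, w^2 * C))      # p
    db <- dA - drop(crossprod(dC, w))
    dN <- cv^2 * dS + 2 * b * db
    out$gradient <- if (relative) dN / A^2 - 2 * Nval * dA / A^3 else dN
  }
  if (deriv >= 2) {
    p <- length(theta)
    HC <- e$d2C; HA <- e$d2auc
    wHC <- function(coef) {  # sum_i coef_i * HC_i
      M <- matrix(0, p, p)
      for (i in seq_along(C)) M <- M + coef[i] * HC[, , i]
      M
    }
    dC <- e$dC; dA <- e$dauc
    dS <- drop(2 * crossprod(dC, w^2 * C))
    db <- dA - drop(crossprod(dC, w))
    d2S <- 2 * (crossprod(dC * w^2, dC) + wHC(w^2 * C) * 1)
    # crossprod(dC * w^2, dC) = sum_i w_i^2 dC_i dC_i^T
    d2b <- HA - wHC(w)
    dN <- cv^2 * dS + 2 * b * db
    d2N <- cv^2 * d2S + 2 * (tcrossprod(db) + b * d2b)
    if (relative) {
      out$hessian <- d2N / A^2 -
        (outer(dN, dA) + outer(dA, dN)) * 2 / A^3 -
        2 * Nval * HA / A^3 + 6 * Nval * tcrossprod(dA) / A^4
    } else out$hessian <- d2N
    dimnames(out$hessian) <- list(names(dA), names(dA))
  }
  structure(out, class = "risk_evaluation")
}

#' Relative risk of an LC quadrature at a parameter point
#'
#' Expected squared relative estimation error
#' \deqn{R_r(\theta) = \frac{c_v^2 \sum_i w_i^2 C_i^2 +
#'   [AUC(\theta) - \sum_i w_i C_i]^2}{AUC(\theta)^2},}
#' the quantity whose worst case over the parameter box the minimax design
#' minimizes.  The value decomposes into a variance term and a squared-bias
#' term, both reported.
#'
#' @inheritParams estimator_variance
#' @param deriv 0, 1 or 2: also return the gradient and Hessian in
#'   \eqn{\theta} (assembled from model sensitivities by the chain rule).
#' @return a list of class \code{"risk_evaluation"} with elements
#'   \code{value}, \code{variance_term}, \code{bias_term}, \code{expected},
#'   \code{auc}, and optionally \code{gradient} and \code{hessian}.
#' @export
relative_risk <- function(quad, model, theta, cv, deriv = 0, rtol = 1e-10) {
  .risk_eval(quad, model, theta, cv, deriv = deriv, relative = TRUE,
             rtol = rtol)
}

#' Absolute risk of an LC quadrature at a parameter point
#'
#' \eqn{E[(\hat Q - AUC)^2] = c_v^2 \sum_i w_i^2 C_i^2 +
#' [AUC - \sum_i w_i C_i]^2}; equal to the relative risk times
#' \eqn{AUC^2}.
#'
#' @inheritParams relative_risk
#' @return a \code{"risk_evaluation"} (units conc^2 x h^2).
#' @export
absolute_risk <- function(quad, model, theta, cv, deriv = 0, rtol = 1e-10) {
  .risk_eval(quad, model, theta, cv, deriv = deriv, relative = FALSE,
             rtol = rtol)
}

#' @export
print.risk_evaluation <- function(x, ...) {
  cat(if (x$relative) "Relative" else "Absolute", "risk:",
      format(x$value, digits = 6), "\n")
  cat("  variance term:", format(x$variance_term, digits = 6),
      " bias term:", format(x$bias_term, digits = 6), "\n")
  cat("  E(Qhat) =", format(x$expected, digits = 8),
      "  AUC =", format(x$auc, digits = 8), "\n")
  invisible(x)
}

# Vectorized relative risk over a matrix of parameter vectors (one row per
# theta).  Used by grid oracles and the inner-maximization grid stage.
.risk_profile <- function(quad, model, Theta, cv, rtol = 1e-8) {
  mb <- .model_batch(model, Theta, quad$knots, rtol = rtol)
  w <- quad$weights
  S <- drop((mb$C^2) %*% w^2)
  b <- mb$auc - drop(mb$C %*% w)
  (cv^2 * S + b^2) / mb$auc^2
}
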