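# Concentration-time models: closed forms, implicit Michaelis-Menten bolus,
# and ODE-integrated Michaelis-Menten with first-order input.

.MODELS <- list(
  list(name = "one-compartment, first-order absorption, single dose",
       parameters = c("ka", "ke"), constants = c(A = 20),
       c0_positive = FALSE),
  list(name = "one-compartment, first-order absorption, steady state",
       parameters = c("ka", "ke"), constants = c(A = 20, tau = 24),
       c0_positive = TRUE),
  list(name = "two-compartment, iv bolus",
       parameters = c("k1", "k2", "alpha"), constants = c(A1 = 10),
       c0_positive = TRUE),
  list(name = "one-compartment iv bolus, Michaelis-Menten elimination",
       parameters = c("KM", "Vm"), constants = c(C0 = 10),
       c0_positive = TRUE),
  list(name = "one-compartment, first-order absorption, Michaelis-Menten elimination",
       parameters = c("KM", "Vm", "ka"), constants = c(A = 5),
       c0_positive = FALSE)
)

#' Construct a pharmacokinetic concentration-time model
#'
#' Builds one of five hypothetical models commonly used when an area under
#' the concentration-time curve (AUC) has to be estimated from sparse
#' sampling:
#' \enumerate{
#'   \item one-compartment, first-order absorption, single oral dose:
#'     \eqn{C = A(e^{-k_e t} - e^{-k_a t})};
#'   \item the same model at steady state with dosing interval \eqn{\tau}:
#'     \eqn{C = A(e^{-k_e t}/(1-e^{-k_e\tau}) - e^{-k_a t}/(1-e^{-k_a\tau}))};
#'   \item two-compartment iv bolus (biexponential):
#'     \eqn{C = A_1 e^{-k_1 t} + \alpha A_1 e^{-k_2 t}};
#'   \item one-compartment iv bolus with Michaelis-Menten elimination:
#'     \eqn{dC/dt = -V_m C/(K_M + C)}, \eqn{C(0) = C_0};
#'   \item Michaelis-Menten elimination with first-order input:
#'     \eqn{dC/dt = -V_m C/(K_M + C) + A e^{-k_a t}}, \eqn{C(0) = 0}.
#' }
#' Models 1-3 have closed-form concentration and AUC.  Model 4 has no closed
#' form for \eqn{C(t)} but satisfies the implicit relation
#' \eqn{K_M \ln(C/C_0) + (C - C_0) = -V_m t}, and its AUC over \eqn{[0, T]}
#' has the closed form
#' \eqn{[K_M(C_0 - C_T) + (C_0^2 - C_T^2)/2]/V_m} with \eqn{C_T = C(T)}.
#' Model 5 is integrated numerically, with forward-sensitivity equations for
#' the parameter derivatives.
#'
#' The amplitude constants (\eqn{A}, \eqn{A_1}, \eqn{C_0}) bundle dose,
#' bioavailability and volume of distribution; they are treated as known
#' fixed values, never as free parameters.
#'
#' @param model_id integer 1-5 selecting the model.
#' @param constants optional named list overriding the default fixed
#'   constants (e.g. \code{list(A = 40)}); mainly useful for unit-rescaling
#'   checks.
#' @param interval integration interval in hours, default \code{c(0, 24)}.
#' @return an object of class \code{"pk_model"}.
#' @examples
#' m <- pk_model(1)
#' concentration(m, c(ka = 3 * log(2), ke = log(2) / 12), t = c(1, 2, 4))
#' auc(m, c(ka = 3 * log(2), ke = log(2) / 12))
#' @export
pk_model <- function(model_id, constants = list(), interval = c(0, 24)) {
  if (length(model_id) != 1L || !is.numeric(model_id) ||
      is.na(model_id) || !(model_id %in% 1:5))
    stop("`model_id` must be a single integer between 1 and 5.", call. = FALSE)
  id <- as.integer(model_id)
  spec <- .MODELS[[id]]
  cst <- spec$constants
  if (length(constants)) {
    constants <- unlist(constants)
    unknown <- setdiff(names(constants), names(cst))
    if (length(unknown))
      stop("Unknown constant(s) for model ", id, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cst[names(constants)] <- constants
  }
  interval <- as.numeric(interval)
  if (length(interval) != 2L || interval[1] < 0 || interval[2] <= interval[1])
    stop("`interval` must be an increasing pair of non-negative times.",
         call. = FALSE)
  structure(list(model_id = id, name = spec$name,
                 parameters = spec$parameters, constants = cst,
                 interval = interval, c0_positive = spec$c0_positive),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("PK model ", x$model_id, ": ", x$name, "\n", sep = "")
  cat("  free parameters:", paste(x$parameters, collapse = ", "), "\n")
  cat("  fixed constants:",
      paste(sprintf("%s = %g", names(x$constants), x$constants),
            collapse = ", "), "\n")
  cat("  interval: [", x$interval[1], ", ", x$interval[2], "] h\n", sep = "")
  invisible(x)
}

# Validate / order a parameter vector against a model.
.check_theta <- function(model, theta) {
  p <- model$parameters
  theta <- unlist(theta)
  if (!is.numeric(theta) || length(theta) != length(p))
    stop("theta must be a numeric vector of length ", length(p),
         " (", paste(p, collapse = ", "), ").", call. = FALSE)
  if (is.null(names(theta)) || !all(nzchar(names(theta)))) {
    names(theta) <- p
  } else {
    if (!setequal(names(theta), p))
      stop("theta names must be {", paste(p, collapse = ", "), "}.",
           call. = FALSE)
    theta <- theta[p]
  }
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("All model parameters must be strictly positive and finite.",
         call. = FALSE)
  theta
}

# (1 - exp(-T k)) / k and its first two derivatives in k (k > 0).
.gfun <- function(k, T) {
  E <- exp(-T * k)
  g <- (1 - E) / k
  gp <- T * E / k - g / k
  gpp <- -T^2 * E / k - 2 * gp / k
  list(g = g, gp = gp, gpp = gpp)
}

# --- model 1: C = A (exp(-ke t) - exp(-ka t)) -------------------------------

.m1_eval <- function(model, theta, times, deriv) {
  A <- model$constants[["A"]]
  T <- model$interval[2]
  ka <- theta[["ka"]]; ke <- theta[["ke"]]
  Ea <- exp(-ka * times); Ee <- exp(-ke * times)
  out <- list(C = A * (Ee - Ea), Cdot = A * (-ke * Ee + ka * Ea))
  ga <- .gfun(ka, T); ge <- .gfun(ke, T)
  out$auc <- A * (ge$g - ga$g)
  if (deriv >= 1) {
    out$dC <- cbind(ka = A * times * Ea, ke = -A * times * Ee)
    out$dauc <- c(ka = -A * ga$gp, ke = A * ge$gp)
  }
  if (deriv >= 2) {
    nt <- length(times)
    d2C <- array(0, c(2, 2, nt), dimnames = list(names(theta), names(theta)))
    d2C[1, 1, ] <- -A * times^2 * Ea
    d2C[2, 2, ] <- A * times^2 * Ee
    out$d2C <- d2C
    out$d2auc <- diag(c(-A * ga$gpp, A * ge$gpp))
    dimnames(out$d2auc) <- list(names(theta), names(theta))
  }
  out
}

# --- model 2: steady state --------------------------------------------------

.m2_eval <- function(model, theta, times, deriv) {
  A <- model$constants[["A"]]
  tau <- model$constants[["tau"]]
  ka <- theta[["ka"]]; ke <- theta[["ke"]]
  # h(k, t) = exp(-k t) / (1 - exp(-k tau)) and k-derivatives
  hfun <- function(k) {
    Et <- exp(-k * times); Etau <- exp(-k * tau)
    D <- 1 - Etau; Dp <- tau * Etau; Dpp <- -tau^2 * Etau
    u <- 1 / D; up <- -Dp / D^2; upp <- -Dpp / D^2 + 2 * Dp^2 / D^3
    list(h = Et * u, hk = Et * (-times * u + up),
         hkk = Et * (times^2 * u - 2 * times * up + upp),
         ht = -k * Et * u)
  }
  ha <- hfun(ka); he <- hfun(ke)
  out <- list(C = A * (he$h - ha$h), Cdot = A * (he$ht - ha$ht))
  out$auc <- A * (1 / ke - 1 / ka)
  if (deriv >= 1) {
    out$dC <- cbind(ka = -A * ha$hk, ke = A * he$hk)
    out$dauc <- c(ka = A / ka^2, ke = -A / ke^2)
  }
  if (deriv >= 2) {
    nt <- length(times)
    d2C <- array(0, c(2, 2, nt), dimnames = list(names(theta), names(theta)))
    d2C[1, 1, ] <- -A * ha$hkk
    d2C[2, 2, ] <- A * he$hkk
    out$d2C <- d2C
    out$d2auc <- diag(c(-2 * A / ka^3, 2 * A / ke^3))
    dimnames(out$d2auc) <- list(names(theta), names(theta))
  }
  out
}

# --- model 3: biexponential -------------------------------------------------

.m3_eval <- function(model, theta, times, deriv) {
  A1 <- model$constants[["A1"]]
  T <- model$interval[2]
  k1 <- theta[["k1"]]; k2 <- theta[["k2"]]; al <- theta[["alpha"]]
  E1 <- exp(-k1 * times); E2 <- exp(-k2 * times)
  out <- list(C = A1 * (E1 + al * E2),
              Cdot = A1 * (-k1 * E1 - al * k2 * E2))
  g1 <- .gfun(k1, T); g2 <- .gfun(k2, T)
  out$auc <- A1 * g1$g + al * A1 * g2$g
  if (deriv >= 1) {
    out$dC <- cbind(k1 = -A1 * times * E1, k2 = -al * A1 * times * E2,
                    alpha = A1 * E2)
    out$dauc <- c(k1 = A1 * g1$gp, k2 = al * A1 * g2$gp, alpha = A1 * g2$g)
  }
  if (deriv >= 2) {
    nt <- length(times)
    nm <- names(theta)
    d2C <- array(0, c(3, 3, nt), dimnames = list(nm, nm))
    d2C[1, 1, ] <- A1 * times^2 * E1
    d2C[2, 2, ] <- al * A1 * times^2 * E2
    d2C[2, 3, ] <- d2C[3, 2, ] <- -A1 * times * E2
    out$d2C <- d2C
    H <- matrix(0, 3, 3, dimnames = list(nm, nm))
    H[1, 1] <- A1 * g1$gpp
    H[2, 2] <- al * A1 * g2$gpp
    H[2, 3] <- H[3, 2] <- A1 * g2$gp
    out$d2auc <- H
  }
  out
}

# --- model 4: Michaelis-Menten bolus, implicit C(t) -------------------------

# Solve KM log(C/C0) + C - C0 + Vm t = 0 for C, vectorized damped Newton.
# f is strictly increasing in C with f(0+) = -Inf, f(C0) = Vm t >= 0.
.m4_solve <- function(KM, Vm, C0, t, tol = 1e-13, maxit = 60) {
  C <- C0 * exp(-Vm * t / (KM + C0))
  for (i in seq_len(maxit)) {
    f <- KM * log(C / C0) + C - C0 + Vm * t
    step <- f / (KM / C + 1)
    Cn <- C - step
    bad <- !is.finite(Cn) | Cn <= 0
    if (any(bad)) Cn[bad] <- C[bad] / 2
    C <- Cn
    if (max(abs(f)) < tol * (1 + max(abs(Vm * t)))) break
  }
  f <- KM * log(C / C0) + C - C0 + Vm * t
  if (max(abs(f)) > 1e-8 * (1 + max(abs(Vm * t))))
    stop("Implicit Michaelis-Menten solve failed to converge (model 4, ",
         sprintf("KM = %g, Vm = %g).", KM[1], Vm[1]), call. = FALSE)
  C
}

.m4_eval <- function(model, theta, times, deriv) {
  C0 <- model$constants[["C0"]]
  T <- model$interval[2]
  KM <- theta[["KM"]]; Vm <- theta[["Vm"]]
  tt <- c(times, T)
  C_all <- .m4_solve(KM, Vm, C0, tt)
  nt <- length(times)
  C <- C_all[seq_len(nt)]; CT <- C_all[nt + 1L]
  out <- list(C = C, Cdot = -Vm * C / (KM + C))
  out$auc <- (KM * (C0 - CT) + (C0^2 - CT^2) / 2) / Vm
  if (deriv >= 1) {
    # implicit-function derivatives: dC/dp = -(df/dp)/(df/dC)
    dCdKM_all <- -log(C_all / C0) * C_all / (KM + C_all)
    dCdVm_all <- -tt * C_all / (KM + C_all)
    out$dC <- cbind(KM = dCdKM_all[seq_len(nt)], Vm = dCdVm_all[seq_len(nt)])
    dCT <- c(dCdKM_all[nt + 1L], dCdVm_all[nt + 1L])
    out$dauc <- c(
      KM = ((C0 - CT) - (KM + CT) * dCT[1]) / Vm,
      Vm = -out$auc / Vm - (KM + CT) * dCT[2] / Vm)
  }
  if (deriv >= 2) {
    fd <- .fd_model_hessian(model, theta, times)
    out$d2C <- fd$d2C; out$d2auc <- fd$d2auc
  }
  out
}

# --- model 5: Michaelis-Menten elimination, first-order input ---------------

.m5_rhs <- function(t, y, p) {
  C <- y[1]
  den <- p$KM + C
  inp <- p$A * exp(-p$ka * t)
  dC <- inp - p$Vm * C / den
  if (!p$sens) return(list(c(dC, C)))
  J <- -p$Vm * p$KM / den^2
  fp <- c(p$Vm * C / den^2, -C / den, -p$A * t * exp(-p$ka * t))
  S <- y[3:5]
  list(c(dC, C, J * S + fp, S))
}

.m5_eval <- function(model, theta, times, deriv, rtol = 1e-10, atol = 1e-12) {
  A <- model$constants[["A"]]
  T <- model$interval[2]
  KM <- theta[["KM"]]; Vm <- theta[["Vm"]]; ka <- theta[["ka"]]
  sens <- deriv >= 1
  tout <- sort(unique(c(0, times, T)))
  y0 <- if (sens) numeric(8) else numeric(2)
  sol <- try(deSolve::lsoda(
    y = y0, times = tout, func = .m5_rhs,
    parms = list(KM = KM, Vm = Vm, ka = ka, A = A, sens = sens),
    rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(tout) ||
      any(!is.finite(sol[, 2])))
    stop("ODE integration failed for model 5 at KM = ", KM, ", Vm = ", Vm,
         ", ka = ", ka, ".", call. = FALSE)
  idx <- match(times, tout)
  iT <- match(T, tout)
  C <- sol[idx, 2]
  out <- list(C = C,
              Cdot = A * exp(-ka * times) - Vm * C / (KM + C),
              auc = sol[iT, 3])
  if (sens) {
    out$dC <- cbind(KM = sol[idx, 4], Vm = sol[idx, 5], ka = sol[idx, 6])
    out$dauc <- c(KM = sol[iT, 7], Vm = sol[iT, 8], ka = sol[iT, 9])
  }
  if (deriv >= 2) {
    fd <- .fd_model_hessian(model, theta, times, rtol = rtol, atol = atol)
    out$d2C <- fd$d2C; out$d2auc <- fd$d2auc
  }
  out
}

# Central finite differences of the analytic gradients; used for the second
# derivatives of models 4-5 where no closed-form Hessian is available.
.fd_model_hessian <- function(model, theta, times, rel = 1e-5,
                              rtol = 1e-10, atol = 1e-12) {
  p <- length(theta); nt <- length(times); nm <- names(theta)
  d2C <- array(0, c(p, p, nt), dimnames = list(nm, nm))
  d2auc <- matrix(0, p, p, dimnames = list(nm, nm))
  for (j in seq_len(p)) {
    h <- rel * max(abs(theta[j]), 1e-3)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    ep <- .model_eval(model, tp, times, deriv = 1, rtol = rtol, atol = atol)
    em <- .model_eval(model, tm, times, deriv = 1, rtol = rtol, atol = atol)
    d2C[j, , ] <- t((ep$dC - em$dC) / (2 * h))
    d2auc[j, ] <- (ep$dauc - em$dauc) / (2 * h)
  }
  # symmetrize
  for (k in seq_len(nt)) d2C[, , k] <- (d2C[, , k] + t(d2C[, , k])) / 2
  list(d2C = d2C, d2auc = (d2auc + t(d2auc)) / 2)
}

# Time derivative of C at given times for a batch of parameter vectors,
# reusing an already computed concentration matrix (N x nt).
.model_batch_cdot <- function(model, Theta, times, C) {
  Theta <- as.matrix(Theta)
  colnames(Theta) <- model$parameters
  switch(model$model_id,
    { A <- model$constants[["A"]]
      A * (-Theta[, "ke"] * exp(-outer(Theta[, "ke"], times)) +
             Theta[, "ka"] * exp(-outer(Theta[, "ka"], times))) },
    { A <- model$constants[["A"]]; tau <- model$constants[["tau"]]
      ue <- 1 / (1 - exp(-tau * Theta[, "ke"]))
      ua <- 1 / (1 - exp(-tau * Theta[, "ka"]))
      A * (-Theta[, "ke"] * ue * exp(-outer(Theta[, "ke"], times)) +
             Theta[, "ka"] * ua * exp(-outer(Theta[, "ka"], times))) },
    { A1 <- model$constants[["A1"]]
      A1 * (-Theta[, "k1"] * exp(-outer(Theta[, "k1"], times)) -
              Theta[, "alpha"] * Theta[, "k2"] *
                exp(-outer(Theta[, "k2"], times))) },
    -Theta[, "Vm"] * C / (Theta[, "KM"] + C),
    { A <- model$constants[["A"]]
      exp(-outer(Theta[, "ka"], times)) * A -
        Theta[, "Vm"] * C / (Theta[, "KM"] + C) })
}

# Single entry point used throughout the package.
# deriv 0: C, Cdot, auc; deriv 1: + gradients; deriv 2: + Hessians.
.model_eval <- function(model, theta, times, deriv = 0,
                        rtol = 1e-10, atol = 1e-12) {
  theta <- .check_theta(model, theta)
  if (any(times < model$interval[1] - 1e-12) ||
      any(times > model$interval[2] + 1e-12))
    stop("times must lie inside the integration interval [",
         model$interval[1], ", ", model$interval[2], "].", call. = FALSE)
  switch(model$model_id,
         .m1_eval(model, theta, times, deriv),
         .m2_eval(model, theta, times, deriv),
         .m3_eval(model, theta, times, deriv),
         .m4_eval(model, theta, times, deriv),
         .m5_eval(model, theta, times, deriv, rtol = rtol, atol = atol))
}

#' Model concentration at given times
#'
#' @param model a \code{\link{pk_model}}.
#' @param theta named (or correctly ordered) positive parameter vector.
#' @param t times in the model interval (h).
#' @param rtol,atol ODE tolerances (model 5 only).
#' @return numeric vector of concentrations \eqn{C(t, \theta)}.
#' @export
concentration <- function(model, theta, t, rtol = 1e-10, atol = 1e-12) {
  .model_eval(model, theta, t, deriv = 0, rtol = rtol, atol = atol)$C
}

#' Exact AUC of a model over its integration interval
#'
#' Closed forms for models 1-3, the Michaelis-Menten integral identity for
#' model 4, and an ODE-augmented integral state for model 5.
#'
#' @inheritParams concentration
#' @return AUC in concentration x hours.
#' @export
auc <- function(model, theta, rtol = 1e-10, atol = 1e-12) {
  .model_eval(model, theta, model$interval[2], deriv = 0,
              rtol = rtol, atol = atol)$auc
}

#' Concentration and AUC parameter sensitivities
#'
#' Returns concentrations, AUC, and their first (and optionally second)
#' derivatives in the model parameters at a set of sampling times.
#' Derivatives are analytic for models 1-3, implicit-function based for
#' model 4 and forward-sensitivity ODE based for model 5; second derivatives
#' of models 4-5 are central finite differences of the exact gradients.
#'
#' @inheritParams concentration
#' @param knots sampling times inside the model interval.
#' @param hessians logical; also compute second derivatives.
#' @return a list of class \code{"sensitivity_bundle"} with elements
#'   \code{concentration}, \code{conc_gradient} (times x parameters),
#'   \code{conc_dot} (time derivative of C at the knots), \code{auc},
#'   \code{auc_gradient}, and when requested \code{conc_hessian}
#'   (parameters x parameters x times) and \code{auc_hessian}.
#' @export
sensitivities <- function(model, theta, knots, hessians = TRUE,
                          rtol = 1e-10, atol = 1e-12) {
  e <- .model_eval(model, theta, knots, deriv = if (hessians) 2 else 1,
                   rtol = rtol, atol = atol)
  structure(list(times = knots, parameters = .check_theta(model, theta),
                 concentration = e$C, conc_dot = e$Cdot,
                 conc_gradient = e$dC, conc_hessian = e$d2C,
                 auc = e$auc, auc_gradient = e$dauc, auc_hessian = e$d2auc),
            class = "sensitivity_bundle")
}

# ---- vectorized batch paths (profile simulation, grids) --------------------

# Theta: N x p matrix (columns in model parameter order).
# Returns list(C = N x nt matrix, auc = length-N vector).
.model_batch <- function(model, Theta, times, rtol = 1e-8, atol = 1e-10,
                         chunk = 250L) {
  Theta <- as.matrix(Theta)
  colnames(Theta) <- model$parameters
  N <- nrow(Theta); nt <- length(times)
  T <- model$interval[2]
  id <- model$model_id
  if (id == 1L) {
    A <- model$constants[["A"]]
    Ee <- exp(-outer(Theta[, "ke"], times))
    Ea <- exp(-outer(Theta[, "ka"], times))
    C <- A * (Ee - Ea)
    auc <- A * ((1 - exp(-T * Theta[, "ke"])) / Theta[, "ke"] -
                (1 - exp(-T * Theta[, "ka"])) / Theta[, "ka"])
    return(list(C = C, auc = auc))
  }
  if (id == 2L) {
    A <- model$constants[["A"]]; tau <- model$constants[["tau"]]
    ue <- 1 / (1 - exp(-tau * Theta[, "ke"]))
    ua <- 1 / (1 - exp(-tau * Theta[, "ka"]))
    C <- A * (exp(-outer(Theta[, "ke"], times)) * ue -
              exp(-outer(Theta[, "ka"], times)) * ua)
    auc <- A * (1 / Theta[, "ke"] - 1 / Theta[, "ka"])
    return(list(C = C, auc = auc))
  }
  if (id == 3L) {
    A1 <- model$constants[["A1"]]
    C <- A1 * (exp(-outer(Theta[, "k1"], times)) +
               Theta[, "alpha"] * exp(-outer(Theta[, "k2"], times)))
    auc <- A1 * ((1 - exp(-T * Theta[, "k1"])) / Theta[, "k1"] +
                 Theta[, "alpha"] *
                   (1 - exp(-T * Theta[, "k2"])) / Theta[, "k2"])
    return(list(C = C, auc = auc))
  }
  if (id == 4L) {
    C0 <- model$constants[["C0"]]
    KM <- Theta[, "KM"]; Vm <- Theta[, "Vm"]
    tt <- c(times, T)
    Tm <- matrix(rep(tt, each = N), nrow = N)
    Call <- .m4_solve(matrix(KM, N, length(tt)), matrix(Vm, N, length(tt)),
                      C0, Tm)
    C <- Call[, seq_len(nt), drop = FALSE]
    CT <- Call[, nt + 1L]
    return(list(C = C, auc = (KM * (C0 - CT) + (C0^2 - CT^2) / 2) / Vm))
  }
  # model 5: stacked ODE systems, integrated in chunks
  A <- model$constants[["A"]]
  tout <- sort(unique(c(0, times, T)))
  idx <- match(times, tout); iT <- match(T, tout)
  C <- matrix(0, N, nt); auc <- numeric(N)
  for (start in seq(1L, N, by = chunk)) {
    rows <- start:min(start + chunk - 1L, N)
    M <- length(rows)
    KM <- Theta[rows, "KM"]; Vm <- Theta[rows, "Vm"]; ka <- Theta[rows, "ka"]
    rhs <- function(t, y, p) {
      Cc <- y[seq_len(M)]
      dC <- p$A * exp(-p$ka * t) - p$Vm * Cc / (p$KM + Cc)
      list(c(dC, Cc))
    }
    sol <- deSolve::lsoda(y = numeric(2 * M), times = tout, func = rhs,
                          parms = list(KM = KM, Vm = Vm, ka = ka, A = A),
                          rtol = rtol, atol = atol)
    if (nrow(sol) < length(tout))
      stop("Batch ODE integration failed for model 5.", call. = FALSE)
    C[rows, ] <- t(sol[idx, 1 + seq_len(M), drop = FALSE])
    auc[rows] <- sol[iT, 1 + M + seq_len(M)]
  }
  list(C = C, auc = auc)
}
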