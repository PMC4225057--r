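# Nested minimax optimization.
#
# Inner level: maximize the relative risk over the parameter box
# (second-order box-constrained ascent, multistart from box corners, a
# low-discrepancy interior set and the best point of a dense grid; any
# linear constraint is folded into a smooth reparameterization).
#
# Outer level: minimize the worst-case risk over trapezoid knots, or over
# knots and weights jointly.  The worst case is approached by progressive
# discretization: a working set of parameter points (a coarse grid plus
# every inner maximizer found so far) defines a finite minimax problem,
# solved by quasi-Newton descent on a smoothed (log-sum-exp) maximum with
# exact envelope gradients; re-running the full inner maximization on the
# trial design then either confirms the worst case or contributes a new
# working point.  Every candidate design -- including the unmodified
# baselines -- is re-verified with a full-strength inner maximization, and
# the best verified design wins.

# Deterministic Halton sequence in [0,1]^d (no RNG anywhere in the
# optimizers, so results are bit-reproducible).
.halton <- function(n, d) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  H <- matrix(0, n, d)
  for (j in seq_len(d)) {
    b <- primes[j]
    for (i in seq_len(n)) {
      f <- 1; r <- 0; k <- i
      while (k > 0) {
        f <- f / b
        r <- r + f * (k %% b)
        k <- k %/% b
      }
      H[i, j] <- r
    }
  }
  H
}

#' Optimizer settings for the nested minimax search
#'
#' @param inner_starts number of low-discrepancy interior start points for
#'   the inner maximization (box corners are always added).
#' @param outer_starts number of initial designs from which the outer
#'   descent is run (all baseline designs are always evaluated, but only
#'   the first \code{outer_starts} are refined).
#' @param inner_tolerance relative objective-change tolerance of the inner
#'   ascent.
#' @param outer_tolerance gradient/step tolerance of the outer descent.
#' @param max_iterations iteration cap for each outer descent stage.
#' @param grid_points verification-grid density per axis for the inner
#'   maximization (\code{NULL} = per-model default; 0 disables the grid).
#' @param lawson_iterations iterations of the multiplicative-weight
#'   (Lawson-type) minimax weight solve at fixed knots.
#' @param nm_iterations simplex-iteration cap for the knots-only stage of
#'   \code{\link{optimize_lc}} (\code{NULL} = per-model default).
#' @param exchange_rounds alternations of finite-minimax descent and full
#'   inner maximization (working-set exchange).
#' @param working_grid density per axis of the coarse parameter grid
#'   seeding the working set (\code{NULL} = per-model default).
#' @param use_hessian supply the analytic risk Hessian to the inner ascent
#'   (\code{NULL} = yes except for the ODE-integrated model 5).
#' @param rtol ODE relative tolerance inside optimizer loops.
#' @param final_rtol ODE relative tolerance for final verification.
#' @param seed integer recorded with results; the search itself is
#'   deterministic (low-discrepancy starts, no RNG).
#' @return an object of class \code{"optimizer_settings"}.
#' @export
optimizer_settings <- function(inner_starts = 16L, outer_starts = 4L,
                               inner_tolerance = 1e-10,
                               outer_tolerance = 1e-8,
                               max_iterations = 200L,
                               grid_points = NULL,
                               lawson_iterations = 80L,
                               nm_iterations = NULL,
                               exchange_rounds = 4L,
                               working_grid = NULL,
                               use_hessian = NULL,
                               rtol = 1e-8, final_rtol = 1e-10,
                               seed = 1L) {
  stopifnot(inner_starts >= 1, outer_starts >= 1,
            inner_tolerance > 0, outer_tolerance > 0, max_iterations >= 1)
  structure(list(inner_starts = as.integer(inner_starts),
                 outer_starts = as.integer(outer_starts),
                 inner_tolerance = inner_tolerance,
                 outer_tolerance = outer_tolerance,
                 max_iterations = as.integer(max_iterations),
                 grid_points = grid_points,
                 lawson_iterations = as.integer(lawson_iterations),
                 nm_iterations = nm_iterations,
                 exchange_rounds = as.integer(exchange_rounds),
                 working_grid = working_grid,
                 use_hessian = use_hessian,
                 rtol = rtol, final_rtol = final_rtol,
                 seed = as.integer(seed)),
            class = "optimizer_settings")
}

.default_grid <- function(model, dim, settings) {
  g <- settings$grid_points
  if (!is.null(g)) return(as.integer(g))
  if (model$model_id == 5L) return(6L)
  if (dim <= 2) 150L else 40L
}

# Indices of lattice local maxima (>= all orthogonal neighbours) of a
# value vector laid out on an expand.grid lattice with `gp` points per
# axis in `dim` dimensions.
.grid_local_maxima <- function(rv, gp, dim) {
  arr <- array(rv, dim = rep(gp, dim))
  is_max <- array(TRUE, dim = dim(arr))
  idx <- seq_len(gp)
  for (d in seq_len(dim)) {
    shift <- function(k) {
      pos <- pmin(pmax(idx + k, 1L), gp)
      switch(dim,
             arr[pos],
             if (d == 1) arr[pos, , drop = FALSE]
             else arr[, pos, drop = FALSE],
             if (d == 1) arr[pos, , , drop = FALSE]
             else if (d == 2) arr[, pos, , drop = FALSE]
             else arr[, , pos, drop = FALSE])
    }
    is_max <- is_max & (arr >= shift(1L)) & (arr >= shift(-1L))
  }
  which(as.vector(is_max))
}

.default_working_grid <- function(model, dim, settings) {
  g <- settings$working_grid
  if (!is.null(g)) return(as.integer(g))
  if (model$model_id == 5L) return(5L)
  if (dim <= 2) 17L else 7L
}

#' Worst-case risk of a design over a parameter box
#'
#' Maximizes the relative risk \eqn{R_r(\theta)} of a fixed quadrature over
#' the feasible parameter region: multistart second-order box-constrained
#' ascent from all box corners, a deterministic low-discrepancy interior
#' set, optional extra starts, and the best point of a dense verification
#' grid.  Any linear constraint of the box is folded into a smooth
#' reparameterization, so every iterate is feasible.
#'
#' @param quad a \code{\link{quadrature}}.
#' @param model a \code{\link{pk_model}}.
#' @param box a \code{\link{parameter_box}}.
#' @param cv noise coefficient of variation.
#' @param settings an \code{\link{optimizer_settings}}.
#' @param extra_starts optional list/matrix of additional parameter vectors
#'   to start from (e.g. warm starts).
#' @return list of class \code{"max_risk"} with \code{theta_star},
#'   \code{objective} (the maximum relative risk; equal to
#'   \code{relative_risk(quad, model, theta_star, cv)$value}),
#'   \code{sqrt_objective}, \code{trace}, \code{converged}.
#' @export
max_risk <- function(quad, model, box, cv, settings = optimizer_settings(),
                     extra_starts = NULL) {
  sp <- .param_space(box)
  rtol <- settings$final_rtol
  use_h <- settings$use_hessian
  if (is.null(use_h)) use_h <- model$model_id != 5L
  use_h <- use_h && length(box$constraints) == 0L

  negf <- function(z) -.risk_eval(quad, model, sp$to_theta(z), cv,
                                  deriv = 0, rtol = rtol)$value
  negg <- function(z) {
    r <- .risk_eval(quad, model, sp$to_theta(z), cv, deriv = 1, rtol = rtol)
    -drop(crossprod(sp$jacobian(z), r$gradient))
  }
  negh <- function(z) {
    r <- .risk_eval(quad, model, sp$to_theta(z), cv, deriv = 2, rtol = rtol)
    -r$hessian
  }

  # start set in z-space: corners + low-discrepancy interior + extras
  zc <- .box_corners(structure(list(lower = sp$lower, upper = sp$upper,
                                    constraints = list()),
                               class = "parameter_box"))
  zh <- .halton(settings$inner_starts, sp$dim)
  zh <- sweep(sweep(zh, 2, sp$upper - sp$lower, `*`), 2, sp$lower, `+`)
  starts <- rbind(zc, zh)
  if (!is.null(extra_starts)) {
    if (!is.matrix(extra_starts))
      extra_starts <- do.call(rbind, lapply(extra_starts, function(th)
        sp$from_theta(th)))
    starts <- rbind(starts, extra_starts)
  }

  # verification grid (vectorized risk); near-optimal designs
  # equioscillate, leaving many near-equal local maxima, so every lattice
  # local maximum of the grid (capped to the best 12) is polished, not
  # just the single best point
  gp <- .default_grid(model, sp$dim, settings)
  grid_best <- NULL
  if (gp >= 2) {
    axes <- lapply(seq_len(sp$dim), function(j)
      seq(sp$lower[[j]], sp$upper[[j]], length.out = gp))
    Z <- as.matrix(expand.grid(axes))
    rv <- .risk_profile(quad, model, sp$to_theta_mat(Z), cv,
                        rtol = settings$rtol)
    ib <- which.max(rv)
    grid_best <- list(z = Z[ib, ], value = rv[ib])
    lm <- .grid_local_maxima(rv, gp, sp$dim)
    lm <- lm[order(rv[lm], decreasing = TRUE)]
    lm <- utils::head(lm, 20L)
    starts <- rbind(starts, Z[lm, , drop = FALSE])
  }

  best <- list(value = -Inf, z = NULL)
  trace <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- try(stats::nlminb(
      start = pmin(pmax(starts[s, ], sp$lower), sp$upper),
      objective = negf, gradient = negg,
      hessian = if (use_h) negh else NULL,
      lower = sp$lower, upper = sp$upper,
      control = list(iter.max = 300, eval.max = 600,
                     rel.tol = settings$inner_tolerance)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      trace[[s]] <- list(start = starts[s, ], value = NA_real_, ok = FALSE)
      next
    }
    val <- -fit$objective
    trace[[s]] <- list(start = starts[s, ], value = val,
                       ok = fit$convergence == 0)
    if (is.finite(val) && val > best$value)
      best <- list(value = val, z = fit$par)
  }
  if (is.null(best$z)) {
    if (!is.null(grid_best)) best <- grid_best
    else stop("All inner maximization starts failed.", call. = FALSE)
  }
  if (!is.null(grid_best) && grid_best$value > best$value)
    best <- grid_best
  theta_star <- sp$to_theta(best$z)
  obj <- .risk_eval(quad, model, theta_star, cv, deriv = 0,
                    rtol = rtol)$value
  structure(list(theta_star = theta_star, objective = obj,
                 sqrt_objective = sqrt(obj),
                 grid_value = if (!is.null(grid_best)) grid_best$value,
                 trace = trace,
                 converged = any(vapply(trace, function(t)
                   isTRUE(t$ok), logical(1)))),
            class = "max_risk")
}

#' Envelope gradient of the worst-case risk in the design variables
#'
#' By the envelope (Danskin) property, the derivative of
#' \eqn{\max_\theta R_r(\theta)} with respect to a knot or a weight equals
#' the partial derivative of \eqn{R_r} at the maximizer \eqn{\theta^*}:
#' \deqn{\partial R_r/\partial w_i = [2 c_v^2 w_i C_i^2 - 2 b C_i]/AUC^2,
#'  \qquad
#'  \partial R_r/\partial t_i = [2 c_v^2 w_i^2 C_i - 2 b w_i]
#'    \dot C_i / AUC^2,}
#' with \eqn{b = AUC - \sum_j w_j C_j} and \eqn{\dot C_i} the time
#' derivative of the concentration at knot \eqn{i}.
#'
#' @inheritParams max_risk
#' @param theta_star the inner maximizer.
#' @param rtol ODE relative tolerance.
#' @return list with components \code{knots} and \code{weights}.
#' @export
outer_gradient <- function(quad, model, theta_star, cv, rtol = 1e-10) {
  e <- .model_eval(model, theta_star, quad$knots, deriv = 0, rtol = rtol,
                   atol = rtol * 1e-2)
  w <- quad$weights; C <- e$C; A <- e$auc
  b <- A - sum(w * C)
  dw <- (2 * cv^2 * w * C^2 - 2 * b * C) / A^2
  dt <- (2 * cv^2 * w^2 * C - 2 * b * w) * e$Cdot / A^2
  list(knots = dt, weights = dw)
}

# ---- knot parameterization -------------------------------------------------
# Ordered knots are optimized through positive increments: with
# e = exp(c(x, 0)) the knots are t_k = T * cumsum(e)_k / sum(e).  With
# fixed_end the last knot is exactly T (trapezoid); otherwise one extra
# increment keeps t_n < T free (general LC).

.knots_from_x <- function(x, T, fixed_end) {
  e <- exp(c(x, 0))
  t_all <- T * cumsum(e) / sum(e)
  if (fixed_end) t_all else t_all[-length(t_all)]
}

.x_from_knots <- function(knots, T, fixed_end, eps = 1e-4) {
  if (fixed_end) {
    inner <- pmin(pmax(knots[-length(knots)], eps), T - eps)
    d <- diff(c(0, inner, T))
  } else {
    knots <- pmin(pmax(knots, eps), T - eps)
    d <- diff(c(0, knots, T))
  }
  d <- pmax(d, 1e-6)
  x <- log(d / d[length(d)])
  x[-length(x)]
}

# Jacobian d t_k / d x_j of the increment parameterization.
.knots_jacobian <- function(x, T, fixed_end) {
  e <- exp(c(x, 0))
  m <- length(e)
  S <- cumsum(e); Stot <- S[m]
  nk <- if (fixed_end) m else m - 1L
  J <- matrix(0, nk, length(x))
  for (j in seq_along(x))
    for (k in seq_len(nk))
      J[k, j] <- T * e[j] * ((j <= k) - S[k] / Stot) / Stot
  J
}

# Jacobian of trapezoid weights (plus optional extrapolation correction)
# in the knots: dw/dt, n x n.
.trap_weight_jacobian <- function(knots, extrapolate) {
  n <- length(knots)
  J <- matrix(0, n, n)
  J[1, 1] <- -0.5; J[1, 2] <- 0.5
  if (n > 2)
    for (i in 2:(n - 1)) { J[i, i - 1] <- -0.5; J[i, i + 1] <- 0.5 }
  J[n, n - 1] <- -0.5; J[n, n] <- 0.5
  if (extrapolate && knots[1] > 0) {
    t1 <- knots[1]; g <- knots[2] - knots[1]
    J[1, 1] <- J[1, 1] + 1 + t1 / g + t1^2 / (2 * g^2)
    J[1, 2] <- J[1, 2] - t1^2 / (2 * g^2)
    J[2, 1] <- J[2, 1] - t1 / g - t1^2 / (2 * g^2)
    J[2, 2] <- J[2, 2] + t1^2 / (2 * g^2)
  }
  J
}

# ---- finite minimax over a working set of parameter points -----------------

# Lawson-type multiplicative-weight refinement of LC weights at fixed
# knots: approximately minimizes the maximum over a finite theta set of the
# per-theta convex quadratic risk, by iteratively reweighted least squares.
.lawson_weights <- function(Cmat, aucs, cv, w0, iterations) {
  G <- nrow(Cmat); nk <- ncol(Cmat)
  lam <- rep(1 / G, G)
  Q_of <- function(w) {
    r <- (aucs - drop(Cmat %*% w)) / aucs
    drop((Cmat^2) %*% w^2) * cv^2 / aucs^2 + r^2
  }
  best_w <- w0; best_val <- max(Q_of(w0))
  Ca <- Cmat / aucs
  for (it in seq_len(iterations)) {
    M <- crossprod(Ca * sqrt(lam))
    if (cv > 0) M <- M + cv^2 * diag(colSums(lam * Ca^2), nk)
    v <- colSums(lam * Ca)
    w <- try(solve(M + diag(1e-13 * (1 + mean(diag(M))), nk), v),
             silent = TRUE)
    if (inherits(w, "try-error")) break
    Q <- Q_of(w)
    mv <- max(Q)
    if (mv < best_val) { best_val <- mv; best_w <- w }
    lam <- lam * (Q + 1e-300)
    lam <- lam / sum(lam)
  }
  best_w
}

# Descend the smoothed maximum of R_r over a fixed finite set Theta with
# respect to the free design vector v.  type "lc": v = (x, w); type
# "trap": v = x with trapezoid(+extrapolation) weights regenerated from the
# knots.  Exact gradients (envelope partials at each working point, chained
# through the weight map and the knot parameterization).
.fm_descent <- function(v0, model, cv, Theta, n, type = c("lc", "trap"),
                        extrapolate = FALSE, settings,
                        beta_factors = c(30, 100, 300, 1000, 3000)) {
  type <- match.arg(type)
  T <- model$interval[2]
  fixed_end <- type == "trap"
  nx <- if (fixed_end) n - 1L else n

  design <- function(v) {
    x <- v[seq_len(nx)]
    knots <- .knots_from_x(x, T, fixed_end)
    if (type == "lc") {
      list(x = x, knots = knots, weights = v[nx + seq_len(n)])
    } else {
      w <- trapezoid_weights(knots)
      if (extrapolate && knots[1] > 0)
        w <- w + extrapolate_to_zero_adjustment(knots)
      list(x = x, knots = knots, weights = w)
    }
  }

  cache <- new.env(parent = emptyenv())
  terms <- function(v) {
    key <- paste(format(v, digits = 17), collapse = ",")
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    d <- design(v)
    mb <- .model_batch(model, Theta, d$knots, rtol = settings$rtol)
    Cdot <- .model_batch_cdot(model, Theta, d$knots, mb$C)
    b <- mb$auc - drop(mb$C %*% d$weights)
    R <- (cv^2 * drop((mb$C^2) %*% d$weights^2) + b^2) / mb$auc^2
    val <- list(d = d, C = mb$C, auc = mb$auc, Cdot = Cdot, b = b, R = R)
    cache$key <- key; cache$val <- val
    val
  }

  v <- v0
  for (bf in beta_factors) {
    t0 <- terms(v)
    beta <- bf / max(t0$R, 1e-300)
    fn <- function(v) {
      tt <- terms(v)
      Rm <- max(tt$R)
      Rm + log(sum(exp(beta * (tt$R - Rm)))) / beta
    }
    gr <- function(v) {
      tt <- terms(v)
      Rm <- max(tt$R)
      s <- exp(beta * (tt$R - Rm)); s <- s / sum(s)
      w <- tt$d$weights
      A2 <- tt$auc^2
      # G x n envelope partials
      dRdw <- (2 * cv^2 * sweep(tt$C^2, 2, w, `*`) - 2 * tt$b * tt$C) / A2
      dRdt <- (2 * cv^2 * sweep(tt$C, 2, w^2, `*`) -
                 2 * tt$b * rep(1, length(tt$b)) %o% w) * tt$Cdot / A2
      gw <- drop(crossprod(dRdw, s))
      gt <- drop(crossprod(dRdt, s))
      if (type == "trap") {
        gt <- gt + drop(crossprod(
          .trap_weight_jacobian(tt$d$knots, extrapolate && tt$d$knots[1] > 0),
          gw))
        drop(crossprod(.knots_jacobian(tt$d$x, T, fixed_end), gt))
      } else {
        c(drop(crossprod(.knots_jacobian(tt$d$x, T, fixed_end), gt)), gw)
      }
    }
    lower <- c(rep(-6, nx), if (type == "lc") rep(-Inf, n))
    upper <- c(rep(6, nx), if (type == "lc") rep(Inf, n))
    fit <- try(stats::optim(v, fn, gr, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(
                              maxit = settings$max_iterations,
                              factr = max(1, settings$outer_tolerance / 1e-12),
                              pgtol = 0)), silent = TRUE)
    if (!inherits(fit, "try-error")) v <- fit$par
  }
  list(v = v, design = design(v))
}

.minimax_result <- function(model, box, cv, settings, candidates,
                            converged, kind = NULL) {
  vals <- vapply(candidates, function(c) c$value, numeric(1))
  ib <- which.min(vals)
  bq <- candidates[[ib]]
  mr <- bq$mr
  # tighten the winner's worst-case certificate with a denser grid
  # (closed-form models only; the batch evaluation there is cheap)
  if (model$model_id != 5L) {
    s2 <- settings
    s2$grid_points <- if (length(box$lower) <= 2) 400L else 50L
    mr2 <- max_risk(bq$quad, model, box, cv, s2,
                    extra_starts = list(mr$theta_star))
    if (mr2$objective > mr$objective) mr <- mr2
  }
  quad <- bq$quad
  if (!is.null(kind)) quad$kind <- kind
  structure(list(quadrature = quad, theta_star = mr$theta_star,
                 objective = mr$objective,
                 sqrt_objective = sqrt(mr$objective),
                 model_id = model$model_id, cv = cv, n = quad$n,
                 outer_trace = data.frame(
                   candidate = vapply(candidates, function(c) c$label,
                                      character(1)),
                   objective = vals,
                   sqrt_objective = sqrt(vals)),
                 settings = settings,
                 converged = converged),
            class = "minimax_result")
}

#' @export
print.minimax_result <- function(x, ...) {
  cat("Minimax design (", x$quadrature$kind, "), model ", x$model_id,
      ", n = ", x$n, ", cv = ", x$cv, "\n", sep = "")
  print(x$quadrature)
  cat("  worst-case theta:",
      paste(sprintf("%s = %.6g", names(x$theta_star), x$theta_star),
            collapse = ", "), "\n")
  cat("  objective =", format(x$objective, digits = 6),
      " sqrt =", format(x$sqrt_objective, digits = 4), "\n")
  invisible(x)
}

# Evaluate a candidate design at full strength and record it.
.score_candidate <- function(quad, model, box, cv, settings, label,
                             extra_starts = NULL) {
  mr <- max_risk(quad, model, box, cv, settings,
                 extra_starts = extra_starts)
  list(quad = quad, mr = mr, value = mr$objective, label = label)
}

# Shared exchange loop: alternate finite-minimax descent on the working
# set with a full inner maximization that either certifies the design or
# contributes a new working point.
.exchange_optimize <- function(v0, model, box, cv, n, type, extrapolate,
                               settings, working, label, candidates) {
  v <- v0
  theta_new <- NULL
  for (round in seq_len(settings$exchange_rounds)) {
    fm <- .fm_descent(v, model, cv, working$Theta, n, type = type,
                      extrapolate = extrapolate, settings = settings)
    v <- fm$v
    quad <- if (type == "lc")
      quadrature(fm$design$knots, fm$design$weights, kind = "lc",
                 interval = model$interval)
    else
      trapezoid_quadrature(fm$design$knots, extrapolate = extrapolate &&
                             fm$design$knots[1] > 0,
                           interval = model$interval)
    sc <- .score_candidate(quad, model, box, cv, settings,
                           label = sprintf("%s_round%d", label, round),
                           extra_starts = theta_new)
    candidates[[length(candidates) + 1L]] <- sc
    theta_new <- list(sc$mr$theta_star)
    working$Theta <- rbind(working$Theta, matrix(sc$mr$theta_star, nrow = 1))
    working_max <- max(.risk_profile(quad, model, working$Theta, cv,
                                     rtol = settings$rtol))
    # certified when the continuum worst case matches the working set
    if (sc$value <= working_max * (1 + 1e-6)) break
  }
  candidates
}

#' Minimax-optimal trapezoid sampling schedule
#'
#' Minimizes the worst-case relative risk over trapezoid knot vectors with
#' the last knot fixed at the end of the interval, the weights regenerated
#' from the trapezoid formula at every trial schedule, and (for models with
#' positive concentration at time zero) an optional linear
#' extrapolation-to-zero weight correction.  Deterministic multistart over
#' structured schedules (equispaced, geometric early- and late-dense,
#' Chebyshev-spaced); every candidate is re-verified with a full-strength
#' inner maximization and the best verified design is returned, so the
#' result can never be worse than the equispaced trapezoid.
#'
#' @inheritParams max_risk
#' @param n number of sampled concentrations (knots), >= 2.
#' @param allow_extrapolation logical; default is the model's
#'   \code{c0_positive} flag.
#' @return a \code{"minimax_result"}.
#' @export
optimize_trapezoid <- function(model, box = default_box(model), cv, n,
                               allow_extrapolation = NULL,
                               settings = optimizer_settings()) {
  if (n < 2) stop("The trapezoid rule needs n >= 2 knots.", call. = FALSE)
  if (is.null(allow_extrapolation)) allow_extrapolation <- model$c0_positive
  T <- model$interval[2]
  working <- .new_working_set(model, box, settings)

  eq <- T * seq_len(n) / n
  geo_early <- T * cumsum(1.6^(seq_len(n))) / sum(1.6^(seq_len(n)))
  geo_late <- T * cumsum(1.6^(rev(seq_len(n)))) / sum(1.6^(seq_len(n)))
  cheb <- T * (1 - cos(pi * seq_len(n) / n)) / 2
  cheb[n] <- T
  starts <- list(equispaced = eq, geometric_early = geo_early,
                 geometric_late = geo_late, chebyshev = cheb)

  candidates <- list()
  for (i in seq_along(starts)) {
    q0 <- trapezoid_quadrature(starts[[i]], extrapolate = allow_extrapolation,
                               interval = model$interval)
    sc0 <- .score_candidate(q0, model, box, cv, settings,
                            label = names(starts)[i])
    candidates[[length(candidates) + 1L]] <- sc0
    working$Theta <- rbind(working$Theta,
                           matrix(sc0$mr$theta_star, nrow = 1))
  }
  for (i in seq_len(min(settings$outer_starts, length(starts)))) {
    v0 <- .x_from_knots(starts[[i]], T, fixed_end = TRUE)
    candidates <- .exchange_optimize(v0, model, box, cv, n, "trap",
                                     allow_extrapolation, settings, working,
                                     names(starts)[i], candidates)
  }
  .minimax_result(model, box, cv, settings, candidates,
                  converged = TRUE)
}

.new_working_set <- function(model, box, settings) {
  sp <- .param_space(box)
  gp <- .default_working_grid(model, sp$dim, settings)
  axes <- lapply(seq_len(sp$dim), function(j)
    seq(sp$lower[[j]], sp$upper[[j]], length.out = gp))
  Z <- as.matrix(expand.grid(axes))
  env <- new.env(parent = emptyenv())
  env$Theta <- sp$to_theta_mat(Z)
  env
}

#' Minimax-optimal LC quadrature
#'
#' Minimizes the worst-case relative risk jointly over \eqn{n} ordered
#' knots inside the interval and \eqn{n} unconstrained real weights.
#' Initial designs are Gauss-Legendre, the optimal trapezoid,
#' Clenshaw-Curtis and the equispaced trapezoid; each is refined by
#' alternating (i) a Lawson-type minimax weight solve at fixed knots over a
#' working set of parameter points, (ii) a joint quasi-Newton descent of
#' knots and weights on the smoothed working-set maximum with exact
#' envelope gradients, and (iii) a full inner maximization that either
#' certifies the design's worst case or adds it to the working set.  All
#' candidates, including the unmodified baselines, are re-verified with a
#' full-strength inner maximization, so the returned objective never
#' exceeds the best baseline's.
#'
#' @inheritParams optimize_trapezoid
#' @param n number of knots, >= 1.
#' @param trapezoid optional precomputed \code{optimize_trapezoid} result to
#'   reuse as a starting design (avoids recomputation); \code{NULL} runs it
#'   internally when \code{n >= 2}.
#' @return a \code{"minimax_result"} with kind \code{"optimal_lc"}.
#' @export
optimize_lc <- function(model, box = default_box(model), cv, n,
                        settings = optimizer_settings(), trapezoid = NULL) {
  if (n < 1) stop("n >= 1 knots required.", call. = FALSE)
  T <- model$interval[2]
  working <- .new_working_set(model, box, settings)

  starts <- list(list(label = "gauss_legendre",
                      quad = gauss_legendre(n, model$interval)))
  if (n >= 2) {
    if (is.null(trapezoid))
      trapezoid <- optimize_trapezoid(model, box, cv, n, settings = settings)
    starts <- c(starts,
                list(list(label = "optimal_trapezoid",
                          quad = trapezoid$quadrature),
                     list(label = "clenshaw_curtis",
                          quad = clenshaw_curtis(n, model$interval)),
                     list(label = "equispaced_trapezoid",
                          quad = trapezoid_quadrature(
                            T * seq_len(n) / n,
                            extrapolate = model$c0_positive,
                            interval = model$interval))))
  }

  candidates <- list()
  for (st in starts) {  # baselines always scored
    sc0 <- .score_candidate(st$quad, model, box, cv, settings,
                            label = st$label)
    candidates[[length(candidates) + 1L]] <- sc0
    working$Theta <- rbind(working$Theta,
                           matrix(sc0$mr$theta_star, nrow = 1))
  }

  nm_it <- settings$nm_iterations
  if (is.null(nm_it)) nm_it <- if (model$model_id == 5L) 120L else 2000L

  # nested stage: knots by simplex descent, with the weights solved to
  # working-set minimax optimality (Lawson) at every trial knot vector
  solve_weights <- function(knots, w0) {
    mb <- .model_batch(model, working$Theta, knots, rtol = settings$rtol)
    w <- .lawson_weights(mb$C, mb$auc, cv, w0, settings$lawson_iterations)
    r <- (cv^2 * drop((mb$C^2) %*% w^2) +
            (mb$auc - drop(mb$C %*% w))^2) / mb$auc^2
    list(w = w, value = max(r))
  }
  for (i in seq_len(min(settings$outer_starts, length(starts)))) {
    quad <- starts[[i]]$quad
    x <- .x_from_knots(quad$knots, T, fixed_end = FALSE)
    w_prev <- quad$weights
    theta_new <- NULL
    for (round in seq_len(settings$exchange_rounds)) {
      Vfun <- function(x) solve_weights(.knots_from_x(x, T, FALSE),
                                        w_prev)$value
      fit <- try(if (length(x) == 1L)
        stats::optim(x, Vfun, method = "Brent", lower = -6, upper = 6)
      else
        stats::optim(x, Vfun, method = "Nelder-Mead",
                     control = list(maxit = nm_it, reltol = 1e-12)),
        silent = TRUE)
      if (!inherits(fit, "try-error")) x <- fit$par
      knots <- .knots_from_x(x, T, FALSE)
      sw <- solve_weights(knots, w_prev)
      w_prev <- sw$w
      quad_r <- quadrature(knots, sw$w, kind = "lc",
                           interval = model$interval)
      sc <- .score_candidate(quad_r, model, box, cv, settings,
                             label = sprintf("%s_round%d",
                                             starts[[i]]$label, round),
                             extra_starts = theta_new)
      candidates[[length(candidates) + 1L]] <- sc
      theta_new <- list(sc$mr$theta_star)
      working$Theta <- rbind(working$Theta,
                             matrix(sc$mr$theta_star, nrow = 1))
      # certified when the continuum worst case matches the working set
      if (sc$value <= sw$value * (1 + 1e-6)) break
    }
  }
  .minimax_result(model, box, cv, settings, candidates,
                  converged = TRUE, kind = "optimal_lc")
}
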