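# Parameter boxes: bounds, linear inequality constraints, and a smooth
# reparameterization of the feasible region used by every optimizer in the
# package.

#' Parameter box with optional linear constraints
#'
#' A hyper-rectangle of admissible parameter values, optionally intersected
#' with linear inequality constraints \eqn{a^T \theta \ge b}.  Constraints
#' may be given as structured lists or as strings such as
#' \code{"ka >= 2*ke"}.
#'
#' @param lower,upper named numeric vectors of per-parameter bounds.
#' @param constraints list of constraints; each element is either a string
#'   (\code{"<par> >= <coef>*<par>"} or \code{"<par> >= <number>"}) or a
#'   list with elements \code{coef} (named numeric) and \code{rhs}, meaning
#'   \code{sum(coef * theta) >= rhs}.
#' @return an object of class \code{"parameter_box"}.
#' @examples
#' parameter_box(c(ka = log(2) / 4, ke = log(2) / 12),
#'               c(ka = 3 * log(2), ke = log(2) / 4),
#'               constraints = list("ka >= 2*ke"))
#' @export
parameter_box <- function(lower, upper, constraints = list()) {
  if (is.null(names(lower)) || is.null(names(upper)))
    stop("`lower` and `upper` must be named numeric vectors.", call. = FALSE)
  if (!setequal(names(lower), names(upper)))
    stop("`lower` and `upper` must have the same names.", call. = FALSE)
  upper <- upper[names(lower)]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower > upper))
    stop("Bounds must be finite with lower <= upper elementwise.",
         call. = FALSE)
  cons <- lapply(constraints, .parse_constraint, parameters = names(lower))
  box <- structure(list(lower = lower, upper = upper, constraints = cons),
                   class = "parameter_box")
  # satisfiability: the reparameterized feasible region must be non-empty
  sp <- .param_space(box)
  mid <- sp$to_theta((sp$lower + sp$upper) / 2)
  if (!box_contains(box, mid, tol = 1e-9))
    stop("Constraints are not satisfiable within the bounds.", call. = FALSE)
  box
}

.parse_constraint <- function(con, parameters) {
  if (is.character(con)) {
    s <- gsub("[[:space:]]", "", con)
    m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9_]*)>=(.*)$", s))[[1]]
    if (length(m) != 3L)
      stop("Cannot parse constraint string: ", con, call. = FALSE)
    lhs <- m[2]; rhs <- m[3]
    coef <- stats::setNames(numeric(length(parameters)), parameters)
    if (!(lhs %in% parameters))
      stop("Unknown parameter in constraint: ", lhs, call. = FALSE)
    coef[lhs] <- 1
    mr <- regmatches(rhs,
                     regexec("^([0-9.]+)\\*([A-Za-z][A-Za-z0-9_]*)$", rhs))[[1]]
    if (length(mr) == 3L) {
      if (!(mr[3] %in% parameters))
        stop("Unknown parameter in constraint: ", mr[3], call. = FALSE)
      coef[mr[3]] <- -as.numeric(mr[2])
      return(list(coef = coef, rhs = 0))
    }
    val <- suppressWarnings(as.numeric(rhs))
    if (is.na(val))
      stop("Cannot parse constraint string: ", con, call. = FALSE)
    return(list(coef = coef, rhs = val))
  }
  if (!is.list(con) || is.null(con$coef) || is.null(con$rhs))
    stop("Constraints must be strings or list(coef=, rhs=).", call. = FALSE)
  coef <- stats::setNames(numeric(length(parameters)), parameters)
  if (is.null(names(con$coef)) ||
      !all(names(con$coef) %in% parameters))
    stop("Constraint coefficients must be named after box parameters.",
         call. = FALSE)
  coef[names(con$coef)] <- con$coef
  list(coef = coef, rhs = as.numeric(con$rhs))
}

#' @export
print.parameter_box <- function(x, ...) {
  cat("Parameter box:\n")
  for (nm in names(x$lower))
    cat(sprintf("  %-6s [%g, %g]\n", nm, x$lower[[nm]], x$upper[[nm]]))
  for (cn in x$constraints) {
    nz <- cn$coef[cn$coef != 0]
    cat("  constraint:",
        paste(sprintf("%+g*%s", nz, names(nz)), collapse = " "),
        ">=", cn$rhs, "\n")
  }
  invisible(x)
}

#' Default parameter box of a model
#'
#' Standard ranges for the five models' free parameters.  For the
#' first-order-absorption models (1 and 2) the box is intersected by
#' default with the constraint \eqn{k_a \ge 2 k_e}, which keeps absorption
#' distinctly faster than elimination and excludes the degenerate
#' flip-flop boundary \eqn{k_a = k_e} where the single-dose concentration
#' (and hence AUC) collapses towards zero.
#'
#' @param model a \code{\link{pk_model}} or model id 1-5.
#' @param constrain_ka logical; impose \code{ka >= 2*ke} for models 1-2.
#' @return a \code{\link{parameter_box}}.
#' @export
default_box <- function(model, constrain_ka = TRUE) {
  id <- if (inherits(model, "pk_model")) model$model_id else as.integer(model)
  l2 <- log(2)
  switch(id,
    parameter_box(c(ka = l2 / 4, ke = l2 / 12),
                  c(ka = 3 * l2, ke = l2 / 4),
                  constraints = if (constrain_ka) list("ka >= 2*ke") else list()),
    parameter_box(c(ka = l2 / 4, ke = l2 / 12),
                  c(ka = 3 * l2, ke = l2 / 4),
                  constraints = if (constrain_ka) list("ka >= 2*ke") else list()),
    parameter_box(c(k1 = 0.5 * l2, k2 = l2 / 24, alpha = 0.8),
                  c(k1 = 6 * l2, k2 = l2 / 4, alpha = 1.25)),
    parameter_box(c(KM = 2, Vm = 0.2), c(KM = 20, Vm = 1)),
    parameter_box(c(KM = 2, Vm = 0.4, ka = l2 / 2),
                  c(KM = 5, Vm = 0.7, ka = l2)))
}

#' Test whether a parameter vector lies in a box
#'
#' @param box a \code{\link{parameter_box}}.
#' @param theta named parameter vector.
#' @param tol feasibility tolerance.
#' @export
box_contains <- function(box, theta, tol = 1e-9) {
  theta <- unlist(theta)[names(box$lower)]
  if (any(theta < box$lower - tol) || any(theta > box$upper + tol))
    return(FALSE)
  for (cn in box$constraints)
    if (sum(cn$coef * theta) < cn$rhs - tol) return(FALSE)
  TRUE
}

# All 2^p corner points of the bounds (ignoring constraints), as a matrix.
.box_corners <- function(box) {
  p <- length(box$lower)
  g <- as.matrix(expand.grid(rep(list(c(0, 1)), p)))
  corners <- sweep(g, 2, box$upper - box$lower, `*`)
  corners <- sweep(corners, 2, box$lower, `+`)
  colnames(corners) <- names(box$lower)
  corners
}

# Smooth bijection between the feasible region and a plain box ("z-space").
# Without constraints z = theta.  With a single constraint a^T theta >= b
# (the only case the shipped boxes need), the parameter with coefficient +1
# is replaced by u in [0, 1] interpolating between its
# constraint-dependent lower bound and its upper bound.
.param_space <- function(box) {
  nm <- names(box$lower); p <- length(nm)
  if (length(box$constraints) == 0L) {
    return(list(
      dim = p, names = nm, lower = box$lower, upper = box$upper,
      to_theta = function(z) stats::setNames(as.numeric(z), nm),
      to_theta_mat = function(Z) {
        Z <- as.matrix(Z); colnames(Z) <- nm; Z
      },
      from_theta = function(theta) unlist(theta)[nm],
      jacobian = function(z) diag(p)))
  }
  if (length(box$constraints) > 1L)
    stop("At most one linear constraint is supported by the optimizers.",
         call. = FALSE)
  cn <- box$constraints[[1]]
  i <- which(cn$coef == 1)
  if (length(i) != 1L)
    stop("The constraint must have coefficient +1 on exactly one parameter.",
         call. = FALSE)
  rest <- setdiff(seq_len(p), i)
  lo_i <- box$lower[[i]]; hi_i <- box$upper[[i]]
  Lfun <- function(th_rest) # lower bound of theta_i given the others
    pmax(lo_i, cn$rhs - drop(th_rest %*% cn$coef[rest]))
  zl <- c(box$lower[rest], u = 0)
  zu <- c(box$upper[rest], u = 1)
  list(
    dim = p, names = c(nm[rest], "u"), lower = zl, upper = zu,
    to_theta = function(z) {
      th <- stats::setNames(numeric(p), nm)
      th[rest] <- z[seq_along(rest)]
      L <- Lfun(matrix(th[rest], nrow = 1))
      th[i] <- L + z[p] * (hi_i - L)
      th
    },
    to_theta_mat = function(Z) {
      Z <- as.matrix(Z)
      Th <- matrix(0, nrow(Z), p, dimnames = list(NULL, nm))
      Th[, rest] <- Z[, seq_along(rest), drop = FALSE]
      L <- Lfun(Th[, rest, drop = FALSE])
      Th[, i] <- L + Z[, p] * (hi_i - L)
      Th
    },
    from_theta = function(theta) {
      theta <- unlist(theta)[nm]
      L <- Lfun(matrix(theta[rest], nrow = 1))
      u <- if (hi_i > L) (theta[[i]] - L) / (hi_i - L) else 0
      c(theta[rest], u = min(max(u, 0), 1))
    },
    jacobian = function(z) { # d theta / d z, p x p
      th <- stats::setNames(numeric(p), nm)
      th[rest] <- z[seq_along(rest)]
      L <- Lfun(matrix(th[rest], nrow = 1))
      J <- matrix(0, p, p)
      for (k in seq_along(rest)) J[rest[k], k] <- 1
      active <- (cn$rhs - sum(th[rest] * cn$coef[rest])) > lo_i
      if (active)
        for (k in seq_along(rest))
          J[i, k] <- (1 - z[p]) * (-cn$coef[rest][k])
      J[i, p] <- hi_i - L
      J
    })
}

#' Extremes of AUC over a parameter box
#'
#' Scans a dense grid of the feasible region (after mapping any linear
#' constraint onto a plain box) and polishes the best grid points with a
#' gradient-based local optimizer, returning the minimum and maximum AUC.
#' Fully deterministic.
#'
#' @param model a \code{\link{pk_model}}.
#' @param box a \code{\link{parameter_box}}; default \code{default_box(model)}.
#' @param grid_points grid density per axis; default 100 for two-parameter
#'   models and 40 for three-parameter models.
#' @param rtol ODE relative tolerance for the grid stage (the polish stage
#'   always uses tight tolerances).
#' @return list with elements \code{min}, \code{max}, \code{theta_min},
#'   \code{theta_max}, \code{grid_points}.
#' @examples
#' auc_range(pk_model(2))  # approx. c(57.7, 336.6)
#' @export
auc_range <- function(model, box = default_box(model), grid_points = NULL,
                      rtol = 1e-8) {
  sp <- .param_space(box)
  if (is.null(grid_points))
    grid_points <- if (sp$dim <= 2) 100L else 40L
  axes <- lapply(seq_len(sp$dim), function(j)
    seq(sp$lower[[j]], sp$upper[[j]], length.out = grid_points))
  Z <- as.matrix(expand.grid(axes))
  Theta <- sp$to_theta_mat(Z)
  vals <- .model_batch(model, Theta, times = model$interval[2],
                       rtol = rtol)$auc
  polish <- function(z0, sign) {
    obj <- function(z) sign * .model_eval(model, sp$to_theta(z),
                                          model$interval[2], deriv = 0)$auc
    grz <- function(z) {
      e <- .model_eval(model, sp$to_theta(z), model$interval[2], deriv = 1)
      sign * drop(crossprod(sp$jacobian(z), e$dauc))
    }
    fit <- stats::nlminb(z0, obj, gradient = grz,
                         lower = sp$lower, upper = sp$upper,
                         control = list(iter.max = 200))
    list(value = sign * fit$objective, theta = sp$to_theta(fit$par))
  }
  lo <- polish(Z[which.min(vals), ], +1)
  hi <- polish(Z[which.max(vals), ], -1)
  list(min = min(lo$value, vals), max = max(hi$value, vals),
       theta_min = lo$theta, theta_max = hi$theta,
       grid_points = grid_points)
}
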