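# LC quadratures: Q = sum(w_i * C(t_i)).  Trapezoid weights, linear
# extrapolation to time zero, Gauss-Legendre and Clenshaw-Curtis rules.

#' Construct an LC quadrature
#'
#' An LC ("linear combination") quadrature estimates an integral over a
#' finite interval as \eqn{Q = \sum_i w_i C(t_i)} with arbitrary real
#' weights.  Trapezoid, Gauss-Legendre and Clenshaw-Curtis rules are all
#' members of this class, as is the minimax-optimal rule returned by
#' \code{\link{optimize_lc}}.
#'
#' @param knots strictly increasing sampling times inside the interval.
#' @param weights real weights, one per knot (h); unconstrained in sign.
#' @param kind tag: one of \code{"trapezoid"}, \code{"trapezoid_extrapolated"},
#'   \code{"gauss_legendre"}, \code{"clenshaw_curtis"}, \code{"optimal_lc"},
#'   \code{"lc"}.
#' @param interval integration interval, default \code{c(0, 24)} h.
#' @return an object of class \code{"quadrature"} with fields \code{knots},
#'   \code{weights}, \code{kind}, \code{n} (number of sampled
#'   concentrations) and \code{interval}.
#' @export
quadrature <- function(knots, weights, kind = "lc", interval = c(0, 24)) {
  knots <- as.numeric(knots); weights <- as.numeric(weights)
  if (length(knots) < 1L)
    stop("A quadrature needs at least one knot.", call. = FALSE)
  if (length(weights) != length(knots))
    stop("`weights` must have one entry per knot.", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("Knots must be strictly increasing.", call. = FALSE)
  if (any(knots < interval[1] - 1e-9) || any(knots > interval[2] + 1e-9))
    stop("Knots must lie inside the interval [", interval[1], ", ",
         interval[2], "].", call. = FALSE)
  kinds <- c("trapezoid", "trapezoid_extrapolated", "gauss_legendre",
             "clenshaw_curtis", "optimal_lc", "lc")
  kind <- match.arg(kind, kinds)
  if (kind %in% c("trapezoid", "trapezoid_extrapolated") &&
      abs(knots[length(knots)] - interval[2]) > 1e-9)
    stop("Trapezoid rules must place the last knot at the end of the ",
         "interval (t = ", interval[2], ").", call. = FALSE)
  structure(list(knots = knots, weights = weights, kind = kind,
                 n = length(knots), interval = as.numeric(interval)),
            class = "quadrature")
}

#' @export
print.quadrature <- function(x, digits = 6, ...) {
  cat("LC quadrature (", x$kind, "), n = ", x$n, " on [",
      x$interval[1], ", ", x$interval[2], "]\n", sep = "")
  cat("  knots:  ", paste(signif(x$knots, digits), collapse = ", "), "\n")
  cat("  weights:", paste(signif(x$weights, digits), collapse = ", "), "\n")
  invisible(x)
}

#' Trapezoid-rule weights for given knots
#'
#' For strictly increasing knots \eqn{t_1 < \dots < t_n} the linear
#' trapezoid rule has weights \eqn{w_1 = (t_2 - t_1)/2},
#' \eqn{w_i = (t_{i+1} - t_{i-1})/2} for interior knots, and
#' \eqn{w_n = (t_n - t_{n-1})/2}; they telescope to
#' \eqn{\sum w_i = t_n - t_1}.
#'
#' @param knots strictly increasing numeric vector, length >= 2.
#' @return numeric vector of weights (h).
#' @examples
#' trapezoid_weights(c(0, 6, 12, 24))  # 3 6 9 6
#' @export
trapezoid_weights <- function(knots) {
  knots <- as.numeric(knots)
  n <- length(knots)
  if (n < 2L) stop("At least two knots are required.", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("Knots must be strictly increasing.", call. = FALSE)
  w <- numeric(n)
  w[1] <- (knots[2] - knots[1]) / 2
  if (n > 2L) w[2:(n - 1)] <- (knots[3:n] - knots[1:(n - 2)]) / 2
  w[n] <- (knots[n] - knots[n - 1]) / 2
  w
}

#' Weight adjustment for linear extrapolation to time zero
#'
#' When the first sample is taken at \eqn{t_1 > 0} but the model
#' concentration at time zero is positive, the area on \eqn{[0, t_1]} can
#' be recovered by extrapolating the line through the first two measured
#' concentrations back to \eqn{t = 0} and adding the trapezoid on
#' \eqn{[0, t_1]}.  Because the extrapolated intercept is itself a linear
#' combination of the first two concentrations, the correction stays inside
#' the LC class: it only increments the first two weights by
#' \deqn{\Delta w_1 = t_1 + t_1^2 / (2 (t_2 - t_1)), \qquad
#'       \Delta w_2 = - t_1^2 / (2 (t_2 - t_1)).}
#' The extrapolated point is not a sample and does not count towards
#' \eqn{n}.
#'
#' @param knots strictly increasing times, length >= 2.
#' @return numeric vector of length \code{length(knots)}: the weight
#'   increments (zero beyond the first two knots; all zero when
#'   \code{knots[1] == 0}).
#' @examples
#' extrapolate_to_zero_adjustment(c(2, 4, 6))  # 3 -1 0
#' @export
extrapolate_to_zero_adjustment <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 2L) stop("At least two knots are required.",
                               call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("Knots must be strictly increasing.", call. = FALSE)
  d <- numeric(length(knots))
  t1 <- knots[1]
  if (t1 == 0) return(d)
  if (t1 < 0) stop("Knots must be non-negative.", call. = FALSE)
  gap <- knots[2] - knots[1]
  d[1] <- t1 + t1^2 / (2 * gap)
  d[2] <- -t1^2 / (2 * gap)
  d
}

#' Trapezoid quadrature on given knots
#'
#' Convenience constructor combining \code{\link{trapezoid_weights}} with
#' the optional \code{\link{extrapolate_to_zero_adjustment}}.
#'
#' @param knots strictly increasing times whose last element is the end of
#'   the interval.
#' @param extrapolate logical; add the linear extrapolation-to-zero weight
#'   correction (only meaningful for models with positive concentration at
#'   time zero).
#' @param interval integration interval.
#' @return a \code{\link{quadrature}}.
#' @export
trapezoid_quadrature <- function(knots, extrapolate = FALSE,
                                 interval = c(0, 24)) {
  w <- trapezoid_weights(knots)
  kind <- "trapezoid"
  if (extrapolate && knots[1] > 0) {
    w <- w + extrapolate_to_zero_adjustment(knots)
    kind <- "trapezoid_extrapolated"
  }
  quadrature(knots, w, kind = kind, interval = interval)
}

#' Gauss-Legendre quadrature on an interval
#'
#' Standard Gauss-Legendre nodes and weights affinely mapped onto the
#' interval; exact for polynomials of degree up to \eqn{2n - 1}.
#'
#' @param n number of knots, >= 1.
#' @param interval integration interval.
#' @return a \code{\link{quadrature}}.
#' @export
gauss_legendre <- function(n, interval = c(0, 24)) {
  if (n < 1) stop("Gauss-Legendre requires n >= 1.", call. = FALSE)
  a <- interval[1]; b <- interval[2]
  if (n == 1L) {
    knots <- (a + b) / 2; w <- b - a
  } else {
    gl <- pracma::gaussLegendre(n, a, b)
    knots <- gl$x; w <- gl$w
    o <- order(knots); knots <- knots[o]; w <- w[o]
  }
  quadrature(knots, w, kind = "gauss_legendre", interval = interval)
}

#' Clenshaw-Curtis quadrature on an interval
#'
#' Classical closed Clenshaw-Curtis rule on the Chebyshev extrema
#' (both endpoints included), exact for polynomials of degree up to
#' \eqn{n - 1}; weights sum to the interval length.
#'
#' @param n number of knots, >= 2.
#' @param interval integration interval.
#' @return a \code{\link{quadrature}}.
#' @export
clenshaw_curtis <- function(n, interval = c(0, 24)) {
  if (n < 2) stop("Clenshaw-Curtis requires n >= 2.", call. = FALSE)
  N <- n - 1L
  k <- 0:N
  x <- cos(k * pi / N)                  # 1 .. -1
  w <- numeric(n)
  jmax <- N %/% 2L
  j <- seq_len(jmax)
  b <- ifelse(j == N / 2, 1, 2)
  for (i in seq_along(k)) {
    s <- if (jmax > 0) sum(b / (4 * j^2 - 1) * cos(2 * j * k[i] * pi / N)) else 0
    ck <- if (k[i] %in% c(0L, N)) 1 else 2
    w[i] <- ck / N * (1 - s)
  }
  a <- interval[1]; bb <- interval[2]
  knots <- a + (bb - a) * (1 - x) / 2   # ascending
  quadrature(knots, rev(w) * (bb - a) / 2, kind = "clenshaw_curtis",
             interval = interval)
}

#' Apply an LC quadrature to measured concentrations
#'
#' @param quad a \code{\link{quadrature}}.
#' @param concentrations numeric vector, one value per knot (or a matrix
#'   with one column per knot for many profiles at once).
#' @return the estimate \eqn{\sum_i w_i C_i} (vector for matrix input).
#' @examples
#' q <- trapezoid_quadrature(c(0, 6, 12, 24))
#' estimate(q, c(10, 5, 2, 1))  # 84
#' @export
estimate <- function(quad, concentrations) {
  stopifnot(inherits(quad, "quadrature"))
  if (is.matrix(concentrations)) {
    if (ncol(concentrations) != quad$n)
      stop("Need one concentration column per knot.", call. = FALSE)
    return(drop(concentrations %*% quad$weights))
  }
  if (length(concentrations) != quad$n)
    stop("Need one concentration per knot.", call. = FALSE)
  sum(quad$weights * concentrations)
}

# ---- design-file (JSON) I/O ------------------------------------------------

#' Write a design to a JSON file
#'
#' Serializes a quadrature -- or a full \code{\link{optimize_lc}} /
#' \code{\link{optimize_trapezoid}} / \code{\link{max_risk}} result -- at
#' full double precision.
#'
#' @param x a \code{quadrature} or \code{minimax_result}.
#' @param path output file path.
#' @param model_id,cv optional metadata stored in the file (taken from the
#'   result object when available).
#' @return \code{path}, invisibly.
#' @export
write_design <- function(x, path, model_id = NA_integer_, cv = NA_real_) {
  if (inherits(x, "minimax_result")) {
    rec <- list(model = x$model_id, n = x$quadrature$n, cv = x$cv,
                kind = x$quadrature$kind,
                knots = x$quadrature$knots, weights = x$quadrature$weights,
                objective = x$objective,
                theta_star = as.list(x$theta_star))
  } else if (inherits(x, "quadrature")) {
    rec <- list(model = model_id, n = x$n, cv = cv, kind = x$kind,
                knots = x$knots, weights = x$weights,
                objective = NA_real_, theta_star = NULL)
  } else stop("`x` must be a quadrature or minimax_result.", call. = FALSE)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a design from a JSON file
#'
#' @param path file written by \code{\link{write_design}}.
#' @return a list with the \code{quadrature} plus the stored metadata
#'   (\code{model}, \code{cv}, \code{objective}, \code{theta_star}).
#' @export
read_design <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  quad <- quadrature(rec$knots, rec$weights, kind = rec$kind)
  list(quadrature = quad, model = rec$model, cv = rec$cv,
       objective = rec$objective,
       theta_star = if (!is.null(rec$theta_star)) unlist(rec$theta_star))
}
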