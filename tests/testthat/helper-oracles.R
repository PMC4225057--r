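# Shared oracles and fixtures, all built in code.

# Central finite-difference gradient of a scalar- or vector-valued f.
fd_gradient <- function(f, x, rel = 1e-6) {
  sapply(seq_along(x), function(j) {
    h <- rel * max(abs(x[j]), 1e-3)
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  })
}

rel_err <- function(a, b, floor = 1e-8) max(abs(a - b) / pmax(abs(b), floor))

# Independent bisection solve of the Michaelis-Menten implicit relation
# KM log(C/C0) + (C - C0) = -Vm t.
mm_bisect <- function(KM, Vm, C0, t, tol = 1e-12) {
  f <- function(C) KM * log(C / C0) + C - C0 + Vm * t
  lo <- 1e-12; hi <- C0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Interior test points per model
interior_theta <- function(id) {
  switch(id,
         c(ka = 1.2, ke = 0.12),
         c(ka = 1.2, ke = 0.12),
         c(k1 = 1.0, k2 = 0.1, alpha = 1.0),
         c(KM = 8, Vm = 0.6),
         c(KM = 3.5, Vm = 0.55, ka = 0.6))
}

cheap_settings <- function(...) {
  base <- list(inner_starts = 4, outer_starts = 1,
               exchange_rounds = 2, nm_iterations = 300,
               lawson_iterations = 40, max_iterations = 60,
               grid_points = 12)
  do.call(optimizer_settings, utils::modifyList(base, list(...)))
}
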