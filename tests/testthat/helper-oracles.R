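# Independent oracles used across the suite.

# Crowley-Martin response with the *expanded* denominator (the implementation
# uses the factored form).
predation_expanded <- function(x, y, p) {
  p$beta * x * y / (1 + p$a * x + p$b * y + p$a * p$b * x * y)
}

# central finite-difference Jacobian of the reaction terms
fd_jacobian <- function(s, p, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    sp <- s; sm <- s
    sp[j] <- sp[j] + h
    sm[j] <- sm[j] - h
    J[, j] <- (reaction_rhs(sp, p) - reaction_rhs(sm, p)) / (2 * h)
  }
  J
}

# dimensional reaction right-hand side (prey, predator), for checking the
# nondimensionalization against the dimensionless model
dimensional_rhs <- function(X, Y, dpars) {
  with(dpars, {
    den <- 1 + A * X + B * Y + A * B * X * Y
    c(R * X * (1 - X / K) * (X - L) - M * X * Y / den,
      E * M * X * Y / den - D * Y)
  })
}

# brute-force interior-equilibrium finder for the logistic (no-Allee) model:
# scan x, take y from the predator nullcline, bracket sign changes of the
# prey nullcline residual and polish with uniroot
grid_search_no_allee <- function(p, x_max = 1.2, res = 1e-3) {
  xs <- seq(res, x_max, by = res)
  ys <- (p$beta * xs - (1 + p$a * xs) * p$d) / (p$b * p$d * (1 + p$a * xs))
  f <- (1 - xs) - p$beta * ys / ((1 + p$a * xs) * (1 + p$b * ys))
  ok <- ys > 0
  roots <- numeric(0)
  idx <- which(ok[-length(ok)] & ok[-1] & f[-length(f)] * f[-1] < 0)
  for (i in idx) {
    g <- function(x) {
      y <- (p$beta * x - (1 + p$a * x) * p$d) / (p$b * p$d * (1 + p$a * x))
      (1 - x) - p$beta * y / ((1 + p$a * x) * (1 + p$b * y))
    }
    roots <- c(roots, stats::uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-12)$root)
  }
  roots
}

# copy of a parameter set with beta nudged by delta
.beta_shift <- function(p, delta) {
  model_params(l = p$l, beta = p$beta + delta, a = p$a, b = p$b, d = p$d,
               allee = p$allee)
}

# random valid Allee-model parameter set
random_params <- function() {
  model_params(l = stats::runif(1, -0.5, 0.8),
               beta = stats::runif(1, 0.2, 12),
               a = stats::runif(1, 0.1, 12),
               b = stats::runif(1, 0.1, 6),
               d = stats::runif(1, 0.05, 1))
}
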