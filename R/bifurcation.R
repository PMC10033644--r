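# Bifurcation analysis in the capture rate beta: Hopf (trace zero crossing on
# a followed coexistence branch) and fold (nullcline tangency, Q = Q' = 0).

.with_beta <- function(p, beta) {
  p$beta <- beta
  p
}

# coexistence branch value at a given beta, tracked by nearest x to x_prev;
# errors if the branch count changes (collision inside the bracket)
.branch_at <- function(p, beta, x_prev, n_expect) {
  eqs <- coexistence_equilibria(.with_beta(p, beta))
  if (length(eqs) != n_expect)
    stop("coexistence branch collision: equilibrium count changed from ",
         n_expect, " to ", length(eqs), " at beta = ", format(beta),
         call. = FALSE)
  xs <- vapply(eqs, `[[`, numeric(1), "x")
  eqs[[which.min(abs(xs - x_prev))]]
}

#' Hopf bifurcation point in the capture rate
#'
#' Follows one coexistence-equilibrium branch across a bracket in `beta`
#' (continued by nearest prey level from the left endpoint) and locates the
#' zero crossing of the Jacobian trace. At the returned critical value
#' `beta_c` the trace vanishes, so the eigenvalues are a purely imaginary
#' pair `+/- i*omega0` with `omega0 = sqrt(det J)` provided `det J > 0`
#' (`valid`). The transversality value is the total derivative of the trace
#' along the branch, estimated by central finite differences; a nonzero
#' value confirms the eigenvalue pair crosses the imaginary axis with
#' nonvanishing speed, so a Hopf bifurcation occurs at `beta_c`.
#'
#' @param p a [model_params()] object supplying `l, a, b, d` (its `beta` is
#'   ignored); `allee = TRUE` and `allee = FALSE` are both supported.
#' @param bracket length-2 numeric, the `beta` search interval.
#' @param which index (ascending `x`) of the branch to follow when several
#'   coexistence equilibria exist at the left endpoint.
#' @param n_grid number of continuation steps across the bracket.
#' @param tol root tolerance on `beta`.
#' @return An object of class `"hopf_result"`: list with `found`, `beta_c`,
#'   `omega0`, `transversality`, `valid` (det > 0 at criticality), and the
#'   critical `equilibrium`. When the trace does not change sign in the
#'   bracket, `found = FALSE` and `beta_c = NA`.
#' @examples
#' p <- model_params(l = 0.04, beta = 1, a = 0.5, b = 1.0, d = 0.3)
#' hopf_critical_beta(p, bracket = c(0.9, 1.2))
#' @export
hopf_critical_beta <- function(p, bracket, which = 1L, n_grid = 41L,
                               tol = 1e-12) {
  stopifnot(inherits(p, "model_params"), length(bracket) == 2,
            bracket[1] < bracket[2])
  interior <- function(q) if (q$allee) coexistence_equilibria(q) else
    no_allee_equilibria(q)
  eqs0 <- interior(.with_beta(p, bracket[1]))
  if (!length(eqs0))
    stop("no coexistence equilibrium at the left bracket endpoint",
         call. = FALSE)
  if (which > length(eqs0)) stop("branch index out of range", call. = FALSE)
  n_expect <- length(eqs0)
  branch <- if (p$allee) {
    function(beta, x_prev) .branch_at(p, beta, x_prev, n_expect)
  } else {
    function(beta, x_prev) {
      eqs <- no_allee_equilibria(.with_beta(p, beta))
      if (length(eqs) != n_expect)
        stop("coexistence branch collision at beta = ", format(beta),
             call. = FALSE)
      xs <- vapply(eqs, `[[`, numeric(1), "x")
      eqs[[which.min(abs(xs - x_prev))]]
    }
  }
  tr_at <- function(beta, x_prev) {
    eq <- branch(beta, x_prev)
    J <- jacobian_matrix(c(eq$x, eq$y), .with_beta(p, beta))
    list(tr = J[1, 1] + J[2, 2], det = J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1],
         eq = eq)
  }
  betas <- seq(bracket[1], bracket[2], length.out = n_grid)
  x_prev <- eqs0[[which]]$x
  trs <- numeric(n_grid)
  for (i in seq_len(n_grid)) {
    z <- tr_at(betas[i], x_prev)
    trs[i] <- z$tr
    x_prev <- z$eq$x
  }
  flip <- which(trs[-n_grid] * trs[-1] <= 0 & abs(trs[-n_grid]) > 0)
  if (!length(flip))
    return(structure(list(found = FALSE, beta_c = NA_real_, omega0 = NA_real_,
                          transversality = NA_real_, valid = FALSE,
                          equilibrium = NULL),
                     class = "hopf_result"))
  i <- flip[1]
  x_seed <- NULL
  f <- function(beta) {
    z <- tr_at(beta, if (is.null(x_seed)) x_prev else x_seed)
    x_seed <<- z$eq$x
    z$tr
  }
  x_seed <- tr_at(betas[i], x_prev)$eq$x
  beta_c <- stats::uniroot(f, c(betas[i], betas[i + 1]), tol = tol)$root
  zc <- tr_at(beta_c, x_seed)
  h <- 1e-6 * max(1, abs(beta_c))
  slope <- (tr_at(beta_c + h, zc$eq$x)$tr - tr_at(beta_c - h, zc$eq$x)$tr) /
    (2 * h)
  structure(list(found = TRUE, beta_c = beta_c,
                 omega0 = if (zc$det > 0) sqrt(zc$det) else NA_real_,
                 transversality = slope, valid = zc$det > 0,
                 equilibrium = classify_equilibrium(zc$eq,
                                                    .with_beta(p, beta_c))),
            class = "hopf_result")
}

#' @export
print.hopf_result <- function(x, ...) {
  if (!x$found) cat("<hopf_result> no trace sign change in bracket\n")
  else cat(sprintf(
    "<hopf_result> beta_c = %.12g, omega0 = %.6g, d(tr)/d(beta) = %.4g%s\n",
    x$beta_c, x$omega0, x$transversality,
    if (x$valid) "" else " [det <= 0: not a Hopf point]"))
  invisible(x)
}

#' Fold (saddle-node) bifurcation of coexistence equilibria
#'
#' Locates the value `beta_sn` at which two coexistence equilibria collide:
#' the prey level `x_t` is then a double root of the quartic `Q`
#' ([quartic_coefficients()]), i.e. `Q(x_t) = Q'(x_t) = 0`. The transition is
#' first bracketed by bisection on the coexistence-equilibrium count, then
#' refined by Newton iteration on the 2x2 system `(Q, Q') = 0` in `(x, beta)`
#' (only `k1` depends on `beta`, with `dQ/dbeta = x`).
#'
#' @param p a [model_params()] object (`allee = TRUE`) supplying
#'   `l, a, b, d`; its `beta` is ignored.
#' @param bracket length-2 numeric `beta` interval whose endpoints have
#'   different coexistence counts.
#' @return An object of class `"fold_result"`: list with `beta_sn`,
#'   `x_tangency`, `y_tangency`, `counts` (counts just below/above the fold)
#'   and `residual` (max of |Q|, |Q'| at the solution).
#' @examples
#' p <- model_params(l = 0.2, beta = 9, a = 7.5, b = 4.1, d = 0.7)
#' fold_beta(p, bracket = c(9, 10.7))
#' @export
fold_beta <- function(p, bracket) {
  stopifnot(inherits(p, "model_params"), length(bracket) == 2,
            bracket[1] < bracket[2])
  if (!p$allee)
    stop("fold tracking uses the quartic of the Allee model", call. = FALSE)
  count <- function(beta) length(coexistence_equilibria(.with_beta(p, beta)))
  lo <- bracket[1]; hi <- bracket[2]
  c_lo <- count(lo); c_hi <- count(hi)
  if (c_lo == c_hi)
    stop("no fold: coexistence counts agree (", c_lo, ") at both endpoints",
         call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (count(mid) == c_lo) lo <- mid else hi <- mid
  }
  beta <- (lo + hi) / 2
  # seed x at the near-double root: positive real root minimizing |Q'|
  q <- quartic_coefficients(.with_beta(p, beta))
  roots <- .positive_real_roots(q, im_tol = 1e-3, merge_tol = 0)
  if (!nrow(roots)) stop("no positive root near the fold", call. = FALSE)
  x <- roots$x[which.min(abs(eval_poly_deriv(q, roots$x)))]
  for (it in 1:60) {
    q <- quartic_coefficients(.with_beta(p, beta))
    F <- c(eval_poly(q, x), eval_poly_deriv(q, x))
    J <- matrix(c(eval_poly_deriv(q, x), x,
                  eval_poly_deriv(q, x, 2L), 1), 2, 2, byrow = TRUE)
    dz <- solve(J, -F)
    x <- x + dz[1]; beta <- beta + dz[2]
    if (max(abs(dz)) < 1e-15) break
  }
  q <- quartic_coefficients(.with_beta(p, beta))
  y <- (beta * x - (1 + p$a * x) * p$d) / (p$b * p$d * (1 + p$a * x))
  eps <- 1e-9 * max(1, abs(beta))
  structure(list(beta_sn = beta, x_tangency = x, y_tangency = y,
                 counts = c(below = count(beta - eps), above = count(beta + eps)),
                 residual = max(abs(eval_poly(q, x)),
                                abs(eval_poly_deriv(q, x)))),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf(
    "<fold_result> beta_sn = %.15g at x = %.10g (counts %d -> %d)\n",
    x$beta_sn, x$x_tangency, x$counts[1], x$counts[2]))
  invisible(x)
}
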