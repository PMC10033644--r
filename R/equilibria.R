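#' Quartic whose positive roots are the coexistence prey levels
#'
#' For the Allee model, eliminating the predator nullcline
#' `y*(x) = (beta*x - (1+a*x)*d) / (b*d*(1+a*x))` from the prey nullcline
#' leaves a quartic `Q(x) = k4 x^4 + k3 x^3 + k2 x^2 + k1 x + k0` with
#' `k4 = a*b`, `k3 = b*(1 - a*(1+l))`, `k2 = -b*(1+l) + l*a*b`,
#' `k1 = l*b + beta - a*d`, `k0 = -d`.
#'
#' @param p a [model_params()] object with `allee = TRUE`.
#' @return An object of class `"quartic"`: named numeric vector
#'   `c(k0, k1, k2, k3, k4)` (ascending powers, as [polyroot()] expects).
#' @export
quartic_coefficients <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (!p$allee)
    stop("the quartic reduction applies to the Allee model only; ",
         "see no_allee_equilibria()", call. = FALSE)
  structure(c(k0 = -p$d,
              k1 = p$l * p$b + p$beta - p$a * p$d,
              k2 = -p$b * (1 + p$l) + p$l * p$a * p$b,
              k3 = p$b * (1 - p$a * (1 + p$l)),
              k4 = p$a * p$b),
            class = "quartic")
}

#' Evaluate a quartic and its first two derivatives
#' @param q a `"quartic"` (or any ascending coefficient vector).
#' @param x evaluation point(s).
#' @return numeric.
#' @keywords internal
eval_poly <- function(q, x) {
  pow <- seq_along(q) - 1L
  vapply(x, function(z) sum(unclass(q) * z^pow), numeric(1))
}

eval_poly_deriv <- function(q, x, order = 1L) {
  q <- unclass(q)
  for (i in seq_len(order)) q <- q[-1] * seq_along(q[-1])
  eval_poly(q, x)
}

# real positive roots of an ascending-coefficient polynomial, Newton-polished,
# near-duplicates merged into one root with a multiplicity count
.positive_real_roots <- function(coefs, im_tol = 1e-8, merge_tol = 1e-7) {
  r <- polyroot(coefs)
  re <- Re(r)[abs(Im(r)) < im_tol * pmax(1, abs(Re(r)))]
  re <- re[re > 0]
  if (!length(re)) return(data.frame(x = numeric(), multiplicity = integer()))
  # Newton polish, safeguarded: companion-matrix roots are already accurate
  # to ~1e-8, so any large proposed step means Q' ~ 0 (a multiple root) where
  # Newton would scatter the pair — skip polishing there
  for (i in seq_along(re)) {
    x <- re[i]
    for (it in 1:8) {
      fp <- eval_poly_deriv(coefs, x)
      if (abs(fp) < 1e-12) break
      step <- eval_poly(coefs, x) / fp
      if (!is.finite(step) || abs(step) > 1e-6) break
      x <- x - step
      if (abs(step) < 1e-15) break
    }
    if (x > 0) re[i] <- x
  }
  re <- sort(re)
  grp <- cumsum(c(TRUE, diff(re) > merge_tol))
  out <- data.frame(x = as.numeric(tapply(re, grp, mean)),
                    multiplicity = as.integer(table(grp)))
  # tangency-aware second pass: a close pair whose midpoint leaves the
  # polynomial at rounding level is an unresolvable double root (parameters
  # printed to finite precision cannot separate a nullcline tangency)
  if (nrow(out) > 1) {
    scale <- max(abs(coefs)) * max(1, max(abs(out$x))^(length(coefs) - 1))
    i <- 1L
    while (i < nrow(out)) {
      sep <- out$x[i + 1] - out$x[i]
      mid <- (out$x[i] + out$x[i + 1]) / 2
      if (sep < 1e-3 && abs(eval_poly(coefs, mid)) < 1e-10 * scale) {
        out$x[i] <- mid
        out$multiplicity[i] <- out$multiplicity[i] + out$multiplicity[i + 1]
        out <- out[-(i + 1), , drop = FALSE]
      } else i <- i + 1L
    }
  }
  out
}

.equilibrium <- function(x, y, kind, multiplicity = 1L) {
  structure(list(x = x, y = y, kind = kind,
                 multiplicity = as.integer(multiplicity),
                 eigenvalues = NULL, stability = NA_character_),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium %s> (x, y) = (%.10g, %.10g)", x$kind, x$x, x$y))
  if (x$multiplicity > 1L) cat(sprintf(" [multiplicity %d]", x$multiplicity))
  if (!is.na(x$stability)) cat(" -", x$stability)
  cat("\n")
  invisible(x)
}

#' Coexistence equilibria of the Allee model
#'
#' Finds every interior steady state `(x*, y*)` with `x* > 0`, `y* > 0`:
#' `x*` ranges over the positive real roots of the quartic
#' ([quartic_coefficients()]) and `y*` follows from the predator nullcline
#' `y* = (beta*x* - (1+a*x*)*d) / (b*d*(1+a*x*))`. Roots whose `y*` is not
#' strictly positive are dropped (this subsumes the side condition
#' `beta > a*d`). A nullcline tangency appears as a single equilibrium with
#' `multiplicity = 2`.
#'
#' @param p a [model_params()] object with `allee = TRUE`.
#' @return A list of `"equilibrium"` objects sorted by increasing `x`
#'   (possibly empty).
#' @examples
#' coexistence_equilibria(model_params(l = 0.01, beta = 7.8, a = 10.5,
#'                                     b = 5.2, d = 0.3))
#' @export
coexistence_equilibria <- function(p) {
  q <- quartic_coefficients(p)
  roots <- .positive_real_roots(q)
  out <- list()
  for (i in seq_len(nrow(roots))) {
    x <- roots$x[i]
    y <- (p$beta * x - (1 + p$a * x) * p$d) / (p$b * p$d * (1 + p$a * x))
    if (y > 1e-12)
      out[[length(out) + 1L]] <-
        .equilibrium(x, y, "coexistence", roots$multiplicity[i])
  }
  out
}

#' Boundary equilibria
#'
#' The total-extinction state `E0 = (0, 0)` and the prey-only state
#' `E1 = (1, 0)` always exist. Under a strong Allee effect the threshold
#' state `E2 = (l, 0)` is reported when `0 < l < 1`; outside that range it
#' lies outside the admissible quadrant or collides with `E1`.
#'
#' @param p a [model_params()] object.
#' @return A list of `"equilibrium"` objects.
#' @export
boundary_equilibria <- function(p) {
  stopifnot(inherits(p, "model_params"))
  out <- list(.equilibrium(0, 0, "trivial"),
              .equilibrium(1, 0, "axial prey"))
  if (p$allee && is.finite(p$l) && p$l > 0 && p$l < 1)
    out[[3]] <- .equilibrium(p$l, 0, "axial threshold")
  out
}

#' Coexistence equilibria of the logistic (no-Allee) model
#'
#' With logistic prey growth the same nullcline elimination yields a cubic
#' `a*b*x^3 + b*(1-a)*x^2 + (beta - a*d - b)*x - d = 0`; positive roots with
#' positive `y*` (same formula as the Allee case) are the interior states.
#'
#' @param p a [model_params()] object with `allee = FALSE`.
#' @return A list of `"equilibrium"` objects sorted by increasing `x`.
#' @export
no_allee_equilibria <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (p$allee)
    stop("no_allee_equilibria() requires allee = FALSE; ",
         "see coexistence_equilibria()", call. = FALSE)
  coefs <- c(-p$d, p$beta - p$a * p$d - p$b, p$b * (1 - p$a), p$a * p$b)
  roots <- .positive_real_roots(coefs)
  out <- list()
  for (i in seq_len(nrow(roots))) {
    x <- roots$x[i]
    y <- (p$beta * x - (1 + p$a * x) * p$d) / (p$b * p$d * (1 + p$a * x))
    if (y > 1e-12)
      out[[length(out) + 1L]] <-
        .equilibrium(x, y, "coexistence", roots$multiplicity[i])
  }
  out
}

#' All equilibria, classified
#'
#' Convenience wrapper: boundary plus interior equilibria (dispatching on the
#' Allee flag), each classified by [classify_equilibrium()].
#'
#' @param p a [model_params()] object.
#' @return A list of classified `"equilibrium"` objects.
#' @export
all_equilibria <- function(p) {
  interior <- if (p$allee) coexistence_equilibria(p) else no_allee_equilibria(p)
  lapply(c(boundary_equilibria(p), interior), classify_equilibrium, p = p)
}

#' Tabulate a list of equilibria
#'
#' @param eqs a list of `"equilibrium"` objects.
#' @return A data.frame with columns `x`, `y`, `kind`, `multiplicity`,
#'   `eigenvalue1_re`, `eigenvalue1_im`, `eigenvalue2_re`, `eigenvalue2_im`,
#'   `stability`.
#' @export
equilibria_table <- function(eqs) {
  ev <- function(e, i, part) {
    if (is.null(e$eigenvalues)) NA_real_ else part(e$eigenvalues[i])
  }
  data.frame(
    x = vapply(eqs, `[[`, numeric(1), "x"),
    y = vapply(eqs, `[[`, numeric(1), "y"),
    kind = vapply(eqs, `[[`, character(1), "kind"),
    multiplicity = vapply(eqs, `[[`, integer(1), "multiplicity"),
    eigenvalue1_re = vapply(eqs, ev, numeric(1), i = 1, part = Re),
    eigenvalue1_im = vapply(eqs, ev, numeric(1), i = 1, part = Im),
    eigenvalue2_re = vapply(eqs, ev, numeric(1), i = 2, part = Re),
    eigenvalue2_im = vapply(eqs, ev, numeric(1), i = 2, part = Im),
    stability = vapply(eqs, `[[`, character(1), "stability")
  )
}
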