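#' Classify the local stability of an equilibrium
#'
#' Routh-Hurwitz classification from the trace, determinant and discriminant
#' of the reaction Jacobian at the equilibrium: a saddle iff `det < 0`;
#' otherwise stable/unstable by the sign of the trace and node/focus by the
#' sign of `tr^2 - 4 det`. States with `|tr| < tr_tol` and `det > 0`, or
#' `|det| < det_tol`, are labelled `"marginal"` (a Hopf or fold point up to
#' numerical tolerance).
#'
#' @param eq an `"equilibrium"` object (see [coexistence_equilibria()]).
#' @param p a [model_params()] object.
#' @param tr_tol,det_tol marginality tolerances.
#' @return The equilibrium with `eigenvalues` (complex pair) and `stability`
#'   filled in; one of `"stable node"`, `"stable focus"`, `"unstable node"`,
#'   `"unstable focus"`, `"saddle"`, `"marginal"`.
#' @examples
#' p <- model_params(l = 0.1, beta = 9.8, a = 7.8, b = 4.1, d = 0.7)
#' classify_equilibrium(boundary_equilibria(p)[[1]], p)
#' @export
classify_equilibrium <- function(eq, p, tr_tol = 1e-9, det_tol = 1e-12) {
  stopifnot(inherits(eq, "equilibrium"), inherits(p, "model_params"))
  J <- jacobian_matrix(c(eq$x, eq$y), p)
  tr <- J[1, 1] + J[2, 2]
  det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * det
  root <- sqrt(as.complex(disc))
  eq$eigenvalues <- c((tr + root) / 2, (tr - root) / 2)
  eq$stability <-
    if (abs(det) < det_tol || (abs(tr) < tr_tol && det > 0)) "marginal"
    else if (det < 0) "saddle"
    else if (tr < 0 && disc >= 0) "stable node"
    else if (tr < 0) "stable focus"
    else if (disc >= 0) "unstable node"
    else "unstable focus"
  eq
}

#' Closed-form boundary eigenvalues
#'
#' Eigenvalues of the reaction Jacobian at the boundary states of the Allee
#' model, in closed form: `(-l, -d)` at `(0,0)`; `(l-1, beta/(1+a) - d)` at
#' `(1,0)`; `(l(1-l), beta*l/(1+a*l) - d)` at `(l,0)`. Provided for
#' cross-checks against the numerically computed Jacobian spectrum.
#'
#' Note the first eigenvalue at the threshold state `(l, 0)` is *positive*
#' for `0 < l < 1`: the strong-Allee threshold repels along the prey axis
#' (prey just above `l` grows, just below declines), so `(l, 0)` is a saddle
#' when `beta*l < d*(1 + a*l)` and an unstable node otherwise — it is never
#' attracting.
#'
#' @param p a [model_params()] object with `allee = TRUE`.
#' @param which one of `"E0"`, `"E1"`, `"E2"`.
#' @return numeric length-2 vector of eigenvalues.
#' @export
boundary_eigenvalues <- function(p, which = c("E0", "E1", "E2")) {
  stopifnot(inherits(p, "model_params"), p$allee)
  switch(match.arg(which),
    E0 = c(-p$l, -p$d),
    E1 = c(p$l - 1, p$beta / (1 + p$a) - p$d),
    E2 = c(p$l * (1 - p$l), p$beta * p$l / (1 + p$a * p$l) - p$d))
}
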