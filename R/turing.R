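# Linearized spatial analysis about a homogeneous coexistence state:
# dispersion relation, Turing instability conditions, parameter-space scans.

.jacobian_at <- function(p, eq) jacobian_matrix(c(eq$x, eq$y), p)

.unique_interior <- function(p) {
  eqs <- if (p$allee) coexistence_equilibria(p) else no_allee_equilibria(p)
  if (length(eqs) != 1) return(NULL)
  eqs[[1]]
}

#' Dispersion relation of the linearized reaction-diffusion system
#'
#' For a perturbation `exp(mu*t + i*k.x)` about the homogeneous coexistence
#' state, the growth rate satisfies `mu^2 + alpha_k*mu + beta_k = 0` with
#' `alpha_k = k2*(d1+d2) - (J11+J22)` and
#' `beta_k = d1*d2*k2^2 - (d1*J22 + d2*J11)*k2 + det(J)`, where `k2 = k^2`
#' is the squared wavenumber. Both roots are returned; instability at `k2`
#' means `max_re > 0`.
#'
#' @param k2 squared wavenumber(s), `>= 0`; vectorized.
#' @param p a [model_params()] object.
#' @param dp a [diffusion_params()] object.
#' @param eq the coexistence `"equilibrium"`; computed (and required unique)
#'   when omitted.
#' @return A data.frame with columns `k2`, `alpha_k`, `beta_k`, complex
#'   `mu_plus`, `mu_minus`, and `max_re`.
#' @examples
#' p <- model_params(l = 0.01, beta = 1, a = 0.5, b = 0.9, d = 0.3)
#' dp <- diffusion_params(0.1, 20)
#' dispersion(seq(0, 1, 0.25), p, dp)
#' @export
dispersion <- function(k2, p, dp, eq = NULL) {
  stopifnot(inherits(p, "model_params"), inherits(dp, "diffusion_params"),
            all(k2 >= 0))
  if (is.null(eq)) {
    eq <- .unique_interior(p)
    if (is.null(eq))
      stop("coexistence equilibrium absent or non-unique; pass eq explicitly",
           call. = FALSE)
  }
  J <- .jacobian_at(p, eq)
  tr <- J[1, 1] + J[2, 2]
  det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  alpha <- k2 * (dp$d1 + dp$d2) - tr
  beta <- dp$d1 * dp$d2 * k2^2 - (dp$d1 * J[2, 2] + dp$d2 * J[1, 1]) * k2 + det
  root <- sqrt(as.complex(alpha^2 - 4 * beta))
  mu_p <- (-alpha + root) / 2
  mu_m <- (-alpha - root) / 2
  data.frame(k2 = k2, alpha_k = alpha, beta_k = beta,
             mu_plus = mu_p, mu_minus = mu_m,
             max_re = pmax(Re(mu_p), Re(mu_m)))
}

#' Turing instability conditions
#'
#' Evaluates the four conditions for diffusion-driven instability of the
#' (unique) homogeneous coexistence state:
#' (i) `J11 + J22 < 0`, (ii) `det(J) > 0` (the state is stable without
#' diffusion), (iii) `d1*J22 + d2*J11 > 0`, and (iv)
#' `d1*J22 + d2*J11 > 2*sqrt(d1*d2*det(J))`. Condition (iv) is applied in
#' this signed form, which together with (ii) entails (iii), so
#' `turing_unstable = (i) & (ii) & (iv)` and the unstable band of squared
#' wavenumbers (`beta_k < 0`) is nonempty exactly when (iv) holds.
#'
#' @inheritParams dispersion
#' @return An object of class `"turing_report"`: list with logicals
#'   `cond_i`..`cond_iv`, `turing_unstable`, the fastest-growing squared
#'   wavenumber `k2_crit = (d1*J22 + d2*J11)/(2*d1*d2)` (minimizer of
#'   `beta_k`), `band = c(k2_minus, k2_plus)` (or `NULL` when empty), and
#'   the Jacobian entries used.
#' @examples
#' p <- model_params(l = 0.01, beta = 1, a = 0.5, b = 0.9, d = 0.3)
#' turing_conditions(p, diffusion_params(0.1, 20))
#' @export
turing_conditions <- function(p, dp, eq = NULL) {
  stopifnot(inherits(p, "model_params"), inherits(dp, "diffusion_params"))
  if (is.null(eq)) {
    eq <- .unique_interior(p)
    if (is.null(eq))
      stop("coexistence equilibrium absent or non-unique; pass eq explicitly",
           call. = FALSE)
  }
  J <- .jacobian_at(p, eq)
  tr <- J[1, 1] + J[2, 2]
  det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  m <- dp$d1 * J[2, 2] + dp$d2 * J[1, 1]
  cond_i <- tr < 0
  cond_ii <- det > 0
  cond_iii <- m > 0
  cond_iv <- cond_ii && m > 2 * sqrt(dp$d1 * dp$d2 * det)
  k2_crit <- m / (2 * dp$d1 * dp$d2)
  band <- NULL
  disc <- m^2 - 4 * dp$d1 * dp$d2 * det
  if (cond_iv && disc >= 0) {
    r <- sqrt(disc)
    band <- c((m - r) / (2 * dp$d1 * dp$d2), (m + r) / (2 * dp$d1 * dp$d2))
  }
  structure(list(cond_i = cond_i, cond_ii = cond_ii, cond_iii = cond_iii,
                 cond_iv = cond_iv,
                 turing_unstable = cond_i && cond_ii && cond_iv,
                 k2_crit = if (k2_crit > 0) k2_crit else NA_real_,
                 band = band, equilibrium = eq, jacobian = J),
            class = "turing_report")
}

#' @export
print.turing_report <- function(x, ...) {
  cat(sprintf(
    "<turing_report> (i)%s (ii)%s (iii)%s (iv)%s -> %s\n",
    x$cond_i, x$cond_ii, x$cond_iii, x$cond_iv,
    if (x$turing_unstable) "TURING UNSTABLE" else "no diffusion-driven instability"))
  if (!is.null(x$band))
    cat(sprintf("  unstable band k2 in (%.5g, %.5g), k2_crit = %.5g\n",
                x$band[1], x$band[2], x$k2_crit))
  invisible(x)
}

#' Two-parameter Turing-space scan
#'
#' Evaluates [turing_conditions()] over a rectangular grid in two model or
#' diffusion parameters. Grid points at which the coexistence equilibrium is
#' absent or non-unique are marked `"indeterminate"` (the linear analysis
#' presumes a unique homogeneous state).
#'
#' @param p base [model_params()].
#' @param dp base [diffusion_params()].
#' @param axis1,axis2 lists `list(name =, values =)` with `name` one of
#'   `"l", "beta", "a", "b", "d", "d1", "d2"`.
#' @return A data.frame with one row per grid cell: the two parameter
#'   values (named after the axes), `status` in
#'   `c("unstable", "stable", "indeterminate")`, `k2_crit`, and the band
#'   endpoints (`NA` when empty).
#' @export
turing_scan <- function(p, dp, axis1, axis2) {
  stopifnot(is.list(axis1), is.list(axis2),
            axis1$name %in% c("l", "beta", "a", "b", "d", "d1", "d2"),
            axis2$name %in% c("l", "beta", "a", "b", "d", "d1", "d2"))
  grid <- expand.grid(v1 = axis1$values, v2 = axis2$values,
                      KEEP.OUT.ATTRS = FALSE)
  set_par <- function(p, dp, name, value) {
    if (name %in% c("d1", "d2")) dp[[name]] <- value else p[[name]] <- value
    list(p = p, dp = dp)
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    z <- set_par(p, dp, axis1$name, grid$v1[i])
    z <- set_par(z$p, z$dp, axis2$name, grid$v2[i])
    if (z$p$beta <= 0 || z$p$a <= 0 || z$p$b <= 0 || z$p$d <= 0 ||
        z$dp$d1 <= 0 || z$dp$d2 <= 0)
      return(list(status = "indeterminate", k2_crit = NA_real_,
                  band = c(NA_real_, NA_real_)))
    eq <- .unique_interior(z$p)
    if (is.null(eq))
      return(list(status = "indeterminate", k2_crit = NA_real_,
                  band = c(NA_real_, NA_real_)))
    rep <- turing_conditions(z$p, z$dp, eq)
    list(status = if (rep$turing_unstable) "unstable" else "stable",
         k2_crit = rep$k2_crit,
         band = if (is.null(rep$band)) c(NA_real_, NA_real_) else rep$band)
  })
  out <- data.frame(
    grid$v1, grid$v2,
    status = vapply(res, `[[`, character(1), "status"),
    k2_crit = vapply(res, `[[`, numeric(1), "k2_crit"),
    k2_minus = vapply(res, function(r) r$band[1], numeric(1)),
    k2_plus = vapply(res, function(r) r$band[2], numeric(1))
  )
  names(out)[1:2] <- c(axis1$name, axis2$name)
  out
}
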