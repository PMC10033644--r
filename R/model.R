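#' Dimensionless model parameters
#'
#' Constructs the parameter set of the dimensionless predator-prey model
#' \deqn{dx/dt = x(1-x)(x-l) - \beta x y / ((1+ax)(1+by)),}
#' \deqn{dy/dt = \beta x y / ((1+ax)(1+by)) - d y,}
#' where `x` is prey and `y` predator density. With `allee = FALSE` the prey
#' growth term is plain logistic `x(1-x)` and `l` is ignored.
#'
#' The Allee threshold `l` is *strong* for `0 < l < 1` (extinction below the
#' threshold) and *weak* for `-1 < l <= 0`. Values `l <= -1` fall outside the
#' weak-Allee range and are rejected unless `permissive = TRUE`, in which case
#' they are accepted with a warning (some published phase portraits use such
#' values).
#'
#' @param l Allee threshold (dimensionless, prey units of carrying capacity).
#' @param beta capture rate \eqn{\beta = ME/R} (dimensionless).
#' @param a handling-time coefficient \eqn{a = AK}.
#' @param b predator-interference coefficient \eqn{b = BKE}.
#' @param d predator death rate \eqn{d = D/(KR)}.
#' @param allee logical; if `FALSE` use logistic prey growth (no Allee effect).
#' @param permissive logical; allow `l <= -1` with a warning.
#' @return An object of class `"model_params"`.
#' @examples
#' p <- model_params(l = 0.1, beta = 9.8, a = 7.8, b = 4.1, d = 0.7)
#' reaction_rhs(c(0.5, 0.5), p)
#' @export
model_params <- function(l = NA_real_, beta, a, b, d, allee = TRUE,
                         permissive = FALSE) {
  stopifnot(is.numeric(beta), is.numeric(a), is.numeric(b), is.numeric(d))
  if (beta <= 0 || a <= 0 || b <= 0 || d <= 0)
    stop("beta, a, b and d must be strictly positive", call. = FALSE)
  if (allee) {
    if (!is.finite(l)) stop("l is required when allee = TRUE", call. = FALSE)
    if (l <= -1) {
      if (!permissive)
        stop("l <= -1 lies outside the weak-Allee range (-1, 0]; ",
             "use permissive = TRUE to override", call. = FALSE)
      warning("l <= -1 accepted in permissive mode (outside the weak-Allee range)",
              call. = FALSE)
    }
    if (l >= 1)
      warning("l >= 1: Allee threshold at or above the carrying capacity",
              call. = FALSE)
  } else {
    l <- NA_real_
  }
  structure(list(l = l, beta = beta, a = a, b = b, d = d, allee = allee),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ",
      if (x$allee) sprintf("Allee (l = %g), ", x$l) else "no Allee, ",
      sprintf("beta = %g, a = %g, b = %g, d = %g\n", x$beta, x$a, x$b, x$d),
      sep = "")
  invisible(x)
}

#' Diffusion coefficients of the spatial model
#'
#' @param d1 prey diffusion coefficient (dimensionless).
#' @param d2 predator diffusion coefficient (dimensionless).
#' @return An object of class `"diffusion_params"`.
#' @export
diffusion_params <- function(d1, d2) {
  if (!is.numeric(d1) || !is.numeric(d2) || d1 <= 0 || d2 <= 0)
    stop("d1 and d2 must be strictly positive", call. = FALSE)
  structure(list(d1 = d1, d2 = d2), class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("<diffusion_params> d1 = %g, d2 = %g\n", x$d1, x$d2))
  invisible(x)
}

#' Nondimensionalize the dimensional model
#'
#' Maps the dimensional parameters of the reaction-diffusion model to the
#' dimensionless groups used throughout the package:
#' `l = L/K`, `beta = M*E/R`, `a = A*K`, `b = B*K*E`, `d = D/(K*R)`,
#' `d1 = D1/(R*K*L1^2)`, `d2 = D2/(R*K*L1^2)`.
#'
#' The accompanying change of variables is `x = X/K`, `y = Y/(K*E)`,
#' `t = K*R*T`, and space is scaled by the characteristic domain length `L1`.
#' Under this scaling the dimensional reaction rates satisfy
#' `dX/dT = K^2*R * fx(x, y)` and `dY/dT = K^2*R*E * fy(x, y)` where
#' `(fx, fy)` is [reaction_rhs()].
#'
#' @param R intrinsic prey growth-rate scale (> 0).
#' @param K carrying capacity (> 0).
#' @param L Allee threshold density; requires `-K < L` (strong Allee if
#'   `L > 0`, weak if `-K < L <= 0`).
#' @param M capture rate (> 0).
#' @param A handling-time coefficient (> 0).
#' @param B predator-interference coefficient (> 0).
#' @param E conversion efficiency, `0 < E < 1`.
#' @param D predator death rate (> 0).
#' @param D1,D2 prey and predator diffusion coefficients (> 0).
#' @param L1 characteristic length of the square spatial domain (> 0).
#' @param allee logical; passed through to [model_params()].
#' @return A list with components `params` ([model_params()]) and
#'   `diffusion` ([diffusion_params()]).
#' @examples
#' nondimensionalize(R = 1, K = 1, L = 0.1, M = 2, A = 3, B = 4, E = 1 - 1e-9,
#'                   D = 0.5, D1 = 0.1, D2 = 20, L1 = 1)
#' @export
nondimensionalize <- function(R, K, L, M, A, B, E, D, D1, D2, L1, allee = TRUE) {
  pos <- c(R = R, K = K, M = M, A = A, B = B, D = D, D1 = D1, D2 = D2, L1 = L1)
  if (any(pos <= 0))
    stop("parameters ", paste(names(pos)[pos <= 0], collapse = ", "),
         " must be strictly positive", call. = FALSE)
  if (E <= 0 || E >= 1) stop("E must lie in (0, 1)", call. = FALSE)
  if (allee && L <= -K) stop("L must exceed -K", call. = FALSE)
  list(
    params = model_params(l = L / K, beta = M * E / R, a = A * K, b = B * K * E,
                          d = D / (K * R), allee = allee),
    diffusion = diffusion_params(d1 = D1 / (R * K * L1^2),
                                 d2 = D2 / (R * K * L1^2))
  )
}

#' Crowley-Martin predation rate
#'
#' Evaluates \eqn{\beta x y / ((1+ax)(1+by))}; the factored denominator is
#' algebraically identical to the expanded form \eqn{1+ax+by+abxy}.
#' Vectorized over `x` and `y`.
#'
#' @param x,y prey and predator densities (>= 0).
#' @param p a [model_params()] object.
#' @return Predation rate(s); zero whenever `x = 0` or `y = 0`.
#' @export
predation_rate <- function(x, y, p) {
  stopifnot(inherits(p, "model_params"))
  p$beta * x * y / ((1 + p$a * x) * (1 + p$b * y))
}

# prey per-capita growth contribution x * G(x); shared by rhs and jacobian
.growth <- function(x, p) {
  if (p$allee) x * (1 - x) * (x - p$l) else x * (1 - x)
}

.growth_deriv <- function(x, p) {
  if (p$allee) -3 * x^2 + 2 * (1 + p$l) * x - p$l else 1 - 2 * x
}

#' Reaction right-hand side
#'
#' Rates of change of prey and predator densities for the non-spatial model.
#' Accepts a length-2 state vector, or two conformable arrays via `x`/`y`
#' recycling when `s` is a list (used by the spatial stepper).
#'
#' @param s state: numeric vector `c(x, y)` or a list with elements `x`, `y`
#'   (arrays allowed, evaluated elementwise).
#' @param p a [model_params()] object.
#' @return For a vector state, `c(dx, dy)`; for a list state, a list with
#'   elements `x`, `y` of the same shape.
#' @export
reaction_rhs <- function(s, p) {
  stopifnot(inherits(p, "model_params"))
  if (is.list(s)) {
    pr <- predation_rate(s$x, s$y, p)
    list(x = .growth(s$x, p) - pr, y = pr - p$d * s$y)
  } else {
    pr <- predation_rate(s[1], s[2], p)
    c(.growth(s[1], p) - pr, pr - p$d * s[2])
  }
}

#' Jacobian of the reaction terms
#'
#' Exact partial derivatives of [reaction_rhs()] at an arbitrary state.
#' At a coexistence equilibrium the entries reduce to
#' \deqn{J_{11} = x(1+l-2x) + \beta a x y/((1+ax)^2(1+by)),\quad
#'       J_{12} = -\beta x/((1+ax)(1+by)^2),}
#' \deqn{J_{21} = \beta y/((1+ax)^2(1+by)),\quad
#'       J_{22} = -\beta b x y/((1+ax)(1+by)^2).}
#' (Note the `+` sign on the predation contribution to \eqn{J_{11}}: the
#' saturating response steepens, not flattens, prey self-regulation at an
#' interior equilibrium, which is what allows \eqn{J_{11} > 0} and hence
#' diffusion-driven instability.)
#'
#' @param s numeric state vector `c(x, y)` with `x, y >= 0`.
#' @param p a [model_params()] object.
#' @return A 2x2 numeric matrix.
#' @export
jacobian_matrix <- function(s, p) {
  stopifnot(inherits(p, "model_params"), length(s) == 2)
  x <- s[1]; y <- s[2]
  dax <- 1 + p$a * x
  dby <- 1 + p$b * y
  Px <- p$beta * y / (dax^2 * dby)   # d/dx of predation
  Py <- p$beta * x / (dax * dby^2)   # d/dy of predation
  matrix(c(.growth_deriv(x, p) - Px, -Py,
           Px, Py - p$d),
         nrow = 2, byrow = TRUE)
}

#' Read or write a parameter set as flat JSON
#'
#' Parameter files are flat JSON objects with keys
#' `l, beta, a, b, d, d1, d2, allee`; the diffusion keys are optional.
#'
#' @param path file path.
#' @param p a [model_params()] object.
#' @param dp optional [diffusion_params()] object.
#' @param permissive passed to [model_params()] on read.
#' @return `params_from_json()` returns a list with components `params` and
#'   `diffusion` (the latter `NULL` when `d1`/`d2` are absent);
#'   `params_to_json()` returns `path` invisibly.
#' @export
params_from_json <- function(path, permissive = FALSE) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  allee <- isTRUE(j$allee) || is.null(j$allee)  # default: Allee model
  p <- model_params(l = if (is.null(j$l)) NA_real_ else j$l,
                    beta = j$beta, a = j$a, b = j$b, d = j$d,
                    allee = allee, permissive = permissive)
  dp <- if (!is.null(j$d1) && !is.null(j$d2)) diffusion_params(j$d1, j$d2)
  list(params = p, diffusion = dp)
}

#' @rdname params_from_json
#' @export
params_to_json <- function(p, path, dp = NULL) {
  stopifnot(inherits(p, "model_params"))
  x <- list(l = p$l, beta = p$beta, a = p$a, b = p$b, d = p$d, allee = p$allee)
  if (!is.null(dp)) { x$d1 <- dp$d1; x$d2 <- dp$d2 }
  if (!p$allee) x$l <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
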