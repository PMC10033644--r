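# Phase-plane machinery: ODE integration (deSolve), limit-cycle detection via
# a Poincare section, separatrix reconstruction and basin classification.

.ode_func <- function(p, sign = 1) {
  function(t, state, parms) {
    s <- pmax(state, 0)  # model is defined on the closed quadrant
    list(sign * reaction_rhs(s, p))
  }
}

#' Integrate the non-spatial model
#'
#' Adaptive Runge-Kutta (Dormand-Prince 4(5), via [deSolve::ode()]) solution
#' of the reaction system from a nonnegative initial state. Small negative
#' excursions (down to `-100 * atol`) produced by the adaptive stepper near
#' the extinction state are clipped to zero; anything more negative, or any
#' state magnitude above `1e6`, raises an error.
#'
#' @param p a [model_params()] object.
#' @param s0 initial state `c(x, y)`, both `>= 0`.
#' @param t_end final time.
#' @param dt_out output sampling interval.
#' @param rtol,atol integrator tolerances.
#' @param method [deSolve::ode()] method; `"ode45"` by default.
#' @return An object of class `"trajectory"`: data.frame with columns
#'   `time`, `x`, `y`.
#' @export
integrate_model <- function(p, s0, t_end, dt_out = 0.1,
                            rtol = 1e-8, atol = 1e-10, method = "ode45") {
  stopifnot(inherits(p, "model_params"), length(s0) == 2, t_end > 0)
  if (any(s0 < 0)) stop("initial state must be nonnegative", call. = FALSE)
  times <- seq(0, t_end, by = dt_out)
  out <- deSolve::ode(y = c(x = s0[1], y = s0[2]), times = times,
                      func = .ode_func(p), parms = NULL, method = method,
                      rtol = rtol, atol = atol)
  m <- as.data.frame(out)
  names(m) <- c("time", "x", "y")
  clip_floor <- -100 * atol
  vals <- as.matrix(m[, c("x", "y")])
  if (any(!is.finite(vals)) || max(abs(vals), na.rm = TRUE) > 1e6)
    stop("trajectory blow-up: state magnitude exceeded 1e6", call. = FALSE)
  if (min(vals) < clip_floor)
    stop("trajectory left the nonnegative quadrant beyond clip tolerance (",
         format(min(vals)), ")", call. = FALSE)
  m$x <- pmax(m$x, 0)
  m$y <- pmax(m$y, 0)
  class(m) <- c("trajectory", "data.frame")
  m
}

#' Detect a stable limit cycle around a coexistence equilibrium
#'
#' Integrates from the equilibrium plus a small radial offset and monitors
#' upward crossings of the Poincare section `x = x*` (prey increasing).
#' After discarding `transient` crossings, the cycle is declared found when
#' successive crossing predator levels converge (relative change below
#' `conv_tol`) to a value bounded away from `y*`; convergence onto `y*`
#' itself is a spiral-in (`found = FALSE`).
#'
#' @param p a [model_params()] object.
#' @param eq a coexistence `"equilibrium"`.
#' @param offset initial radial offset as a fraction of `(x*, y*)`.
#' @param transient number of initial section crossings to ignore.
#' @param max_crossings cap on recorded crossings.
#' @param conv_tol relative convergence tolerance on crossing levels.
#' @param t_chunk,chunk_max integration chunk length and maximum number of
#'   chunks (total horizon `t_chunk * chunk_max`).
#' @param dt_out trajectory sampling interval.
#' @return A list with `found`, `y_section` (limiting crossing level),
#'   `period` (median inter-crossing time), `amplitude` (range of `x` and
#'   `y` over the final cycle) and `n_crossings`.
#' @examples
#' \donttest{
#' p <- model_params(l = 0.04, beta = 1.1, a = 0.5, b = 1.0, d = 0.3)
#' eq <- coexistence_equilibria(p)[[1]]
#' detect_limit_cycle(p, eq)$found
#' }
#' @export
detect_limit_cycle <- function(p, eq, offset = 0.05, transient = 200L,
                               max_crossings = 2000L, conv_tol = 1e-4,
                               t_chunk = 2000, chunk_max = 5L, dt_out = 0.05) {
  stopifnot(inherits(eq, "equilibrium"), eq$x > 0, eq$y > 0)
  s0 <- c(eq$x * (1 + offset), eq$y * (1 + offset))
  crossings_t <- numeric(0)
  crossings_y <- numeric(0)
  for (chunk in seq_len(chunk_max)) {
    tr <- integrate_model(p, s0, t_end = t_chunk, dt_out = dt_out,
                          method = "lsoda")
    up <- which(tr$x[-nrow(tr)] < eq$x & tr$x[-1] >= eq$x)
    if (length(up)) {
      f <- (eq$x - tr$x[up]) / (tr$x[up + 1] - tr$x[up])
      crossings_t <- c(crossings_t,
                       (chunk - 1) * t_chunk + tr$time[up] + f * dt_out)
      crossings_y <- c(crossings_y, tr$y[up] + f * (tr$y[up + 1] - tr$y[up]))
    }
    s0 <- c(tr$x[nrow(tr)], tr$y[nrow(tr)])
    n <- length(crossings_y)
    if (n >= max_crossings) break
    if (n > transient + 3) {
      tail_y <- crossings_y[(n - 2):n]
      if (max(abs(diff(tail_y))) < conv_tol * max(abs(tail_y), 1e-12)) break
    }
    # spiral-in: trajectory has collapsed onto the equilibrium
    if (max(abs(s0 - c(eq$x, eq$y))) < 1e-8) break
  }
  n <- length(crossings_y)
  if (n < 3)
    return(list(found = FALSE, y_section = NA_real_, period = NA_real_,
                amplitude = NULL, n_crossings = n))
  y_lim <- crossings_y[n]
  converged <- abs(crossings_y[n] - crossings_y[n - 1]) <
    conv_tol * max(abs(y_lim), 1e-12)
  away <- abs(y_lim - eq$y) > 0.02 * max(abs(eq$y), 1e-6)
  found <- converged && away
  period <- if (n >= 2) stats::median(diff(crossings_t[max(1, n - 10):n]))
            else NA_real_
  amplitude <- NULL
  if (found) {
    last <- integrate_model(p, c(eq$x, y_lim), t_end = 3 * period,
                            dt_out = dt_out, method = "lsoda")
    amplitude <- list(x = range(last$x), y = range(last$y))
  }
  list(found = found, y_section = y_lim, period = period,
       amplitude = amplitude, n_crossings = n)
}

#' Stable manifold (separatrix) of a saddle
#'
#' Reconstructs the two branches of the stable manifold by backward-time
#' integration from `saddle +/- eps * v_s`, where `v_s` is the eigenvector of
#' the negative eigenvalue. Branches are truncated on leaving the box
#' `[0, x_max] x [0, y_max]`.
#'
#' @param p a [model_params()] object.
#' @param saddle a classified `"equilibrium"` with `stability = "saddle"`.
#' @param t_back backward-time horizon.
#' @param eps offset along the stable eigenvector.
#' @param x_max,y_max truncation box.
#' @param dt_out sampling interval.
#' @return An object of class `"separatrix"`: list with the `saddle`, the
#'   unit `stable_eigenvector`, and `branches` (two data.frames of `x`, `y`).
#' @export
separatrix <- function(p, saddle, t_back = 400, eps = 1e-6,
                       x_max = 1.5, y_max = 3, dt_out = 0.05) {
  stopifnot(inherits(saddle, "equilibrium"))
  if (is.na(saddle$stability) || saddle$stability != "saddle")
    stop("separatrix() requires a saddle equilibrium", call. = FALSE)
  J <- jacobian_matrix(c(saddle$x, saddle$y), p)
  ed <- eigen(J)
  if (any(Im(ed$values) != 0) || prod(Re(ed$values)) >= 0)
    stop("not a saddle: eigenvalues ", paste(format(ed$values), collapse = ", "),
         call. = FALSE)
  vs <- Re(ed$vectors[, which.min(Re(ed$values))])
  vs <- vs / sqrt(sum(vs^2))
  speed0 <- abs(min(Re(ed$values))) * eps
  run_branch <- function(sign) {
    s0 <- c(saddle$x, saddle$y) + sign * eps * vs
    times <- seq(0, t_back, by = dt_out)
    # stop on leaving the box or when the backward flow stalls at an
    # equilibrium (e.g. spiralling into a backward-stable focus)
    rootfun <- function(t, s, parms) {
      f <- reaction_rhs(pmax(s, 0), p)
      c(sqrt(sum(f^2)) - min(1e-8, 0.1 * speed0),
        x_max - s[1], y_max - s[2], s[1] + 0.05, s[2] + 0.05)
    }
    out <- deSolve::lsodar(y = c(x = s0[1], y = s0[2]), times = times,
                           func = .ode_func(p, sign = -1), parms = NULL,
                           rootfunc = rootfun, rtol = 1e-10, atol = 1e-12)
    m <- as.data.frame(out)
    names(m) <- c("time", "x", "y")
    inside <- m$x >= -1e-9 & m$x <= x_max & m$y >= -1e-9 & m$y <= y_max
    cut <- which(!inside)[1]
    if (!is.na(cut)) m <- m[seq_len(cut), ]  # keep first exterior point
    m[, c("x", "y")]
  }
  structure(list(saddle = saddle, stable_eigenvector = vs,
                 branches = list(run_branch(1), run_branch(-1))),
            class = "separatrix")
}

#' Classify initial conditions by their attractor
#'
#' Integrates each initial state to `t_end` and labels it by the attractor
#' (point or cycle) its endpoint has approached within `tol`; `"unresolved"`
#' otherwise.
#'
#' @param p a [model_params()] object.
#' @param init matrix (or data.frame) with columns `x`, `y` of initial states.
#' @param attractors named list; each element either a length-2 numeric
#'   point, an `"equilibrium"`, or a two-column matrix of points on a cycle.
#' @param t_end integration horizon.
#' @param tol acceptance distance.
#' @return Character vector of attractor names (or `"unresolved"`).
#' @export
basin_classify <- function(p, init, attractors, t_end = 500, tol = 1e-3) {
  init <- as.matrix(init)
  stopifnot(ncol(init) == 2, length(names(attractors)) == length(attractors))
  targets <- lapply(attractors, function(a) {
    if (inherits(a, "equilibrium")) matrix(c(a$x, a$y), 1)
    else if (is.matrix(a) || is.data.frame(a)) as.matrix(a)[, 1:2, drop = FALSE]
    else matrix(a, 1)
  })
  apply(init, 1, function(s0) {
    tr <- integrate_model(p, s0, t_end = t_end, dt_out = t_end / 200,
                          method = "lsoda")
    end <- c(tr$x[nrow(tr)], tr$y[nrow(tr)])
    d <- vapply(targets, function(m)
      min(sqrt((m[, 1] - end[1])^2 + (m[, 2] - end[2])^2)), numeric(1))
    if (min(d) <= tol) names(targets)[which.min(d)] else "unresolved"
  })
}
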