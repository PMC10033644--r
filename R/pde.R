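# 2D reaction-diffusion simulation: explicit Euler in time, five-point
# Laplacian in space, zero-flux boundaries via mirrored ghost cells.

#' Simulation configuration
#'
#' Settings for [simulate_pattern()]. Defaults mirror the reference
#' protocol: a 200 x 200 grid with unit spacing, explicit Euler time step
#' 0.01, and the initial condition a small (1%) seeded uniform random
#' perturbation of the homogeneous coexistence state. The explicit scheme
#' requires the CFL-type bound `dt <= h^2 / (4 * max(d1, d2))`, checked at
#' construction.
#'
#' @param dp a [diffusion_params()] object (needed for the CFL check).
#' @param n grid points per side.
#' @param h grid spacing.
#' @param dt time step.
#' @param t_end simulation horizon.
#' @param seed RNG seed for the initial perturbation.
#' @param perturb_amp perturbation amplitude as a fraction of the
#'   equilibrium value (`0` gives the exact homogeneous state).
#' @param snapshot_times times at which fields are recorded (each rounded to
#'   a multiple of `dt`); defaults to `t_end` only.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(dp, n = 200L, h = 1.0, dt = 0.01, t_end = 5000,
                       seed = 1L, perturb_amp = 0.01,
                       snapshot_times = NULL) {
  stopifnot(inherits(dp, "diffusion_params"), n >= 3, h > 0, dt > 0,
            t_end > 0, perturb_amp >= 0)
  cfl <- h^2 / (4 * max(dp$d1, dp$d2))
  if (dt > cfl + 1e-15)
    stop(sprintf("dt = %g violates the CFL bound h^2/(4*max(d1,d2)) = %g",
                 dt, cfl), call. = FALSE)
  if (is.null(snapshot_times)) snapshot_times <- t_end
  snapshot_times <- sort(unique(round(snapshot_times / dt) * dt))
  if (any(snapshot_times > t_end + 1e-9))
    stop("snapshot times must not exceed t_end", call. = FALSE)
  structure(list(n = as.integer(n), h = h, dt = dt, t_end = t_end,
                 seed = as.integer(seed), perturb_amp = perturb_amp,
                 snapshot_times = snapshot_times),
            class = "sim_config")
}

#' Five-point Laplacian with zero-flux boundaries
#'
#' Discrete Laplacian on a rectangular grid using mirrored ghost cells
#' (the ghost value equals the boundary cell itself), the second-order
#' discretization of the homogeneous Neumann condition on a cell-centered
#' grid. Under zero flux the Laplacian sums to zero over the grid.
#'
#' @param field numeric matrix, at least 3 x 3.
#' @param h grid spacing.
#' @return Matrix of the same shape.
#' @export
laplacian_neumann <- function(field, h = 1.0) {
  if (!is.matrix(field) || nrow(field) < 3 || ncol(field) < 3)
    stop("field must be a matrix with at least 3 rows and columns",
         call. = FALSE)
  n <- nrow(field); m <- ncol(field)
  up <- field[c(1, seq_len(n - 1)), ]
  down <- field[c(seq_len(n - 1) + 1, n), ]
  left <- field[, c(1, seq_len(m - 1))]
  right <- field[, c(seq_len(m - 1) + 1, m)]
  (up + down + left + right - 4 * field) / h^2
}

#' One explicit Euler step (reference implementation)
#'
#' Advances both fields by `dt`: `u <- u + dt * (reaction + d * lap(u))`.
#' This vectorized R version defines the scheme; [simulate_pattern()] uses a
#' compiled stepper that is cross-checked against it in the test suite.
#' Negative values are clipped to zero (count returned as an attribute).
#'
#' @param state list with matrices `x`, `y` and time `t`.
#' @param p a [model_params()] object.
#' @param dp a [diffusion_params()] object.
#' @param dt time step (caller is responsible for the CFL bound; see
#'   [sim_config()]).
#' @param h grid spacing.
#' @return Updated state list, with attribute `"clipped"`.
#' @export
pde_step <- function(state, p, dp, dt, h = 1.0) {
  stopifnot(is.matrix(state$x), is.matrix(state$y))
  r <- reaction_rhs(list(x = state$x, y = state$y), p)
  xn <- state$x + dt * (r$x + dp$d1 * laplacian_neumann(state$x, h))
  yn <- state$y + dt * (r$y + dp$d2 * laplacian_neumann(state$y, h))
  clipped <- sum(xn < 0) + sum(yn < 0)
  xn[xn < 0] <- 0
  yn[yn < 0] <- 0
  if (any(!is.finite(xn)) || any(!is.finite(yn)) ||
      max(xn, yn) > 1e6)
    stop("numerical instability: field value not finite or exceeds 1e6",
         call. = FALSE)
  structure(list(x = xn, y = yn, t = (state$t %||% 0) + dt),
            clipped = clipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the 2D reaction-diffusion model
#'
#' Integrates the spatial model from a seeded random perturbation of the
#' unique homogeneous coexistence state, recording snapshots (fields plus
#' [pattern_summary()]) at the configured times. Runs are bitwise
#' reproducible for a given seed.
#'
#' @param p a [model_params()] object.
#' @param dp a [diffusion_params()] object.
#' @param cfg a [sim_config()] object.
#' @param init optional list with matrices `x`, `y` overriding the default
#'   random initial condition (e.g. a single-mode perturbation).
#' @return An object of class `"pattern_sim"`: list with `params`,
#'   `diffusion`, `config`, `equilibrium`, `clipped` (total clip count) and
#'   `snapshots`, a list of `list(time, x, y, summary)`.
#' @examples
#' \donttest{
#' p <- model_params(l = 0.01, beta = 1, a = 0.5, b = 0.9, d = 0.3)
#' dp <- diffusion_params(0.1, 20)
#' cfg <- sim_config(dp, n = 48, t_end = 50, seed = 1)
#' sim <- simulate_pattern(p, dp, cfg)
#' }
#' @export
simulate_pattern <- function(p, dp, cfg, init = NULL) {
  stopifnot(inherits(p, "model_params"), inherits(dp, "diffusion_params"),
            inherits(cfg, "sim_config"))
  eqs <- if (p$allee) coexistence_equilibria(p) else no_allee_equilibria(p)
  if (length(eqs) != 1)
    stop("simulate_pattern() requires a unique coexistence equilibrium (found ",
         length(eqs), ")", call. = FALSE)
  eq <- eqs[[1]]
  if (is.null(init)) {
    init <- perturbed_initial_condition(eq, n = cfg$n, amp = cfg$perturb_amp,
                                        seed = cfg$seed)
  }
  x <- init$x; y <- init$y
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  t_now <- 0
  clipped <- 0
  snapshots <- vector("list", length(cfg$snapshot_times))
  for (i in seq_along(cfg$snapshot_times)) {
    target <- cfg$snapshot_times[i]
    nsteps <- as.integer(round((target - t_now) / cfg$dt))
    if (nsteps > 0) {
      adv <- euler_advance_cpp(x, y, if (is.na(p$l)) 0 else p$l,
                               p$beta, p$a, p$b, p$d, p$allee,
                               dp$d1, dp$d2, cfg$h, cfg$dt, nsteps)
      x <- adv$x; y <- adv$y
      clipped <- clipped + adv$clipped
      t_now <- t_now + nsteps * cfg$dt
    }
    snapshots[[i]] <- list(time = t_now, x = x, y = y,
                           summary = pattern_summary(x))
  }
  structure(list(params = p, diffusion = dp, config = cfg, equilibrium = eq,
                 clipped = clipped, snapshots = snapshots),
            class = "pattern_sim")
}

#' @export
print.pattern_sim <- function(x, ...) {
  last <- x$snapshots[[length(x$snapshots)]]
  cat(sprintf(
    "<pattern_sim> %d x %d grid, t = %g; final prey pattern: %s (var %.3g)\n",
    nrow(last$x), ncol(last$x), last$time, last$summary$label,
    last$summary$variance))
  invisible(x)
}

#' Write simulation snapshots as CSV matrices
#'
#' Writes `prey_t{T}.csv` / `pred_t{T}.csv` per snapshot plus a
#' `summary.json` manifest (parameters, seed, per-snapshot summaries).
#'
#' @param sim a `"pattern_sim"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_snapshots <- function(sim, dir) {
  stopifnot(inherits(sim, "pattern_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (snap in sim$snapshots) {
    tag <- format(snap$time)
    utils::write.table(snap$x, file.path(dir, paste0("prey_t", tag, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(snap$y, file.path(dir, paste0("pred_t", tag, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(
    params = list(l = sim$params$l, beta = sim$params$beta, a = sim$params$a,
                  b = sim$params$b, d = sim$params$d, allee = sim$params$allee,
                  d1 = sim$diffusion$d1, d2 = sim$diffusion$d2),
    config = unclass(sim$config),
    equilibrium = list(x = sim$equilibrium$x, y = sim$equilibrium$y),
    clipped = sim$clipped,
    snapshots = lapply(sim$snapshots, function(s)
      list(time = s$time, label = s$summary$label, mean = s$summary$mean,
           variance = s$summary$variance, skewness = s$summary$skewness))
  )
  jsonlite::write_json(manifest, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
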