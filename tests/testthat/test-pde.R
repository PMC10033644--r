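test_that("Neumann Laplacian: stencil arithmetic, mirroring, zero total flux", {
  expect_equal(laplacian_neumann(matrix(3.7, 5, 5)), matrix(0, 5, 5))
  f <- matrix(0, 3, 3); f[2, 2] <- 1
  L <- laplacian_neumann(f, h = 1)
  expect_equal(L[2, 2], -4)
  expect_equal(c(L[1, 2], L[3, 2], L[2, 1], L[2, 3]), rep(1, 4))
  expect_equal(c(L[1, 1], L[1, 3], L[3, 1], L[3, 3]), rep(0, 4))
  # mirrored ghosts: an edge maximum sees its own value across the boundary
  g <- matrix(0, 3, 3); g[1, 2] <- 1
  Lg <- laplacian_neumann(g, h = 1)
  expect_equal(Lg[1, 2], -3)  # one neighbour is the mirror of itself
  set.seed(23)
  r <- matrix(runif(64^2), 64, 64)
  expect_lt(abs(sum(laplacian_neumann(r, h = 0.7))), 1e-10)
  expect_error(laplacian_neumann(matrix(1, 2, 2)), "at least 3")
})

test_that("an exact homogeneous equilibrium is a fixed point of the step", {
  fx <- get_fixture("fig7")
  eq <- coexistence_equilibria(fx$params)[[1]]
  st <- list(x = matrix(eq$x, 16, 16), y = matrix(eq$y, 16, 16), t = 0)
  st1 <- pde_step(st, fx$params, fx$diffusion, dt = 0.01)
  expect_lt(max(abs(st1$x - eq$x), abs(st1$y - eq$y)), 1e-12)
})

test_that("explicit Euler is additive in reaction and diffusion", {
  fx <- get_fixture("fig7")
  eq <- coexistence_equilibria(fx$params)[[1]]
  init <- perturbed_initial_condition(eq, n = 24, amp = 0.2, seed = 3)
  st <- list(x = init$x, y = init$y, t = 0)
  dt <- 0.01
  full <- pde_step(st, fx$params, fx$diffusion, dt)
  r <- reaction_rhs(list(x = st$x, y = st$y), fx$params)
  reaction_only <- list(x = st$x + dt * r$x, y = st$y + dt * r$y)
  diffusion_only <- list(
    x = st$x + dt * fx$diffusion$d1 * laplacian_neumann(st$x, 1),
    y = st$y + dt * fx$diffusion$d2 * laplacian_neumann(st$y, 1))
  expect_equal(full$x, reaction_only$x + diffusion_only$x - st$x,
               tolerance = 1e-14)
  expect_equal(full$y, reaction_only$y + diffusion_only$y - st$y,
               tolerance = 1e-14)
})

test_that("diffusion moves no net mass; reaction sets the total budget", {
  fx <- get_fixture("fig7")
  eq <- coexistence_equilibria(fx$params)[[1]]
  init <- perturbed_initial_condition(eq, n = 32, amp = 0.3, seed = 4)
  st <- list(x = init$x, y = init$y, t = 0)
  dt <- 0.01
  st1 <- pde_step(st, fx$params, fx$diffusion, dt)
  r <- reaction_rhs(list(x = st$x, y = st$y), fx$params)
  expect_equal(sum(st1$x) - sum(st$x), dt * sum(r$x), tolerance = 1e-9)
  expect_equal(sum(st1$y) - sum(st$y), dt * sum(r$y), tolerance = 1e-9)
})

test_that("the CFL bound is enforced at configuration time", {
  dp <- diffusion_params(0.1, 20)
  expect_error(sim_config(dp, n = 32, dt = 0.02, t_end = 1), "CFL")
  expect_silent(sim_config(dp, n = 32, dt = 0.0125, t_end = 1))
})

test_that("the compiled stepper reproduces the R reference step", {
  fx <- get_fixture("fig7")
  eq <- coexistence_equilibria(fx$params)[[1]]
  init <- perturbed_initial_condition(eq, n = 20, amp = 0.1, seed = 5)
  p <- fx$params; dp <- fx$diffusion
  ref <- list(x = init$x, y = init$y, t = 0)
  for (i in 1:5) ref <- pde_step(ref, p, dp, dt = 0.01)
  cfg <- sim_config(dp, n = 20, dt = 0.01, t_end = 0.05, seed = 5,
                    perturb_amp = 0.1)
  sim <- simulate_pattern(p, dp, cfg)
  expect_equal(sim$snapshots[[1]]$x, ref$x, tolerance = 1e-13)
  expect_equal(sim$snapshots[[1]]$y, ref$y, tolerance = 1e-13)
})

test_that("runs with the same seed are bitwise identical", {
  fx <- get_fixture("fig7")
  cfg <- sim_config(fx$diffusion, n = 24, t_end = 2, seed = 42)
  s1 <- simulate_pattern(fx$params, fx$diffusion, cfg)
  s2 <- simulate_pattern(fx$params, fx$diffusion, cfg)
  expect_identical(s1$snapshots[[1]]$x, s2$snapshots[[1]]$x)
  expect_identical(s1$snapshots[[1]]$y, s2$snapshots[[1]]$y)
})

test_that("a linearly stable state damps random perturbations", {
  # equal diffusion rates: no Turing instability, perturbation must decay
  p <- get_fixture("fig7")$params
  dp <- diffusion_params(0.1, 0.1)
  expect_false(turing_conditions(p, dp)$turing_unstable)
  cfg <- sim_config(dp, n = 48, t_end = 100, seed = 6, dt = 0.01)
  sim <- simulate_pattern(p, dp, cfg)
  eq <- sim$equilibrium
  init_var <- stats::var(as.vector(
    perturbed_initial_condition(eq, 48, 0.01, 6)$x))
  expect_lt(sim$snapshots[[1]]$summary$variance, init_var)
})

test_that("field blow-up raises an instability error", {
  fx <- get_fixture("fig7")
  st <- list(x = matrix(0.5, 8, 8), y = matrix(0.4, 8, 8), t = 0)
  st$x[4, 4] <- Inf
  expect_error(pde_step(st, fx$params, fx$diffusion, dt = 0.01),
               "instability")
  # same contract from the compiled stepper
  expect_error(
    alleeCM:::euler_advance_cpp(st$x, st$y, 0.01, 1, 0.5, 0.9, 0.3, TRUE,
                                0.1, 20, 1, 0.01, 1L),
    "instability")
})
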