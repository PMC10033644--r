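test_that("nondimensionalization reproduces the stated parameter groups", {
  nd <- nondimensionalize(R = 1, K = 1, L = 0.1, M = 2, A = 3, B = 4,
                          E = 1 - 1e-12, D = 0.5, D1 = 0.1, D2 = 20, L1 = 1)
  expect_equal(nd$params$l, 0.1)
  expect_equal(nd$params$beta, 2, tolerance = 1e-9)
  expect_equal(nd$params$a, 3)
  expect_equal(nd$params$b, 4, tolerance = 1e-9)
  expect_equal(nd$params$d, 0.5)
  expect_equal(nd$diffusion$d1, 0.1)
  expect_equal(nd$diffusion$d2, 20)
  # L = 0 sits exactly on the strong/weak Allee boundary
  nd0 <- nondimensionalize(R = 2, K = 3, L = 0, M = 2, A = 3, B = 4,
                           E = 0.5, D = 0.5, D1 = 0.1, D2 = 20, L1 = 5)
  expect_identical(nd0$params$l, 0)
  expect_error(nondimensionalize(R = -1, K = 1, L = 0, M = 1, A = 1, B = 1,
                                 E = 0.5, D = 1, D1 = 1, D2 = 1, L1 = 1),
               "positive")
  expect_error(nondimensionalize(R = 1, K = 1, L = 0, M = 1, A = 1, B = 1,
                                 E = 1.5, D = 1, D1 = 1, D2 = 1, L1 = 1),
               "E must")
})

test_that("dimensional and dimensionless reaction rates agree under the variable scaling", {
  set.seed(11)
  for (i in 1:25) {
    dpars <- list(R = runif(1, 0.5, 3), K = runif(1, 0.5, 4),
                  M = runif(1, 0.5, 3), A = runif(1, 0.1, 2),
                  B = runif(1, 0.1, 2), E = runif(1, 0.2, 0.9),
                  D = runif(1, 0.1, 1), D1 = 0.1, D2 = 1, L1 = 1)
    dpars$L <- runif(1, -0.5, 0.5) * dpars$K
    nd <- do.call(nondimensionalize, dpars)
    X <- runif(1, 0, 1.5 * dpars$K)
    Y <- runif(1, 0, dpars$K)
    f_dim <- dimensional_rhs(X, Y, dpars)
    f_nd <- reaction_rhs(c(X / dpars$K, Y / (dpars$K * dpars$E)), nd$params)
    # dX/dT = K^2 R fx, dY/dT = K^2 R E fy under x=X/K, y=Y/(KE), t=KRT
    expect_equal(f_dim[1], dpars$K^2 * dpars$R * f_nd[1], tolerance = 1e-10)
    expect_equal(f_dim[2], dpars$K^2 * dpars$R * dpars$E * f_nd[2],
                 tolerance = 1e-10)
  }
})

test_that("predation rate: zeros, factored/expanded identity, interference limits", {
  p <- model_params(l = 0.1, beta = 2, a = 3, b = 4, d = 0.5)
  expect_identical(predation_rate(0, 5, p), 0)
  expect_identical(predation_rate(2, 0, p), 0)
  set.seed(21)
  for (i in 1:1000) {
    q <- random_params()
    x <- runif(1, 0, 3); y <- runif(1, 0, 3)
    v1 <- predation_rate(x, y, q)
    v2 <- predation_expanded(x, y, q)
    expect_lt(abs(v1 - v2), 1e-12 * max(1, abs(v1)))
  }
  # a, b -> 0 recovers the bilinear (Holling I) rate beta*x*y
  tiny <- model_params(l = 0.1, beta = 2, a = 1e-13, b = 1e-13, d = 0.5)
  expect_equal(predation_rate(1.3, 0.7, tiny), 2 * 1.3 * 0.7,
               tolerance = 1e-10)
  # b -> 0: Holling II; a -> 0: Harrison (predator-dependent only)
  pb0 <- model_params(l = 0.1, beta = 2, a = 3, b = 1e-13, d = 0.5)
  expect_equal(predation_rate(1.3, 0.7, pb0), 2 * 1.3 * 0.7 / (1 + 3 * 1.3),
               tolerance = 1e-10)
  pa0 <- model_params(l = 0.1, beta = 2, a = 1e-13, b = 4, d = 0.5)
  expect_equal(predation_rate(1.3, 0.7, pa0), 2 * 1.3 * 0.7 / (1 + 4 * 0.7),
               tolerance = 1e-10)
})

test_that("reaction rhs vanishes at the structural zeros", {
  p <- model_params(l = 0.3, beta = 5, a = 2, b = 1, d = 0.4)
  expect_equal(reaction_rhs(c(1, 0), p), c(0, 0))
  expect_equal(reaction_rhs(c(0.3, 0), p), c(0, 0))
  expect_equal(reaction_rhs(c(0, 0.7), p), c(0, -0.4 * 0.7))
  # logistic variant loses the Allee factor
  pl <- model_params(beta = 5, a = 2, b = 1, d = 0.4, allee = FALSE)
  expect_equal(reaction_rhs(c(0.25, 0), pl)[1], 0.25 * 0.75)
})

test_that("analytic Jacobian matches a finite-difference oracle", {
  set.seed(31)
  for (i in 1:30) {
    p <- random_params()
    s <- c(runif(1, 0.05, 1.4), runif(1, 0.05, 2))
    J <- jacobian_matrix(s, p)
    expect_equal(J, fd_jacobian(s, p), tolerance = 1e-5)
    # predation hurts prey, feeds predator
    expect_lte(J[1, 2], 0)
    expect_gte(J[2, 1], 0)
  }
  pl <- model_params(beta = 6, a = 2.1, b = 3.01, d = 0.2, allee = FALSE)
  s <- c(0.3, 0.5)
  expect_equal(jacobian_matrix(s, pl), fd_jacobian(s, pl), tolerance = 1e-5)
})

test_that("Jacobian at boundary states reduces to the closed forms", {
  p <- model_params(l = 0.17, beta = 4, a = 1.5, b = 2, d = 0.45)
  J0 <- jacobian_matrix(c(0, 0), p)
  expect_equal(J0, diag(c(-0.17, -0.45)))
  J1 <- jacobian_matrix(c(1, 0), p)
  expect_equal(J1[2, 1], 0)  # upper-triangular
  expect_equal(sort(eigen(J1)$values),
               sort(c(p$l - 1, p$beta / (1 + p$a) - p$d)), tolerance = 1e-12)
})

test_that("parameter validation enforces the admissible ranges", {
  expect_error(model_params(l = 0.1, beta = -1, a = 1, b = 1, d = 1),
               "positive")
  expect_error(model_params(l = -1.5, beta = 1, a = 1, b = 1, d = 1),
               "weak-Allee")
  expect_warning(model_params(l = -1.5, beta = 1, a = 1, b = 1, d = 1,
                              permissive = TRUE), "permissive")
  expect_error(diffusion_params(0, 1), "positive")
  # l is ignored (and absent) for the logistic variant
  pl <- model_params(beta = 1, a = 1, b = 1, d = 1, allee = FALSE)
  expect_true(is.na(pl$l))
})

test_that("parameter sets round-trip through flat JSON", {
  p <- model_params(l = 0.04, beta = 1.1, a = 0.5, b = 1.0, d = 0.3)
  dp <- diffusion_params(0.1, 20)
  f <- tempfile(fileext = ".json")
  params_to_json(p, f, dp)
  back <- params_from_json(f)
  expect_equal(back$params, p)
  expect_equal(back$diffusion, dp)
  unlink(f)
})
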