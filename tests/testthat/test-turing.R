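test_that("dispersion at k2 = 0 collapses to the non-spatial spectrum", {
  p <- get_fixture("fig7")$params
  dp <- get_fixture("fig7")$diffusion
  eq <- coexistence_equilibria(p)[[1]]
  d0 <- dispersion(0, p, dp, eq)
  ev <- eigen(jacobian_matrix(c(eq$x, eq$y), p), only.values = TRUE)$values
  expect_equal(sort(Re(c(d0$mu_plus, d0$mu_minus))), sort(Re(ev)),
               tolerance = 1e-10)
  expect_equal(sort(Im(c(d0$mu_plus, d0$mu_minus))), sort(Im(ev)),
               tolerance = 1e-10)
  # vanishing diffusion: every mode behaves like k2 = 0
  dp0 <- diffusion_params(1e-300, 1e-300)
  dk <- dispersion(c(0.5, 5), p, dp0, eq)
  expect_equal(dk$max_re, rep(d0$max_re, 2), tolerance = 1e-8)
})

test_that("dispersion roots satisfy their quadratic and the Vieta identities", {
  set.seed(17)
  n_checked <- 0
  while (n_checked < 200) {
    p <- random_params()
    eqs <- coexistence_equilibria(p)
    if (length(eqs) == 0) next
    eq <- eqs[[sample(length(eqs), 1)]]
    dp <- diffusion_params(runif(1, 0.01, 1), runif(1, 1, 40))
    k2 <- runif(1, 0, 4)
    dres <- dispersion(k2, p, dp, eq)
    for (mu in c(dres$mu_plus, dres$mu_minus)) {
      J <- jacobian_matrix(c(eq$x, eq$y), p)
      lhs <- (J[1, 1] - k2 * dp$d1 - mu) * (J[2, 2] - k2 * dp$d2 - mu) -
        J[1, 2] * J[2, 1]
      expect_lt(Mod(lhs), 1e-10)
    }
    expect_lt(Mod(dres$mu_plus + dres$mu_minus + dres$alpha_k), 1e-10)
    expect_lt(Mod(dres$mu_plus * dres$mu_minus - dres$beta_k), 1e-10)
    n_checked <- n_checked + 1
  }
})

test_that("equal diffusion cannot destabilize a stable state", {
  p <- get_fixture("fig7")$params  # stable focus without diffusion
  dp <- diffusion_params(0.1, 0.1)
  rep <- turing_conditions(p, dp)
  expect_true(rep$cond_i)
  expect_false(rep$cond_iii)
  expect_false(rep$turing_unstable)
  expect_null(rep$band)
})

test_that("the reference pattern-forming set is Turing unstable with a growing band", {
  fx <- get_fixture("fig7")
  rep <- turing_conditions(fx$params, fx$diffusion)
  expect_true(rep$cond_i && rep$cond_ii && rep$cond_iii && rep$cond_iv)
  expect_true(rep$turing_unstable)
  # beta_k < 0 at its minimizer and positive growth inside the band
  k2c <- rep$k2_crit
  dmin <- dispersion(k2c, fx$params, fx$diffusion, rep$equilibrium)
  expect_lt(dmin$beta_k, 0)
  expect_gt(dmin$max_re, 0)
  # band endpoints are the zeros of beta_k
  dends <- dispersion(rep$band, fx$params, fx$diffusion, rep$equilibrium)
  expect_lt(max(abs(dends$beta_k)), 1e-10)
  scan <- dispersion(seq(0, 2 * k2c, length.out = 500), fx$params,
                     fx$diffusion, rep$equilibrium)
  expect_gt(max(scan$max_re), 0)
})

test_that("condition (iv) is equivalent to a negative minimum of beta_k", {
  set.seed(19)
  n_checked <- 0
  while (n_checked < 40) {
    p <- random_params()
    eqs <- coexistence_equilibria(p)
    if (length(eqs) != 1) next
    dp <- diffusion_params(runif(1, 0.02, 0.5), runif(1, 1, 40))
    rep <- turing_conditions(p, dp, eqs[[1]])
    if (!rep$cond_ii) next  # minimization test needs det > 0 at k2 = 0
    k2max <- if (is.na(rep$k2_crit)) 5 else 2.5 * rep$k2_crit
    grid <- dispersion(seq(0, k2max, by = 1e-3 * k2max), p, dp, eqs[[1]])
    expect_identical(rep$cond_iv, min(grid$beta_k) < 0)
    if (rep$cond_iv && rep$cond_ii) expect_true(rep$cond_iii)
    n_checked <- n_checked + 1
  }
})

test_that("Turing scans mark no-coexistence cells indeterminate and are transpose-symmetric", {
  fx <- get_fixture("fig7")
  p <- fx$params
  # beta axis includes values at/below a*d (no interior equilibrium)
  ax_beta <- list(name = "beta", values = c(0.1, 1.0, 1.1))
  ax_d <- list(name = "d", values = c(0.25, 0.3))
  scan <- turing_scan(p, fx$diffusion, ax_beta, ax_d)
  expect_identical(scan$status[scan$beta == 0.1], rep("indeterminate", 2))
  cell <- scan$status[scan$beta == 1.0 & scan$d == 0.3]
  expect_identical(cell, "unstable")
  scan_t <- turing_scan(p, fx$diffusion, ax_d, ax_beta)
  key <- paste(scan$beta, scan$d)
  key_t <- paste(scan_t$beta, scan_t$d)
  expect_identical(scan$status[order(key)], scan_t$status[order(key_t)])
})
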