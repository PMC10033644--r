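# Registry of the published figure-caption parameter sets, seeded initial
# conditions, and constructed morphology fields. All inputs to the analyses
# are generated here; nothing is downloaded.

.fixture <- function(key, l = NA, beta, a, b, d, d1 = NULL, d2 = NULL,
                     allee = TRUE, permissive = FALSE, partial = FALSE,
                     expected = list()) {
  p <- if (partial) NULL else
    suppressWarnings(model_params(l = l, beta = beta, a = a, b = b, d = d,
                                  allee = allee, permissive = permissive))
  dp <- if (!is.null(d1)) diffusion_params(d1, d2)
  structure(list(key = key, params = p, diffusion = dp,
                 partial = partial, permissive = permissive,
                 expected = expected),
            class = "fixture")
}

.fixture_registry <- local({
  reg <- NULL
  function() {
    if (!is.null(reg)) return(reg)
    f <- .fixture
    r <- list(
      # nullcline-multiplicity panels, strong Allee
      f("fig1a", beta = 10, a = NA, b = NA, d = NA, partial = TRUE,
        expected = list(count = 3L,
                        note = "caption gives beta only; excluded from regressions")),
      f("fig1b", 0.01, 7.8, 10.5, 5.2, 0.3, expected = list(count = 3L)),
      f("fig1c", 0.2, 9, 7.5, 4.1, 0.7, expected = list(count = 2L)),
      f("fig1d", 0.2, 5, 10.5, 5.2, 0.3, expected = list(count = 2L)),
      f("fig1e", 0.2, 10.1267155062337, 7.5, 4.1, 0.7,
        expected = list(count = 1L, note = "fold point: tangent nullclines")),
      f("fig1f", 0.01, 1, 0.5, 0.9, 0.3, expected = list(count = 1L)),
      f("fig1g", 0.1, 5, 10.5, 5.2, 0.3, expected = list(count = 1L)),
      f("fig1h", 0.2, 10.7, 7.5, 4.1, 0.7, expected = list(count = 0L)),
      # weak Allee
      f("fig2a", -0.2, 10.7, 10.9, 3.2, 0.3, expected = list(count = 3L)),
      f("fig2b", -0.2, 10.7, 10.9, 5.2, 0.3, expected = list(count = 3L)),
      f("fig2c", -0.2, 11.494054912906, 10.9, 3.2, 0.3,
        expected = list(count = 2L, note = "fold point: two equilibria collide")),
      f("fig2d", -0.2, 1, 0.5, 0.9, 0.3, expected = list(count = 1L)),
      f("fig2e", -0.2, 6.4, 10.5, 5.2, 0.3, expected = list(count = 1L)),
      # phase portraits
      f("fig3", 0.1, 9.8, 7.8, 4.1, 0.7,
        expected = list(count = 3L, bistable = TRUE,
                        note = "E0 and E3 attractors separated by the stable manifolds of the interior saddles")),
      f("fig4", -2, 10.5, 11, 3, 0.3, permissive = TRUE,
        expected = list(count = 3L, bistable = TRUE,
                        note = "l = -2 lies outside the weak-Allee range; permissive")),
      f("fig5", 0.04, 1.1, 0.5, 1.0, 0.3,
        expected = list(count = 1L, limit_cycle = TRUE,
                        note = "unstable interior point surrounded by a stable limit cycle")),
      f("fig6", -0.01, 1.2, 0.5, 1.0, 0.3,
        expected = list(count = 1L, limit_cycle = TRUE)),
      # spatial patterns, Allee model
      f("fig7", 0.01, 1.0, 0.5, 0.9, 0.3, d1 = 0.1, d2 = 20,
        expected = list(pattern = "holes and short stripes")),
      f("fig8a", 0.01, 1.05, 0.5, 0.9, 0.3, d1 = 0.05, d2 = 20,
        expected = list(pattern = "holes")),
      f("fig8b", 0.01, 1.05, 0.5, 0.9, 0.3, d1 = 0.1, d2 = 20,
        expected = list(pattern = "holes")),
      f("fig8c", 0.01, 1.05, 0.5, 0.9, 0.3, d1 = 0.2, d2 = 20,
        expected = list(pattern = "holes")),
      f("fig8d", 0.01, 1.05, 0.5, 0.9, 0.3, d1 = 0.5, d2 = 20,
        expected = list(pattern = "holes, larger radius")),
      f("fig9a", -0.01, 1.05, 0.5, 0.9, 0.3, d1 = 0.1, d2 = 20,
        expected = list(pattern = "holes")),
      f("fig9b", -0.04, 1.05, 0.5, 0.9, 0.3, d1 = 0.1, d2 = 20,
        expected = list(pattern = "holes with short stripes")),
      f("fig10a", -0.01, 1.05, 0.5, 1.0, 0.3, d1 = 0.1, d2 = 20,
        expected = list(pattern = "hole and short-stripe mixtures")),
      f("fig10b", 0.04, 1.05, 0.5, 1.0, 0.3, d1 = 0.1, d2 = 20,
        expected = list(pattern = "holes")),
      f("fig11a", -0.03, 1.1, 0.6, 0.98, 0.3, d1 = 0.1, d2 = 20,
        expected = list(pattern = "hole and short-stripe mixtures")),
      f("fig11b", 0.0, 1.1, 0.6, 0.98, 0.3, d1 = 0.1, d2 = 20,
        expected = list(pattern = "holes")),
      f("fig11c", 0.025, 1.1, 0.6, 0.98, 0.3, d1 = 0.1, d2 = 20,
        expected = list(pattern = "holes"))
    )
    # no-Allee pattern sequences
    beta12 <- c(4.8, 4.9, 5.1, 5.2, 5.4, 6.0)
    pat12 <- c("holes", "hole-stripe mixtures", "stripes", "labyrinthine",
               "spot-stripe mixtures", "spots")
    for (i in seq_along(beta12))
      r[[length(r) + 1L]] <- f(paste0("fig12", letters[i]),
                               beta = beta12[i], a = 2.1, b = 3.01, d = 0.2,
                               d1 = 0.1, d2 = 20, allee = FALSE,
                               expected = list(pattern = pat12[i]))
    d13 <- c(0.2, 0.24, 0.261, 0.3, 0.32, 0.34)
    pat13 <- rev(pat12)
    for (i in seq_along(d13))
      r[[length(r) + 1L]] <- f(paste0("fig13", letters[i]),
                               beta = 6.0, a = 2.1, b = 3.01, d = d13[i],
                               d1 = 0.1, d2 = 20, allee = FALSE,
                               expected = list(pattern = pat13[i]))
    names(r) <- vapply(r, `[[`, character(1), "key")
    reg <<- r
    reg
  }
})

#' Published parameter sets by figure key
#'
#' Returns the registered parameter set for one figure panel (keys like
#' `"fig1b"`, `"fig5"`, `"fig12a"`), together with its caption annotation
#' (`expected`: equilibrium count, limit-cycle / bistability flags, or the
#' reported pattern word). Entries flagged `partial = TRUE` record captions
#' that do not state a complete parameter set and carry `params = NULL`.
#'
#' @param key figure identifier.
#' @return An object of class `"fixture"`: list with `key`, `params`
#'   ([model_params()] or `NULL`), `diffusion` ([diffusion_params()] or
#'   `NULL`), `partial`, `permissive` and `expected`.
#' @examples
#' get_fixture("fig1b")$expected$count
#' @export
get_fixture <- function(key) {
  reg <- .fixture_registry()
  if (!key %in% names(reg))
    stop("unknown fixture key: ", key, " (see fixture_keys())", call. = FALSE)
  reg[[key]]
}

#' @rdname get_fixture
#' @export
fixture_keys <- function() names(.fixture_registry())

#' @export
print.fixture <- function(x, ...) {
  cat("<fixture ", x$key, ">", if (x$partial) " [partial caption]", "\n",
      sep = "")
  if (!is.null(x$params)) print(x$params)
  if (!is.null(x$diffusion)) print(x$diffusion)
  if (length(x$expected))
    cat("  caption: ", paste(names(x$expected), unlist(x$expected),
                             sep = " = ", collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Seeded random perturbation of a homogeneous state
#'
#' Initial fields `eq * (1 + amp * U)` with `U` i.i.d. Uniform(-1, 1) from a
#' seeded generator; `amp = 0` gives exact homogeneity. The calling RNG
#' state is left untouched.
#'
#' @param eq a coexistence `"equilibrium"` (or list with `x`, `y` scalars).
#' @param n grid points per side.
#' @param amp perturbation amplitude (fraction of the equilibrium value).
#' @param seed RNG seed.
#' @return list with `n x n` matrices `x` and `y`.
#' @export
perturbed_initial_condition <- function(eq, n, amp = 0.01, seed = 1L) {
  stopifnot(amp >= 0, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u1 <- matrix(stats::runif(n * n, -1, 1), n, n)
  u2 <- matrix(stats::runif(n * n, -1, 1), n, n)
  list(x = eq$x * (1 + amp * u1), y = eq$y * (1 + amp * u2))
}

#' Deterministic morphology fixtures
#'
#' Synthetic fields of known morphology for exercising the pattern
#' classifier: `"spots"` (a lattice of Gaussian bumps on a flat background),
#' `"holes"` (the same bumps subtracted) and `"stripes"` (a parallel
#' sinusoidal band pattern).
#'
#' @param kind one of `"spots"`, `"holes"`, `"stripes"`.
#' @param n grid points per side (>= 32).
#' @return an `n x n` numeric matrix.
#' @export
morphology_fixture <- function(kind = c("spots", "holes", "stripes"), n = 64L) {
  kind <- match.arg(kind)
  stopifnot(n >= 32)
  idx <- seq_len(n) - 0.5
  if (kind == "stripes") {
    return(outer(rep(1, n), 1 + 0.3 * sin(2 * pi * 5 * idx / n)))
  }
  nb <- 4L                          # bumps per side
  centers <- (seq_len(nb) - 0.5) * n / nb
  sigma <- n / (6 * nb)
  gx <- outer(idx, centers, function(i, c) exp(-(i - c)^2 / (2 * sigma^2)))
  bump <- rowSums(gx)
  field <- 1 + outer(bump, bump) * if (kind == "spots") 0.5 else -0.5
  field
}
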