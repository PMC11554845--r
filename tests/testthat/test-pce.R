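test_that("prior bounds, canonical mapping and sampling are reproducible", {
  pr <- parameter_prior()
  expect_equal(unname(pr$lower["K_A"]), 5.60e5)
  expect_equal(unname(pr$upper["r_min"]), 1e-2)
  s1 <- sample_prior(pr, 50, seed = 3)
  s2 <- sample_prior(pr, 50, seed = 3)
  expect_identical(s1$theta, s2$theta)
  expect_true(all(sweep(s1$theta, 2, pr$lower, ">=")))
  expect_true(all(sweep(s1$theta, 2, pr$upper, "<=")))
  expect_equal(pr$from_canonical(pr$to_canonical(s1$theta)), s1$theta,
               tolerance = 1e-12)
  expect_true(all(abs(s1$z) <= 1))
})

test_that("basis counts follow the total-degree binomial formula", {
  expect_equal(nrow(pulmnet:::.multi_indices(8, 4)), choose(12, 4))  # 495
  expect_equal(nrow(pulmnet:::.multi_indices(2, 2)), 6)
  expect_equal(nrow(pulmnet:::.multi_indices(3, 9)), choose(12, 3))
})

test_that("normalized Legendre basis is orthonormal under the uniform
           measure", {
  x <- seq(-1, 1, length.out = 20001)
  P <- pulmnet:::.legendre_norm(x, 5)
  G <- crossprod(P) * (x[2] - x[1]) / 2   # Riemann estimate of E[Pi Pj]
  expect_equal(unname(diag(G)), rep(1, 6), tolerance = 1e-3)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-3)
})

test_that("OLS fit exactly recovers polynomials in the basis", {
  set.seed(1)
  z <- matrix(runif(300 * 3, -1, 1), 300)
  y <- z[, 1]                      # affine in one canonical variable
  fit <- pce(z, y, order = 2)
  co <- coef(fit)[, 1]
  mi <- fit$multi_indices
  k1 <- which(mi[, 1] == 1 & rowSums(mi) == 1)
  expect_equal(unname(co[k1]), 1 / sqrt(3), tolerance = 1e-10)  # P1 = sqrt(3) z
  expect_lt(max(abs(co[-k1])), 1e-10)
  # predictions reproduce the truth everywhere
  znew <- matrix(runif(50 * 3, -1, 1), 50)
  expect_equal(c(predict(fit, znew)), znew[, 1], tolerance = 1e-10)
})

test_that("moments match closed forms and a Monte-Carlo oracle", {
  set.seed(2)
  z <- matrix(runif(500 * 2, -1, 1), 500)
  fit_const <- pce(z, rep(4.2, 500), order = 2)
  m <- pce_moments(fit_const)
  expect_equal(unname(m$mean), 4.2, tolerance = 1e-12)
  expect_equal(unname(m$variance), 0, tolerance = 1e-20)

  fit_lin <- pce(z, z[, 1], order = 2)
  expect_equal(unname(pce_moments(fit_lin)$variance), 1 / 3,
               tolerance = 1e-10)

  f <- function(z) 1 + z[, 1] + 0.5 * z[, 2]^2 + 0.25 * z[, 1] * z[, 2]
  fit <- pce(z, f(z), order = 3)
  zmc <- matrix(runif(1e5 * 2, -1, 1), 1e5)
  expect_equal(unname(pce_moments(fit)$variance), var(f(zmc)),
               tolerance = 0.01)
})

test_that("Sobol' indices are exact for additive and interaction models", {
  set.seed(3)
  z <- matrix(runif(400 * 2, -1, 1), 400)
  rep_add <- sobol_indices(pce(z, z[, 1] + z[, 2], order = 2))
  expect_equal(unname(rep_add$S[, 1]), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(unname(rep_add$S2[1, 1]), 0, tolerance = 1e-10)

  rep_int <- sobol_indices(pce(z, z[, 1] * z[, 2], order = 2))
  expect_equal(unname(rep_int$S[, 1]), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(rep_int$S2[1, 1]), 1, tolerance = 1e-10)
  expect_equal(unname(rep_int$S_T[, 1]), c(1, 1), tolerance = 1e-10)
})

test_that("Ishigami Sobol' indices match their closed forms", {
  set.seed(4)
  z <- matrix(runif(4000 * 3, -1, 1), 4000)
  fit <- pce(z, ishigami(z), order = 9)
  rep_ <- sobol_indices(fit)
  # closed-form variance decomposition for a = 7, b = 0.1
  expect_lt(abs(rep_$S[1, 1] - 0.3139), 0.02)
  expect_lt(abs(rep_$S[2, 1] - 0.4424), 0.02)
  expect_lt(abs(rep_$S[3, 1] - 0), 0.02)
  expect_lt(abs(rep_$S_T[3, 1] - 0.2437), 0.02)
})

test_that("coefficient-based Sobol' indices agree with a pick-freeze
           Monte-Carlo estimator", {
  set.seed(5)
  z <- matrix(runif(2000 * 3, -1, 1), 2000)
  f <- function(m) m[, 1] + 2 * m[, 2]^2 + m[, 1] * m[, 3]
  fit <- pce(z, f(z), order = 4)
  rep_ <- sobol_indices(fit)
  mc <- pick_freeze_sobol(f, 3, N = 1e5)
  expect_lt(max(abs(rep_$S[, 1] - mc$S)), 0.03)
  expect_lt(max(abs(rep_$S_T[, 1] - mc$S_T)), 0.03)
})

test_that("generalized indices reduce to constants and hand integrals", {
  # fabricate a surrogate over 2 parameters, order 1: coefficients chosen so
  # the first half of the cycle is Z = theta1-like with Var = 1 and the
  # second half is independent of theta1 with Var = 3
  mi <- pulmnet:::.multi_indices(2, 1)
  r1 <- which(mi[, 1] == 1)      # degree-1 row of theta1
  r2 <- which(mi[, 2] == 1)
  m <- 100
  co <- matrix(0, 3, m)
  co[r1, 1:50] <- 1              # degree-1 in theta1, Var = 1
  co[r2, 51:100] <- sqrt(3)      # degree-1 in theta2, Var = 3
  fake <- structure(list(multi_indices = mi, coefficients = co, order = 1,
                         n_train = 10, n_param = 2,
                         param_names = c("a", "b"), prior = NULL,
                         condition = 1), class = "pce")
  gs <- generalized_sobol(fake, times = seq(0, 1, length.out = m))
  expect_equal(unname(gs$GS["a"]), 0.25, tolerance = 0.02)
  expect_equal(unname(gs$GS["b"]), 0.75, tolerance = 0.02)

  # constant-in-time indices are returned unchanged
  co2 <- matrix(0, 3, m); co2[r1, ] <- 2
  fake2 <- fake; fake2$coefficients <- co2
  gs2 <- generalized_sobol(fake2, times = seq(0, 1, length.out = m))
  expect_equal(unname(gs2$GS["a"]), 1, tolerance = 1e-12)
})

test_that("validation error is near machine zero on in-basis truth and
           improves with order on a smooth function", {
  set.seed(6)
  z <- matrix(runif(400 * 2, -1, 1), 400)
  y <- 1 + z[, 1] - z[, 2] + z[, 1] * z[, 2]
  fit <- pce(z, y, order = 2)
  zv <- matrix(runif(100 * 2, -1, 1), 100)
  yv <- 1 + zv[, 1] - zv[, 2] + zv[, 1] * zv[, 2]
  expect_lt(validation_mse(fit, zv, yv)$mean, 1e-20)

  g <- function(m) exp(0.8 * m[, 1]) * cos(2 * m[, 2])
  yg <- g(z); ygv <- g(zv)
  err <- vapply(2:4, function(K)
    validation_mse(pce(z, yg, order = K), zv, ygv)$mean, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_error(validation_mse(fit, zv, yv[1:10]), "mismatch")
})

test_that("degenerate fits are rejected with informative errors", {
  z <- matrix(runif(20, -1, 1), 10, 2)
  expect_error(pce(z, rnorm(10), order = 4), "training points")
  expect_warning(pce(z, rnorm(10), order = 2), "ill-conditioning")
})
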