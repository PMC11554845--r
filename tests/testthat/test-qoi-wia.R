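test_that("proximal WSS follows the blunt-profile formula", {
  # q = 100 cm^3/s in a 1 cm vessel: U = 31.83 cm/s, WSS = mu U (gamma+2)/R
  n <- 8
  A <- rep(pi, n)
  sim <- fake_sim(p = rep(0, n), q = rep(100, n), A = A, r0 = 1)
  wss <- proximal_wss(sim, "V1")
  expect_equal(wss[1], 0.032 * (100 / pi) * 11 / 1, tolerance = 1e-12)
  sim0 <- fake_sim(p = rep(0, n), q = rep(0, n), A = A)
  expect_equal(proximal_wss(sim0, "V1"), rep(0, n))
  simn <- fake_sim(p = rep(0, n), q = rep(-100, n), A = A)
  expect_true(all(proximal_wss(simn, "V1") < 0))
})

test_that("cyclic stretch is the relative radial excursion", {
  n <- 16
  sim <- fake_sim(p = rep(0, n), q = rep(0, n), A = rep(2, n))
  expect_equal(cyclic_stretch(sim, "V1"), 0)
  R <- c(rep(1.00, 8), rep(1.05, 8))
  sim2 <- fake_sim(p = rep(0, n), q = rep(0, n), A = pi * R^2)
  expect_equal(cyclic_stretch(sim2, "V1"), 0.05, tolerance = 1e-12)
})

test_that("small-amplitude proximal CS matches the wall-law linearization", {
  sim <- shared_sim()
  for (nm in c("MPA", "LIV")) {
    side <- sim$network$segments$side[sim$network$segments$name == nm]
    K <- if (side == "arterial") sim$network$materials$K_A else
      sim$network$materials$K_V
    mid <- ceiling(ncol(sim$p[[nm]]) / 2)
    p <- sim$p[[nm]][, mid]
    dp <- max(p) - min(p)
    cs_lin <- (3 * dp / (4 * K)) / (1 + 3 * min(p) / (4 * K))
    expect_equal(cyclic_stretch(sim, nm), cs_lin, tolerance = 0.03)
  }
})

test_that("the characteristic split reproduces hand arithmetic", {
  # rho = 1.055, K = 8e5, A = A0 -> c = sqrt(2K/(3 rho)) = 711.0 cm/s
  K <- 8e5; rho <- 1.055
  c0 <- sqrt(2 * K / (3 * rho))
  expect_equal(c0, 711.0, tolerance = 1e-3)
  n <- 8
  # one step with dP = 1000 dyn/cm^2 and dU = 5 cm/s at sample 2
  A0 <- pi
  p <- c(0, 1000, rep(1000, n - 2)); u <- c(0, 5, rep(5, n - 2))
  sim <- fake_sim(p = p, q = u * A0, A = rep(A0, n), r0 = 1, K_A = K)
  wi <- wave_intensity(sim, "V1")
  rc <- rho * c0
  dPp <- (1000 + rc * 5) / 2
  expect_equal(wi$dI_forward[2], dPp^2 / rc, tolerance = 1e-9)
  expect_equal(wi$dI_forward[2], 7521, tolerance = 1e-3)
  dPm <- (1000 - rc * 5) / 2
  expect_equal(wi$dI_backward[2], -dPm^2 / rc, tolerance = 1e-9)
})

test_that("a pure forward wave has identically zero backward intensity", {
  K <- 8e5; rho <- 1.055
  c0 <- sqrt(2 * K / (3 * rho))
  n <- 64
  p <- 500 * sin(2 * pi * (1:n) / n)
  u <- p / (rho * c0)        # characteristic identity dP = rho c dU
  sim <- fake_sim(p = p, q = u * pi, A = rep(pi, n), r0 = 1, K_A = K)
  wi <- wave_intensity(sim, "V1")
  expect_equal(max(abs(wi$dI_backward)), 0, tolerance = 1e-14)
  expect_equal(sum(wi$integrated[c("BCW", "BEW")]), 0, tolerance = 1e-14)
})

test_that("forward plus backward intensity equals dP dU pointwise and the
           labels partition the samples", {
  sim <- shared_sim()
  for (nm in c("MPA", "RIV")) {
    wi <- wave_intensity(sim, nm)
    expect_equal(wi$dI_forward + wi$dI_backward, wi$dP * wi$dU,
                 tolerance = 1e-10)
    expect_true(all(wi$dI_forward >= 0))
    expect_true(all(wi$dI_backward <= 0))
    expect_true(all(wi$labels %in% c("FCW", "FEW", "BCW", "BEW")))
    expect_true(all(wi$integrated >= 0))
  }
})

test_that("venous backward-wave energy grows with the atrial a-wave", {
  cfg <- solver_config(dx = 0.25, n_per = 4096)
  back <- vapply(c(1, 3, 5), function(aa) {
    sim <- pulmsim(la = la_pressure(a_amp = aa), config = cfg)
    sum(vapply(sim$network$venous_outlets, function(nm)
      sum(wave_intensity(sim, nm)$integrated[c("BCW", "BEW")]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(back) > 0))
})

test_that("the QoI table assembles one labelled row per vessel", {
  tb <- qoi_table(shared_sim())
  expect_equal(nrow(tb), 27)
  expect_true(all(c("FCW", "FEW", "BCW", "BEW", "cs", "mean_wss") %in%
                    names(tb)))
  expect_true(all(tb$sys_p_mmHg >= tb$dia_p_mmHg))
})
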