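# direct access to the compiled core for single-vessel and junction checks
.cpp_cfg <- function(n_per, period = 0.85, max_cycles = 40, tol = 1.0,
                     inlet = 0L, la = integer(0), ramp = TRUE) {
  list(n_per = n_per, n_kern = 256L, max_cycles = max_cycles, tol = tol,
       rho = 1.055, nu = 3.03e-2, gamma = 9, period = period,
       ramp_first_cycle = ramp, p_init = 0, inlet_vessel = inlet,
       la_vessels = la)
}

.vessel_spec <- function(r0, L, K, dx) {
  n <- max(3L, round(L / dx) + 1L)
  list(n = n, dx = L / (n - 1), A0 = pi * r0^2, f = 4 * K / 3)
}

test_that("zero forcing leaves the trivial equilibrium unchanged", {
  v <- .vessel_spec(0.3, 5, 8e5, 0.25)
  out <- pulmnet:::solve_network_cpp(
    list(v), matrix(integer(0), 0, 6), matrix(0, 0, 3),
    matrix(integer(0), 0, 2), list(), rep(0, 2 * 4096), rep(0, 4096),
    .cpp_cfg(4096, max_cycles = 3))
  expect_lt(max(abs(out$q[[1]])), 1e-12)
  expect_lt(max(abs(out$A[[1]] - v$A0)), 1e-12)
  expect_lt(max(abs(out$p[[1]])), 1e-9)
})

test_that("steady single-vessel pressure drop matches the ODE oracle", {
  # q0 chosen so u << c: the oracle neglects the advective momentum flux
  q0 <- 5; r0 <- 0.3; L <- 5; K <- 8e5
  v <- .vessel_spec(r0, L, K, 0.125)
  out <- pulmnet:::solve_network_cpp(
    list(v), matrix(integer(0), 0, 6), matrix(0, 0, 3),
    matrix(integer(0), 0, 2), list(), rep(q0, 2 * 8192), rep(0, 8192),
    .cpp_cfg(8192, max_cycles = 40, tol = 0.01, la = 0L))
  expect_true(out$converged)
  drop_solver <- mean(out$p[[1]][, 1]) - mean(out$p[[1]][, v$n])
  drop_oracle <- steady_pressure_oracle(q0, r0, L, K, p_out = 0)
  expect_equal(drop_solver, drop_oracle, tolerance = 5e-3)
  # flow is uniform along the vessel in steady state
  expect_lt(max(abs(out$q[[1]] - q0)) / q0, 1e-3)
})

test_that("identical daughters split the parent flow symmetrically and the
           junction enforces its coupling conditions", {
  # one parent feeding two identical daughters, pressure-clamped outlets
  par <- .vessel_spec(0.5, 4, 8e5, 0.25)
  d <- .vessel_spec(0.35, 3, 8e5, 0.25)
  junc <- matrix(c(0L, 1L, 1L, 0L, 2L, 0L), 1, 6)
  sg <- matrix(c(1, -1, -1), 1, 3)
  n_per <- 4096
  t <- (0:(2 * n_per - 1)) / (2 * n_per)
  inflow <- 40 + 30 * sin(2 * pi * t)
  out <- pulmnet:::solve_network_cpp(
    list(par, d, d), junc, sg, matrix(integer(0), 0, 2), list(),
    inflow, rep(0, n_per), .cpp_cfg(n_per, max_cycles = 30, la = c(1L, 2L)))
  expect_true(out$converged)
  expect_equal(out$q[[2]], out$q[[3]], tolerance = 1e-12)
  expect_equal(out$q[[2]][, 1] * 2, out$q[[1]][, par$n], tolerance = 1e-9)
  # junction diagnostics: mass defect and static-pressure continuity
  expect_lt(out$junction_mass_defect, 1e-10)
  expect_lt(out$junction_pressure_defect, 1e-8)
  expect_equal(out$p[[2]][, 1], out$p[[1]][, par$n], tolerance = 1e-6)
})

test_that("full network run conserves mass and orders mean pressures", {
  sim <- shared_sim()
  expect_true(sim$converged)
  expect_lt(sim$cfl_max, 1)
  mb <- mass_balance(sim)
  expect_lt(mb$relative_error, 0.01)
  expect_lt(sim$junction_mass_defect, 1e-10)
  # energy sanity: mean MPA pressure above mean LA pressure
  expect_gt(mean(sim$p[["MPA"]]), mean(sim$la$samples))
  # pressure-area closure: p recomputed from A matches pointwise
  f <- 4 * sim$network$materials$K_A / 3
  A0 <- pi * 1.35^2
  expect_equal(sim$p[["MPA"]],
               f * (sqrt(sim$A[["MPA"]] / A0) - 1), tolerance = 1e-10)
})

test_that("terminal coupling transmits the mean flow through each bed", {
  sim <- shared_sim()
  for (k in seq_len(nrow(sim$network$pairs))) {
    a <- sim$network$pairs$artery[k]; v <- sim$network$pairs$vein[k]
    qa <- mean(sim$q[[a]][, ncol(sim$q[[a]])])
    qv <- mean(sim$q[[v]][, 1])
    expect_equal(qa, qv, tolerance = 5e-3)
  }
})

test_that("halving the time step changes the converged trace by <0.5% RMS", {
  sim1 <- shared_sim()
  sim2 <- pulmsim(config = solver_config(dx = 0.25, n_per = 8192))
  mid <- ceiling(ncol(sim1$p[["MPA"]]) / 2)
  p1 <- sim1$p[["MPA"]][, mid]; p2 <- sim2$p[["MPA"]][, mid]
  expect_lt(sqrt(mean((p1 - p2)^2)) / sqrt(mean(p2^2)), 5e-3)
})

test_that("weak-forcing runs scale linearly with the inflow amplitude", {
  # at 1-2% of the nominal inflow the wall operates in its linear regime,
  # so pulse pressure must scale linearly with the inflow amplitude
  net <- default_network()
  tp <- list(alpha = 0.86, beta = 0.65, lrr_A = 30, lrr_V = 30,
             r_min = 5.5e-3, K_ST = 2.5e5)
  mk_inflow <- function(scale) {
    wf <- mpa_inflow()
    wf$samples <- wf$samples * scale
    wf
  }
  la0 <- la_pressure(p_base = 8, a_amp = 0, v_amp = 0)
  cfg <- solver_config(dx = 0.25, n_per = 4096, max_cycles = 40,
                       convergence_tol = 0.05)
  s1 <- pulmsim(net, tp, mk_inflow(0.01), la0, cfg)
  s2 <- pulmsim(net, tp, mk_inflow(0.02), la0, cfg)
  pp <- function(s) {
    p <- s$p[["MPA"]][, 1]
    max(p) - min(p)
  }
  expect_equal(pp(s2) / pp(s1), 2, tolerance = 0.02)
})

test_that("simulation summary reports physiological magnitudes", {
  s <- summary(shared_sim())
  art <- s[s$side == "arterial", ]
  ven <- s[s$side == "venous", ]
  expect_true(all(art$mean_p_mmHg > 8 & art$mean_p_mmHg < 60))
  expect_true(all(ven$mean_p_mmHg > 5 & ven$mean_p_mmHg < 20))
  expect_true(all(art$sys_p_mmHg > art$dia_p_mmHg))
  expect_equal(mean(shared_sim()$q[["MPA"]][, 1]) * 0.85, 70 * 0.98,
               tolerance = 0.02)
})
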