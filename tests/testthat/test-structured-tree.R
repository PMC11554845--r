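test_that("viscosity law matches hand-evaluated values and its asymptote", {
  # d = 10 um: eta = 3.2 - 2.44 exp(-0.06 * 10^0.645) ~ 1.33
  expect_equal(viscosity_of_radius(5e-4), 0.0133, tolerance = 2e-3)
  # d = 1000 um: eta ~ 3.186
  expect_equal(viscosity_of_radius(0.05), 0.0319, tolerance = 2e-3)
  # large-diameter limit equals the proximal viscosity 0.032
  expect_equal(viscosity_of_radius(10), 0.032, tolerance = 1e-4)
  expect_error(viscosity_of_radius(-1), "positive")
})

test_that("tree index follows the self-similar radius law and termination", {
  tp <- tree_parameters(alpha = 0.86, beta = 0.66, root_radius = 0.4,
                        r_min = 0.005)
  ti <- generate_tree_index(tp)
  expect_equal(ti$radius[ti$i == 2 & ti$j == 1], 0.86^2 * 0.66 * 0.4,
               tolerance = 1e-12)
  # pure-alpha path terminates at the first i with 0.4 * 0.86^i < 0.005
  expect_equal(max(ti$i[ti$j == 0]), 30)
  expect_true(ti$terminal[ti$i == 30 & ti$j == 0])
  # a node is terminal exactly when its radius first crosses the cutoff
  expect_equal(ti$terminal, ti$radius < 0.005)
  # lengths scale with the length-to-radius ratios
  expect_equal(ti$L_A, ti$radius * tp$lrr_A)
  expect_equal(ti$L_V, ti$radius * tp$lrr_V)
})

test_that("a cutoff above both daughter radii yields the 3-node tree", {
  tp <- tree_parameters(alpha = 0.8, beta = 0.7, root_radius = 0.1,
                        r_min = 0.09)
  ti <- generate_tree_index(tp)
  expect_equal(nrow(ti), 3)
  expect_equal(sum(ti$terminal), 2)
  expect_false(ti$terminal[ti$i == 0 & ti$j == 0])
})

test_that("node-count cap raises an informative error", {
  tp <- tree_parameters(alpha = 0.95, beta = 0.94, root_radius = 1,
                        r_min = 1e-4)
  expect_error(generate_tree_index(tp, max_nodes = 100), "r_min")
})

test_that("vessel admittance reduces to Poiseuille at DC and is symmetric", {
  Y0 <- vessel_admittance(0.05, 1.0, 2.5e5, 0, mu = 0.03)
  y <- pi * 0.05^4 / (8 * 0.03 * 1.0)
  expect_equal(Re(Y0[1, 1]), y, tolerance = 1e-12)
  expect_equal(Y0[1, 2], -Y0[1, 1])
  for (w in c(0.5, 7.4, 50, 300)) {
    Y <- vessel_admittance(0.05, 1.0, 2.5e5, w)
    expect_identical(Y[1, 2], Y[2, 1])
  }
})

test_that("oscillatory admittance converges to the DC form as omega -> 0", {
  r0 <- 0.05; L <- 1.0; K <- 2.5e5; mu <- 0.012
  Y0 <- vessel_admittance(r0, L, K, 0, mu = mu)
  # choose omega so that |omega L / c| ~ 1e-3
  C <- 1.5 * pi * r0^2 / K
  A0 <- pi * r0^2
  # small-omega wave speed: c ~ sqrt(i A0 r0^2 omega / (8 mu C)) -> |c|
  for (target in c(1e-3)) {
    w <- 1e-8
    for (iter in 1:40) {
      cmag <- sqrt(A0 * r0^2 * w / (8 * mu * C))
      w <- target * cmag / L
    }
    Yw <- vessel_admittance(r0, L, K, w, mu = mu)
    expect_lt(max(Mod(Yw - Y0)) / Mod(Y0[1, 1]), 1e-3)
  }
})

test_that("grand admittance of a single terminal pair is the series of two
           Poiseuille resistances", {
  tp <- tree_parameters(alpha = 0.8, beta = 0.7, root_radius = 0.1,
                        r_min = 0.09, lrr_A = 20, lrr_V = 15)
  g <- spectral_grid(0.85, 16)
  # root with two terminal daughters; compare against explicit arithmetic
  ga <- grand_admittance(params = tp, grid = g)
  Rp <- function(r, L) 8 * viscosity_of_radius(r) * L / (pi * r^4)
  seg <- function(r) Rp(r, r * tp$lrr_A) + Rp(r, r * tp$lrr_V)
  Rd <- 1 / (1 / seg(0.08) + 1 / seg(0.07))
  R_expect <- Rp(0.1, 0.1 * 20) + Rd + Rp(0.1, 0.1 * 15)
  expect_equal(ga$R_total, R_expect, tolerance = 1e-10)
})

test_that("grand DC admittance matches the explicit resistance-network
           oracle", {
  tp <- tree_parameters(alpha = 0.82, beta = 0.7, root_radius = 0.1,
                        r_min = 0.018, lrr_A = 25, lrr_V = 18)
  g <- spectral_grid(0.85, 8)
  ga <- grand_admittance(params = tp, grid = g)
  expect_lte(nrow(ga$tree), 200)
  oracle <- resistance_network_oracle(tp)
  Ydc <- matrix(c(Re(ga$Y$Y11[1]), Re(ga$Y$Y21[1]),
                  Re(ga$Y$Y12[1]), Re(ga$Y$Y22[1])), 2, 2)
  expect_equal(Ydc, oracle, tolerance = 1e-8)
})

test_that("grand admittance obeys reciprocity, DC sign structure and real
           kernels", {
  tp <- tree_parameters(root_radius = 0.4)
  g <- spectral_grid(0.85, 128)
  ga <- grand_admittance(params = tp, grid = g)
  expect_equal(ga$Y$Y12, ga$Y$Y21, tolerance = 1e-12)
  expect_equal(Re(ga$Y$Y11[1]), Re(ga$Y$Y22[1]), tolerance = 1e-10)
  expect_equal(Re(ga$Y$Y12[1]), -Re(ga$Y$Y11[1]), tolerance = 1e-10)
  expect_gt(ga$R_total, 0)
  # kernels are real by construction; verify DC gains
  expect_equal(sum(ga$kernels[, "Y11"]) * g$period / g$n_samples,
               1 / ga$R_total, tolerance = 1e-10)
})

test_that("DC resistance is monotone in the tree geometry", {
  g <- spectral_grid(0.85, 8)
  R <- function(...) grand_admittance(params = tree_parameters(...),
                                      grid = g)$R_total
  base <- list(alpha = 0.86, beta = 0.65, root_radius = 0.3, r_min = 0.01)
  expect_gt(do.call(R, base), do.call(R, modifyList(base, list(alpha = 0.9))))
  expect_gt(do.call(R, base), do.call(R, modifyList(base, list(beta = 0.68))))
  # lowering the cutoff adds generations and raises the total resistance
  expect_gt(do.call(R, modifyList(base, list(r_min = 0.005))), do.call(R, base))
})

test_that("DC resistance scales linearly with a constant viscosity override", {
  tp <- tree_parameters(root_radius = 0.2, r_min = 0.02)
  g <- spectral_grid(0.85, 8)
  R1 <- grand_admittance(params = tp, grid = g,
                         mu_fun = function(r) 0.02)$R_total
  R3 <- grand_admittance(params = tp, grid = g,
                         mu_fun = function(r) 0.06)$R_total
  expect_equal(R3 / R1, 3, tolerance = 1e-10)
})

test_that("coupling convolution reproduces the DC gain and conserves flow", {
  tp <- tree_parameters(root_radius = 0.3, r_min = 0.03)
  g <- spectral_grid(0.85, 64)
  ga <- grand_admittance(params = tp, grid = g)
  pA <- rep(2e4, 64); pV <- rep(8e3, 64)
  cv <- coupling_convolution(pA, pV, ga$kernels, g$period)
  expect_equal(cv$q_A, (2e4 - 8e3) / ga$R_total, tolerance = 1e-10)
  expect_equal(cv$q_A, cv$q_V, tolerance = 1e-10)
  cv0 <- coupling_convolution(pA, pA, ga$kernels, g$period)
  expect_equal(cv0$q_A, 0, tolerance = 1e-12)
  expect_equal(cv0$q_V, 0, tolerance = 1e-12)
  expect_error(coupling_convolution(pA[1:10], pV, ga$kernels, g$period),
               "mismatch")
})
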