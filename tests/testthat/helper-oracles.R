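# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths.

# Brute-force Poiseuille resistance-network solution of a two-sided
# structured-tree bed at DC: the tree is expanded into explicit vessel
# instances (no index-pair memoization), assembled as a nodal conductance
# system and solved with base R linear algebra.  Returns the 2x2 DC
# admittance in the into-port convention.
resistance_network_oracle <- function(params, mu_fun = viscosity_of_radius) {
  cond <- function(r, L) pi * r^4 / (8 * mu_fun(r) * L)
  nodes <- 0L                       # interior potential counter
  rows <- list()                    # edges: (n1, n2, g); 0 = P_A, -1 = P_V
  new_node <- function() { nodes <<- nodes + 1L; nodes }
  # returns nothing; appends edges between 'top' (arterial side) and
  # 'vtop' (venous side) for the instance with radius r
  build <- function(r, top, vtop) {
    terminal <- r < params$r_min
    bottom <- new_node()
    rows[[length(rows) + 1]] <<- c(top, bottom, cond(r, r * params$lrr_A))
    if (terminal) {
      rows[[length(rows) + 1]] <<- c(bottom, vtop, cond(r, r * params$lrr_V))
    } else {
      vbottom <- new_node()
      rows[[length(rows) + 1]] <<- c(vbottom, vtop, cond(r, r * params$lrr_V))
      build(r * params$alpha, bottom, vbottom)
      build(r * params$beta, bottom, vbottom)
    }
  }
  build(params$root_radius, 0L, -1L)
  E <- do.call(rbind, rows)
  solve_for <- function(PA, PV) {
    G <- matrix(0, nodes, nodes); b <- numeric(nodes)
    src <- function(id) if (id == 0L) PA else PV
    for (k in seq_len(nrow(E))) {
      n1 <- E[k, 1]; n2 <- E[k, 2]; g <- E[k, 3]
      for (pair in list(c(n1, n2), c(n2, n1))) {
        i <- pair[1]; j <- pair[2]
        if (i > 0) {
          G[i, i] <- G[i, i] + g
          if (j > 0) G[i, j] <- G[i, j] - g else b[i] <- b[i] + g * src(j)
        }
      }
    }
    phi <- solve(G, b)
    pot <- function(id) if (id > 0) phi[id] else src(id)
    # into-port currents at the two sources
    qA <- 0; qV <- 0
    for (k in seq_len(nrow(E))) {
      n1 <- E[k, 1]; n2 <- E[k, 2]; g <- E[k, 3]
      if (n1 == 0L) qA <- qA + g * (PA - pot(n2))
      if (n2 == 0L) qA <- qA + g * (PA - pot(n1))
      if (n1 == -1L) qV <- qV + g * (PV - pot(n2))
      if (n2 == -1L) qV <- qV + g * (PV - pot(n1))
    }
    c(qA, qV)
  }
  cbind(solve_for(1, 0), solve_for(0, 1))  # columns: unit P_A, unit P_V
}

# Pick-freeze (Saltelli/Jansen) Monte-Carlo Sobol' estimator for a function
# f of independent U(-1,1) inputs; independent of the PCE path.
pick_freeze_sobol <- function(f, n_param, N = 1e5, seed = 42) {
  set.seed(seed)
  A <- matrix(stats::runif(N * n_param, -1, 1), N)
  B <- matrix(stats::runif(N * n_param, -1, 1), N)
  yA <- f(A); yB <- f(B)
  V <- stats::var(c(yA, yB))
  S <- ST <- numeric(n_param)
  for (i in seq_len(n_param)) {
    ABi <- A; ABi[, i] <- B[, i]
    yABi <- f(ABi)
    S[i] <- mean(yB * (yABi - yA)) / V
    ST[i] <- 0.5 * mean((yA - yABi)^2) / V
  }
  list(S = S, S_T = ST)
}

# Steady 1D pressure-drop oracle: integrate dp/dx = -2 pi nu rho (gamma+2)
# q0 / A(p)^2 from the outlet (p = p_out) back to the inlet with RK4.
steady_pressure_oracle <- function(q0, r0, L, K, p_out = 0, rho = 1.055,
                                   nu = 3.03e-2, gamma = 9, n = 4000) {
  A0 <- pi * r0^2
  f <- 4 * K / 3
  A_of_p <- function(p) A0 * (1 + p / f)^2
  dpdx <- function(p) -2 * pi * nu * rho * (gamma + 2) * q0 / A_of_p(p)^2
  h <- -L / n   # integrate from x = L to x = 0
  p <- p_out
  for (k in seq_len(n)) {
    k1 <- dpdx(p); k2 <- dpdx(p + h * k1 / 2)
    k3 <- dpdx(p + h * k2 / 2); k4 <- dpdx(p + h * k3)
    p <- p + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  p - p_out   # inlet minus outlet pressure
}

ishigami <- function(z) {
  x <- pi * z   # map [-1,1] -> [-pi,pi]
  sin(x[, 1]) + 7 * sin(x[, 2])^2 + 0.1 * x[, 3]^4 * sin(x[, 1])
}
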