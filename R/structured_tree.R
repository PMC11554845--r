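#' Radius-dependent apparent blood viscosity
#'
#' Empirical in-vitro relative viscosity of blood in small tubes as a function
#' of diameter, anchored so the large-vessel limit equals the proximal dynamic
#' viscosity: \eqn{\mu(r) = \mu_{plasma}\,\eta_{rel}(d)} with \eqn{d = 2r} in
#' micrometres, \eqn{\eta_{rel}(d) = 220 e^{-1.3 d} + 3.2 - 2.44
#' e^{-0.06 d^{0.645}}} and \eqn{\mu_{plasma} = 0.032/3.2 = 0.01} g/(cm s).
#'
#' @param r vessel radius, cm (vectorized).
#' @param mu_plasma plasma viscosity scale, g/(cm s).
#' @return dynamic viscosity, g/(cm s).
#' @export
viscosity_of_radius <- function(r, mu_plasma = 0.01) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("radius must be positive")
  d <- 2 * r * 1e4  # diameter in micrometres
  eta <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  mu_plasma * eta
}

#' Structured-tree parameters
#'
#' Parameters of the self-similar, bifurcating distal bed: daughter radius
#' scaling factors `alpha` (major) and `beta` (minor), arterial and venous
#' length-to-radius ratios, the terminal radius cutoff `r_min`, the distal wall
#' stiffness `K_ST` = Eh/r0, and the root radius inherited from the attached
#' terminal proximal artery.
#'
#' @param alpha,beta dimensionless radius scaling factors, 0 < beta <= alpha < 1.
#' @param lrr_A,lrr_V dimensionless length-to-radius ratios.
#' @param r_min terminal radius cutoff, cm; must be below `root_radius`.
#' @param K_ST distal wall stiffness, dyn/cm^2.
#' @param root_radius radius of the attached terminal proximal artery, cm.
#' @return A list of class `"tree_parameters"`.
#' @export
tree_parameters <- function(alpha = 0.86, beta = 0.65, lrr_A = 30, lrr_V = 30,
                            r_min = 5.5e-3, K_ST = 2.5e5, root_radius = 0.5) {
  if (!(alpha > 0 && alpha < 1 && beta > 0 && beta <= alpha))
    stop("need 0 < beta <= alpha < 1")
  if (!(r_min > 0 && r_min < root_radius))
    stop("need 0 < r_min < root_radius")
  if (any(c(lrr_A, lrr_V, K_ST) <= 0)) stop("lrr and K_ST must be positive")
  structure(list(alpha = alpha, beta = beta, lrr_A = lrr_A, lrr_V = lrr_V,
                 r_min = r_min, K_ST = K_ST, root_radius = root_radius),
            class = "tree_parameters")
}

#' Enumerate the distinct nodes of a structured tree
#'
#' Nodes are indexed by the pair (i, j): the number of major (alpha) and minor
#' (beta) radius scalings from the root, with radius
#' \eqn{r_{ij} = \alpha^i \beta^j r_{root}}. Nodes reachable along several
#' branching paths share one index pair. A node is terminal when its radius
#' first drops below `r_min` (its parent's radius is still at or above the
#' cutoff); terminal nodes carry no daughters.
#'
#' @param params a [tree_parameters()] object.
#' @param max_nodes cap on the number of distinct (i,j) nodes.
#' @return A data.frame of class `"tree_index"` with columns
#'   `i, j, radius, L_A, L_V, terminal`.
#' @export
generate_tree_index <- function(params, max_nodes = 1e6) {
  a <- params$alpha; b <- params$beta; r0 <- params$root_radius
  rmin <- params$r_min
  imax <- ceiling(log(rmin / r0) / log(a))  # first i with r0*a^i < rmin
  jmax <- ceiling(log(rmin / r0) / log(b))
  if ((imax + 1) * (jmax + 1) > 4 * max_nodes)
    stop("projected structured-tree node count exceeds cap; increase r_min")
  # DP over the index grid: a node exists iff some parent exists with r >= rmin
  exists <- matrix(FALSE, imax + 2, jmax + 2)
  radius <- outer(a^(0:(imax + 1)), b^(0:(jmax + 1))) * r0
  exists[1, 1] <- TRUE
  for (i in 0:(imax + 1)) for (j in 0:(jmax + 1)) {
    if (i == 0 && j == 0) next
    ok <- FALSE
    if (i > 0 && exists[i, j + 1] && radius[i, j + 1] >= rmin) ok <- TRUE
    if (!ok && j > 0 && exists[i + 1, j] && radius[i + 1, j] >= rmin) ok <- TRUE
    exists[i + 1, j + 1] <- ok
  }
  idx <- which(exists, arr.ind = TRUE)
  if (nrow(idx) > max_nodes)
    stop("structured tree has ", nrow(idx),
         " distinct nodes, over the cap; increase r_min")
  i <- idx[, 1] - 1L; j <- idx[, 2] - 1L
  r <- radius[idx]
  ord <- order(i + j, i)
  out <- data.frame(i = i[ord], j = j[ord], radius = r[ord],
                    L_A = r[ord] * params$lrr_A, L_V = r[ord] * params$lrr_V,
                    terminal = r[ord] < rmin)
  class(out) <- c("tree_index", "data.frame")
  attr(out, "params") <- params
  out
}

#' Spectral grid for the frequency-domain distal model
#'
#' Angular frequencies \eqn{\omega_k = 2\pi k / T}, k = 0..n_modes, with
#' `n_modes = n_samples/2`; the associated time grid has `n_samples` uniform
#' points per period.
#'
#' @param period cardiac period T, s.
#' @param n_samples samples per period (even; default 1024).
#' @return A list of class `"spectral_grid"` with `period`, `n_samples`,
#'   `n_modes` and `omegas`.
#' @export
spectral_grid <- function(period, n_samples = 1024) {
  stopifnot(period > 0, n_samples %% 2 == 0)
  n_modes <- n_samples / 2
  structure(list(period = period, n_samples = n_samples, n_modes = n_modes,
                 omegas = 2 * pi * (0:n_modes) / period),
            class = "spectral_grid")
}

# Womersley factor F_J = 2 J1(w0)/(w0 J0(w0)) with w0 = i^(3/2) x, for real
# Womersley number x >= 0.  Power series of J0, J1 for |x| <= 20; Hankel
# asymptotics (dominant exponential branch, Im w0 > 0) beyond.  Vectorized.
womersley_factor <- function(x) {
  out <- complex(length(x))
  small <- x <= 20
  if (any(small)) {
    z <- x[small] * exp(3i * pi / 4)
    z2 <- -(z * z) / 4          # series variable: J0 = sum (z2)^k / (k!)^2
    j0 <- rep(1 + 0i, length(z)); j1s <- rep(1 + 0i, length(z))
    t0 <- rep(1 + 0i, length(z)); t1 <- rep(1 + 0i, length(z))
    for (k in 1:60) {
      t0 <- t0 * z2 / (k * k)
      t1 <- t1 * z2 / (k * (k + 1))
      j0 <- j0 + t0
      j1s <- j1s + t1
      if (max(Mod(t0)) < 1e-18 * max(Mod(j0))) break
    }
    # J1(z) = (z/2) * j1s ; F = 2 J1/(z J0) = j1s/j0
    F <- j1s / j0
    F[x[small] == 0] <- 1 + 0i
    out[small] <- F
  }
  if (any(!small)) {
    z <- x[!small] * exp(3i * pi / 4)
    zi <- 1 / (8 * z)
    # Hankel P/Q series, dominant branch: J1/J0 = i (P1 + iQ1)/(P0 + iQ0)
    P0 <- 1 - 9 / 2 * zi^2 + 3675 / 8 * zi^4
    Q0 <- -zi + 75 / 2 * zi^3
    P1 <- 1 + 15 / 2 * zi^2 - 4725 / 8 * zi^4
    Q1 <- 3 * zi - 105 / 2 * zi^3
    ratio <- 1i * (P1 + 1i * Q1) / (P0 + 1i * Q0)  # J1/J0
    out[!small] <- 2 * ratio / z
  }
  out
}

#' Frequency-domain admittance of one structured-tree vessel
#'
#' The symmetric 2x2 admittance relating into-port flows to end pressures of a
#' single distal vessel. For \eqn{\omega > 0} it is the sinusoidal two-port
#' \deqn{Y = \frac{i g_\omega}{\sin(\omega L/c)}
#'   \begin{pmatrix} -\cos(\omega L/c) & 1 \\ 1 & -\cos(\omega L/c)\end{pmatrix}}
#' with \eqn{g_\omega = \sqrt{C A_0 (1-F_J)/\rho}}, the compliance per unit
#' length \eqn{C = (3/2)\pi r_0^2/K_{ST}}, the Womersley factor
#' \eqn{F_J = 2J_1(w_0)/(w_0 J_0(w_0))}, \eqn{w_0 = i^{3/2} r_0
#' \sqrt{\omega\rho/\mu}}, and wave speed \eqn{c = g_\omega / C}. At
#' \eqn{\omega = 0} it reduces exactly to the Poiseuille form
#' \eqn{(\pi r_0^4 / 8 \mu L)\,[1, -1; -1, 1]}.
#'
#' @param r0 reference radius, cm.
#' @param L vessel length, cm.
#' @param K_ST wall stiffness Eh/r0, dyn/cm^2.
#' @param omega angular frequency, rad/s (scalar or vector).
#' @param rho blood density, g/cm^3.
#' @param mu dynamic viscosity, g/(cm s); defaults to the radius-dependent law.
#' @return For scalar `omega`, a complex 2x2 matrix; for a vector, a list with
#'   complex vectors `Yd` (diagonal) and `Yo` (off-diagonal).
#' @export
vessel_admittance <- function(r0, L, K_ST, omega, rho = 1.055,
                              mu = viscosity_of_radius(r0)) {
  stopifnot(r0 > 0, L > 0, K_ST > 0, all(omega >= 0))
  v <- .vessel_admittance_vec(r0, L, K_ST, omega, rho, mu)
  if (length(omega) == 1L)
    return(matrix(c(v$Yd, v$Yo, v$Yo, v$Yd), 2, 2))
  v
}

# vectorized core; returns diagonal and off-diagonal entries per omega
.vessel_admittance_vec <- function(r0, L, K_ST, omega, rho, mu) {
  A0 <- pi * r0^2
  C <- 1.5 * A0 / K_ST
  Yd <- complex(length(omega)); Yo <- complex(length(omega))
  z0 <- omega == 0
  if (any(z0)) {
    y <- pi * r0^4 / (8 * mu * L)
    Yd[z0] <- y; Yo[z0] <- -y
  }
  if (any(!z0)) {
    w <- omega[!z0]
    x <- r0 * sqrt(w * rho / mu)
    FJ <- womersley_factor(x)
    g <- sqrt(C * A0 * (1 - FJ) / rho)
    g <- ifelse(Re(g) < 0, -g, g)
    cph <- g / C
    arg <- w * L / cph
    s <- sin(arg)
    bad <- Mod(s) < 1e-300
    if (any(bad))
      stop("resonant frequency in vessel admittance (sin(wL/c) ~ 0)")
    pre <- 1i * g / s
    Yd[!z0] <- -pre * cos(arg)
    Yo[!z0] <- pre
  }
  list(Yd = Yd, Yo = Yo)
}

# cascade two 2x2 two-ports sharing an interior node (into-port convention);
# each argument/result is a list of 4 complex vectors Y11, Y12, Y21, Y22
.cascade <- function(A, B) {
  D <- A$Y22 + B$Y11
  list(Y11 = A$Y11 - A$Y12 * A$Y21 / D,
       Y12 = -A$Y12 * B$Y12 / D,
       Y21 = -A$Y21 * B$Y21 / D,
       Y22 = B$Y22 - B$Y21 * B$Y12 / D)
}

.sym2port <- function(v) list(Y11 = v$Yd, Y12 = v$Yo, Y21 = v$Yo, Y22 = v$Yd)

#' Grand admittance of a two-sided structured-tree bed
#'
#' Condenses the paired arterial and venous self-similar trees into a single
#' 2x2 frequency-domain map between the terminal proximal artery outlet and
#' the terminal proximal vein inlet. At each terminal node the arterial segment
#' connects in series with its venous mirror; at each junction the daughter
#' subtrees add in parallel; parent segments are composed by two-port
#' condensation. The recursion is memoized on the (i,j) index pair. Real
#' periodic time-domain coupling kernels are obtained by inverse discrete
#' Fourier transform with Hermitian extension.
#'
#' The stored matrices use the symmetric into-port convention: at
#' \eqn{\omega = 0}, `Y11 = Y22 = -Y12 = -Y21 = 1/R_total`, where a positive
#' arteriovenous pressure difference drives positive artery-to-vein flow.
#'
#' @param tree a [generate_tree_index()] result (or `NULL` to generate it).
#' @param params a [tree_parameters()] object.
#' @param grid a [spectral_grid()] object.
#' @param venous_root_radius recorded for provenance; radii of the venous
#'   mirror tree equal the arterial radii node-for-node, so it does not enter
#'   the geometry.
#' @param rho blood density, g/cm^3.
#' @param keep_memo keep per-node subtree two-ports (needed by
#'   [propagate_pathway()]).
#' @param mu_fun viscosity law, a function of radius; override with a constant
#'   function for scaling checks.
#' @return A list of class `"grand_admittance"`: `omegas`, `Y` (four complex
#'   vectors, one per matrix entry), `kernels` (n_samples x 4 real matrix,
#'   columns y11, y12, y21, y22), `R_total`, the tree, params and grid, and
#'   optionally the memoized per-node two-ports.
#' @export
grand_admittance <- function(tree = NULL, params, grid,
                             venous_root_radius = NULL, rho = 1.055,
                             keep_memo = FALSE,
                             mu_fun = viscosity_of_radius) {
  if (is.null(tree)) tree <- generate_tree_index(params)
  nw <- length(grid$omegas)
  n <- nrow(tree)
  key <- paste(tree$i, tree$j)
  rowof <- seq_len(n); names(rowof) <- key
  memo <- vector("list", n)
  # bottom-up over decreasing generation i+j
  ord <- order(-(tree$i + tree$j))
  for (idx in ord) {
    r <- tree$radius[idx]
    mu <- mu_fun(r)
    Ya <- .sym2port(.vessel_admittance_vec(r, tree$L_A[idx], params$K_ST,
                                           grid$omegas, rho, mu))
    Yv <- .sym2port(.vessel_admittance_vec(r, tree$L_V[idx], params$K_ST,
                                           grid$omegas, rho, mu))
    if (tree$terminal[idx]) {
      memo[[idx]] <- .cascade(Ya, Yv)
    } else {
      d1 <- rowof[[paste(tree$i[idx] + 1L, tree$j[idx])]]
      d2 <- rowof[[paste(tree$i[idx], tree$j[idx] + 1L)]]
      Yp <- Map(`+`, memo[[d1]], memo[[d2]])
      memo[[idx]] <- .cascade(Ya, .cascade(Yp, Yv))
    }
  }
  root <- rowof[["0 0"]]
  Y <- memo[[root]]
  R_total <- 1 / Re(Y$Y11[1])
  kernels <- sapply(Y, .kernel_from_spectrum, grid = grid)
  out <- list(omegas = grid$omegas, Y = Y, kernels = kernels,
              R_total = R_total, tree = tree, params = params, grid = grid,
              rho = rho, mu_fun = mu_fun)
  if (keep_memo) out$memo <- list(rowof = rowof, nodes = memo)
  class(out) <- "grand_admittance"
  out
}

# inverse DFT with Hermitian extension: kernel y(t_m), m = 0..n-1, such that
# q(t) = sum_m y_m p(t - m dt) dt reproduces Y_k at every retained mode
.kernel_from_spectrum <- function(Yk, grid) {
  n <- grid$n_samples
  full <- complex(n)
  full[1] <- Yk[1]
  full[2:(n / 2)] <- Yk[2:(n / 2)]
  full[n / 2 + 1] <- Re(Yk[n / 2 + 1])  # Nyquist mode kept real
  full[(n / 2 + 2):n] <- Conj(Yk[(n / 2):2])
  y <- stats::fft(full, inverse = TRUE) / grid$period
  if (max(abs(Im(y))) > 1e-10 * max(abs(Re(y))))
    stop("kernel inverse transform is not real; Hermitian symmetry broken")
  Re(y)
}

#' Terminal coupling flows by periodic convolution
#'
#' Discrete periodic convolution of the paired terminal-artery outlet and
#' terminal-vein inlet pressure histories with the grand-admittance kernels.
#' Both returned flows are physical through-flows (artery outlet flow toward
#' the bed; vein inlet flow out of the bed), so at DC both equal
#' \eqn{(\bar p_A - \bar p_V)/R_{total}}.
#'
#' @param p_A_history,p_V_history pressure samples over one period (dyn/cm^2),
#'   length equal to the kernel length, sample m at time t - m*dt.
#' @param kernels the `kernels` matrix of a [grand_admittance()] object.
#' @param period cardiac period, s.
#' @return A list with `q_A` and `q_V` (cm^3/s) evaluated at the current time.
#' @export
coupling_convolution <- function(p_A_history, p_V_history, kernels, period) {
  n <- nrow(kernels)
  if (length(p_A_history) != n || length(p_V_history) != n)
    stop("kernel/period mismatch: histories must have ", n, " samples")
  dt <- period / n
  q_A <- sum(kernels[, "Y11"] * p_A_history + kernels[, "Y12"] * p_V_history) * dt
  q_V <- -sum(kernels[, "Y21"] * p_A_history + kernels[, "Y22"] * p_V_history) * dt
  list(q_A = q_A, q_V = q_V)
}
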