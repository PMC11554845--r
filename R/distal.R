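# inverse real DFT from half-spectrum X (modes 0..n/2, fft(x)/n convention)
.irdft <- function(X, n) {
  full <- complex(n)
  full[1] <- X[1]
  full[2:(n / 2)] <- X[2:(n / 2)]
  full[n / 2 + 1] <- Re(X[n / 2 + 1])
  full[(n / 2 + 2):n] <- Conj(X[(n / 2):2])
  Re(stats::fft(full, inverse = TRUE))
}

#' Reconstruct haemodynamics along a structured-tree pathway
#'
#' Walks the alpha pathway (repeated major daughters; the longest root-to-
#' termination path) or the beta pathway (repeated minor daughters; the
#' shortest) of a two-sided bed, from the root pressure spectra of the
#' attached terminal proximal artery and vein. At each vessel the per-vessel
#' admittance and the memoized downstream subtree two-port give the entrance
#' flow, the exit pressure and the through-flow; at the terminal node the walk
#' crosses to the venous mirror and continues toward the venous root. Mean
#' (DC) pressure and flow, Poiseuille wall shear stress and cyclic stretch are
#' reported per node, with a normalized distance-from-termination coordinate
#' (0 = smallest vessel, 1 = bed root) per side.
#'
#' @param bed a [grand_admittance()] object built with `keep_memo = TRUE`.
#' @param P_root_A,P_root_V half-spectra (modes 0..n_modes, `fft(p)/n`
#'   convention) of the terminal-artery outlet and terminal-vein inlet
#'   pressures on the bed's spectral grid.
#' @param pathway `"alpha"` or `"beta"`.
#' @return A data.frame of class `"pathway_profile"` with columns `side,
#'   pathway, node, i, j, radius, dist, xnorm, mean_p, mean_q, wss, cs`
#'   (CGS units), arterial rows root-to-termination followed by venous rows
#'   termination-to-root.
#' @export
propagate_pathway <- function(bed, P_root_A, P_root_V,
                              pathway = c("alpha", "beta")) {
  pathway <- match.arg(pathway)
  if (is.null(bed$memo))
    stop("bed must be built with keep_memo = TRUE")
  tree <- bed$tree; pars <- bed$params
  n_kern <- bed$grid$n_samples
  rowof <- bed$memo$rowof
  # pathway node rows until the terminal node
  steps <- if (pathway == "alpha") cbind(0:max(tree$i), 0L)
           else cbind(0L, 0:max(tree$j))
  keys <- paste(steps[, 1], steps[, 2])
  keys <- keys[keys %in% names(rowof)]
  rows <- rowof[keys]
  term <- which(tree$terminal[rows])[1]
  rows <- rows[seq_len(term)]

  PA <- P_root_A; PV <- P_root_V
  art <- list(); ven <- list()
  for (m in seq_along(rows)) {
    idx <- rows[m]
    r <- tree$radius[idx]
    mu <- bed$mu_fun(r)
    Ya <- .sym2port(.vessel_admittance_vec(r, tree$L_A[idx], pars$K_ST,
                                           bed$omegas, bed$rho, mu))
    Yv <- .sym2port(.vessel_admittance_vec(r, tree$L_V[idx], pars$K_ST,
                                           bed$omegas, bed$rho, mu))
    Ys <- bed$memo$nodes[[idx]]
    Qin <- Ys$Y11 * PA + Ys$Y12 * PV
    PL <- (Qin - Ya$Y11 * PA) / Ya$Y12
    Qv_out <- -(Ys$Y21 * PA + Ys$Y22 * PV)
    pm <- (-Qv_out - Yv$Y22 * PV) / Yv$Y21
    art[[m]] <- list(idx = idx, r = r, mu = mu,
                     Pmid = (PA + PL) / 2, Qdc = Re(Qin[1]))
    ven[[m]] <- list(idx = idx, r = r, mu = mu,
                     Pmid = (pm + PV) / 2, Qdc = Re(Qv_out[1]))
    PA <- PL; PV <- pm
  }

  node_row <- function(x, side, dist) {
    p_t <- .irdft(x$Pmid, n_kern)
    # WSS on the tree's reference radii: the frequency-domain bed is
    # linearized about r_ij, so the DC radius is the reference radius
    data.frame(side = side, pathway = pathway,
               i = tree$i[x$idx], j = tree$j[x$idx], radius = x$r,
               dist = dist, mean_p = Re(x$Pmid[1]), mean_q = x$Qdc,
               wss = distal_wss(x$Qdc, x$r, pars$K_ST, mu = x$mu),
               cs = distal_cs(p_t, x$r, pars$K_ST))
  }
  lens_a <- tree$L_A[rows]; lens_v <- tree$L_V[rows]
  mid_a <- cumsum(lens_a) - lens_a / 2
  Sa <- sum(lens_a); Sv <- sum(lens_v)
  out_a <- do.call(rbind, Map(node_row, art, "arterial", mid_a))
  out_a$xnorm <- pmax(0, 1 - mid_a / Sa)
  # venous rows mirror back: termination first, root last
  ven <- rev(ven)
  lens_vr <- rev(lens_v)
  mid_v <- cumsum(lens_vr) - lens_vr / 2
  out_v <- do.call(rbind, Map(node_row, ven, "venous", Sa + mid_v))
  out_v$xnorm <- pmin(1, mid_v / Sv)
  out <- rbind(out_a, out_v)
  out$node <- seq_len(nrow(out))
  class(out) <- c("pathway_profile", "data.frame")
  out
}

#' Poiseuille wall shear stress in a distal vessel
#'
#' \eqn{WSS = 4\mu(r)\bar Q / (\pi \bar R^3)}. The frequency-domain tree is
#' linearized about its reference radii, so by default \eqn{\bar R = r_0};
#' passing a mean pressure applies the linear wall-law distension
#' \eqn{\bar R = r_0(1 + 3\bar p/(4K_{ST}))} instead.
#'
#' @param q_mean time-averaged flow, cm^3/s.
#' @param r0 reference radius, cm.
#' @param K_ST distal wall stiffness, dyn/cm^2.
#' @param p_mean time-averaged pressure, dyn/cm^2 (default 0: no distension).
#' @param mu viscosity, g/(cm s); default radius-dependent.
#' @return Mean wall shear stress, dyn/cm^2.
#' @export
distal_wss <- function(q_mean, r0, K_ST, p_mean = 0,
                       mu = viscosity_of_radius(r0)) {
  Rbar <- r0 * (1 + 3 * p_mean / (4 * K_ST))
  4 * mu * q_mean / (pi * Rbar^3)
}

#' Cyclic stretch of a distal vessel from its pressure series
#'
#' Linearized wall law \eqn{R(t) = r_0(1 + 3p(t)/(4K_{ST}))};
#' \eqn{CS = (\max R - \min R)/\min R}, independent of \eqn{r_0}.
#'
#' @param p_t pressure time series over one period, dyn/cm^2.
#' @param r0 reference radius, cm.
#' @param K_ST distal wall stiffness, dyn/cm^2.
#' @return Dimensionless cyclic stretch.
#' @export
distal_cs <- function(p_t, r0, K_ST) {
  R <- r0 * (1 + 3 * p_t / (4 * K_ST))
  if (min(R) <= 0) stop("non-physical pressure excursion in distal vessel")
  (max(R) - min(R)) / min(R)
}

#' Alpha and beta pathway profiles of one bed of a simulation
#'
#' Rebuilds the requested bed with per-node memoization, Fourier-transforms
#' the converged terminal coupling pressures, and reconstructs both pathways.
#'
#' @param sim a `"pulmsim"` object.
#' @param bed_name terminal artery label (e.g. `"RIA D1"`).
#' @return A list with elements `alpha` and `beta`, each a
#'   `"pathway_profile"`.
#' @export
distal_pathways <- function(sim, bed_name = sim$network$pairs$artery[1]) {
  if (!bed_name %in% sim$network$pairs$artery)
    stop("unknown bed: ", bed_name)
  bed <- sim$beds[[bed_name]]
  if (is.null(bed$memo)) {
    bed <- grand_admittance(tree = bed$tree, params = bed$params,
                            grid = bed$grid, rho = bed$rho,
                            keep_memo = TRUE, mu_fun = bed$mu_fun)
  }
  n <- sim$config$n_kern
  PA <- stats::fft(sim$pA_term[, bed_name]) / n
  PV <- stats::fft(sim$pV_term[, bed_name]) / n
  nm <- n / 2 + 1
  list(alpha = propagate_pathway(bed, PA[1:nm], PV[1:nm], "alpha"),
       beta = propagate_pathway(bed, PA[1:nm], PV[1:nm], "beta"))
}

#' Interpolate a pathway profile onto a fixed normalized grid
#'
#' Because `r_min` varies across parameter draws, ensemble profiles are
#' compared on a normalized distance-from-termination coordinate
#' (0 = smallest vessel, 1 = bed root).
#'
#' @param profile a `"pathway_profile"`.
#' @param side `"arterial"` or `"venous"`.
#' @param xout grid of normalized coordinates in `[0, 1]`.
#' @return A data.frame with `xnorm` and interpolated `mean_p, mean_q, wss, cs`.
#' @export
profile_on_grid <- function(profile, side = "arterial",
                            xout = seq(0, 1, length.out = 33)) {
  pr <- profile[profile$side == side, ]
  pr <- pr[order(pr$xnorm), ]
  interp <- function(y) stats::approx(pr$xnorm, y, xout = xout, rule = 2)$y
  data.frame(xnorm = xout, mean_p = interp(pr$mean_p),
             mean_q = interp(pr$mean_q), wss = interp(pr$wss),
             cs = interp(pr$cs))
}
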