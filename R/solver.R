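#' Solver configuration for the proximal 1D model
#'
#' Time step and grid resolution for the two-step Lax-Wendroff scheme. Each
#' vessel is discretized with `n = max(3, round(L/dx) + 1)` nodes so vessel
#' ends land on nodes; the per-vessel spacing is `L/(n-1)`. The time step is
#' `dt = T/n_per`; with the defaults (`dx = 0.125` cm, `n_per = 8192`,
#' T = 0.85 s) dt is about 1.04e-4 s and the CFL number stays near 0.7 across
#' the parameter priors. `n_per` must be a multiple of `n_kern`, the
#' samples-per-period of the coupling kernels and of the stored output fields.
#'
#' @param dx target spatial step, cm.
#' @param n_per solver time steps per cardiac cycle.
#' @param n_kern kernel/output samples per cycle (spectral modes 0..n_kern/2).
#' @param max_cycles cap on cardiac cycles run to periodic steady state.
#' @param convergence_tol beat-to-beat pressure tolerance, dyn/cm^2.
#' @param ramp_first_cycle ramp the inflow over the first cycle to soften the
#'   impulsive start (fields initialize at the mean left-atrial pressure).
#' @return A list of class `"solver_config"`.
#' @export
solver_config <- function(dx = 0.125, n_per = 8192, n_kern = 1024,
                          max_cycles = 150, convergence_tol = 1.0,
                          ramp_first_cycle = TRUE) {
  if (n_per %% n_kern != 0) stop("n_per must be a multiple of n_kern")
  structure(list(dx = dx, n_per = n_per, n_kern = n_kern,
                 max_cycles = max_cycles, convergence_tol = convergence_tol,
                 ramp_first_cycle = ramp_first_cycle),
            class = "solver_config")
}

#' Build the eight structured-tree beds of a network
#'
#' One two-sided bed per terminal artery-vein pair, rooted at the terminal
#' artery radius, all sharing one set of structured-tree parameters.
#'
#' @param network a `"proximal_network"`.
#' @param tree_pars a list with `alpha, beta, lrr_A, lrr_V, r_min, K_ST`.
#' @param grid a [spectral_grid()].
#' @return A named list of [grand_admittance()] objects (names = terminal
#'   artery labels).
#' @export
build_beds <- function(network, tree_pars, grid) {
  beds <- lapply(seq_len(nrow(network$pairs)), function(k) {
    pr <- do.call(tree_parameters,
                  c(tree_pars[c("alpha", "beta", "lrr_A", "lrr_V",
                                "r_min", "K_ST")],
                    list(root_radius = network$pairs$root_radius[k])))
    grand_admittance(params = pr, grid = grid,
                     rho = network$materials$rho)
  })
  names(beds) <- network$pairs$artery
  beds
}

#' Simulate multiscale pulmonary haemodynamics
#'
#' Runs the nonlinear 1D proximal solver on the arterial and venous network,
#' driven by a prescribed MPA inflow, a left-atrial pressure at the four
#' proximal venous outlets, and grand-admittance convolution coupling across
#' the eight structured-tree beds, to a periodic steady state (beat-to-beat
#' inlet pressure change below `convergence_tol`). Pressure, flow and area
#' over the final cycle are returned on a grid of `n_kern` samples per period.
#'
#' @param network a `"proximal_network"` (default Table-style 15+12 network).
#' @param tree_pars structured-tree parameter list (`alpha, beta, lrr_A,
#'   lrr_V, r_min, K_ST`); see [tree_parameters()] for defaults.
#' @param inflow MPA inflow `"pulm_waveform"`; default [mpa_inflow()].
#' @param la left-atrial pressure `"pulm_waveform"`; default [la_pressure()].
#' @param config a [solver_config()].
#' @param beds optional precomputed [build_beds()] result on the matching
#'   spectral grid.
#' @return An object of class `"pulmsim"`: per-vessel `p` (dyn/cm^2), `q`
#'   (cm^3/s), `A` (cm^2) matrices (time x space), terminal coupling pressure
#'   histories, the converged-cycle time grid, convergence diagnostics, and
#'   the inputs.
#' @export
pulmsim <- function(network = default_network(),
                    tree_pars = tree_parameters(root_radius = 0.5),
                    inflow = mpa_inflow(), la = la_pressure(),
                    config = solver_config(), beds = NULL) {
  stopifnot(inherits(network, "proximal_network"))
  if (!isTRUE(all.equal(inflow$period, la$period)))
    stop("inflow and left-atrial waveforms must share one period")
  T <- inflow$period
  grid <- spectral_grid(T, config$n_kern)
  if (is.null(beds)) beds <- build_beds(network, tree_pars, grid)
  if (length(beds) != nrow(network$pairs))
    stop("need one structured-tree bed per terminal pair")
  if (!isTRUE(all.equal(beds[[1]]$grid$period, T)))
    stop("beds were built on a different spectral grid")

  tab <- network$segments
  mat <- network$materials
  id0 <- function(nm) match(nm, tab$name) - 1L
  vessels <- lapply(seq_len(nrow(tab)), function(i) {
    L <- tab$length_cm[i]
    n <- max(3L, round(L / config$dx) + 1L)
    K <- if (tab$side[i] == "arterial") mat$K_A else mat$K_V
    list(n = n, dx = L / (n - 1), A0 = pi * tab$radius_cm[i]^2, f = 4 * K / 3)
  })

  # junctions: arterial diverging (parent x=L feeds daughters x=0) and venous
  # converging (daughters x=L merge into the structural parent at its x=0)
  jrows <- list(); jsg <- list()
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(tab$daughter1[i])) next
    d1 <- tab$daughter1[i]; d2 <- tab$daughter2[i]
    if (tab$side[i] == "arterial") {
      jrows[[length(jrows) + 1]] <- c(id0(tab$name[i]), 1L, id0(d1), 0L, id0(d2), 0L)
    } else {
      jrows[[length(jrows) + 1]] <- c(id0(tab$name[i]), 0L, id0(d1), 1L, id0(d2), 1L)
    }
    jsg[[length(jsg) + 1]] <- c(ifelse(tab$side[i] == "arterial", 1, -1),
                                ifelse(tab$side[i] == "arterial", -1, 1),
                                ifelse(tab$side[i] == "arterial", -1, 1))
  }
  junctions <- do.call(rbind, jrows)
  jsigns <- do.call(rbind, jsg)

  pairs <- cbind(id0(network$pairs$artery), id0(network$pairs$vein))
  kernels <- lapply(network$pairs$artery, function(a) beds[[a]]$kernels)

  inflow_fine <- resample_waveform(inflow, 2L * config$n_per)
  la_fine <- resample_waveform(la, config$n_per)

  cfg <- list(n_per = config$n_per, n_kern = config$n_kern,
              max_cycles = config$max_cycles, tol = config$convergence_tol,
              rho = mat$rho, nu = mat$nu, gamma = mat$gamma, period = T,
              ramp_first_cycle = config$ramp_first_cycle,
              p_init = mean(la_fine$samples),  # start at mean LA pressure
              inlet_vessel = id0(network$inlet),
              la_vessels = id0(network$venous_outlets))

  raw <- solve_network_cpp(vessels, junctions, jsigns, pairs, kernels,
                           inflow_fine$samples, la_fine$samples, cfg)
  if (!raw$converged)
    warning(sprintf("not converged after %d cycles (last change %.3g dyn/cm^2)",
                    raw$cycles, raw$last_cycle_change))

  names(raw$p) <- names(raw$q) <- names(raw$A) <- tab$name
  colnames(raw$pA_term) <- colnames(raw$pV_term) <- network$pairs$artery
  structure(list(p = raw$p, q = raw$q, A = raw$A,
                 pA_term = raw$pA_term, pV_term = raw$pV_term,
                 times = T * seq_len(config$n_kern) / config$n_kern,
                 cycles = raw$cycles, converged = raw$converged,
                 cfl_max = raw$cfl_max,
                 junction_mass_defect = raw$junction_mass_defect,
                 junction_pressure_defect = raw$junction_pressure_defect,
                 last_cycle_change = raw$last_cycle_change,
                 network = network, tree_pars = tree_pars, beds = beds,
                 inflow = inflow, la = la, config = config),
            class = "pulmsim")
}

#' @export
print.pulmsim <- function(x, ...) {
  cat(sprintf("Multiscale pulmonary haemodynamics simulation (%s, %d cycles, CFL max %.2f)\n",
              if (x$converged) "converged" else "NOT converged",
              x$cycles, x$cfl_max))
  mp <- x$p[[x$network$inlet]]
  mid <- ceiling(ncol(mp) / 2)
  cat(sprintf("MPA pressure (mmHg): %.1f / %.1f (mean %.1f); cardiac output %.2f L/min\n",
              max(mp[, mid]) / 1333.22, min(mp[, mid]) / 1333.22,
              mean(mp[, mid]) / 1333.22,
              mean(x$q[[x$network$inlet]][, 1]) * 60 / 1000))
  invisible(x)
}

#' Per-vessel haemodynamic summary
#'
#' @param object a `"pulmsim"` object.
#' @param ... unused.
#' @return A data.frame with systolic/diastolic/mean midpoint pressure (mmHg),
#'   mean midpoint flow (cm^3/s), cyclic stretch and mean/peak wall shear
#'   stress (dyn/cm^2) per proximal vessel.
#' @export
summary.pulmsim <- function(object, ...) {
  tab <- object$network$segments
  rows <- lapply(tab$name, function(nm) {
    mid <- ceiling(ncol(object$p[[nm]]) / 2)
    p <- object$p[[nm]][, mid] / 1333.22
    q <- object$q[[nm]][, mid]
    wss <- proximal_wss(object, nm)
    data.frame(vessel = nm, side = tab$side[match(nm, tab$name)],
               sys_p_mmHg = max(p), dia_p_mmHg = min(p), mean_p_mmHg = mean(p),
               mean_q = mean(q), cs = cyclic_stretch(object, nm),
               mean_wss = mean(wss), peak_wss = max(abs(wss)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
plot.pulmsim <- function(x, vessels = x$network$inlet,
                         what = c("p", "q"), ...) {
  what <- match.arg(what)
  scale <- if (what == "p") 1 / 1333.22 else 1
  ylab <- if (what == "p") "pressure (mmHg)" else "flow (cm^3/s)"
  mats <- sapply(vessels, function(nm) {
    m <- x[[what]][[nm]]
    m[, ceiling(ncol(m) / 2)] * scale
  })
  graphics::matplot(x$times, mats, type = "l", lty = 1, xlab = "time (s)",
                    ylab = ylab, ...)
  graphics::legend("topright", legend = vessels, lty = 1,
                   col = seq_along(vessels), bty = "n")
  invisible(x)
}

#' Conservation audit over the converged cycle
#'
#' Compares the mean MPA inflow with the summed mean outflow of the eight
#' terminal arteries (flow into the microvascular beds).
#'
#' @param sim a `"pulmsim"` object.
#' @return A list with `inflow`, `terminal_outflow` and `relative_error`.
#' @export
mass_balance <- function(sim) {
  qin <- mean(sim$q[[sim$network$inlet]][, 1])
  qout <- sum(vapply(sim$network$pairs$artery, function(a) {
    m <- sim$q[[a]]
    mean(m[, ncol(m)])
  }, numeric(1)))
  list(inflow = qin, terminal_outflow = qout,
       relative_error = abs(qin - qout) / abs(qin))
}
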