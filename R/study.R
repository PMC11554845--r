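#' Run the multiscale model for one parameter draw
#'
#' Maps a named parameter vector (K_A, K_ST, K_V, alpha, beta, lrr_A, lrr_V,
#' r_min) onto the model inputs and runs [pulmsim()]. On a CFL failure the
#' solver is retried once with a halved time step.
#'
#' @param theta named numeric vector of the eight uncertain parameters.
#' @param inflow,la boundary waveforms.
#' @param config a [solver_config()].
#' @param network_base a `"proximal_network"` supplying the geometry.
#' @return A `"pulmsim"` object.
#' @export
simulate_sample <- function(theta, inflow = mpa_inflow(), la = la_pressure(),
                            config = solver_config(),
                            network_base = default_network()) {
  theta <- as.list(theta)
  mats <- material_parameters(K_A = theta$K_A, K_V = theta$K_V)
  net <- network_base
  net$materials <- mats
  tp <- theta[c("alpha", "beta", "lrr_A", "lrr_V", "r_min", "K_ST")]
  tryCatch(
    pulmsim(net, tree_pars = tp, inflow = inflow, la = la, config = config),
    error = function(e) {
      if (!grepl("CFL", conditionMessage(e))) stop(e)
      cfg2 <- config
      cfg2$n_per <- 2L * config$n_per
      pulmsim(net, tree_pars = tp, inflow = inflow, la = la, config = cfg2)
    })
}

# scalar QoIs of one simulation, as a flat named list of arrays
.collect_qois <- function(sim, distal_bed, nt_keep = 128, n_grid = 33) {
  tab <- sim$network$segments
  vn <- tab$name
  mid_q <- vapply(vn, function(nm) {
    m <- sim$q[[nm]]; mean(m[, ceiling(ncol(m) / 2)])
  }, numeric(1))
  mid_p <- vapply(vn, function(nm) {
    m <- sim$p[[nm]]; mean(m[, ceiling(ncol(m) / 2)])
  }, numeric(1))
  cs <- vapply(vn, function(nm) cyclic_stretch(sim, nm), numeric(1))
  wss <- vapply(vn, function(nm) mean(proximal_wss(sim, nm)), numeric(1))
  wia <- t(vapply(vn, function(nm) wave_intensity(sim, nm)$integrated,
                  numeric(4)))
  keep <- round(seq(1, length(sim$times), length.out = nt_keep))
  mpa_mid <- ceiling(ncol(sim$p[[sim$network$inlet]]) / 2)
  paths <- distal_pathways(sim, distal_bed)
  grids <- lapply(paths, profile_on_grid, xout = seq(0, 1, length.out = n_grid))
  list(vessels = vn, side = tab$side, mean_q = mid_q, mean_p = mid_p,
       cs = cs, mean_wss = wss, wia = wia,
       mpa_p = sim$p[[sim$network$inlet]][keep, mpa_mid],
       times = sim$times[keep],
       distal_alpha = grids$alpha, distal_beta = grids$beta,
       cycles = sim$cycles, converged = sim$converged)
}

#' Run a prior ensemble of multiscale simulations
#'
#' Draws `N` parameter sets from the uniform prior, runs the model for each,
#' and collects the quantities of interest: per-vessel time-averaged pressure,
#' flow and wall shear stress, cyclic stretch, integrated wave-intensity
#' magnitudes, the MPA midpoint pressure time series, and distal alpha/beta
#' pathway profiles of one bed on the normalized distance-from-termination
#' grid. Per-sample failures are caught, reported and excluded (with a warning
#' above a 2% failure fraction).
#'
#' @param N ensemble size.
#' @param seed RNG seed for the prior sample.
#' @param prior a [parameter_prior()].
#' @param inflow,la boundary waveforms.
#' @param config a [solver_config()]; ensemble studies typically use the
#'   coarse grid (`dx = 0.25`, `n_per = 4096`).
#' @param distal_bed terminal artery label of the bed whose pathways are kept.
#' @param design sampling design passed to [sample_prior()].
#' @param verbose print one line per sample.
#' @return A list of class `"pulm_ensemble"` with the prior draw, a logical
#'   `ok` vector, QoI arrays over successful samples, and metadata.
#' @export
run_ensemble <- function(N = 64, seed = 1, prior = parameter_prior(),
                         inflow = mpa_inflow(), la = la_pressure(),
                         config = solver_config(dx = 0.25, n_per = 4096),
                         distal_bed = "RIA D1", design = "random",
                         verbose = FALSE) {
  draw <- sample_prior(prior, N, seed = seed, design = design)
  res <- vector("list", N)
  ok <- logical(N)
  errors <- character(N)
  for (s in seq_len(N)) {
    out <- tryCatch(
      .collect_qois(simulate_sample(draw$theta[s, ], inflow, la, config),
                    distal_bed = distal_bed),
      error = function(e) conditionMessage(e))
    if (is.character(out)) {
      errors[s] <- out
    } else {
      res[[s]] <- out
      ok[s] <- TRUE
    }
    if (verbose)
      cat(sprintf("sample %d/%d: %s\n", s, N,
                  if (ok[s]) sprintf("ok (%d cycles)", res[[s]]$cycles)
                  else errors[s]))
  }
  if (!any(ok)) stop("all ensemble samples failed; first error: ", errors[1])
  fail_frac <- mean(!ok)
  if (fail_frac > 0.02)
    warning(sprintf("%.1f%% of ensemble samples failed and were excluded",
                    100 * fail_frac))
  good <- which(ok)
  first <- res[[good[1]]]
  nv <- length(first$vessels)
  gather <- function(field) {
    m <- t(vapply(good, function(s) res[[s]][[field]], numeric(nv)))
    colnames(m) <- first$vessels
    m
  }
  wia <- array(NA_real_, c(length(good), nv, 4),
               dimnames = list(NULL, first$vessels, colnames(first$wia)))
  for (k in seq_along(good)) wia[k, , ] <- res[[good[k]]]$wia
  dist_arr <- function(path_field, col) {
    t(vapply(good, function(s) res[[s]][[path_field]][[col]],
             numeric(nrow(first$distal_alpha))))
  }
  structure(list(
    prior = prior, theta = draw$theta, z = draw$z, seed = seed,
    design = design, ok = ok, errors = errors[!ok],
    vessels = first$vessels, side = first$side,
    mean_q = gather("mean_q"), mean_p = gather("mean_p"),
    cs = gather("cs"), mean_wss = gather("mean_wss"), wia = wia,
    mpa_p = t(vapply(good, function(s) res[[s]]$mpa_p,
                     numeric(length(first$mpa_p)))),
    times = first$times,
    distal_xnorm = first$distal_alpha$xnorm,
    distal = list(
      alpha = list(mean_p = dist_arr("distal_alpha", "mean_p"),
                   mean_q = dist_arr("distal_alpha", "mean_q"),
                   wss = dist_arr("distal_alpha", "wss"),
                   cs = dist_arr("distal_alpha", "cs")),
      beta = list(mean_p = dist_arr("distal_beta", "mean_p"),
                  mean_q = dist_arr("distal_beta", "mean_q"),
                  wss = dist_arr("distal_beta", "wss"),
                  cs = dist_arr("distal_beta", "cs"))),
    distal_bed = distal_bed,
    cycles = vapply(good, function(s) res[[s]]$cycles, numeric(1)),
    config = config), class = "pulm_ensemble")
}

#' @export
print.pulm_ensemble <- function(x, ...) {
  cat(sprintf("Prior ensemble: %d/%d successful samples (seed %d, %s design)\n",
              sum(x$ok), length(x$ok), x$seed, x$design))
  art <- x$side == "arterial"
  cat(sprintf("mean arterial CS %.2f%%, mean venous CS %.2f%%\n",
              100 * mean(x$cs[, art]), 100 * mean(x$cs[, !art])))
  invisible(x)
}

#' Run the full uncertainty study and write its artifacts
#'
#' Orchestrates the pipeline: prior sampling, ensemble simulation, PCE fits
#' for the scalar QoIs and the MPA pressure series, Sobol' and generalized
#' Sobol' reports, and uncertainty summaries, written as CSV and a JSON
#' manifest to `out_dir`.
#'
#' @param out_dir output directory (created if missing).
#' @param N ensemble size.
#' @param seed RNG seed.
#' @param order PCE polynomial order.
#' @param ... further arguments to [run_ensemble()].
#' @return Invisibly, a list with the ensemble, fits and report paths.
#' @export
run_study <- function(out_dir, N = 64, seed = 1, order = 2, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ens <- run_ensemble(N = N, seed = seed, ...)
  z_ok <- ens$z[ens$ok, , drop = FALSE]
  tag <- function(m, what) { colnames(m) <- paste(what, colnames(m)); m }
  scalars <- cbind(tag(ens$cs, "cs"), tag(ens$mean_wss, "wss"),
                   tag(ens$mean_p, "p"), tag(ens$mean_q, "q"))
  fit_sc <- pce(z_ok, scalars, order = order, prior = ens$prior)
  fit_p <- pce(z_ok, ens$mpa_p, order = order, prior = ens$prior)
  sob_sc <- sobol_indices(fit_sc)
  gsob_p <- generalized_sobol(fit_p, ens$times)
  mom <- pce_moments(fit_sc)

  qoi_csv <- file.path(out_dir, "qoi_summary.csv")
  utils::write.csv(data.frame(
    qoi = colnames(scalars), mean = mom$mean, sd = sqrt(mom$variance)),
    qoi_csv, row.names = FALSE)
  sob_csv <- file.path(out_dir, "sobol_indices.csv")
  long <- do.call(rbind, lapply(seq_len(ncol(sob_sc$S)), function(j) {
    data.frame(qoi = colnames(sob_sc$S)[j], param = rownames(sob_sc$S),
               index_type = rep(c("S", "S_T"), each = nrow(sob_sc$S)),
               value = c(sob_sc$S[, j], sob_sc$S_T[, j]))
  }))
  utils::write.csv(long, sob_csv, row.names = FALSE)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    seed = seed, N = N, order = order, n_ok = sum(ens$ok),
    failed = ens$errors, design = ens$design,
    generalized_sobol_mpa_pressure = as.list(gsob_p$GS_T),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ensemble = ens, fit_scalars = fit_sc, fit_pressure = fit_p,
                 sobol = sob_sc, generalized_sobol = gsob_p,
                 paths = c(qoi_csv, sob_csv, manifest)))
}
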