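#' Proximal wall shear stress time series
#'
#' Wall shear stress under the blunt power-law velocity profile,
#' \eqn{WSS(t) = \mu \bar U (\gamma + 2)/R(x,t)} with \eqn{\bar U = q/A} and
#' \eqn{R = \sqrt{A/\pi}}, evaluated at the vessel midpoint (x = L/2).
#'
#' @param sim a `"pulmsim"` object.
#' @param vessel vessel name.
#' @return WSS time series over the converged cycle, dyn/cm^2.
#' @export
proximal_wss <- function(sim, vessel) {
  mat <- sim$network$materials
  mid <- ceiling(ncol(sim$A[[vessel]]) / 2)
  A <- sim$A[[vessel]][, mid]
  q <- sim$q[[vessel]][, mid]
  U <- q / A
  R <- sqrt(A / pi)
  mat$mu * U * (mat$gamma + 2) / R
}

#' Cyclic stretch of a proximal vessel
#'
#' Relative radial excursion over the heartbeat,
#' \eqn{CS = (\max R - \min R)/\min R}, from the midpoint area trace.
#'
#' @param sim a `"pulmsim"` object.
#' @param vessel vessel name.
#' @return Dimensionless scalar.
#' @export
cyclic_stretch <- function(sim, vessel) {
  mid <- ceiling(ncol(sim$A[[vessel]]) / 2)
  R <- sqrt(sim$A[[vessel]][, mid] / pi)
  if (min(R) <= 0) stop("non-physical radius excursion")
  (max(R) - min(R)) / min(R)
}

#' Wave intensity decomposition at a vessel midpoint
#'
#' Characteristic separation of the midpoint pressure/velocity increments into
#' forward and backward components: with successive differences dP and dU over
#' the converged cycle (periodic wrap) and local wave speed
#' \eqn{c(t) = \sqrt{(2K/3\rho)\sqrt{A/A_0}}} from the wall law,
#' \eqn{dP_\pm = (dP \pm \rho c\, dU)/2}, \eqn{dU_\pm = \pm dP_\pm/(\rho c)},
#' \eqn{dI_\pm = dP_\pm dU_\pm}. Samples are classified as forward/backward
#' compression/expansion waves (FCW: forward, pressure rising; FEW: forward,
#' falling; BCW: backward, rising; BEW: backward, falling) and the intensity
#' magnitudes are integrated per wave type.
#'
#' @param sim a `"pulmsim"` object.
#' @param vessel vessel name.
#' @return A list of class `"wave_intensity"`: time series `dI_forward` (>= 0),
#'   `dI_backward` (<= 0), `dP`, `dU`, `labels`, and `integrated`, the named
#'   vector of time-integrated magnitudes (FCW, FEW, BCW, BEW).
#' @export
wave_intensity <- function(sim, vessel) {
  mat <- sim$network$materials
  side <- sim$network$segments$side[match(vessel, sim$network$segments$name)]
  K <- if (side == "arterial") mat$K_A else mat$K_V
  mid <- ceiling(ncol(sim$A[[vessel]]) / 2)
  A <- sim$A[[vessel]][, mid]
  if (any(A <= 0)) stop("non-positive area")
  p <- sim$p[[vessel]][, mid]
  u <- sim$q[[vessel]][, mid] / A
  A0 <- pi * sim$network$segments$radius_cm[match(vessel, sim$network$segments$name)]^2
  cw <- sqrt((2 * K / (3 * mat$rho)) * sqrt(A / A0))
  dP <- diff(c(p[length(p)], p))
  dU <- diff(c(u[length(u)], u))
  rc <- mat$rho * cw
  dPp <- (dP + rc * dU) / 2
  dPm <- (dP - rc * dU) / 2
  dIf <- dPp^2 / rc          # forward intensity, >= 0
  dIb <- -dPm^2 / rc         # backward intensity, <= 0
  labels <- ifelse(abs(dPp) >= abs(dPm),
                   ifelse(dPp > 0, "FCW", "FEW"),
                   ifelse(dPm > 0, "BCW", "BEW"))
  dt <- sim$times[2] - sim$times[1]
  integrated <- c(
    FCW = sum(dIf[dPp > 0]) * dt,
    FEW = sum(dIf[dPp < 0]) * dt,
    BCW = sum(abs(dIb[dPm > 0])) * dt,
    BEW = sum(abs(dIb[dPm < 0])) * dt)
  structure(list(dI_forward = dIf, dI_backward = dIb, dP = dP, dU = dU,
                 wave_speed = cw, labels = labels, integrated = integrated),
            class = "wave_intensity")
}

#' @export
print.wave_intensity <- function(x, ...) {
  cat("Wave intensity decomposition; integrated magnitudes (CGS):\n")
  print(round(x$integrated, 3))
  invisible(x)
}

#' Per-vessel quantity-of-interest table
#'
#' Convenience wrapper combining [summary.pulmsim()] with the four integrated
#' wave-intensity magnitudes per vessel.
#'
#' @param sim a `"pulmsim"` object.
#' @return A data.frame, one row per proximal vessel.
#' @export
qoi_table <- function(sim) {
  base <- summary(sim)
  wia <- t(vapply(base$vessel, function(nm) wave_intensity(sim, nm)$integrated,
                  numeric(4)))
  cbind(base, as.data.frame(wia))
}
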