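MMHG <- 1333.22  # dyn/cm^2 per mmHg

.waveform <- function(period, samples, kind) {
  if (any(!is.finite(samples))) stop("waveform samples must be finite")
  structure(list(period = period, samples = samples, kind = kind,
                 times = period * (seq_along(samples) - 1) / length(samples)),
            class = "pulm_waveform")
}

#' Synthetic main-pulmonary-artery inflow waveform
#'
#' Parametric periodic stand-in for a measured MPA flow waveform: a half-sine
#' ejection pulse over the systolic interval, an optional brief negative lobe
#' carrying a fraction of the stroke volume, zero in diastole, with the corners
#' rounded by a short periodic smoothing kernel. The cycle integral equals
#' `stroke_volume * (1 - backflow_fraction)`.
#'
#' @param T cardiac period, s.
#' @param stroke_volume ejected volume per beat, cm^3.
#' @param systolic_fraction fraction of the period spent in ejection, in (0,1).
#' @param backflow_fraction fraction of stroke volume regurgitated, in [0, 0.1).
#' @param n_samples samples per period.
#' @return A `"pulm_waveform"` of kind `"flow"` (cm^3/s).
#' @export
mpa_inflow <- function(T = 0.85, stroke_volume = 70, systolic_fraction = 0.4,
                       backflow_fraction = 0.02, n_samples = 1024) {
  if (!(T > 0 && stroke_volume > 0)) stop("T and stroke_volume must be positive")
  if (!(systolic_fraction > 0 && systolic_fraction < 1))
    stop("systolic_fraction must lie in (0,1)")
  if (!(backflow_fraction >= 0 && backflow_fraction < 0.1))
    stop("backflow_fraction must lie in [0, 0.1)")
  t <- T * (0:(n_samples - 1)) / n_samples
  t_sys <- systolic_fraction * T
  q <- ifelse(t < t_sys, pi * stroke_volume / (2 * t_sys) * sin(pi * t / t_sys), 0)
  if (backflow_fraction > 0) {
    t_b <- 0.15 * t_sys
    inlobe <- t >= t_sys & t < t_sys + t_b
    amp <- 2 * stroke_volume * backflow_fraction / t_b
    q[inlobe] <- -amp * sin(pi * (t[inlobe] - t_sys) / t_b)^2
  }
  q <- .smooth_periodic(q, half_width = max(1L, round(n_samples / 512)))
  .waveform(T, q, "flow")
}

#' Synthetic left-atrial pressure waveform
#'
#' Baseline pressure plus two Gaussian bumps: a v wave centred mid-cycle
#' (atrial filling against a closed mitral valve) and an a wave centred at
#' 0.9 T (atrial contraction). Inputs in mmHg; samples in dyn/cm^2
#' (1 mmHg = 1333.22 dyn/cm^2).
#'
#' @param T cardiac period, s.
#' @param p_base baseline left-atrial pressure, mmHg.
#' @param a_amp,v_amp a- and v-wave amplitudes, mmHg.
#' @param n_samples samples per period.
#' @param width Gaussian standard deviation as a fraction of T.
#' @return A `"pulm_waveform"` of kind `"pressure"` (dyn/cm^2).
#' @export
la_pressure <- function(T = 0.85, p_base = 8, a_amp = 3, v_amp = 2,
                        n_samples = 1024, width = 0.045) {
  if (p_base <= 0) stop("p_base must be positive")
  if (a_amp < 0 || v_amp < 0) stop("amplitudes must be non-negative")
  t <- (0:(n_samples - 1)) / n_samples  # phase in [0,1)
  bump <- function(center, amp) {
    d <- t - center
    d <- d - round(d)  # periodic wrap to [-0.5, 0.5)
    amp * exp(-0.5 * (d / width)^2)
  }
  p <- p_base + bump(0.5, v_amp) + bump(0.9, a_amp)
  p <- p * MMHG
  if (any(p <= 0)) stop("left-atrial pressure waveform is not strictly positive")
  .waveform(T, p, "pressure")
}

# periodic moving smoothing with a small Hann kernel; preserves the mean
# exactly and non-negativity of non-negative inputs
.smooth_periodic <- function(x, half_width) {
  k <- -half_width:half_width
  w <- 0.5 * (1 + cos(pi * k / (half_width + 1)))
  w <- w / sum(w)
  n <- length(x)
  out <- numeric(n)
  for (m in seq_along(k))
    out <- out + w[m] * x[((seq_len(n) - 1 + k[m]) %% n) + 1]
  out
}

#' Resample a periodic waveform by periodic cubic interpolation
#'
#' @param wf a `"pulm_waveform"`.
#' @param n_samples target samples per period.
#' @return A `"pulm_waveform"` on the new grid.
#' @export
resample_waveform <- function(wf, n_samples) {
  stopifnot(inherits(wf, "pulm_waveform"))
  n <- length(wf$samples)
  if (n == n_samples) return(wf)
  xout <- wf$period * (0:(n_samples - 1)) / n_samples
  sp <- stats::spline(c(wf$times, wf$period), c(wf$samples, wf$samples[1]),
                      method = "periodic", xout = xout)
  .waveform(wf$period, sp$y, wf$kind)
}

#' Read / write waveforms as two-column CSV
#'
#' Files have a `time_s,value` header; samples must be uniform on [0, T).
#'
#' @param path CSV path.
#' @param kind `"flow"` or `"pressure"`.
#' @return `read_waveform` returns a `"pulm_waveform"`; `write_waveform`
#'   returns `path` invisibly.
#' @export
read_waveform <- function(path, kind) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("waveform CSV must have columns time_s,value")
  dt <- diff(df$time_s)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("waveform samples must be uniform")
  .waveform(dt[1] * nrow(df), df$value, kind)
}

#' @rdname read_waveform
#' @param wf a `"pulm_waveform"`.
#' @export
write_waveform <- function(wf, path) {
  utils::write.csv(data.frame(time_s = wf$times, value = wf$samples), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pulm_waveform <- function(x, ...) {
  cat(sprintf("Periodic %s waveform: T = %g s, %d samples, mean %.4g, range [%.4g, %.4g]\n",
              x$kind, x$period, length(x$samples), mean(x$samples),
              min(x$samples), max(x$samples)))
  invisible(x)
}
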