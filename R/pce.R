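#' Uniform parameter prior for the uncertainty study
#'
#' The eight uncertain parameters of the multiscale model with their uniform
#' bounds: proximal arterial, structured-tree and proximal venous stiffnesses
#' (dyn/cm^2), the radius scaling factors alpha and beta, the arterial and
#' venous length-to-radius ratios, and the terminal radius cutoff (cm).
#' Parameters are mapped affinely to the canonical cube \eqn{[-1,1]^8} for the
#' Legendre basis.
#'
#' @param bounds optional named list overriding individual `c(lower, upper)`
#'   bounds.
#' @return A list of class `"parameter_prior"` with `names`, `lower`, `upper`
#'   and mapping helpers `to_canonical` / `from_canonical`.
#' @export
parameter_prior <- function(bounds = NULL) {
  lower <- c(K_A = 5.60e5, K_ST = 1.75e5, K_V = 5.95e5, alpha = 0.80,
             beta = 0.60, lrr_A = 10, lrr_V = 10, r_min = 1e-3)
  upper <- c(K_A = 1.04e6, K_ST = 3.25e5, K_V = 1.11e6, alpha = 0.92,
             beta = 0.70, lrr_A = 50, lrr_V = 50, r_min = 1e-2)
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      lower[nm] <- bounds[[nm]][1]
      upper[nm] <- bounds[[nm]][2]
    }
  }
  if (any(lower >= upper)) stop("prior bounds need lower < upper")
  pr <- list(names = names(lower), lower = lower, upper = upper)
  pr$to_canonical <- function(x) {
    x <- as.matrix(x)
    sweep(sweep(x, 2, (pr$lower + pr$upper) / 2), 2, (pr$upper - pr$lower) / 2, "/")
  }
  pr$from_canonical <- function(z) {
    z <- as.matrix(z)
    out <- sweep(sweep(z, 2, (pr$upper - pr$lower) / 2, "*"), 2,
                 (pr$lower + pr$upper) / 2, "+")
    colnames(out) <- pr$names
    out
  }
  class(pr) <- "parameter_prior"
  pr
}

#' Sample the parameter prior
#'
#' @param prior a [parameter_prior()].
#' @param N number of samples.
#' @param seed RNG seed (recorded; sampling is reproducible).
#' @param design `"random"` (plain uniform) or `"lhs"` (Latin hypercube,
#'   requires the lhs package).
#' @return A list with `theta` (N x 8 matrix in physical units) and `z`
#'   (canonical-cube images).
#' @export
sample_prior <- function(prior = parameter_prior(), N, seed = 1,
                         design = c("random", "lhs")) {
  design <- match.arg(design)
  stopifnot(N >= 1)
  set.seed(seed)
  d <- length(prior$names)
  u <- if (design == "lhs") {
    if (!requireNamespace("lhs", quietly = TRUE))
      stop("design = 'lhs' requires the lhs package")
    lhs::randomLHS(N, d)
  } else {
    matrix(stats::runif(N * d), N, d)
  }
  z <- 2 * u - 1
  colnames(z) <- prior$names
  list(theta = prior$from_canonical(z), z = z, seed = seed, design = design)
}

# normalized Legendre polynomials evaluated at x in [-1,1]: matrix over
# degrees 0..K with E[P_k^2] = 1 under the uniform measure
.legendre_norm <- function(x, K) {
  out <- matrix(0, length(x), K + 1)
  P0 <- rep(1, length(x)); out[, 1] <- P0
  if (K >= 1) { P1 <- x; out[, 2] <- P1 * sqrt(3) }
  if (K >= 2) for (k in 2:K) {
    P2 <- ((2 * k - 1) * x * P1 - (k - 1) * P0) / k
    out[, k + 1] <- P2 * sqrt(2 * k + 1)
    P0 <- P1; P1 <- P2
  }
  out
}

# total-degree <= K multi-index set over n variables, graded order;
# first row is the constant term
.multi_indices <- function(n, K) {
  grids <- rev(rep(list(0:K), n))
  mi <- as.matrix(do.call(expand.grid, grids))[, n:1, drop = FALSE]
  mi <- mi[rowSums(mi) <= K, , drop = FALSE]
  mi <- mi[order(rowSums(mi)), , drop = FALSE]
  dimnames(mi) <- NULL
  mi
}

.pce_basis <- function(z, mi) {
  K <- max(mi)
  n <- ncol(mi)
  uni <- lapply(seq_len(n), function(i) .legendre_norm(z[, i], K))
  Psi <- matrix(1, nrow(z), nrow(mi))
  for (j in seq_len(nrow(mi)))
    for (i in seq_len(n))
      if (mi[j, i] > 0) Psi[, j] <- Psi[, j] * uni[[i]][, mi[j, i] + 1]
  Psi
}

#' Fit a Legendre polynomial chaos emulator by ordinary least squares
#'
#' Expands each output point (time sample, pathway node, or scalar) in the
#' orthonormal Legendre basis over the total-degree <= K multi-index set and
#' solves the least-squares coefficient problem through a rank-revealing QR
#' factorization. With n parameters the basis has `choose(n + K, n)`
#' functions; a warning is issued when the training budget is below twice
#' that count.
#'
#' @param z N x n matrix of canonical-cube training inputs in `[-1,1]^n`.
#' @param outputs N x m matrix of model outputs (one column per output point),
#'   or a length-N vector.
#' @param order polynomial order K.
#' @param prior optional [parameter_prior()] enabling [predict()] on physical
#'   inputs.
#' @return An object of class `"pce"`: multi-index set, coefficient matrix
#'   (basis x output points), order, condition number and metadata.
#' @export
pce <- function(z, outputs, order = 4, prior = NULL) {
  z <- as.matrix(z)
  outputs <- as.matrix(outputs)
  if (nrow(outputs) != nrow(z)) stop("z and outputs need matching rows")
  mi <- .multi_indices(ncol(z), order)
  J <- nrow(mi)
  if (nrow(z) < J)
    stop(sprintf("need at least %d training points for order %d", J, order))
  if (nrow(z) < 2 * J)
    warning(sprintf("N = %d below twice the basis size J = %d; ill-conditioning risk",
                    nrow(z), J))
  Psi <- .pce_basis(z, mi)
  qr_ <- qr(Psi)
  if (qr_$rank < J) stop("rank-deficient PCE design matrix")
  coef <- qr.coef(qr_, outputs)
  d <- svd(Psi, nu = 0, nv = 0)$d
  structure(list(multi_indices = mi, coefficients = coef, order = order,
                 n_train = nrow(z), n_param = ncol(z),
                 param_names = colnames(z), prior = prior,
                 condition = d[1] / d[length(d)]),
            class = "pce")
}

#' @export
print.pce <- function(x, ...) {
  cat(sprintf("Legendre PCE surrogate: %d parameters, order %d, %d basis functions,\n",
              x$n_param, x$order, nrow(x$multi_indices)))
  cat(sprintf("  %d output points, N_train = %d, design condition number %.3g\n",
              ncol(x$coefficients), x$n_train, x$condition))
  invisible(x)
}

#' @export
coef.pce <- function(object, ...) object$coefficients

#' Evaluate a PCE surrogate
#'
#' @param object a `"pce"` fit.
#' @param newdata matrix of inputs; canonical by default, physical if the fit
#'   carries a prior and `canonical = FALSE`.
#' @param canonical whether `newdata` is already on `[-1,1]^n`.
#' @param ... unused.
#' @return Matrix of predictions (rows = inputs, columns = output points).
#' @export
predict.pce <- function(object, newdata, canonical = TRUE, ...) {
  newdata <- as.matrix(newdata)
  if (!canonical) {
    if (is.null(object$prior)) stop("fit carries no prior; supply canonical inputs")
    newdata <- object$prior$to_canonical(newdata)
  }
  .pce_basis(newdata, object$multi_indices) %*% object$coefficients
}

#' Mean and variance of a PCE surrogate
#'
#' In the orthonormal basis the mean is the constant-term coefficient and the
#' variance is the sum of squared non-constant coefficients (Parseval), per
#' output point.
#'
#' @param surrogate a `"pce"` fit.
#' @return A list with vectors `mean` and `variance` over output points.
#' @export
pce_moments <- function(surrogate) {
  co <- surrogate$coefficients
  list(mean = co[1, ], variance = colSums(co[-1, , drop = FALSE]^2))
}

#' Sobol' indices from PCE coefficients
#'
#' First-order indices sum squared coefficients over multi-indices involving
#' only one parameter, second-order over exactly one pair, total-order over
#' any involvement, each divided by the total variance per output point.
#' Zero-variance output points are masked as `NA`.
#'
#' @param surrogate a `"pce"` fit.
#' @return A list of class `"sobol_report"`: matrices `S` and `S_T`
#'   (parameter x output point), array `S2` (pair x output point) with pair
#'   labels, and `variance`.
#' @export
sobol_indices <- function(surrogate) {
  mi <- surrogate$multi_indices
  co <- surrogate$coefficients
  n <- ncol(mi)
  nm <- surrogate$param_names
  if (is.null(nm)) nm <- paste0("theta", seq_len(n))
  V <- colSums(co[-1, , drop = FALSE]^2)
  mask <- V > 0
  sq <- co^2
  active <- mi > 0
  S <- matrix(NA_real_, n, ncol(co), dimnames = list(nm, colnames(co)))
  ST <- S
  for (i in seq_len(n)) {
    only_i <- active[, i] & rowSums(active) == 1
    any_i <- active[, i]
    S[i, mask] <- colSums(sq[only_i, mask, drop = FALSE]) / V[mask]
    ST[i, mask] <- colSums(sq[any_i, mask, drop = FALSE]) / V[mask]
  }
  prs <- utils::combn(n, 2)
  S2 <- matrix(NA_real_, ncol(prs), ncol(co))
  rownames(S2) <- apply(prs, 2, function(p) paste(nm[p], collapse = ":"))
  for (k in seq_len(ncol(prs))) {
    sel <- active[, prs[1, k]] & active[, prs[2, k]] & rowSums(active) == 2
    S2[k, mask] <- colSums(sq[sel, mask, drop = FALSE]) / V[mask]
  }
  structure(list(S = S, S_T = ST, S2 = S2, variance = V,
                 param_names = nm), class = "sobol_report")
}

#' @export
print.sobol_report <- function(x, ...) {
  cat("Sobol' sensitivity report (averages over output points):\n")
  print(round(cbind(S = rowMeans(x$S, na.rm = TRUE),
                    S_T = rowMeans(x$S_T, na.rm = TRUE)), 4))
  invisible(x)
}

#' Generalized (variance-weighted, time-integrated) Sobol' indices
#'
#' \deqn{GS_i(t_j) = \int_0^{t_j} S_i(t)\,Var[Z](t)\,dt \Big/
#'   \int_0^{t_j} Var[Z](t)\,dt} by the trapezoid rule; the value at the final
#' time summarizes parameter importance over the whole cycle.
#'
#' @param surrogate a `"pce"` fit whose output points are ordered time samples.
#' @param times time grid matching the output points.
#' @return A list with `GS` (first-order), `GS_T` (total-order) and `GS2`
#'   (second-order) at the final time, plus the full `GS_t` trajectory of
#'   first-order indices.
#' @export
generalized_sobol <- function(surrogate, times) {
  rep_ <- sobol_indices(surrogate)
  V <- rep_$variance
  if (all(V == 0)) stop("all-zero variance; generalized indices undefined")
  if (length(times) != length(V)) stop("times must match output points")
  wtrap <- function(y) {
    # trapezoid cumulative integral over times
    dy <- diff(times) * (y[-1] + y[-length(y)]) / 2
    c(0, cumsum(dy))
  }
  denom <- wtrap(V)
  gs_of <- function(Smat) {
    t(apply(Smat, 1, function(s) {
      s0 <- ifelse(is.na(s), 0, s)
      num <- wtrap(s0 * V)
      ifelse(denom > 0, num / denom, NA_real_)
    }))
  }
  GSt <- gs_of(rep_$S)
  GTt <- gs_of(rep_$S_T)
  G2t <- gs_of(rep_$S2)
  list(GS = GSt[, length(V)], GS_T = GTt[, length(V)],
       GS2 = G2t[, length(V)], GS_t = GSt, times = times)
}

#' Validation mean squared error of a surrogate
#'
#' @param surrogate a `"pce"` fit.
#' @param z_val validation inputs (canonical cube), disjoint from training.
#' @param y_val validation outputs (rows matching `z_val`).
#' @return A list with per-output-point `mse` and the grand `mean`.
#' @export
validation_mse <- function(surrogate, z_val, y_val) {
  y_val <- as.matrix(y_val)
  pred <- predict(surrogate, z_val)
  if (!all(dim(pred) == dim(y_val))) stop("validation size mismatch")
  mse <- colMeans((y_val - pred)^2)
  list(mse = mse, mean = mean(mse))
}

#' @export
summary.pce <- function(object, ...) {
  m <- pce_moments(object)
  cat(sprintf("PCE order %d, J = %d basis functions, N_train = %d\n",
              object$order, nrow(object$multi_indices), object$n_train))
  cat(sprintf("output points: %d; mean of means %.4g; mean variance %.4g\n",
              ncol(object$coefficients), mean(m$mean), mean(m$variance)))
  invisible(list(moments = m))
}
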