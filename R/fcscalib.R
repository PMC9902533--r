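#' Normalised intensity autocorrelation of a photon trace
#'
#' Computes `G(tau) = <dI(t) dI(t + tau)> / <I>^2` on a user-supplied
#' (typically log-spaced) lag grid. The trace is binned at a fine,
#' uniform width derived from the smallest lag and the correlation at
#' each lag is formed from the overlapping bin products with symmetric
#' normalisation, which removes the bias from the shrinking overlap at
#' long lags.
#'
#' @param trace a [photon_trace()] with at least 100 photons.
#' @param lags lag grid in seconds, strictly increasing and > 0.
#' @param bin_width width of the underlying uniform binning, seconds;
#'   defaults to a quarter of the smallest lag.
#' @return object of class `acf_curve`: a data frame with columns
#'   `lag_s` (the realised lag, an integer multiple of the bin width)
#'   and `G`.
#' @export
autocorrelate <- function(trace, lags, bin_width = min(lags) / 4) {
  stopifnot(inherits(trace, "photon_trace"))
  if (n_photons(trace) < 100)
    stop("data error: at least 100 photons are required for correlation")
  if (any(diff(lags) <= 0) || any(lags <= 0))
    stop("`lags` must be strictly increasing and positive")
  bt <- bin_trace(trace, bin_width)
  I <- as.numeric(bt$counts)
  n <- length(I)
  ks <- unique(pmax(1L, as.integer(round(lags / bin_width))))
  ks <- ks[ks < n - 1]
  G <- vapply(ks, function(k) {
    a <- I[1:(n - k)]
    b <- I[(k + 1):n]
    mean(a * b) / (mean(a) * mean(b)) - 1
  }, numeric(1))
  out <- data.frame(lag_s = ks * bin_width, G = G)
  class(out) <- c("acf_curve", "data.frame")
  out
}

#' Model autocorrelation of 3D diffusion through a Gaussian volume
#'
#' `G(tau) = (1/N) (1 + tau/tau_D)^-1 (1 + tau/(kappa^2 tau_D))^-1/2`.
#'
#' @param lags lag times, seconds.
#' @param N mean number of molecules in the effective volume.
#' @param tau_D diffusion time, seconds.
#' @param kappa axial-to-lateral aspect ratio of the volume.
#' @return model G values.
#' @export
fcs_diffusion_G <- function(lags, N, tau_D, kappa) {
  (1 / N) / (1 + lags / tau_D) / sqrt(1 + lags / (kappa^2 * tau_D))
}

#' Fit the 3D diffusion model to an autocorrelation curve
#'
#' Weighted (relative) nonlinear least squares for `N`, `tau_D` and
#' `kappa`; the weights `1/G^2` make the fit least-squares in relative
#' error, appropriate for the multiplicative noise of measured
#' correlation curves. The calibrant's known diffusion coefficient
#' converts the fitted diffusion time into physical volume dimensions
#' via `w0 = sqrt(4 D tau_D)` (lateral 1/e^2 radius convention),
#' `z0 = kappa * w0` and `V_eff = pi^(3/2) w0^2 z0`. No triplet-state
#' term is included.
#'
#' @param acf an `acf_curve` from [autocorrelate()] or a data frame
#'   with columns `lag_s`, `G`.
#' @param D_um2_s diffusion coefficient of the calibrant, um^2/s.
#' @return object of class `fcs_fit`: list with `N`, `tau_D`, `kappa`,
#'   `w0_um`, `z0_um`, `V_eff_fL`, `D_um2_s`, `residual_norm`.
#' @export
fit_diffusion_model <- function(acf, D_um2_s) {
  if (!is.data.frame(acf) || !all(c("lag_s", "G") %in% names(acf)))
    stop("`acf` must have columns lag_s and G")
  if (!is.numeric(D_um2_s) || D_um2_s <= 0) stop("`D_um2_s` must be > 0")
  dat <- acf[is.finite(acf$G) & acf$G > 0, ]
  if (nrow(dat) < 6) stop("fit error: too few positive correlation points")
  N0 <- 1 / dat$G[1]
  half <- dat$G[1] / 2
  tau0 <- dat$lag_s[which.min(abs(dat$G - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      G ~ fcs_diffusion_G(lag_s, N, tau_D, kappa),
      data = dat,
      start = list(N = N0, tau_D = tau0, kappa = 5),
      weights = 1 / dat$G^2,
      lower = c(N = 1e-9, tau_D = 1e-9, kappa = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(err)
      stop(sprintf("fit error: diffusion-model fit failed (%s)",
                   conditionMessage(err))))
  cf <- stats::coef(fit)
  w0 <- sqrt(4 * D_um2_s * cf[["tau_D"]])   # um
  z0 <- cf[["kappa"]] * w0
  V_eff <- pi^1.5 * w0^2 * z0               # um^3 == fL
  structure(list(N = cf[["N"]], tau_D = cf[["tau_D"]],
                 kappa = cf[["kappa"]], w0_um = w0, z0_um = z0,
                 V_eff_fL = V_eff, D_um2_s = D_um2_s,
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf(paste0("<fcs_fit> N = %.3g, tau_D = %.3g s, kappa = %.3g\n",
                     "  w0 = %.3g um, z0 = %.3g um, V_eff = %.3g fL\n"),
              x$N, x$tau_D, x$kappa, x$w0_um, x$z0_um, x$V_eff_fL))
  invisible(x)
}

#' Write an autocorrelation curve to CSV
#' @param acf an `acf_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_acf <- function(acf, path) {
  utils::write.csv(as.data.frame(acf)[, c("lag_s", "G")], path,
                   row.names = FALSE)
  invisible(path)
}
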