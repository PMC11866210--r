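#' Construct a spectrum object
#'
#' @param wavenumbers strictly increasing grid, cm^-1
#' @param intensity intensity values on the grid
#' @param normalization one of "raw", "per_adsorbate", "unit_area"
#' @param resolution grid spacing, cm^-1
#' @param window descriptor of the taper used
#' @return a `vib_spectrum`
#' @export
vib_spectrum <- function(wavenumbers, intensity,
                         normalization = c("raw", "per_adsorbate",
                                           "unit_area"),
                         resolution = diff(wavenumbers[1:2]),
                         window = "none") {
  normalization <- match.arg(normalization)
  if (any(diff(wavenumbers) <= 0)) stop("wavenumber grid must be increasing")
  if (any(!is.finite(intensity))) stop("non-finite intensity")
  structure(list(wavenumbers = wavenumbers, intensity = intensity,
                 normalization = normalization, resolution = resolution,
                 window = window),
            class = "vib_spectrum")
}

#' @export
print.vib_spectrum <- function(x, ...) {
  cat(sprintf("vib_spectrum: %d points, %.4g..%.4g cm^-1, res %.4g, %s\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              x$resolution, x$normalization))
  invisible(x)
}

.window_vals <- function(window, n) {
  switch(window,
         none = rep(1, n),
         hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)),
         stop("unknown window: ", window))
}

#' Integrate a spectrum over a wavenumber band
#'
#' Rectangle-rule integral (sum times grid spacing), which matches the
#' discrete Parseval identity of the underlying periodogram exactly.
#'
#' @param spec a `vib_spectrum`
#' @param band optional c(lo, hi) band in cm^-1; default whole grid
#' @return the integral (intensity units times cm^-1)
#' @export
spectrum_integral <- function(spec, band = NULL) {
  keep <- if (is.null(band)) rep(TRUE, length(spec$wavenumbers))
          else spec$wavenumbers >= band[1] & spec$wavenumbers <= band[2]
  sum(spec$intensity[keep]) * spec$resolution
}

# Shared periodogram core: x is an N x k matrix of channels, weights length k.
# Returns list(wavenumbers, intensity) with the one-sided convention such
# that sum(intensity) * d_nu = mean over time of sum_channels w * x^2
# (exactly, for window "none").
.psd_core <- function(x, weights, dt, window) {
  n <- nrow(x)
  w <- .window_vals(window, n)
  wpow <- mean(w^2)
  x <- sweep(x, 2, colMeans(x))          # remove per-channel drift
  X <- stats::mvfft(x * w)
  k <- 0:(n %/% 2)
  p <- (abs(X[k + 1L, , drop = FALSE])^2 %*% weights)[, 1] / (n^2 * wpow)
  mult <- rep(2, length(k))
  mult[1] <- 1
  if (n %% 2 == 0) mult[length(k)] <- 1  # Nyquist bin is not doubled
  p <- p * mult
  c_cm <- vib_constants$c_cm_fs
  d_nu <- 1 / (n * dt * c_cm)
  list(wavenumbers = k * d_nu, intensity = p / d_nu, resolution = d_nu)
}

#' Power spectral density of mass-weighted velocity
#'
#' S(nu) = sum over selected atoms and Cartesian components of
#' m_a |FT(v_a)|^2 on a one-sided wavenumber grid, optionally averaged over
#' contiguous segments (Welch). The convention constant is chosen so that the
#' rectangle-rule integral of S over wavenumber equals the time mean of
#' sum_a m_a |v_a|^2, i.e. twice the mean mass-weighted kinetic energy; at
#' equilibrium each vibrational mode then carries spectral weight k_B T and
#' band areas read directly as mode counts (see [band_mode_count()]).
#' Per-atom velocity drift is removed before transforming.
#'
#' @param traj an `md_trajectory` with velocities
#' @param selection optional `atom_selection`
#' @param window taper: "hann" (default) or "none"
#' @param segments number of equal contiguous segments to average over
#' @return a `vib_spectrum` with normalization "raw"
#' @export
mass_weighted_psd <- function(traj, selection = NULL,
                              window = c("hann", "none"), segments = 1) {
  window <- match.arg(window)
  if (is.null(traj$velocities))
    stop("trajectory has no velocities; run derive_velocities() first")
  idx <- .resolve_selection(selection, n_atoms(traj))
  nf <- n_frames(traj)
  seglen <- nf %/% segments
  if (segments < 1 || seglen < 4)
    stop("too few frames for the requested number of segments")
  v <- matrix(traj$velocities[, idx, , drop = FALSE], nf, length(idx) * 3)
  wts <- rep(traj$masses[idx], 3)
  acc <- NULL
  for (s in seq_len(segments)) {
    rows <- ((s - 1) * seglen + 1):(s * seglen)
    res <- .psd_core(v[rows, , drop = FALSE], wts, traj$timestep, window)
    acc <- if (is.null(acc)) res$intensity else acc + res$intensity
  }
  vib_spectrum(res$wavenumbers, acc / segments, "raw",
               resolution = res$resolution, window = window)
}

#' Mass-weighted velocity autocorrelation function
#'
#' C(tau) = < sum_a m_a v_a(t) . v_a(t + tau) >_t, computed by FFT with an
#' unbiased (default) or biased time average. C(0) is the time mean of
#' sum m |v|^2, i.e. twice the mean mass-weighted kinetic energy. Per-atom
#' velocity drift is removed first, matching [mass_weighted_psd()].
#'
#' @param traj an `md_trajectory` with velocities
#' @param selection optional `atom_selection`
#' @param max_lag maximum lag, fs (must be below the trajectory duration);
#'   default half the duration
#' @param normalization "unbiased" divides lag l by (N - l); "biased" divides
#'   by N (the estimator whose transform is exactly the periodogram)
#' @param demean remove per-channel velocity drift first (the default,
#'   matching the PSD convention); with `FALSE` a constant velocity v0 gives
#'   C(tau) = m |v0|^2 at every lag
#' @return a `vib_vacf`: `lags` (fs), `values` (amu Angstrom^2/fs^2),
#'   `n_frames`, `timestep`, `normalization`
#' @export
vacf <- function(traj, selection = NULL, max_lag = NULL,
                 normalization = c("unbiased", "biased"), demean = TRUE) {
  normalization <- match.arg(normalization)
  if (is.null(traj$velocities))
    stop("trajectory has no velocities; run derive_velocities() first")
  idx <- .resolve_selection(selection, n_atoms(traj))
  nf <- n_frames(traj)
  dur <- nf * traj$timestep
  if (is.null(max_lag)) max_lag <- (nf %/% 2) * traj$timestep
  if (max_lag >= dur) stop("max_lag must be smaller than the duration")
  L <- min(nf - 1L, as.integer(round(max_lag / traj$timestep)))
  v <- matrix(traj$velocities[, idx, , drop = FALSE], nf, length(idx) * 3)
  if (demean) v <- sweep(v, 2, colMeans(v))
  wts <- rep(traj$masses[idx], 3)
  m <- stats::nextn(2L * nf, 2)
  Xp <- stats::mvfft(rbind(v, matrix(0, m - nf, ncol(v))))
  raw <- Re(stats::mvfft(abs(Xp)^2, inverse = TRUE))[1:(L + 1L), ,
                                                     drop = FALSE] / m
  acc <- (raw %*% wts)[, 1]
  denom <- if (normalization == "unbiased") nf - 0:L else rep(nf, L + 1L)
  structure(list(lags = (0:L) * traj$timestep, values = acc / denom,
                 n_frames = nf, timestep = traj$timestep,
                 normalization = normalization),
            class = "vib_vacf")
}

#' Spectrum from a velocity autocorrelation function
#'
#' One-sided cosine transform of C(tau) on the same wavenumber convention as
#' [mass_weighted_psd()]. By the Wiener-Khintchine theorem the result is
#' equivalent to the direct periodogram; for the biased full-lag estimator
#' with no taper the equivalence is exact bin for bin. For unbiased or
#' truncated estimates a lag taper ("hann") limits leakage.
#'
#' @param corr a `vib_vacf`
#' @param window lag taper: "none" (default) or "hann"
#' @return a `vib_spectrum` with normalization "raw"
#' @export
psd_from_vacf <- function(corr, window = c("none", "hann")) {
  window <- match.arg(window)
  L <- length(corr$values) - 1L
  w <- if (window == "hann")
    0.5 + 0.5 * cos(pi * (0:L) / L)      # half-Hann over lags, w(0) = 1
  else rep(1, L + 1L)
  cw <- corr$values * w
  m <- corr$n_frames
  y <- numeric(m)
  y[1:(L + 1L)] <- cw
  ft <- Re(stats::fft(y))
  k <- 0:(m %/% 2)
  p2 <- (2 * ft[k + 1L] - cw[1]) / m     # two-sided per-bin power
  mult <- rep(2, length(k)); mult[1] <- 1
  if (m %% 2 == 0) mult[length(k)] <- 1
  c_cm <- vib_constants$c_cm_fs
  d_nu <- 1 / (m * corr$timestep * c_cm)
  vib_spectrum(k * d_nu, p2 * mult / d_nu, "raw", resolution = d_nu,
               window = paste0("vacf_", window))
}

#' Effective number of vibrational modes in a band
#'
#' Under equipartition every vibrational mode contributes spectral weight
#' k_B T to the mass-weighted velocity PSD (twice the mean kinetic energy of
#' 1/2 k_B T per mode), so the band integral divided by k_B T counts modes.
#'
#' @param spec a `vib_spectrum` in "raw" (total) or "per_adsorbate"
#'   (per-molecule counts) normalization
#' @param band c(lo, hi) in cm^-1, within the grid
#' @param T temperature in K
#' @return effective mode count (real)
#' @export
band_mode_count <- function(spec, band, T) {
  if (spec$normalization == "unit_area")
    stop("band_mode_count needs a raw or per_adsorbate spectrum")
  if (T <= 0) stop("T must be positive")
  if (band[1] > band[2] || band[2] < min(spec$wavenumbers) ||
      band[1] > max(spec$wavenumbers))
    stop("band lies outside the spectrum grid")
  spectrum_integral(spec, band) / (vib_constants$kB * T)
}

#' Normalize a spectrum on a per-adsorbate basis
#'
#' @param spec a `vib_spectrum` in raw normalization
#' @param n_adsorbates number of molecules contributing (>= 1)
#' @return rescaled `vib_spectrum`
#' @export
normalize_per_adsorbate <- function(spec, n_adsorbates) {
  if (n_adsorbates < 1) stop("n_adsorbates must be >= 1")
  spec$intensity <- spec$intensity / n_adsorbates
  spec$normalization <- "per_adsorbate"
  spec
}

#' Normalize a spectrum to unit area
#'
#' @param spec a `vib_spectrum`
#' @return `vib_spectrum` whose rectangle-rule integral is 1
#' @export
normalize_unit_area <- function(spec) {
  tot <- spectrum_integral(spec)
  if (tot <= 0) stop("cannot unit-normalize a spectrum with no intensity")
  spec$intensity <- spec$intensity / tot
  spec$normalization <- "unit_area"
  spec
}
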