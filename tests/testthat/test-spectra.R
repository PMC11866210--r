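test_that("the PSD peaks at the oscillation frequency on the wavenumber grid", {
  tr <- sine_trajectory(1000, n = 36000, dt = 0.25)
  S <- mass_weighted_psd(tr, window = "hann")
  expect_lt(abs(peak_of(S) - 1000), S$resolution)
  expect_equal(S$resolution, 1 / (36000 * 0.25 * vib_constants$c_cm_fs))
  expect_true(all(S$intensity >= 0))
  expect_true(all(diff(S$wavenumbers) > 0))
})

test_that("no aliasing across the chemical range at 0.25 fs sampling", {
  for (nu0 in c(100, 650, 1500, 2500, 3800)) {
    tr <- sine_trajectory(nu0, n = 2^14, dt = 0.25)
    S <- mass_weighted_psd(tr, window = "hann")
    expect_lt(abs(peak_of(S) - nu0), S$resolution)
  }
})

test_that("zero velocities give an identically zero spectrum", {
  pos <- array(1, c(128, 1, 3))
  vel <- array(0, c(128, 1, 3))
  tr <- md_trajectory("H", pos, velocities = vel, timestep = 0.25)
  expect_equal(max(mass_weighted_psd(tr, window = "none")$intensity), 0)
  expect_error(mass_weighted_psd(md_trajectory("H", pos, timestep = 0.25)),
               "derive_velocities")
})

test_that("Parseval: the spectrum integrates to the mean mass-weighted |v|^2", {
  mod <- oscillator_model(1200, mass = 15.999)
  tr <- integrate_dynamics(mod, integrator_spec("langevin", T = 400,
                                                dt = 0.25, n_steps = 8192,
                                                friction = 0.02, seed = 3))
  S <- mass_weighted_psd(tr, window = "none")
  v <- matrix(tr$velocities, n_frames(tr), 3)
  v <- sweep(v, 2, colMeans(v))
  rhs <- mean(rowSums(v^2)) * 15.999
  expect_equal(spectrum_integral(S), rhs, tolerance = 1e-6)
})

test_that("the VACF has the correct limits and harmonic form", {
  # constant velocity: C(tau) = m |v|^2 at every lag
  n <- 256
  pos <- array(0, c(n, 1, 3))
  vel <- array(0, c(n, 1, 3)); vel[, 1, 1] <- 0.02
  pos[, 1, 1] <- 0.02 * (seq_len(n) - 1) * 0.25
  tr <- md_trajectory("O", pos, velocities = vel, timestep = 0.25)
  C <- vacf(tr, max_lag = 10 * 0.25, demean = FALSE)
  expect_equal(C$values, rep(15.999 * 0.02^2, 11), tolerance = 1e-12)
  # with the default drift-removal convention pure drift vanishes
  expect_lt(max(abs(vacf(tr, max_lag = 10 * 0.25)$values)), 1e-20)

  # single harmonic mode: C(tau) ~ cos(2 pi nu tau)
  tr2 <- sine_trajectory(800, n = 2^13, dt = 0.25, mass = 1.008)
  C2 <- vacf(tr2, max_lag = 400 * 0.25)
  w <- wavenumber_to_omega(800)
  model <- C2$values[1] * cos(w * C2$lags)
  expect_lt(max(abs(C2$values - model)) / C2$values[1], 0.02)
  # C(0) is twice the mean mass-weighted kinetic energy
  v <- tr2$velocities[, 1, 1]
  expect_equal(C2$values[1], 1.008 * mean((v - mean(v))^2), tolerance = 1e-10)

  # white-noise velocities decorrelate
  set.seed(9)
  veln <- array(rnorm(2^12 * 3, sd = 0.01), c(2^12, 1, 3))
  trn <- md_trajectory("H", array(0, c(2^12, 1, 3)), velocities = veln,
                       timestep = 0.25)
  Cn <- vacf(trn, max_lag = 50 * 0.25)
  expect_gt(Cn$values[1], 0)
  expect_lt(max(abs(Cn$values[-1])), 5 * Cn$values[1] / sqrt(2^12))
  expect_error(vacf(trn, max_lag = 2^12 * 0.25), "duration")
})

test_that("the VACF route reproduces the periodogram (Wiener-Khintchine)", {
  mod <- oscillator_model(1000)
  tr <- integrate_dynamics(mod, integrator_spec("langevin", T = 500,
                                                dt = 0.25, n_steps = 16384,
                                                friction = 0.01, seed = 9))
  S1 <- mass_weighted_psd(tr, window = "none")
  C <- vacf(tr, max_lag = (n_frames(tr) - 1) * tr$timestep,
            normalization = "biased")
  S2 <- psd_from_vacf(C, window = "none")
  expect_equal(S2$wavenumbers, S1$wavenumbers)
  expect_lt(rel_l2(S2$intensity, S1$intensity), 1e-10)

  # cosine correlation peaks at its frequency; delta-like C is flat
  w <- wavenumber_to_omega(600)
  lags <- (0:2047) * 0.25
  Cc <- structure(list(lags = lags, values = cos(w * lags), n_frames = 4096L,
                       timestep = 0.25, normalization = "biased"),
                  class = "vib_vacf")
  Sc <- psd_from_vacf(Cc, window = "hann")
  expect_lt(abs(peak_of(Sc) - 600), 2 * Sc$resolution)
  Cd <- structure(list(lags = lags, values = c(1, rep(0, 2047)),
                       n_frames = 4096L, timestep = 0.25,
                       normalization = "biased"),
                  class = "vib_vacf")
  Sd <- psd_from_vacf(Cd, window = "none")
  inner <- Sd$intensity[2:(length(Sd$intensity) - 1)]  # DC/Nyquist not doubled
  expect_lt(diff(range(inner)) / mean(inner), 1e-6)
})

test_that("band integrals count thermalized modes in 1/2 kT units", {
  mod <- oscillator_model(1000, mass = 12.011)
  tr <- integrate_dynamics(mod, integrator_spec("langevin", T = 500,
                                                dt = 0.25, n_steps = 100000,
                                                friction = 0.05, seed = 14))
  S <- mass_weighted_psd(tr, window = "hann")
  # the tethered atom is isotropic: 3 modes at 1000 cm^-1
  n3 <- band_mode_count(S, c(500, 1500), 500)
  expect_lt(abs(n3 - 3), 0.3)
  expect_equal(band_mode_count(S, c(3000, 4000), 500), 0, tolerance = 0.05)
  expect_error(band_mode_count(S, c(7e4, 8e4), 500), "outside")
})

test_that("per-adsorbate normalization rescales intensities and counts", {
  tr <- sine_trajectory(900, n = 4096)
  S <- mass_weighted_psd(tr, window = "hann")
  expect_equal(normalize_per_adsorbate(S, 1)$intensity, S$intensity)
  S2 <- normalize_per_adsorbate(S, 2)
  expect_equal(S2$intensity, S$intensity / 2)
  expect_equal(S2$normalization, "per_adsorbate")
  expect_equal(band_mode_count(S2, c(800, 1000), 300),
               band_mode_count(S, c(800, 1000), 300) / 2)
  expect_error(normalize_per_adsorbate(S, 0), ">= 1")
})

test_that("unit-area normalization is exact and stable under windows", {
  for (wd in c("hann", "none")) {
    tr <- sine_trajectory(1200, n = 4096)
    S <- normalize_unit_area(mass_weighted_psd(tr, window = wd))
    expect_equal(spectrum_integral(S), 1, tolerance = 1e-8)
  }
})
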