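toy <- glycinate_toy()

test_that("the glycinate basis has 21 unit-norm modes with the canonical names", {
  basis <- build_local_mode_basis(glycinate_topology())
  expect_length(basis, 21L)                      # 3N - 6 for N = 9
  nms <- vapply(basis, `[[`, "", "name")
  expected <- c(paste0(rep(c("nu_s", "nu_a"), 3),
                       "(", rep(c("NH2", "CH2", "CO2"), each = 2), ")"),
                "nu(CN)", "nu(CC)", "tau(CN)", "tau(CC)",
                paste0(rep(c("delta", "omega", "rho"), each = 3),
                       "(", rep(c("NH2", "CH2", "CO2"), 3), ")"),
                "t(CH2)", "delta(NCC)")
  expect_setequal(nms, expected)
  for (b in basis) {
    cf <- vapply(b$primitives, `[[`, 0, "coeff")
    expect_equal(sum(cf^2), 1, tolerance = 1e-12)
  }
  expect_error(glycinate_topology(stats::setNames(c(1:8, 8L),
                                                  names(glycinate_topology()$roles))),
               "exactly one atom index")
})

test_that("rigid translations and rotations give zero local-mode velocities", {
  x0 <- toy$model$positions
  nf <- 40
  pos <- array(NA_real_, c(nf, 9, 3)); vel <- array(NA_real_, c(nf, 9, 3))
  vtr <- c(0.012, -0.02, 0.007)
  for (f in seq_len(nf)) {
    pos[f, , ] <- sweep(x0, 2, (f - 1) * 0.25 * vtr, "+")
    vel[f, , ] <- matrix(vtr, 9, 3, byrow = TRUE)
  }
  tr <- md_trajectory(toy$model$species, pos, velocities = vel,
                      timestep = 0.25)
  expect_lt(max(abs(project_velocities(tr, toy$basis)$series)), 1e-10)

  om <- 1e-4                                      # rad/fs about z
  com <- colMeans(x0)
  for (f in seq_len(nf)) {
    th <- (f - 1) * 0.25 * om
    Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    xc <- sweep(x0, 2, com) %*% t(Rz)
    pos[f, , ] <- sweep(xc, 2, com, "+")
    vel[f, , ] <- cbind(-om * xc[, 2], om * xc[, 1], 0)
  }
  tr <- md_trajectory(toy$model$species, pos, velocities = vel,
                      timestep = 0.25)
  expect_lt(max(abs(project_velocities(tr, toy$basis)$series)), 1e-8)
})

test_that("a pure CN oscillation shows up only in the CN stretch series", {
  # rigid translation of the NH2 moiety along the CN axis changes r(CN)
  # and no other internal coordinate
  x0 <- toy$model$positions
  dirCN <- x0[4, ] - x0[1, ]; dirCN <- dirCN / sqrt(sum(dirCN^2))
  nu0 <- 950; w <- wavenumber_to_omega(nu0); A <- 0.02
  nf <- 4096
  pos <- array(NA_real_, c(nf, 9, 3)); vel <- array(0, c(nf, 9, 3))
  moiety <- 1:3                                   # N, HN1, HN2
  for (f in seq_len(nf)) {
    tt <- (f - 1) * 0.25
    xx <- x0
    xx[moiety, ] <- sweep(xx[moiety, ], 2, A * sin(w * tt) * dirCN, "+")
    pos[f, , ] <- xx
    vel[f, moiety, ] <- matrix(A * w * cos(w * tt) * dirCN, 3, 3, byrow = TRUE)
  }
  tr <- md_trajectory(toy$model$species, pos, velocities = vel,
                      timestep = 0.25)
  mv <- project_velocities(tr, toy$basis)
  amp <- apply(abs(mv$series), 2, max)
  expect_gt(amp["nu(CN)"], 0.9 * A * w)           # sinusoidal at full scale
  others <- amp[setdiff(names(amp), "nu(CN)")]
  expect_lt(max(others) / amp["nu(CN)"], 0.01)
  # the series is sinusoidal at nu0 (spectrum of the CN series alone; the
  # remaining series are identically zero by construction)
  mv_cn <- mv
  mv_cn$series <- mv$series[, "nu(CN)", drop = FALSE]
  mv_cn$mode_names <- "nu(CN)"
  S <- local_mode_spectra(mv_cn)[["nu(CN)"]]
  expect_lt(abs(peak_of(S) - nu0), S$resolution)
  expect_equal(spectrum_integral(S), 1, tolerance = 1e-8)
})

test_that("two molecules with identical dynamics average to either one", {
  ic <- thermal_initial_conditions(toy$model, 500, seed = 2)
  tr <- integrate_dynamics(toy$model,
                           integrator_spec("nve_velocity_verlet", dt = 0.25,
                                           n_steps = 2048, seed = 1),
                           x0 = ic$x0, v0 = ic$v0)
  mv <- project_velocities(tr, toy$basis)
  one <- local_mode_spectra(mv)
  avg <- local_mode_spectra(list(mv, mv))
  for (nm in names(one))
    expect_equal(avg[[nm]]$intensity, one[[nm]]$intensity, tolerance = 1e-12)
})

test_that("all-zero series cannot be unit-normalized", {
  x0 <- toy$model$positions
  tr <- static_trajectory(x0, toy$model$species, n = 16, dt = 0.25)
  tr$velocities <- array(0, dim(tr$positions))
  mv <- project_velocities(tr, toy$basis)
  expect_error(local_mode_spectra(mv), "all-zero|no intensity")
})

test_that("per-mode spectra recover the constructed frequencies", {
  series <- list()
  for (d in 1:4) {
    ic <- thermal_initial_conditions(toy$model, 500, seed = 100 + d)
    tr <- integrate_dynamics(toy$model,
                             integrator_spec("nve_velocity_verlet", dt = 0.05,
                                             n_steps = 18000 * 5,
                                             sample_every = 5, seed = 1),
                             x0 = ic$x0, v0 = ic$v0)
    series[[d]] <- project_velocities(tr, toy$basis)
  }
  ls <- local_mode_spectra(series)
  res <- ls[[1]]$resolution
  rec <- vapply(names(ls), function(nm) peak_of(ls[[nm]]), numeric(1))
  tg <- toy$target_frequencies[names(ls)]
  # non-degenerate, weakly coupled modes must land within one grid spacing;
  # allow the two most strongly mixed coordinates one extra spacing
  err <- sort(abs(rec - tg), decreasing = TRUE)
  expect_lt(err[3], res)
  expect_lt(err[1], 2 * res)
  for (nm in names(ls))
    expect_equal(spectrum_integral(ls[[nm]]), 1, tolerance = 1e-8)
})
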