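test_that("velocity Verlet conserves energy without drift", {
  mod <- oscillator_model(1000)
  period <- 1 / (1000 * vib_constants$c_cm_fs)
  tr <- integrate_dynamics(mod,
    integrator_spec("nve_velocity_verlet", dt = period / 50,
                    n_steps = 100000, seed = 1, sample_every = 10),
    x0 = rbind(c(0.05, 0, 0)))
  nf <- n_frames(tr)
  E <- vapply(seq_len(nf), function(f)
    potential_energy(mod, tr$positions[f, , , drop = TRUE]) +
      0.5 * 1.008 * sum(tr$velocities[f, 1, ]^2), numeric(1))
  head_ <- mean(E[seq_len(nf %/% 10)])
  tail_ <- mean(E[(nf - nf %/% 10):nf])
  expect_lt(abs(tail_ - head_) / mean(E), 1e-5)
})

test_that("the step-size guard warns and then fails", {
  mod <- oscillator_model(3000)
  period <- 1 / (3000 * vib_constants$c_cm_fs)
  expect_warning(integrate_dynamics(mod,
    integrator_spec("nve_velocity_verlet", dt = period / 8, n_steps = 10)),
    "tenth")
  expect_error(integrate_dynamics(mod,
    integrator_spec("nve_velocity_verlet", dt = period / 3, n_steps = 10)),
    "stability")
})

test_that("Langevin dynamics sample the canonical ensemble", {
  nu0 <- 800; mass <- 15.999; T_ <- 500
  mod <- oscillator_model(nu0, mass)
  tr <- integrate_dynamics(mod, integrator_spec("langevin", T = T_, dt = 0.25,
                                                n_steps = 150000,
                                                friction = 0.05, seed = 77))
  pred <- vib_constants$kB * T_ / (mass * wavenumber_to_omega(nu0)^2)
  for (comp in 1:3) {
    bs <- batch_se(tr$positions[, 1, comp], nbatch = 25)
    expect_lt(abs(bs$mean - pred), 3 * bs$se)
  }
  # kinetic temperature
  ke <- rowSums(tr$velocities[, 1, ]^2) * mass
  bs <- batch_se(ke, nbatch = 25, stat = mean)
  expect_lt(abs(bs$mean - 3 * vib_constants$kB * T_), 3 * bs$se)
})

test_that("zero-temperature Langevin from equilibrium stays static", {
  mod <- oscillator_model(1000)
  tr <- integrate_dynamics(mod, integrator_spec("langevin", T = 0, dt = 0.25,
                                                n_steps = 200, seed = 1))
  expect_equal(max(abs(tr$positions)), 0)
  expect_equal(max(abs(tr$velocities)), 0)
})

test_that("the Nose-Hoover chain thermostats a multi-mode system", {
  toy <- glycinate_toy()
  tr <- integrate_dynamics(toy$model,
    integrator_spec("nose_hoover_chain", T = 500, dt = 0.25,
                    n_steps = 30000, seed = 5, tau = 10, chain_length = 5))
  mdof <- rep(toy$model$masses, 3)
  nf <- n_frames(tr)
  keep <- seq(nf %/% 3, nf)
  ke <- vapply(keep, function(f)
    sum(mdof * as.vector(tr$velocities[f, , ])^2), numeric(1))
  Tk <- mean(ke) / (27 * vib_constants$kB)
  expect_lt(abs(Tk - 500) / 500, 0.08)
})

test_that("the glycinate toy places its normal modes at the targets", {
  toy <- glycinate_toy()
  expect_equal(unname(toy$achieved_frequencies),
               unname(toy$target_frequencies), tolerance = 0.02)
  nm <- normal_modes(toy$model)
  internal <- sum(nm$wavenumbers > 250)
  expect_equal(internal, 21L)                    # mobile dof minus externals
  expect_equal(sum(nm$wavenumbers > 0), 27L)
  # custom targets are honoured
  freqs <- glycinate_default_frequencies()
  freqs["nu(CN)"] <- 1000
  toy2 <- glycinate_toy(frequencies = freqs)
  expect_equal(unname(toy2$achieved_frequencies["nu(CN)"]), 1000,
               tolerance = 0.02)
  expect_error(glycinate_toy(frequencies = -freqs), "positive")
})

test_that("the glide pair is exactly symmetric and mirrors its dynamics", {
  toy <- glycinate_toy(layout = "glide_pair")
  ms <- structure(list(species = toy$model$species,
                       mean_positions = toy$model$positions,
                       n_frames_averaged = 1L, cell = toy$model$cell,
                       indices = seq_along(toy$model$species)),
                  class = "mean_structure")
  dev <- rms_symmetry_deviation(ms, toy$glide,
                                unname(toy$selections))
  expect_lt(max(dev), 1e-10)
  # the matcher recovers the constructed pairing
  op <- match_under_symmetry(ms, mirror_axis = "y", plane_offset = 0,
                             glide_vector = c(5.1, 0, 0))
  expect_equal(op$permutation, toy$glide$permutation)

  # mirrored noise drives exactly mirrored trajectories
  single <- glycinate_toy()
  n_steps <- 400
  set.seed(9)
  noise <- matrix(rnorm(n_steps * 27), n_steps, 27)
  sflip <- rep(c(1, -1, 1), each = 9)
  noise_m <- sweep(noise, 2, sflip, "*")
  mirror_model <- single$model
  mirror_model$positions[, 2] <- -mirror_model$positions[, 2]
  mirror_model$hessian <- (sflip %o% sflip) * single$model$hessian
  sp <- integrator_spec("langevin", T = 500, dt = 0.25, n_steps = n_steps,
                        friction = 0.01, seed = 1)
  v0 <- matrix(rnorm(27, 0, 0.002), 9, 3)
  v0_m <- v0; v0_m[, 2] <- -v0_m[, 2]
  tr1 <- integrate_dynamics(single$model, sp, v0 = v0, noise = noise)
  tr2 <- integrate_dynamics(mirror_model, sp, v0 = v0_m, noise = noise_m)
  flipped <- tr1$positions
  flipped[, , 2] <- -flipped[, , 2]
  expect_lt(max(abs(tr2$positions - flipped)), 1e-10)
})

test_that("Morse reference recovers the harmonic limit and softens with T", {
  mass <- 0.95; nu0 <- 3400
  om0 <- wavenumber_to_omega(nu0)
  for (D in c(0.02, 0.2, 2)) {
    a <- om0 * sqrt(mass / (2 * D))
    ref <- morse_bond_reference(D, a, mass, 300)
    expect_equal(ref$harmonic_wavenumber, nu0, tolerance = 1e-10)
    # closed-form classical Morse frequency: nu0 * sqrt(1 - E/D)
    expect_equal(ref$wavenumber,
                 nu0 * sqrt(1 - vib_constants$kB * 300 / D),
                 tolerance = 1e-6)
  }
  # deeper well -> closer to harmonic
  D1 <- 0.02; D2 <- 2
  a1 <- om0 * sqrt(mass / (2 * D1)); a2 <- om0 * sqrt(mass / (2 * D2))
  expect_lt(morse_bond_reference(D1, a1, mass, 300)$wavenumber,
            morse_bond_reference(D2, a2, mass, 300)$wavenumber)
  # monotone softening over a temperature ladder
  D <- 0.0386; a <- om0 * sqrt(mass / (2 * D))
  nus <- vapply(c(100, 300, 500, 800, 1200),
                function(T_) morse_bond_reference(D, a, mass, T_)$wavenumber,
                numeric(1))
  expect_true(all(diff(nus) < 0))
  expect_error(morse_bond_reference(0.001, 2, mass, 5000), "dissociation")
})

test_that("thermal draws reproduce canonical statistics", {
  toy <- glycinate_toy()
  nmod <- normal_modes(toy$model)
  kT <- vib_constants$kB * 500
  set.seed(1)
  vs <- replicate(300, {
    ic <- thermal_initial_conditions(toy$model, 500,
                                     seed = sample.int(1e6, 1))
    sum(rep(toy$model$masses, 3) * as.vector(ic$v0)^2)
  })
  # total mass-weighted v^2 averages 27 kT
  expect_lt(abs(mean(vs) - 27 * kT) / (27 * kT), 3 * sqrt(2 / (27 * 300)))
})
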