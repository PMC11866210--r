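test_that("displacement matrices match analytic second moments", {
  # static atom: U = 0
  tr <- static_trajectory(rbind(c(1, 1, 1)), "H", n = 10)
  U0 <- displacement_matrices(tr, mean_structure(tr))
  expect_equal(max(abs(U0$U)), 0)

  # x-displacement A cos(wt) over whole periods: U_xx = A^2/2
  nu0 <- 700; A <- 0.1; dt <- 0.25
  w <- wavenumber_to_omega(nu0)
  n <- round(2 * pi / w / dt * 40)
  tt <- (seq_len(n) - 1) * dt
  pos <- array(0, c(n, 1, 3))
  pos[, 1, 1] <- A * cos(w * tt)
  tr <- md_trajectory("H", pos, timestep = dt)
  U <- displacement_matrices(tr, mean_structure(tr))$U[1, , ]
  expect_equal(U[1, 1], A^2 / 2, tolerance = 5e-3)
  expect_lt(max(abs(U[2:3, ])), 1e-12)

  # isotropic Gaussian displacements: U ~= sigma^2 I within 3 SE
  set.seed(31)
  nf <- 4e4; sig <- 0.1
  pos <- array(rnorm(nf * 3, sd = sig), c(nf, 1, 3))
  tr <- md_trajectory("H", pos, timestep = 1)
  U <- displacement_matrices(tr, mean_structure(tr))$U[1, , ]
  se <- sig^2 * sqrt(2 / nf)
  expect_lt(max(abs(diag(U) - sig^2)), 3 * se)
  expect_lt(max(abs(U[upper.tri(U)])), 3 * sig^2 / sqrt(nf))
})

test_that("trace of U equals the mean squared displacement", {
  set.seed(5)
  nf <- 500
  pos <- array(rnorm(nf * 2 * 3, sd = 0.2), c(nf, 2, 3))
  tr <- md_trajectory(c("C", "O"), pos, timestep = 1)
  ms <- mean_structure(tr)
  U <- displacement_matrices(tr, ms)
  for (a in 1:2) {
    msd <- mean(rowSums((pos[, a, ] -
      matrix(ms$mean_positions[a, ], nf, 3, byrow = TRUE))^2))
    expect_equal(sum(diag(U$U[a, , ])), msd, tolerance = 1e-10)
  }
})

test_that("glide symmetrization of U is the half-sum and is idempotent", {
  s <- 0.04
  R <- diag(c(1, -1, 1))
  Ua <- diag(c(1, 0, 0)) * s
  Ub <- t(R) %*% (diag(c(0, 1, 0)) * s) %*% R   # so R Ub R^T = diag(0,1,0)s
  U_set <- structure(list(U = array(c(Ua, Ub), c(2, 3, 3)),
                          indices = 1:2, species = c("O", "O")),
                     class = "displacement_matrices")
  U_set$U[1, , ] <- Ua
  U_set$U[2, , ] <- Ub
  op <- glide_operation(R, c(1, 0, 0), c(2L, 1L))
  sym <- symmetrize_displacement_matrices(U_set, op)
  expect_equal(sym$U[1, , ], 0.5 * diag(c(1, 1, 0)) * s)
  sym2 <- symmetrize_displacement_matrices(sym, op)
  expect_equal(sym2$U, sym$U, tolerance = 1e-14)
  # invariance under the operation
  expect_equal(sym$U[1, , ], R %*% sym$U[2, , ] %*% t(R))
  # a symmetric pair is a fixed point
  fix <- structure(list(U = sym$U, indices = 1:2, species = c("O", "O")),
                   class = "displacement_matrices")
  expect_equal(symmetrize_displacement_matrices(fix, op)$U, fix$U)
})

test_that("thermal ellipsoids follow the spectral decomposition", {
  # isotropic: sphere of radius scale * sigma
  e <- ellipsoid(diag(3) * 0.01, scale = 1.5382)
  expect_equal(e$semiaxes, rep(1.5382 * 0.1, 3))

  # closed-form eigenvalues
  e2 <- ellipsoid(diag(c(4, 1, 1)) * 1e-2, scale = 1.5382)
  expect_equal(e2$semiaxes, c(0.30764, 0.15382, 0.15382), tolerance = 1e-10)

  # rotation equivariance (spectral theorem)
  set.seed(8)
  M <- crossprod(matrix(rnorm(9), 3)) * 1e-3 + diag(3) * 1e-3
  th <- 0.5
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  eA <- ellipsoid(M)
  eB <- ellipsoid(Q %*% M %*% t(Q))
  expect_equal(eB$eigenvalues, eA$eigenvalues, tolerance = 1e-10)
  for (k in 1:3) {
    v <- Q %*% eA$axes[, k]
    expect_equal(abs(sum(v * eB$axes[, k])), 1, tolerance = 1e-8)
  }
  expect_error(ellipsoid(diag(c(1, 1, -1)) * 1e-2), "negative eigenvalue")
})

test_that("shape classification separates prolate, oblate and spherical", {
  mk <- function(s) structure(list(semiaxes = s), class = "thermal_ellipsoid")
  expect_equal(shape_descriptor(mk(c(2, 1, 1)), 0.05)$shape_class, "prolate")
  expect_equal(shape_descriptor(mk(c(2, 2, 1)), 0.05)$shape_class, "oblate")
  expect_equal(shape_descriptor(mk(c(1.00, 1.02, 1.04)), 0.05)$shape_class,
               "spherical")
  expect_equal(shape_descriptor(mk(c(3, 2, 1)), 0.05)$shape_class, "triaxial")
  expect_equal(shape_descriptor(mk(c(2, 1, 1)), 0.05)$anisotropy_ratio, 2)
})

test_that("equipartition sets the tethered atom's displacement eigenvalue", {
  nu0 <- 900; mass <- 12.011; T_ <- 500
  mod <- oscillator_model(nu0, mass)
  tr <- integrate_dynamics(mod, integrator_spec("langevin", T = T_,
                                                dt = 0.25, n_steps = 150000,
                                                friction = 0.05, seed = 42))
  pred <- vib_constants$kB * T_ / (mass * wavenumber_to_omega(nu0)^2)
  bs <- batch_se(tr$positions[, 1, 1], nbatch = 25)
  expect_lt(abs(bs$mean - pred), 3 * bs$se)
  U <- displacement_matrices(tr, mean_structure(tr))
  ev <- ellipsoid(U$U[1, , ])$eigenvalues
  expect_lt(abs(mean(ev) - pred), 4 * bs$se)
})

test_that("ADP CIF export round-trips and uses the crystallographic convention", {
  # cubic cell: U_cif equals Cartesian U
  cell <- diag(c(10, 10, 10))
  x <- rbind(c(1, 2, 3), c(4, 5, 6))
  ms <- structure(list(species = c("Cu", "O"), mean_positions = x,
                       n_frames_averaged = 1L, cell = cell, indices = 1:2),
                  class = "mean_structure")
  U <- structure(list(U = array(0, c(2, 3, 3)), indices = 1:2,
                      species = c("Cu", "O")),
                 class = "displacement_matrices")
  U$U[1, , ] <- diag(3) * 0.01
  U$U[2, , ] <- matrix(c(0.02, 0.003, 0, 0.003, 0.015, 0.001,
                         0, 0.001, 0.01), 3, 3)
  f <- withr::local_tempfile(fileext = ".cif")
  write_adp_cif(ms, U, f)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "data_"))
  expect_true(any(grepl("^loop_", lines)))
  expect_true(any(grepl("_atom_site_aniso_U_23", lines)))
  iso <- grep("^Cu1 ", lines, value = TRUE)[2]
  vals <- as.numeric(strsplit(iso, " ")[[1]][-1])
  expect_equal(vals[1:3], rep(0.01, 3), tolerance = 1e-9)
  expect_equal(vals[4:6], rep(0, 3), tolerance = 1e-12)
  back <- read_adp_cif(f, cell = cell)
  expect_lt(max(abs(back$U - U$U)), 1e-8)
  expect_lt(max(abs(back$positions - x)), 1e-8)

  # triclinic cell round trip
  cell2 <- rbind(c(9, 0, 0), c(2, 8, 0), c(1, 1.5, 11))
  ms$cell <- cell2
  f2 <- withr::local_tempfile(fileext = ".cif")
  write_adp_cif(ms, U, f2)
  back2 <- read_adp_cif(f2, cell = cell2)
  expect_lt(max(abs(back2$U - U$U)), 1e-8)
})
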