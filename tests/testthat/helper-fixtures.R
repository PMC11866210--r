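# Shared fixture builders (all generated in code; no stored data).

# single tethered atom: an isotropic harmonic oscillator at nu0 cm^-1
oscillator_model <- function(nu0 = 1000, mass = 1.008) {
  k <- mass * wavenumber_to_omega(nu0)^2
  force_model("H", rbind(c(0, 0, 0)),
              interactions = list(list(type = "site_tether", atom = 1L,
                                       k = k, site = c(0, 0, 0))),
              masses = mass)
}

# analytic sinusoidal 1-atom trajectory: x(t) = A sin(w t) along x
sine_trajectory <- function(nu0, A = 0.05, n = 16384, dt = 0.25,
                            mass = 1.008, with_velocities = TRUE) {
  w <- wavenumber_to_omega(nu0)
  tt <- (seq_len(n) - 1) * dt
  pos <- array(0, c(n, 1, 3))
  pos[, 1, 1] <- A * sin(w * tt)
  vel <- NULL
  if (with_velocities) {
    vel <- array(0, c(n, 1, 3))
    vel[, 1, 1] <- A * w * cos(w * tt)
  }
  md_trajectory("H", pos, velocities = vel, timestep = dt, masses = mass)
}

# static trajectory from a coordinate matrix
static_trajectory <- function(x, species, n = 5, dt = 1, cell = NULL) {
  nat <- nrow(x)
  pos <- array(NA_real_, c(n, nat, 3))
  for (f in seq_len(n)) pos[f, , ] <- x
  md_trajectory(species, pos, timestep = dt, cell = cell)
}

# a 4-atom toy with exact glide symmetry: mirror y=0, translation (2,0,0),
# inside the periodic cell whose a-vector is twice the glide translation
glide_toy_structure <- function(perturb = 0) {
  x <- rbind(c(0.5, 1.0, 0.2), c(1.3, 0.7, 0.9),
             c(2.5, -1.0, 0.2), c(3.3, -0.7, 0.9))
  x[1, ] <- x[1, ] + c(0, 0, perturb)
  structure(list(species = c("C", "O", "C", "O"), mean_positions = x,
                 n_frames_averaged = 1L, cell = diag(c(4, 6, 6)),
                 indices = 1:4),
            class = "mean_structure")
}

# batch-mean standard error of a statistic computed on equal batches
batch_se <- function(x, nbatch = 20, stat = stats::var) {
  n <- length(x) %/% nbatch * nbatch
  b <- vapply(split(x[seq_len(n)], rep(seq_len(nbatch),
                                       each = n / nbatch)),
              stat, numeric(1))
  list(mean = mean(b), se = stats::sd(b) / sqrt(nbatch))
}

peak_of <- function(spec, band = NULL) {
  keep <- if (is.null(band)) seq_along(spec$wavenumbers)
          else which(spec$wavenumbers >= band[1] & spec$wavenumbers <= band[2])
  spec$wavenumbers[keep][which.max(spec$intensity[keep])]
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
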