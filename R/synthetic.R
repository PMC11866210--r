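# Synthetic trajectory generation: thermalized harmonic networks, anharmonic
# Morse bonds and glide-symmetric adsorbate pairs, so that every analysis
# stage has a ground-truth oracle.
#
# Degrees of freedom are stacked component-major: the state vector holds all
# mobile atoms' x components, then y, then z (matching as.vector() on an
# n x 3 coordinate matrix).

#' Construct a force model
#'
#' @param species element symbols, one per particle
#' @param positions n x 3 equilibrium positions, Angstrom
#' @param interactions list of interaction terms; each a list with `type` in
#'   `"site_tether"` (atom, k, site), `"harmonic_bond"` (i, j, k, r0),
#'   `"harmonic_angle"` (i, j, k atoms as `atoms`, k, theta0), `"morse_bond"`
#'   (i, j, D, a, r0). Stiffnesses amu/fs^2, energies amu A^2/fs^2.
#' @param fixed logical vector: particles held immobile (substrate atoms)
#' @param hessian optional precomputed Hessian over the mobile degrees of
#'   freedom (component-major stacking); when present the model's force field
#'   is the harmonic form -H (x - x0) and `interactions` are kept for audit
#' @param cell optional 3x3 cell (rows)
#' @param masses per-particle amu; from species when missing
#' @return a `force_model`
#' @export
force_model <- function(species, positions, interactions = list(),
                        fixed = NULL, hessian = NULL, cell = NULL,
                        masses = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(fixed)) fixed <- rep(FALSE, n)
  if (is.null(masses)) masses <- element_masses(species)
  if (all(fixed)) stop("at least one particle must be mobile")
  for (ia in interactions) {
    if (ia$type %in% c("harmonic_bond", "harmonic_angle") && ia$k <= 0)
      stop("stiffness must be positive")
    if (ia$type == "site_tether" && any(ia$k < 0))
      stop("tether stiffness must be non-negative")
    if (ia$type == "morse_bond" && (ia$D <= 0 || ia$a <= 0))
      stop("Morse depth and range must be positive")
  }
  if (!is.null(hessian)) {
    nm <- 3L * sum(!fixed)
    hessian <- as.matrix(hessian)
    if (!all(dim(hessian) == nm))
      stop("hessian must be 3*n_mobile square")
  }
  structure(list(species = species, masses = masses, positions = positions,
                 interactions = interactions, fixed = fixed,
                 hessian = hessian, cell = cell),
            class = "force_model")
}

# forces (n x 3) and potential energy for the generic interaction list
.force_generic <- function(model, x) {
  f <- matrix(0, nrow(x), 3)
  for (ia in model$interactions) {
    if (ia$type == "site_tether") {
      # k may be a scalar or per-axis length-3 stiffness
      f[ia$atom, ] <- f[ia$atom, ] - ia$k * (x[ia$atom, ] - ia$site)
    } else if (ia$type %in% c("harmonic_bond", "morse_bond")) {
      dvec <- x[ia$j, ] - x[ia$i, ]
      r <- sqrt(sum(dvec^2))
      u <- dvec / r
      dV <- if (ia$type == "harmonic_bond") ia$k * (r - ia$r0)
      else {
        ex <- exp(-ia$a * (r - ia$r0))
        2 * ia$D * ia$a * ex * (1 - ex)
      }
      f[ia$i, ] <- f[ia$i, ] + dV * u
      f[ia$j, ] <- f[ia$j, ] - dV * u
    } else if (ia$type == "harmonic_angle") {
      coords <- lapply(ia$atoms, function(a) matrix(x[a, ], 1, 3))
      th <- .prim_value("bend", coords)
      sv <- .prim_svectors("bend", coords)
      for (m in seq_along(ia$atoms))
        f[ia$atoms[m], ] <- f[ia$atoms[m], ] - ia$k * (th - ia$theta0) * sv[[m]]
    } else stop("unknown interaction type: ", ia$type)
  }
  f
}

.potential_generic <- function(model, x) {
  V <- 0
  for (ia in model$interactions) {
    if (ia$type == "site_tether") {
      V <- V + 0.5 * sum(ia$k * (x[ia$atom, ] - ia$site)^2)
    } else if (ia$type == "harmonic_bond") {
      r <- sqrt(sum((x[ia$j, ] - x[ia$i, ])^2))
      V <- V + 0.5 * ia$k * (r - ia$r0)^2
    } else if (ia$type == "morse_bond") {
      r <- sqrt(sum((x[ia$j, ] - x[ia$i, ])^2))
      V <- V + ia$D * (1 - exp(-ia$a * (r - ia$r0)))^2
    } else if (ia$type == "harmonic_angle") {
      coords <- lapply(ia$atoms, function(a) matrix(x[a, ], 1, 3))
      V <- V + 0.5 * ia$k * (.prim_value("bend", coords) - ia$theta0)^2
    }
  }
  V
}

#' Potential energy of a force model at given coordinates
#' @param model a `force_model`
#' @param x n x 3 coordinates (default equilibrium)
#' @return potential energy, amu A^2/fs^2
#' @export
potential_energy <- function(model, x = model$positions) {
  x <- matrix(x, nrow(model$positions), 3)
  if (!is.null(model$hessian)) {
    mob <- !model$fixed
    u <- as.vector(x[mob, , drop = FALSE] -
                   model$positions[mob, , drop = FALSE])
    0.5 * sum(u * (model$hessian %*% u))
  } else .potential_generic(model, x)
}

# Hessian over mobile dof: analytic form if stored, else central differences
# of the generic forces
.model_hessian <- function(model, h = 1e-5) {
  if (!is.null(model$hessian)) return(model$hessian)
  mob <- which(!model$fixed)
  nd <- 3 * length(mob)
  H <- matrix(0, nd, nd)
  x0 <- model$positions
  for (d in seq_len(nd)) {
    at <- mob[(d - 1) %% length(mob) + 1]
    comp <- (d - 1) %/% length(mob) + 1
    xp <- x0; xp[at, comp] <- xp[at, comp] + h
    xm <- x0; xm[at, comp] <- xm[at, comp] - h
    df <- (.force_generic(model, xp) - .force_generic(model, xm)) / (2 * h)
    H[, d] <- -as.vector(df[mob, , drop = FALSE])
  }
  (H + t(H)) / 2
}

#' Normal-mode analysis of a force model
#'
#' Diagonalizes the mass-weighted Hessian over the mobile degrees of
#' freedom. For models carrying a precomputed Hessian this is exact; for
#' generic interaction lists the Hessian is obtained by central differences
#' of the analytic forces at equilibrium.
#'
#' @param model a `force_model`
#' @return list: `wavenumbers` (cm^-1, descending; negative values flag
#'   imaginary modes), `modes` (mass-weighted eigenvectors, columns),
#'   `masses_dof` (amu per degree of freedom)
#' @export
normal_modes <- function(model) {
  H <- .model_hessian(model)
  mob <- !model$fixed
  mdof <- rep(model$masses[mob], 3)
  W <- H / sqrt(outer(mdof, mdof))
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  nu <- omega_to_wavenumber(sqrt(abs(e$values))) * sign(e$values)
  list(wavenumbers = nu, modes = e$vectors, masses_dof = mdof)
}

#' Draw canonical-ensemble initial conditions for a harmonic model
#'
#' Samples positions and velocities from the exact Boltzmann distribution of
#' the model's harmonic normal modes at temperature T (each mode receives
#' Gaussian position and velocity amplitudes of variance k_B T / omega^2 and
#' k_B T in mass-weighted coordinates). Useful to start energy-conserving
#' production runs from a properly thermalized state.
#'
#' @param model a `force_model` (harmonic: carries a Hessian, or its
#'   numerical Hessian is used)
#' @param T temperature, K
#' @param seed integer seed
#' @return list with `x0` and `v0` (n x 3 matrices including fixed atoms)
#' @export
thermal_initial_conditions <- function(model, T, seed = 1) {
  nm <- normal_modes(model)
  if (min(nm$wavenumbers) <= 0)
    stop("thermal draw requires all normal modes bound (positive frequency)")
  set.seed(seed)
  kT <- vib_constants$kB * T
  om <- wavenumber_to_omega(nm$wavenumbers)
  nd <- length(om)
  a <- stats::rnorm(nd, 0, sqrt(kT) / om)
  b <- stats::rnorm(nd, 0, sqrt(kT))
  du <- (nm$modes %*% a) / sqrt(nm$masses_dof)
  dv <- (nm$modes %*% b) / sqrt(nm$masses_dof)
  mob <- which(!model$fixed)
  x0 <- model$positions
  v0 <- matrix(0, nrow(x0), 3)
  x0[mob, ] <- x0[mob, ] + matrix(du, length(mob), 3)
  v0[mob, ] <- matrix(dv, length(mob), 3)
  list(x0 = x0, v0 = v0)
}

#' Integrator specification
#'
#' @param scheme "nve_velocity_verlet", "langevin" or "nose_hoover_chain"
#' @param T target temperature, K (ignored by NVE except for initial
#'   velocities when requested)
#' @param dt time step, fs
#' @param n_steps number of steps
#' @param friction Langevin friction gamma, 1/fs
#' @param chain_length Nose-Hoover chain length (default 5)
#' @param tau thermostat time constant for the chain, fs
#' @param seed integer seed for all stochastic elements
#' @param sample_every store every k-th step
#' @return an `integrator_spec`
#' @export
integrator_spec <- function(scheme = c("langevin", "nve_velocity_verlet",
                                       "nose_hoover_chain"),
                            T = 500, dt = 0.25, n_steps = 1000,
                            friction = 0.01, chain_length = 5, tau = 10,
                            seed = 1, sample_every = 1) {
  scheme <- match.arg(scheme)
  if (dt <= 0 || T < 0 || chain_length < 1) stop("invalid integrator spec")
  structure(list(scheme = scheme, T = T, dt = dt, n_steps = as.integer(n_steps),
                 friction = friction, chain_length = as.integer(chain_length),
                 tau = tau, seed = seed,
                 sample_every = as.integer(sample_every)),
            class = "integrator_spec")
}

#' Integrate the dynamics of a force model
#'
#' Velocity-Verlet (NVE), BAOAB Langevin, or a Nose-Hoover thermostat chain.
#' Langevin and the chain sample the canonical ensemble at T; NVE conserves
#' energy. The step size is checked against the fastest normal-mode period:
#' a warning above period/10 and an error above period/pi (the Verlet
#' stability bound).
#'
#' @param model a `force_model`
#' @param spec an `integrator_spec`
#' @param x0 optional n x 3 initial positions (default: model equilibrium)
#' @param v0 optional n x 3 initial velocities (default: Maxwell-Boltzmann at
#'   T for thermostated schemes, zero for NVE)
#' @param noise optional pre-generated standard-normal matrix
#'   (n_steps x 3*n_mobile) for the Langevin kicks, overriding the seeded
#'   generator (used e.g. to drive mirrored twins with mirrored noise)
#' @return an `md_trajectory` with positions and velocities
#' @export
integrate_dynamics <- function(model, spec, x0 = NULL, v0 = NULL,
                               noise = NULL) {
  mob <- which(!model$fixed)
  nmob <- length(mob)
  nd <- 3 * nmob
  mdof <- rep(model$masses[mob], 3)
  nm <- normal_modes(model)
  numax <- max(nm$wavenumbers)
  if (numax > 0) {
    pmin_ <- 1 / (numax * vib_constants$c_cm_fs)
    if (spec$dt > pmin_ / pi)
      stop(sprintf("dt = %g fs exceeds the stability bound %g fs", spec$dt,
                   pmin_ / pi))
    if (spec$dt > pmin_ / 10)
      warning(sprintf("dt = %g fs above a tenth of the fastest period %g fs",
                      spec$dt, pmin_))
  }
  kT <- vib_constants$kB * spec$T
  set.seed(spec$seed)
  xfull <- if (is.null(x0)) model$positions else as.matrix(x0)
  u <- as.vector(xfull[mob, , drop = FALSE])
  x0v <- as.vector(model$positions[mob, , drop = FALSE])
  v <- if (!is.null(v0)) as.vector(as.matrix(v0)[mob, , drop = FALSE])
       else if (spec$scheme == "nve_velocity_verlet") numeric(nd)
       else stats::rnorm(nd, 0, sqrt(kT / mdof))
  H <- model$hessian
  forcefun <- if (!is.null(H)) {
    function(uvec) -as.vector(H %*% (uvec - x0v))
  } else {
    function(uvec) {
      xf <- xfull
      xf[mob, ] <- matrix(uvec, nmob, 3)
      as.vector(.force_generic(model, xf)[mob, , drop = FALSE])
    }
  }
  nsamp <- spec$n_steps %/% spec$sample_every
  pos <- array(NA_real_, c(nsamp, nrow(model$positions), 3))
  vel <- array(NA_real_, c(nsamp, nrow(model$positions), 3))
  fixpos <- model$positions
  f <- forcefun(u)
  dt <- spec$dt
  si <- 0L
  if (spec$scheme == "langevin") {
    c1 <- exp(-spec$friction * dt)
    c2 <- sqrt((1 - c1^2) * kT / mdof)
    for (s in seq_len(spec$n_steps)) {
      v <- v + 0.5 * dt * f / mdof
      u <- u + 0.5 * dt * v
      xi <- if (is.null(noise)) stats::rnorm(nd) else noise[s, ]
      v <- c1 * v + c2 * xi
      u <- u + 0.5 * dt * v
      f <- forcefun(u)
      v <- v + 0.5 * dt * f / mdof
      if (s %% spec$sample_every == 0L) {
        si <- si + 1L
        fixpos[mob, ] <- matrix(u, nmob, 3)
        pos[si, , ] <- fixpos
        vel[si, mob, ] <- matrix(v, nmob, 3)
      }
    }
  } else if (spec$scheme == "nve_velocity_verlet") {
    for (s in seq_len(spec$n_steps)) {
      v <- v + 0.5 * dt * f / mdof
      u <- u + dt * v
      f <- forcefun(u)
      v <- v + 0.5 * dt * f / mdof
      if (s %% spec$sample_every == 0L) {
        si <- si + 1L
        fixpos[mob, ] <- matrix(u, nmob, 3)
        pos[si, , ] <- fixpos
        vel[si, mob, ] <- matrix(v, nmob, 3)
      }
    }
  } else {                                     # nose_hoover_chain
    M <- spec$chain_length
    Q <- rep(kT * spec$tau^2, M)
    Q[1] <- nd * kT * spec$tau^2
    eta_v <- numeric(M)
    nhc_half <- function(v) {
      K2 <- sum(mdof * v^2)
      G <- numeric(M)
      G[M] <- (Q[M - 1] * eta_v[M - 1]^2 - kT) / Q[M]
      h <- dt / 2
      for (m in M:1) {
        G[m] <- if (m == 1) (K2 - nd * kT) / Q[1]
                else (Q[m - 1] * eta_v[m - 1]^2 - kT) / Q[m]
        if (m < M) eta_v[m] <- eta_v[m] * exp(-h / 4 * eta_v[m + 1])
        eta_v[m] <- eta_v[m] + G[m] * h / 2
        if (m < M) eta_v[m] <- eta_v[m] * exp(-h / 4 * eta_v[m + 1])
      }
      sc <- exp(-h * eta_v[1])
      v <- v * sc
      K2 <- K2 * sc^2
      for (m in 1:M) {
        G[m] <- if (m == 1) (K2 - nd * kT) / Q[1]
                else (Q[m - 1] * eta_v[m - 1]^2 - kT) / Q[m]
        if (m < M) eta_v[m] <- eta_v[m] * exp(-h / 4 * eta_v[m + 1])
        eta_v[m] <- eta_v[m] + G[m] * h / 2
        if (m < M) eta_v[m] <- eta_v[m] * exp(-h / 4 * eta_v[m + 1])
      }
      eta_v <<- eta_v
      v
    }
    for (s in seq_len(spec$n_steps)) {
      v <- nhc_half(v)
      v <- v + 0.5 * dt * f / mdof
      u <- u + dt * v
      f <- forcefun(u)
      v <- v + 0.5 * dt * f / mdof
      v <- nhc_half(v)
      if (s %% spec$sample_every == 0L) {
        si <- si + 1L
        fixpos[mob, ] <- matrix(u, nmob, 3)
        pos[si, , ] <- fixpos
        vel[si, mob, ] <- matrix(v, nmob, 3)
      }
    }
  }
  vel[is.na(vel)] <- 0                        # fixed atoms: zero velocity
  md_trajectory(model$species, pos, velocities = vel, cell = model$cell,
                timestep = dt * spec$sample_every, time_origin = 0,
                masses = model$masses)
}
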