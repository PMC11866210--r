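# Morse-bond anharmonicity reference: the classical vibration frequency at a
# given energy, from direct numerical integration of the orbit period. The
# vibrational frequency of a Morse oscillator falls with energy, so a
# thermalized Morse bond peaks below its harmonic frequency - the toy
# stand-in for anharmonic softening of real bonds.

#' Classical Morse-bond frequency at thermal energy
#'
#' Numerically integrates the single-period orbit time of a particle of mass
#' `mass` in V(d) = depth * (1 - exp(-range * d))^2 at energy k_B T, and
#' returns the corresponding vibration wavenumber. This is the deterministic
#' prediction against which the spectral peak of a thermalized Morse
#' trajectory can be compared. The infinite-depth limit recovers the
#' harmonic wavenumber range * sqrt(2 * depth / mass) / (2 pi c).
#'
#' @param depth Morse dissociation energy D, amu A^2/fs^2
#' @param range Morse range parameter a, 1/A
#' @param mass oscillating (reduced) mass, amu
#' @param T temperature, K; the orbit is evaluated at energy k_B T
#' @param n_quad quadrature points for the period integral
#' @return list: `wavenumber` (cm^-1 at energy k_B T),
#'   `harmonic_wavenumber` (cm^-1), `energy` (amu A^2/fs^2)
#' @export
morse_bond_reference <- function(depth, range, mass, T, n_quad = 2000) {
  if (depth <= 0 || range <= 0 || mass <= 0) stop("invalid Morse parameters")
  E <- vib_constants$kB * T
  if (E >= depth) stop("thermal energy at or above dissociation: unbound")
  s <- sqrt(E / depth)
  d_in <- -log(1 + s) / range
  d_out <- -log(1 - s) / range
  mid <- (d_in + d_out) / 2
  amp <- (d_out - d_in) / 2
  # midpoint rule in the angle variable; endpoint singularities cancel
  th <- (seq_len(n_quad) - 0.5) / n_quad * pi - pi / 2
  d <- mid + amp * sin(th)
  V <- depth * (1 - exp(-range * d))^2
  integrand <- amp * cos(th) / sqrt(2 * pmax(E - V, .Machine$double.xmin) /
                                    mass)
  period <- 2 * sum(integrand) * pi / n_quad
  nu0 <- omega_to_wavenumber(range * sqrt(2 * depth / mass))
  list(wavenumber = (1 / period) / vib_constants$c_cm_fs,
       harmonic_wavenumber = nu0, energy = E)
}

#' One-dimensional Morse oscillator model
#'
#' A mobile particle bound by a Morse bond to a fixed anchor along x, with
#' stiff transverse tethers pinning y and z so the dynamics are effectively
#' one-dimensional (the Morse bond itself has no transverse restoring force
#' at equilibrium).
#'
#' @param depth Morse dissociation energy, amu A^2/fs^2
#' @param range Morse range parameter, 1/A
#' @param mass mobile particle mass, amu
#' @param r0 equilibrium bond length, Angstrom
#' @param transverse_wavenumber frequency of the pinned transverse motion,
#'   cm^-1 (kept high and out of band)
#' @return a `force_model` (anchor particle fixed)
#' @export
morse_oscillator_model <- function(depth, range, mass, r0 = 1.0,
                                   transverse_wavenumber = 4500) {
  kt <- mass * wavenumber_to_omega(transverse_wavenumber)^2
  force_model(species = c("Cu", "H"),
              positions = rbind(c(0, 0, 0), c(r0, 0, 0)),
              interactions = list(
                list(type = "morse_bond", i = 1L, j = 2L, D = depth,
                     a = range, r0 = r0),
                list(type = "site_tether", atom = 2L, k = c(0, kt, kt),
                     site = c(r0, 0, 0))),
              fixed = c(TRUE, FALSE),
              masses = c(element_masses("Cu"), mass))
}
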