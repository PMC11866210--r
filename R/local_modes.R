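# Internal-coordinate (local-mode) machinery.
#
# Primitive internals: stretch, bend, torsion, out-of-plane. Values are
# computed vectorized over frames; s-vectors (Cartesian gradients of the
# primitive) are obtained by central finite differences of the vectorized
# value functions, recomputed from the instantaneous geometry of every frame
# (a fixed reference geometry would be invalidated by the large-amplitude
# motion these trajectories are meant to capture).

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.rownorm <- function(a) sqrt(rowSums(a^2))

# coords: list of F x 3 matrices, one per atom of the primitive
.prim_value <- function(type, coords) {
  switch(type,
    stretch = .rownorm(coords[[2]] - coords[[1]]),
    bend = {
      u <- coords[[1]] - coords[[2]]
      v <- coords[[3]] - coords[[2]]
      atan2(.rownorm(.rowcross(u, v)), rowSums(u * v))
    },
    torsion = {
      b1 <- coords[[2]] - coords[[1]]
      b2 <- coords[[3]] - coords[[2]]
      b3 <- coords[[4]] - coords[[3]]
      n1 <- .rowcross(b1, b2)
      n2 <- .rowcross(b2, b3)
      atan2(rowSums(.rowcross(n1, n2) * b2) / .rownorm(b2), rowSums(n1 * n2))
    },
    oop = {
      # out-of-plane angle of bond center->apex w.r.t. plane(center->s1,
      # center->s2); atoms ordered (apex, center, s1, s2)
      ea <- coords[[1]] - coords[[2]]
      e1 <- coords[[3]] - coords[[2]]
      e2 <- coords[[4]] - coords[[2]]
      nrm <- .rowcross(e1, e2)
      s <- rowSums(nrm * ea) / (.rownorm(nrm) * .rownorm(ea))
      asin(pmin(pmax(s, -1), 1))
    },
    stop("unknown primitive type: ", type))
}

.wrap_angle <- function(x) {
  x - 2 * pi * round(x / (2 * pi))
}

# numerical s-vectors: returns list of F x 3 gradient matrices, one per atom
.prim_svectors <- function(type, coords, h = 1e-5) {
  angular <- type %in% c("bend", "torsion", "oop")
  lapply(seq_along(coords), function(a) {
    g <- matrix(0, nrow(coords[[1]]), 3)
    for (comp in 1:3) {
      cp <- coords; cm <- coords
      cp[[a]][, comp] <- cp[[a]][, comp] + h
      cm[[a]][, comp] <- cm[[a]][, comp] - h
      d <- .prim_value(type, cp) - .prim_value(type, cm)
      if (angular) d <- .wrap_angle(d)
      g[, comp] <- d / (2 * h)
    }
    g
  })
}

# frames where a primitive's geometry is degenerate (collinear bend/torsion)
.prim_degenerate <- function(type, coords, tol = 1e-3) {
  if (type == "bend") {
    ang <- .prim_value("bend", coords)
    ang < tol | ang > pi - tol
  } else if (type == "torsion") {
    a1 <- .prim_value("bend", coords[1:3])
    a2 <- .prim_value("bend", coords[2:4])
    a1 < tol | a1 > pi - tol | a2 < tol | a2 > pi - tol
  } else if (type == "oop") {
    a1 <- .prim_value("bend", coords[c(3, 2, 4)])
    a1 < tol | a1 > pi - tol
  } else rep(FALSE, nrow(coords[[1]]))
}

# ---- glycinate topology -----------------------------------------------------

.glycinate_roles <- c("N", "HN1", "HN2", "CA", "HC1", "HC2", "C", "O1", "O2")
.glycinate_elements <- c(N = "N", HN1 = "H", HN2 = "H", CA = "C", HC1 = "H",
                         HC2 = "H", C = "C", O1 = "O", O2 = "O")

#' Glycinate molecular topology
#'
#' Atom roles and bonds of the 9-atom glycinate anion (NH2-CH2-CO2):
#' amino nitrogen N with HN1/HN2, alpha carbon CA with HC1/HC2, carboxylate
#' carbon C with O1/O2. `indices` maps each role to an atom index within the
#' molecule selection (default: the canonical order N, HN1, HN2, CA, HC1,
#' HC2, C, O1, O2).
#'
#' @param indices named integer vector role -> atom index (local to the
#'   molecule); default canonical ordering 1..9
#' @return a `glycinate_topology` with `roles`, `elements`, `bonds`
#' @export
glycinate_topology <- function(indices = NULL) {
  if (is.null(indices)) {
    indices <- seq_along(.glycinate_roles)
    names(indices) <- .glycinate_roles
  }
  if (!setequal(names(indices), .glycinate_roles) ||
      anyDuplicated(indices))
    stop("topology must assign each glycinate role exactly one atom index")
  indices <- indices[.glycinate_roles]
  bonds <- rbind(c("N", "HN1"), c("N", "HN2"), c("N", "CA"),
                 c("CA", "HC1"), c("CA", "HC2"), c("CA", "C"),
                 c("C", "O1"), c("C", "O2"))
  structure(list(roles = indices, elements = .glycinate_elements,
                 bonds = bonds),
            class = "glycinate_topology")
}

#' Build the 21 glycinate local-mode definitions
#'
#' Generalized local-mode coordinates in the Shimanouchi tradition:
#' symmetric/antisymmetric XH2 (and CO2) stretches as (dr1 +/- dr2)/sqrt(2);
#' CN and CC stretches; scissors as the H-X-H (O-C-O, N-CA-C) angle; the
#' methylene wag/rock/twist as the standard +/- combinations of the four
#' flanking H-CA-(N|C) bends; terminal NH2/CO2 rock as the in-plane
#' skeletal-bend difference and wag as the out-of-plane coordinate of the
#' skeletal bond against the group plane; torsions as the mean of all six
#' dihedrals about the named bond. Every coefficient vector is normalized to
#' unit Euclidean norm. Exactly 21 definitions (= 3N - 6 for N = 9).
#'
#' Sign conventions for the +/- tables: wag = (t1N + t2N - t1C - t2C)/2,
#' rock = (t1N - t2N + t1C - t2C)/2, twist = (t1N - t2N - t1C + t2C)/2 with
#' tiX the bend HCi-CA-X; terminal rocks take (bend1 - bend2)/sqrt(2) with
#' the first-listed hydrogen/oxygen positive.
#'
#' @param topology a `glycinate_topology`
#' @return list of 21 `local_mode_definition`s (name, primitives)
#' @export
build_local_mode_basis <- function(topology) {
  if (!inherits(topology, "glycinate_topology")) stop("invalid topology")
  r <- topology$roles
  prim <- function(type, roles, coeff)
    list(type = type, atoms = unname(r[roles]), coeff = coeff)
  def <- function(name, ...) {
    prims <- list(...)
    nrm <- sqrt(sum(vapply(prims, `[[`, 0, "coeff")^2))
    prims <- lapply(prims, function(p) { p$coeff <- p$coeff / nrm; p })
    structure(list(name = name, primitives = prims),
              class = "local_mode_definition")
  }
  s2 <- 1 / sqrt(2)
  tors <- function(name, about, starts, ends) {
    combos <- expand.grid(a = starts, b = ends, stringsAsFactors = FALSE)
    do.call(def, c(list(name), lapply(seq_len(nrow(combos)), function(k)
      prim("torsion", c(combos$a[k], about[1], about[2], combos$b[k]), 1))))
  }
  list(
    def("nu_s(NH2)", prim("stretch", c("N", "HN1"), s2),
        prim("stretch", c("N", "HN2"), s2)),
    def("nu_a(NH2)", prim("stretch", c("N", "HN1"), s2),
        prim("stretch", c("N", "HN2"), -s2)),
    def("nu_s(CH2)", prim("stretch", c("CA", "HC1"), s2),
        prim("stretch", c("CA", "HC2"), s2)),
    def("nu_a(CH2)", prim("stretch", c("CA", "HC1"), s2),
        prim("stretch", c("CA", "HC2"), -s2)),
    def("nu_s(CO2)", prim("stretch", c("C", "O1"), s2),
        prim("stretch", c("C", "O2"), s2)),
    def("nu_a(CO2)", prim("stretch", c("C", "O1"), s2),
        prim("stretch", c("C", "O2"), -s2)),
    def("nu(CN)", prim("stretch", c("N", "CA"), 1)),
    def("nu(CC)", prim("stretch", c("CA", "C"), 1)),
    def("delta(NH2)", prim("bend", c("HN1", "N", "HN2"), 1)),
    def("delta(CH2)", prim("bend", c("HC1", "CA", "HC2"), 1)),
    def("delta(CO2)", prim("bend", c("O1", "C", "O2"), 1)),
    def("delta(NCC)", prim("bend", c("N", "CA", "C"), 1)),
    def("omega(CH2)",
        prim("bend", c("HC1", "CA", "N"), 0.5),
        prim("bend", c("HC2", "CA", "N"), 0.5),
        prim("bend", c("HC1", "CA", "C"), -0.5),
        prim("bend", c("HC2", "CA", "C"), -0.5)),
    def("rho(CH2)",
        prim("bend", c("HC1", "CA", "N"), 0.5),
        prim("bend", c("HC2", "CA", "N"), -0.5),
        prim("bend", c("HC1", "CA", "C"), 0.5),
        prim("bend", c("HC2", "CA", "C"), -0.5)),
    def("t(CH2)",
        prim("bend", c("HC1", "CA", "N"), 0.5),
        prim("bend", c("HC2", "CA", "N"), -0.5),
        prim("bend", c("HC1", "CA", "C"), -0.5),
        prim("bend", c("HC2", "CA", "C"), 0.5)),
    def("rho(NH2)", prim("bend", c("HN1", "N", "CA"), s2),
        prim("bend", c("HN2", "N", "CA"), -s2)),
    def("omega(NH2)", prim("oop", c("CA", "N", "HN1", "HN2"), 1)),
    def("rho(CO2)", prim("bend", c("O1", "C", "CA"), s2),
        prim("bend", c("O2", "C", "CA"), -s2)),
    def("omega(CO2)", prim("oop", c("CA", "C", "O1", "O2"), 1)),
    tors("tau(CN)", c("N", "CA"), c("HN1", "HN2"),
         c("HC1", "HC2", "C")),
    tors("tau(CC)", c("CA", "C"), c("N", "HC1", "HC2"),
         c("O1", "O2"))
  )
}

#' Local-mode names of the glycinate basis
#' @return character vector of the 21 mode labels
#' @export
local_mode_names <- function()
  vapply(build_local_mode_basis(glycinate_topology()), `[[`, "", "name")

#' Project Cartesian velocities onto local-mode coordinates
#'
#' q_dot_k(t) = sum over primitive internals of coefficient times
#' s-vector(current geometry) . velocity, with s-vectors recomputed every
#' frame. Frames where a bend or torsion passes within 1e-3 rad of collinear
#' are flagged and their values linearly interpolated from neighbours; more
#' than 1% flagged frames for a mode is an error.
#'
#' @param traj an `md_trajectory` with velocities
#' @param basis list of local-mode definitions ([build_local_mode_basis()])
#' @param molecule_selection `atom_selection` of the molecule's atoms, in the
#'   order the topology indices refer to
#' @return a `mode_velocity_series`: `series` (frames x modes matrix),
#'   `timestep`, `mode_names`
#' @export
project_velocities <- function(traj, basis, molecule_selection = NULL) {
  if (is.null(traj$velocities))
    stop("trajectory has no velocities; run derive_velocities() first")
  idx <- .resolve_selection(molecule_selection, n_atoms(traj))
  nf <- n_frames(traj)
  getcoords <- function(atoms)
    lapply(atoms, function(a) traj$positions[, idx[a], , drop = TRUE])
  getvel <- function(a) traj$velocities[, idx[a], , drop = TRUE]
  out <- matrix(0, nf, length(basis))
  colnames(out) <- vapply(basis, `[[`, "", "name")
  for (k in seq_along(basis)) {
    qdot <- numeric(nf)
    bad <- logical(nf)
    for (p in basis[[k]]$primitives) {
      coords <- getcoords(p$atoms)
      bad <- bad | .prim_degenerate(p$type, coords)
      sv <- .prim_svectors(p$type, coords)
      for (a in seq_along(p$atoms))
        qdot <- qdot + p$coeff * rowSums(sv[[a]] * getvel(p$atoms[a]))
    }
    if (any(bad)) {
      if (mean(bad) > 0.01)
        stop(sprintf("mode %s: %.1f%% of frames have degenerate geometry",
                     basis[[k]]$name, 100 * mean(bad)))
      ok <- which(!bad)
      qdot[bad] <- stats::approx(ok, qdot[ok], xout = which(bad),
                                 rule = 2)$y
    }
    out[, k] <- qdot
  }
  structure(list(series = out, timestep = traj$timestep,
                 mode_names = colnames(out)),
            class = "mode_velocity_series")
}

#' Unit-area power spectra of local-mode velocities
#'
#' PSD of each local-mode velocity series, each normalized to unit area so
#' that per-mode spectra are directly comparable. When a list of series is
#' given (one per molecule), per-mode spectra are averaged over molecules
#' before normalization.
#'
#' @param series a `mode_velocity_series` or list of them
#' @param window "hann" (default) or "none"
#' @return named list of `vib_spectrum` objects (normalization "unit_area")
#' @export
local_mode_spectra <- function(series, window = c("hann", "none")) {
  window <- match.arg(window)
  if (inherits(series, "mode_velocity_series")) series <- list(series)
  nf <- nrow(series[[1]]$series)
  if (nf < 2L) stop("need at least 2 frames")
  modes <- series[[1]]$mode_names
  out <- vector("list", length(modes))
  names(out) <- modes
  for (k in seq_along(modes)) {
    acc <- NULL
    for (s in series) {
      res <- .psd_core(s$series[, k, drop = FALSE], 1, s$timestep, window)
      acc <- if (is.null(acc)) res$intensity else acc + res$intensity
    }
    spec <- vib_spectrum(res$wavenumbers, acc / length(series), "raw",
                         resolution = res$resolution, window = window)
    if (spectrum_integral(spec) <= 0)
      stop("mode ", modes[k], ": all-zero series, normalization undefined")
    out[[k]] <- normalize_unit_area(spec)
  }
  out
}
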