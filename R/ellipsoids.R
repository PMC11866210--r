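#' Atomic displacement matrices from a trajectory
#'
#' For each selected atom, U = <u u^T> where u is the instantaneous Cartesian
#' displacement from the atom's mean position, averaged over all frames.
#' Symmetric positive semidefinite by construction; trace(U) equals the
#' time-averaged squared displacement.
#'
#' @param traj an unwrapped `md_trajectory`
#' @param mean a `mean_structure` computed from the same frames (its atom
#'   `indices` select the atoms)
#' @return a `displacement_matrices` object: `U` (atoms x 3 x 3, Angstrom^2),
#'   `indices`, `species`
#' @export
displacement_matrices <- function(traj, mean) {
  idx <- mean$indices
  if (max(idx) > n_atoms(traj) ||
      any(traj$species[idx] != mean$species))
    stop("mean structure does not match trajectory atoms")
  nf <- n_frames(traj)
  if (nf != mean$n_frames_averaged)
    stop("mean structure was averaged over a different number of frames")
  U <- array(NA_real_, c(length(idx), 3, 3))
  for (a in seq_along(idx)) {
    cc <- traj$positions[, idx[a], ] -
      matrix(mean$mean_positions[a, ], nf, 3, byrow = TRUE)
    U[a, , ] <- crossprod(cc) / nf
  }
  structure(list(U = U, indices = idx, species = mean$species),
            class = "displacement_matrices")
}

#' Impose glide symmetry on displacement matrices
#'
#' U~_i = (U_i + R U_sigma(i) R^T) / 2, after which the set is exactly
#' invariant under the operation (so glide partners have mirror-image
#' ellipsoids). Idempotent.
#'
#' @param U_set a `displacement_matrices` object
#' @param glide a `glide_operation` whose permutation refers to the same atoms
#' @return symmetrized `displacement_matrices`
#' @export
symmetrize_displacement_matrices <- function(U_set, glide) {
  n <- dim(U_set$U)[1]
  if (length(glide$permutation) != n)
    stop("glide permutation length does not match displacement set")
  R <- glide$rotation
  out <- U_set$U
  for (i in seq_len(n)) {
    j <- glide$permutation[i]
    out[i, , ] <- 0.5 * (U_set$U[i, , ] + R %*% U_set$U[j, , ] %*% t(R))
  }
  U_set$U <- out
  U_set
}

#' Thermal ellipsoid from a displacement matrix
#'
#' Eigen-decomposition of U; the ellipsoid semiaxes lie along the
#' eigenvectors with lengths scale * sqrt(eigenvalue), ordered descending.
#' The default scale 1.5382 is the 50% probability surface of a trivariate
#' Gaussian (the scaling in the spirit of Kronenburg's recommendation of a
#' surface enclosing slightly more than half the total probability;
#' configurable). Axis signs are fixed by making each axis's
#' largest-magnitude component positive, for deterministic output.
#'
#' @param U a symmetric PSD 3x3 matrix (Angstrom^2), or one atom's slice of a
#'   `displacement_matrices` object
#' @param scale dimensionless probability scaling factor
#' @return a `thermal_ellipsoid`: `semiaxes` (Angstrom, descending), `axes`
#'   (3x3, columns are unit axis directions), `eigenvalues` (Angstrom^2),
#'   `scale`
#' @export
ellipsoid <- function(U, scale = 1.5382) {
  U <- as.matrix(U)
  if (max(abs(U - t(U))) > 1e-10) stop("U must be symmetric")
  U <- (U + t(U)) / 2
  e <- eigen(U, symmetric = TRUE)
  if (min(e$values) < -1e-9)
    stop("U has a significantly negative eigenvalue: ", min(e$values))
  vals <- pmax(e$values, 0)            # eigen() returns decreasing order
  vecs <- e$vectors
  for (k in 1:3) {
    comp <- which.max(abs(vecs[, k]))
    if (vecs[comp, k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(semiaxes = scale * sqrt(vals), axes = vecs,
                 eigenvalues = vals, scale = scale),
            class = "thermal_ellipsoid")
}

#' Classify the shape of a thermal ellipsoid
#'
#' With semiaxes a >= b >= c and fractional tolerance `tol`: spherical if all
#' three agree within tol; prolate if b and c agree but a exceeds them by
#' more than tol (cigar); oblate if a and b agree but exceed c (disc);
#' triaxial otherwise. Agreement between x >= y means (x - y)/x <= tol.
#'
#' @param e a `thermal_ellipsoid`
#' @param tol fractional tolerance (default 0.05)
#' @return a `shape_descriptor`: `anisotropy_ratio` (a/c), `shape_class`,
#'   `tol`
#' @export
shape_descriptor <- function(e, tol = 0.05) {
  s <- sort(e$semiaxes, decreasing = TRUE)
  if (any(s <= 0)) stop("semiaxes must be positive")
  a <- s[1]; b <- s[2]; c <- s[3]
  agree <- function(x, y) (x - y) / x <= tol
  cls <- if (agree(a, c)) "spherical"
         else if (agree(b, c) && !agree(a, b)) "prolate"
         else if (agree(a, b) && !agree(b, c)) "oblate"
         else "triaxial"
  structure(list(anisotropy_ratio = a / c, shape_class = cls, tol = tol),
            class = "shape_descriptor")
}

#' Per-atom ellipsoid report
#'
#' Convenience wrapper producing a data.frame of eigenvalues, semiaxes and
#' shape classes for a whole displacement set (the JSON/CSV-friendly form of
#' the ellipsoid analysis).
#'
#' @param U_set a `displacement_matrices` object
#' @param scale probability scaling factor passed to [ellipsoid()]
#' @param tol shape tolerance passed to [shape_descriptor()]
#' @return data.frame, one row per atom
#' @export
ellipsoid_report <- function(U_set, scale = 1.5382, tol = 0.05) {
  n <- dim(U_set$U)[1]
  rows <- lapply(seq_len(n), function(i) {
    el <- ellipsoid(U_set$U[i, , ], scale = scale)
    sh <- if (max(el$semiaxes) < 1e-12)       # immobile atom: no ellipsoid
      list(anisotropy_ratio = NA_real_, shape_class = "static")
    else shape_descriptor(el, tol = tol)
    data.frame(atom = U_set$indices[i], species = U_set$species[i],
               eig1 = el$eigenvalues[1], eig2 = el$eigenvalues[2],
               eig3 = el$eigenvalues[3],
               semiaxis1 = el$semiaxes[1], semiaxis2 = el$semiaxes[2],
               semiaxis3 = el$semiaxes[3],
               anisotropy = sh$anisotropy_ratio, shape = sh$shape_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
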