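#' Time-averaged mean structure
#'
#' Per-atom arithmetic mean of Cartesian positions over all frames of a
#' (post-equilibration, unwrapped) trajectory. Time-averaged positions are
#' what diffraction probes such as LEED compare against, so this is the
#' reference structure for all symmetry and displacement statistics.
#'
#' @param traj an `md_trajectory`
#' @param selection optional `atom_selection` (or integer indices) restricting
#'   the atoms retained
#' @return a `mean_structure`: species, `mean_positions` (atoms x 3 Angstrom),
#'   `n_frames_averaged`, `cell`, and the original atom `indices`
#' @export
mean_structure <- function(traj, selection = NULL) {
  nf <- n_frames(traj)
  if (nf < 1L) stop("empty trajectory")
  idx <- .resolve_selection(selection, n_atoms(traj))
  pos <- traj$positions[, idx, , drop = FALSE]
  mp <- apply(pos, c(2, 3), mean)
  if (!all(is.finite(mp))) stop("non-finite mean positions")
  structure(list(species = traj$species[idx], mean_positions = mp,
                 n_frames_averaged = nf, cell = traj$cell, indices = idx),
            class = "mean_structure")
}

#' @export
print.mean_structure <- function(x, ...) {
  cat(sprintf("mean_structure: %d atoms averaged over %d frames\n",
              nrow(x$mean_positions), x$n_frames_averaged))
  invisible(x)
}

# ---- glide operations -------------------------------------------------------

#' Construct a glide (mirror + translation) symmetry operation
#'
#' @param rotation orthogonal 3x3 matrix (the mirror part)
#' @param translation 3-vector, Angstrom (mirror-plane offset plus glide
#'   component folded together)
#' @param permutation integer vector sigma mapping atom i to its image atom
#'   sigma[i]; must be an involution
#' @param species optional species vector to check sigma preserves species
#' @return a `glide_operation`
#' @export
glide_operation <- function(rotation, translation, permutation,
                            species = NULL) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("rotation part must be orthogonal")
  permutation <- as.integer(permutation)
  if (!identical(sort(permutation), seq_along(permutation)) ||
      any(permutation[permutation] != seq_along(permutation)))
    stop("permutation must be an involutive bijection")
  if (!is.null(species) && any(species[permutation] != species))
    stop("permutation does not preserve species")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 permutation = permutation),
            class = "glide_operation")
}

#' Apply a glide operation to Cartesian coordinates
#' @param op a `glide_operation`
#' @param x n x 3 matrix of positions (rows)
#' @param inverse apply the inverse map?
#' @return transformed n x 3 matrix
#' @export
apply_glide <- function(op, x, inverse = FALSE) {
  x <- matrix(x, ncol = 3)
  if (!inverse)
    x %*% t(op$rotation) + matrix(op$translation, nrow(x), 3, byrow = TRUE)
  else
    (x - matrix(op$translation, nrow(x), 3, byrow = TRUE)) %*% op$rotation
}

.wrap_min_image <- function(d, cell) {
  if (is.null(cell)) return(d)
  f <- d %*% solve(cell)
  (f - round(f)) %*% cell
}

#' Find the atom pairing under a candidate glide operation
#'
#' Given a mean structure and a candidate mirror/glide specification, finds
#' the permutation sigma assigning each atom the nearest same-species atom
#' under the operation (greedy, pairing enforced as an involution, ties by
#' smallest index, minimum-image when a cell is present), then refines the
#' translation component by least squares (the mean residual, which refines
#' mirror-plane offset and glide translation together).
#'
#' @param structure a `mean_structure`
#' @param mirror_axis normal axis of the mirror plane: "x", "y" or "z"
#' @param plane_offset position of the mirror plane along that axis, Angstrom
#' @param glide_vector in-plane glide translation, 3-vector Angstrom
#' @param cutoff maximum allowed match distance, Angstrom (default 1.0)
#' @return a `glide_operation` with refined translation
#' @export
match_under_symmetry <- function(structure, mirror_axis = c("y", "x", "z"),
                                 plane_offset = 0, glide_vector = c(0, 0, 0),
                                 cutoff = 1.0) {
  mirror_axis <- match.arg(mirror_axis)
  ax <- match(mirror_axis, c("x", "y", "z"))
  R <- diag(3); R[ax, ax] <- -1
  t0 <- numeric(3); t0[ax] <- 2 * plane_offset
  t0 <- t0 + as.numeric(glide_vector)
  x <- structure$mean_positions
  n <- nrow(x)
  img <- x %*% t(R) + matrix(t0, n, 3, byrow = TRUE)
  sigma <- integer(n)
  assigned <- logical(n)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    cand <- which(!assigned & structure$species == structure$species[i])
    d <- .wrap_min_image(x[cand, , drop = FALSE] -
                         matrix(img[i, ], length(cand), 3, byrow = TRUE),
                         structure$cell)
    dist <- sqrt(rowSums(d^2))
    j <- cand[which.min(dist)]           # which.min takes the smallest index on ties
    sigma[i] <- j; sigma[j] <- i
    assigned[i] <- TRUE; assigned[j] <- TRUE
  }
  # least-squares refinement of the translation: mean minimum-image residual
  res <- .wrap_min_image(x[sigma, , drop = FALSE] - img, structure$cell)
  t_ref <- t0 + colMeans(res)
  img2 <- x %*% t(R) + matrix(t_ref, n, 3, byrow = TRUE)
  d2 <- .wrap_min_image(x[sigma, , drop = FALSE] - img2, structure$cell)
  dist2 <- sqrt(rowSums(d2^2))
  if (max(dist2) > cutoff)
    stop(sprintf(paste0("symmetry matching failure: atom %d (%s) has match ",
                        "distance %.3f Angstrom > cutoff %.3f"),
                 which.max(dist2), structure$species[which.max(dist2)],
                 max(dist2), cutoff))
  glide_operation(R, t_ref, sigma, species = structure$species)
}

.symmetrized_positions <- function(structure, glide) {
  x <- structure$mean_positions
  n <- nrow(x)
  out <- x
  done <- logical(n)
  for (i in seq_len(n)) {
    if (done[i]) next
    j <- glide$permutation[i]
    gi <- apply_glide(glide, x[i, , drop = FALSE])
    shift <- .wrap_min_image(x[j, , drop = FALSE] - gi, structure$cell) -
             (x[j, , drop = FALSE] - gi)
    xj_eff <- x[j, , drop = FALSE] + shift   # image of j nearest to g(x_i)
    xi_new <- 0.5 * (x[i, , drop = FALSE] + apply_glide(glide, xj_eff,
                                                        inverse = TRUE))
    out[i, ] <- xi_new
    if (j != i) out[j, ] <- apply_glide(glide, xi_new) - shift
    done[i] <- TRUE; done[j] <- TRUE
  }
  out
}

#' Impose exact glide symmetry on a mean structure
#'
#' Each atom is replaced by the average of itself and the back-transformed
#' position of its glide partner, yielding the nearest exactly symmetric
#' structure. Idempotent.
#'
#' @param structure a `mean_structure`
#' @param glide a `glide_operation` (from [match_under_symmetry()])
#' @return symmetrized `mean_structure`
#' @export
symmetrize_structure <- function(structure, glide) {
  structure$mean_positions <- .symmetrized_positions(structure, glide)
  structure
}

#' Root-mean-square deviation from perfect glide symmetry
#'
#' Deviation is measured against the symmetrized structure (the nearest
#' exactly symmetric structure), i.e. rms over atoms of |x_i - x~_i|,
#' reported separately per atom selection (e.g. adsorbate / first-layer /
#' second-layer groups).
#'
#' @param structure a `mean_structure`
#' @param glide a `glide_operation`
#' @param selections a single `atom_selection` or list of them (indices refer
#'   to rows of the structure); default: all atoms as one group
#' @return named numeric vector of rms deviations, Angstrom
#' @export
rms_symmetry_deviation <- function(structure, glide, selections = NULL) {
  n <- nrow(structure$mean_positions)
  if (is.null(selections)) selections <- list(atom_selection(seq_len(n), "all"))
  if (inherits(selections, "atom_selection")) selections <- list(selections)
  sym <- .symmetrized_positions(structure, glide)
  dev <- structure$mean_positions - sym
  out <- vapply(selections, function(sel) {
    idx <- .resolve_selection(sel, n)
    if (length(idx) == 0L) stop("empty selection")
    sqrt(mean(rowSums(dev[idx, , drop = FALSE]^2)))
  }, numeric(1))
  names(out) <- vapply(selections, function(sel)
    if (inherits(sel, "atom_selection") && nzchar(sel$label)) sel$label else "",
    character(1))
  out
}
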