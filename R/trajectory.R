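#' Construct an MD trajectory object
#'
#' The central container of the package: time-ordered frames of atomic
#' positions (optionally velocities) together with species, masses, an
#' optional fixed simulation cell, and the sampling timestep. All positions
#' are Cartesian Angstrom, velocities Angstrom/fs, times fs.
#'
#' @param species character vector of element symbols, one per atom
#' @param positions numeric array, frames x atoms x 3 (Angstrom)
#' @param velocities optional numeric array, frames x atoms x 3 (Angstrom/fs)
#' @param cell optional 3x3 matrix of lattice vectors (rows a, b, c; Angstrom);
#'   the cell is fixed over the trajectory
#' @param timestep sampling interval in fs (> 0)
#' @param time_origin time of the first frame in fs
#' @param masses per-atom masses in amu; looked up from `species` when missing
#' @return an object of class `md_trajectory`
#' @export
md_trajectory <- function(species, positions, velocities = NULL, cell = NULL,
                          timestep = 1, time_origin = 0, masses = NULL) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    stop("positions must be a frames x atoms x 3 array")
  n_at <- dim(positions)[2]
  if (length(species) != n_at)
    stop("length(species) does not match the atom dimension of positions")
  if (is.null(masses)) masses <- element_masses(species)
  if (length(masses) != n_at || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be positive and finite, one per atom")
  if (!is.null(velocities) && !identical(dim(velocities), dim(positions)))
    stop("velocities must have the same dimensions as positions")
  if (!is.null(cell)) {
    cell <- as.matrix(cell)
    if (!identical(dim(cell), c(3L, 3L)) || abs(det(cell)) < 1e-10)
      stop("cell must be a non-singular 3x3 matrix")
  }
  if (!is.numeric(timestep) || timestep <= 0) stop("timestep must be > 0")
  structure(list(species = as.character(species), masses = as.numeric(masses),
                 positions = positions, velocities = velocities, cell = cell,
                 timestep = timestep, time_origin = time_origin),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms, dt = %g fs%s%s\n",
              n_frames(x), n_atoms(x), x$timestep,
              if (!is.null(x$velocities)) ", with velocities" else "",
              if (!is.null(x$cell)) ", periodic cell" else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$positions)[1]

#' Number of atoms in a trajectory
#' @param traj an `md_trajectory`
#' @return integer atom count
#' @export
n_atoms <- function(traj) dim(traj$positions)[2]

#' Frame times of a trajectory
#' @param traj an `md_trajectory`
#' @return numeric vector of absolute frame times in fs
#' @export
frame_times <- function(traj)
  traj$time_origin + (seq_len(n_frames(traj)) - 1) * traj$timestep

#' Define an ordered atom selection
#'
#' @param indices integer atom indices (1-based, unique)
#' @param label free-text group label (e.g. "adsorbate", "top-layer Cu")
#' @return an `atom_selection` object
#' @export
atom_selection <- function(indices, label = "") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices) || any(indices < 1L))
    stop("selection indices must be unique positive integers")
  structure(list(indices = indices, label = label), class = "atom_selection")
}

.resolve_selection <- function(selection, n) {
  if (is.null(selection)) return(seq_len(n))
  idx <- if (inherits(selection, "atom_selection")) selection$indices
         else as.integer(selection)
  if (any(idx < 1L | idx > n)) stop("selection index out of range")
  idx
}

# ---- extended-XYZ I/O -------------------------------------------------------

.parse_extxyz_comment <- function(comment) {
  out <- list(lattice = NULL, has_vel = FALSE)
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (length(m) == 1 && nzchar(m)) {
    vals <- as.numeric(strsplit(trimws(sub('Lattice="([^"]*)"', "\\1", m)),
                                "[[:space:]]+")[[1]])
    if (length(vals) != 9) stop("malformed Lattice entry in extxyz comment")
    out$lattice <- matrix(vals, nrow = 3, byrow = TRUE)
  }
  p <- regmatches(comment, regexpr('Properties=[^[:space:]]*', comment))
  if (length(p) == 1 && nzchar(p))
    out$has_vel <- grepl("(vel|velo|velocities):R:3", p)
  out
}

#' Read an MD trajectory from an extended-XYZ file
#'
#' The extended-XYZ dialect expected here carries, on each frame's comment
#' line, optional `Lattice="ax ay az bx by bz cx cy cz"` and
#' `Properties=species:S:1:pos:R:3[:vel:R:3]` entries. Velocities are
#' populated only when present in the file; masses come from the bundled
#' standard-atomic-weights table. The cell is taken from the first frame and
#' must not vary.
#'
#' @param path path to the file
#' @param format currently only "extxyz"
#' @param timestep sampling interval in fs to attach (extxyz does not carry it)
#' @param time_origin time of the first frame in fs
#' @return an `md_trajectory`
#' @export
read_trajectory <- function(path, format = c("extxyz"), timestep = 1,
                            time_origin = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  species0 <- NULL
  cell <- NULL
  has_vel <- NA
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("extxyz format error: expected atom count at line ", i)
    if (i + 1L + nat > length(lines))
      stop("extxyz format error: truncated frame at line ", i)
    info <- .parse_extxyz_comment(lines[i + 1L])
    if (is.na(has_vel)) has_vel <- info$has_vel
    if (!is.null(info$lattice)) {
      if (is.null(cell)) cell <- info$lattice
      else if (max(abs(cell - info$lattice)) > 1e-8)
        stop("varying cell across frames is not supported")
    }
    toks <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "[[:space:]]+")
    ncol_exp <- if (has_vel) 7L else 4L
    if (any(lengths(toks) < ncol_exp))
      stop("extxyz format error: too few columns in frame starting line ", i)
    sp <- vapply(toks, `[[`, "", 1L)
    if (is.null(species0)) species0 <- sp
    else if (length(sp) != length(species0) || any(sp != species0))
      stop("inconsistent atom count or ordering across frames")
    num <- t(vapply(toks, function(tk) as.numeric(tk[2:ncol_exp]),
                    numeric(ncol_exp - 1L)))
    if (anyNA(num))
      stop("extxyz format error: non-numeric coordinate in frame at line ", i)
    frames[[length(frames) + 1L]] <- num
    i <- i + 2L + nat
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  nf <- length(frames); nat <- length(species0)
  pos <- array(NA_real_, c(nf, nat, 3))
  vel <- if (has_vel) array(NA_real_, c(nf, nat, 3)) else NULL
  for (f in seq_len(nf)) {
    pos[f, , ] <- frames[[f]][, 1:3]
    if (has_vel) vel[f, , ] <- frames[[f]][, 4:6]
  }
  md_trajectory(species0, pos, velocities = vel, cell = cell,
                timestep = timestep, time_origin = time_origin)
}

#' Write an MD trajectory to an extended-XYZ file
#'
#' @param traj an `md_trajectory`
#' @param path output path
#' @param digits significant digits for coordinates
#' @param header_comment optional extra text appended to every frame comment
#'   (e.g. a seed or config hash for provenance)
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, digits = 12, header_comment = NULL) {
  nf <- n_frames(traj); nat <- n_atoms(traj)
  has_vel <- !is.null(traj$velocities)
  props <- if (has_vel) "Properties=species:S:1:pos:R:3:vel:R:3"
           else "Properties=species:S:1:pos:R:3"
  lat <- if (!is.null(traj$cell))
    sprintf('Lattice="%s" ', paste(format(t(traj$cell), digits = digits,
                                          scientific = FALSE),
                                   collapse = " ")) else ""
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%.", digits, "g")
  for (f in seq_len(nf)) {
    comment <- paste0(lat, props,
                      if (!is.null(header_comment)) paste0(" ", header_comment)
                      else "")
    writeLines(c(as.character(nat), comment), con)
    mat <- traj$positions[f, , , drop = TRUE]
    if (nat == 1L) mat <- matrix(mat, 1, 3)
    cols <- apply(mat, 2, function(z) sprintf(fmt, z))
    if (nat == 1L) cols <- matrix(cols, 1, 3)
    if (has_vel) {
      vmat <- traj$velocities[f, , , drop = TRUE]
      if (nat == 1L) vmat <- matrix(vmat, 1, 3)
      vcols <- apply(vmat, 2, function(z) sprintf(fmt, z))
      if (nat == 1L) vcols <- matrix(vcols, 1, 3)
      cols <- cbind(cols, vcols)
    }
    writeLines(paste(traj$species, apply(cols, 1, paste, collapse = " ")), con)
  }
  invisible(path)
}

# ---- preparation ------------------------------------------------------------

#' Drop the equilibration segment of a trajectory
#'
#' Frames earlier than `t_equil` after the trajectory's time origin are
#' removed and the time origin is advanced to the first surviving frame, so
#' that subsequent averaging uses only equilibrated data.
#'
#' @param traj an `md_trajectory`
#' @param t_equil equilibration time to discard, fs (measured from the
#'   current time origin)
#' @return trimmed `md_trajectory`
#' @export
trim_equilibration <- function(traj, t_equil) {
  total <- n_frames(traj) * traj$timestep
  if (t_equil < 0 || t_equil >= total)
    stop("t_equil must lie in [0, total duration); trajectory would be empty")
  rel <- (seq_len(n_frames(traj)) - 1) * traj$timestep
  keep <- which(rel >= t_equil)
  if (length(keep) == 0L) stop("no frames remain after equilibration trim")
  traj$positions <- traj$positions[keep, , , drop = FALSE]
  if (!is.null(traj$velocities))
    traj$velocities <- traj$velocities[keep, , , drop = FALSE]
  traj$time_origin <- traj$time_origin + rel[keep[1L]]
  traj
}

#' Unwrap periodic-image jumps in a trajectory
#'
#' Makes per-atom displacements between consecutive frames minimum-image, so
#' that time-averaged positions and displacement statistics are meaningful
#' under periodic boundary conditions. The first frame is left unchanged.
#' Idempotent on already-whole trajectories.
#'
#' @param traj an `md_trajectory` with a cell
#' @return unwrapped `md_trajectory`
#' @export
unwrap <- function(traj) {
  if (is.null(traj$cell)) stop("unwrap requires a periodic cell")
  nf <- n_frames(traj); nat <- n_atoms(traj)
  if (nf < 2L) return(traj)
  inv <- solve(traj$cell)
  flat <- matrix(traj$positions, nf * nat, 3)
  frac <- array(flat %*% inv, c(nf, nat, 3))
  d <- frac[-1L, , , drop = FALSE] - frac[-nf, , , drop = FALSE]
  d <- d - round(d)
  cum <- apply(d, c(2, 3), cumsum)
  if (nf == 2L) cum <- array(cum, c(1L, nat, 3))
  out <- frac
  for (f in 2:nf) out[f, , ] <- frac[1L, , ] + cum[f - 1L, , ]
  traj$positions <- array(matrix(out, nf * nat, 3) %*% traj$cell,
                          c(nf, nat, 3))
  traj
}

#' Derive velocities from positions by central differences
#'
#' v(t) = [x(t + dt) - x(t - dt)] / (2 dt). The endpoint frames, where the
#' central difference is unavailable, are dropped (preserving spectral
#' symmetry rather than mixing one-sided estimates). Exact for positions
#' affine in time. Positions should be unwrapped first when periodic.
#'
#' @param traj an `md_trajectory` with at least 3 frames
#' @param overwrite replace velocities already present? If `FALSE` (default)
#'   and velocities exist, the trajectory is returned untouched.
#' @return `md_trajectory` with velocities, two frames shorter
#' @export
derive_velocities <- function(traj, overwrite = FALSE) {
  if (!is.null(traj$velocities) && !overwrite) return(traj)
  nf <- n_frames(traj)
  if (nf < 3L) stop("derive_velocities needs at least 3 frames")
  v <- (traj$positions[3:nf, , , drop = FALSE] -
        traj$positions[1:(nf - 2L), , , drop = FALSE]) / (2 * traj$timestep)
  traj$positions <- traj$positions[2:(nf - 1L), , , drop = FALSE]
  traj$velocities <- v
  traj$time_origin <- traj$time_origin + traj$timestep
  traj
}
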