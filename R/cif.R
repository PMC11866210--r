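# CIF export of anisotropic displacement parameters.
#
# Convention: with A the matrix whose columns are the cell vectors and
# N = diag(|a*|, |b*|, |c*|) the reciprocal-axis lengths, the CIF U^ij are
# defined by U_cart = A N U_cif N^T A^T (the standard crystallographic
# convention, so the exported values interoperate with refinement software).

.cell_cols <- function(cell) t(as.matrix(cell))   # columns = a, b, c

.recip_lengths <- function(A) {
  Ainv <- solve(A)                                # rows are a*, b*, c*
  sqrt(rowSums(Ainv^2))
}

.ucart_to_ucif <- function(U, A) {
  Ninv <- diag(1 / .recip_lengths(A))
  Ainv <- solve(A)
  Ninv %*% Ainv %*% U %*% t(Ainv) %*% Ninv
}

.ucif_to_ucart <- function(Ucif, A) {
  N <- diag(.recip_lengths(A))
  A %*% N %*% Ucif %*% t(N) %*% t(A)
}

#' Write mean structure and anisotropic displacement parameters to CIF
#'
#' Exports fractional coordinates (`_atom_site_*`) and anisotropic U values
#' (`_atom_site_aniso_U_*`, reciprocal-axis basis per the crystallographic
#' standard) derived from Cartesian displacement matrices and the cell.
#'
#' @param structure a `mean_structure` with a cell
#' @param U_set a `displacement_matrices` object for the same atoms
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_adp_cif <- function(structure, U_set, path) {
  if (is.null(structure$cell)) stop("CIF export requires a cell")
  A <- .cell_cols(structure$cell)
  if (abs(det(A)) < 1e-10) stop("singular cell")
  n <- nrow(structure$mean_positions)
  if (dim(U_set$U)[1] != n) stop("U set does not match structure atoms")
  av <- structure$cell
  len <- sqrt(rowSums(av^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  frac <- structure$mean_positions %*% solve(structure$cell)
  labels <- paste0(structure$species, seq_len(n))
  lines <- c("data_vibmd_adp",
             sprintf("_cell_length_a %.8f", len[1]),
             sprintf("_cell_length_b %.8f", len[2]),
             sprintf("_cell_length_c %.8f", len[3]),
             sprintf("_cell_angle_alpha %.8f", ang(av[2, ], av[3, ])),
             sprintf("_cell_angle_beta %.8f", ang(av[1, ], av[3, ])),
             sprintf("_cell_angle_gamma %.8f", ang(av[1, ], av[2, ])),
             "loop_",
             "_atom_site_label",
             "_atom_site_type_symbol",
             "_atom_site_fract_x",
             "_atom_site_fract_y",
             "_atom_site_fract_z",
             sprintf("%s %s %.10f %.10f %.10f", labels, structure$species,
                     frac[, 1], frac[, 2], frac[, 3]),
             "loop_",
             "_atom_site_aniso_label",
             "_atom_site_aniso_U_11",
             "_atom_site_aniso_U_22",
             "_atom_site_aniso_U_33",
             "_atom_site_aniso_U_12",
             "_atom_site_aniso_U_13",
             "_atom_site_aniso_U_23")
  arows <- vapply(seq_len(n), function(i) {
    Uc <- .ucart_to_ucif(U_set$U[i, , ], A)
    sprintf("%s %.10e %.10e %.10e %.10e %.10e %.10e", labels[i],
            Uc[1, 1], Uc[2, 2], Uc[3, 3], Uc[1, 2], Uc[1, 3], Uc[2, 3])
  }, character(1))
  writeLines(c(lines, arows), path)
  invisible(path)
}

#' Read back a CIF written by [write_adp_cif()]
#'
#' Minimal reader for round-trip validation: parses the cell, fractional
#' coordinates and aniso U values, and reconstructs Cartesian positions and
#' displacement matrices. CIF stores only cell lengths and angles, so the
#' Cartesian frame orientation is not recoverable from the file alone; pass
#' the original `cell` to reconstruct in the original frame, otherwise a
#' standard-orientation cell is built from lengths and angles.
#'
#' @param path CIF file path
#' @param cell optional original 3x3 cell (rows a, b, c)
#' @return list with `species`, `positions` (n x 3 Cartesian), `U`
#'   (n x 3 x 3 Cartesian, Angstrom^2), `cell`
#' @export
read_adp_cif <- function(path, cell = NULL) {
  lines <- readLines(path)
  getval <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]][2])
  }
  if (is.null(cell)) {
    a <- getval("_cell_length_a"); b <- getval("_cell_length_b")
    cc <- getval("_cell_length_c")
    al <- getval("_cell_angle_alpha") * pi / 180
    be <- getval("_cell_angle_beta") * pi / 180
    ga <- getval("_cell_angle_gamma") * pi / 180
    av <- c(a, 0, 0)
    bv <- c(b * cos(ga), b * sin(ga), 0)
    cx <- cc * cos(be)
    cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
    cz <- sqrt(max(cc^2 - cx^2 - cy^2, 0))
    cell <- rbind(av, bv, c(cx, cy, cz))
  }
  A <- .cell_cols(cell)
  # atom site block
  i1 <- grep("^_atom_site_fract_z", lines)[1] + 1L
  site <- character(0)
  i <- i1
  while (i <= length(lines) && !grepl("^loop_", lines[i])) {
    if (nzchar(trimws(lines[i]))) site <- c(site, lines[i])
    i <- i + 1L
  }
  stoks <- strsplit(trimws(site), "[[:space:]]+")
  species <- vapply(stoks, `[[`, "", 2L)
  frac <- t(vapply(stoks, function(tk) as.numeric(tk[3:5]), numeric(3)))
  i2 <- grep("^_atom_site_aniso_U_23", lines)[1] + 1L
  aniso <- lines[i2:length(lines)]
  aniso <- aniso[nzchar(trimws(aniso))]
  atoks <- strsplit(trimws(aniso), "[[:space:]]+")
  n <- length(species)
  U <- array(NA_real_, c(n, 3, 3))
  for (k in seq_len(n)) {
    v <- as.numeric(atoks[[k]][2:7])
    Ucif <- matrix(c(v[1], v[4], v[5],
                     v[4], v[2], v[6],
                     v[5], v[6], v[3]), 3, 3)
    U[k, , ] <- .ucif_to_ucart(Ucif, A)
  }
  list(species = species, positions = frac %*% cell, U = U, cell = cell)
}
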