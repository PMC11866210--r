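# A 9-atom glycinate-like harmonic network whose normal modes are tuned to a
# requested set of 21 local-mode frequencies, optionally laid out as an
# exactly glide-symmetric pair over a fixed Cu substrate. The potential is
# quadratic: per-mode springs on the 21 local-mode coordinates (linearized at
# equilibrium into a Hessian) plus isotropic site tethers on the three
# surface-binding atoms (N, O1, O2) that stand in for adsorption and give
# the six external (frustrated translation/rotation) modes low, phonon-band
# frequencies.

#' Default target frequencies for the glycinate toy
#'
#' A 21-value named vector (cm^-1) covering every local mode, chosen near
#' the peak positions observed for glycinate on Cu{110} at 1/3 ML coverage;
#' modes not resolved in published peak tables (rho(CO2), delta(NCC)) carry
#' typical carboxylate-rock and skeletal-bend values.
#'
#' @return named numeric vector of 21 wavenumbers
#' @export
glycinate_default_frequencies <- function() {
  c("nu_a(NH2)" = 3465, "nu_s(NH2)" = 3375, "nu_a(CH2)" = 3070,
    "nu_s(CH2)" = 2980, "nu_a(CO2)" = 1550, "delta(NH2)" = 1510,
    "delta(CH2)" = 1410, "nu_s(CO2)" = 1380, "omega(CH2)" = 1300,
    "t(CH2)" = 1230, "rho(NH2)" = 1155, "omega(NH2)" = 1085,
    "nu(CN)" = 950, "rho(CH2)" = 910, "nu(CC)" = 885, "omega(CO2)" = 750,
    "delta(CO2)" = 620, "tau(CN)" = 560, "rho(CO2)" = 530, "tau(CC)" = 500,
    "delta(NCC)" = 330)
}

# equilibrium geometry of one molecule (canonical atom order), Angstrom
.glycinate_geometry <- function() {
  unit <- function(v) v / sqrt(sum(v^2))
  ca <- c(0, 0, 2.40)
  n  <- ca + 1.47 * c(-sin(50 * pi / 180), 0, -cos(50 * pi / 180))
  cc <- ca + 1.53 * c(sin(50 * pi / 180), 0, -cos(50 * pi / 180))
  dxz <- c(sin(20 * pi / 180), 0, -cos(20 * pi / 180))
  phi <- 63 * pi / 180
  o1 <- cc + 1.26 * (cos(phi) * dxz + sin(phi) * c(0, 1, 0))
  o2 <- cc + 1.26 * (cos(phi) * dxz - sin(phi) * c(0, 1, 0))
  hn1 <- n + 1.02 * unit(c(-0.5, 0.82, 0.45))
  hn2 <- n + 1.02 * unit(c(-0.5, -0.82, 0.45))
  hc1 <- ca + 1.09 * unit(c(0, 0.82, 0.57))
  hc2 <- ca + 1.09 * unit(c(0, -0.82, 0.57))
  rbind(N = n, HN1 = hn1, HN2 = hn2, CA = ca, HC1 = hc1, HC2 = hc2,
        C = cc, O1 = o1, O2 = o2)
}

# equilibrium B matrix: rows are the unit-norm Cartesian s-vectors of the 21
# local modes, component-major over the 9 atoms
.glycinate_bmatrix <- function(x0, basis) {
  B <- matrix(0, length(basis), 27)
  for (k in seq_along(basis)) {
    g <- matrix(0, 9, 3)
    for (p in basis[[k]]$primitives) {
      coords <- lapply(p$atoms, function(a) matrix(x0[a, ], 1, 3))
      sv <- .prim_svectors(p$type, coords)
      for (m in seq_along(p$atoms))
        g[p$atoms[m], ] <- g[p$atoms[m], ] + p$coeff * sv[[m]]
    }
    B[k, ] <- as.vector(g)
  }
  B
}

# Build the single-molecule Hessian whose normal modes sit exactly at the
# requested local-mode frequencies. The mass-weighted s-vector directions of
# the 21 local modes span the internal subspace but overlap through the
# kinetic metric; symmetric (Loewdin) orthogonalization yields the
# orthonormal set closest to them, each still dominantly associated with its
# parent local mode. Placing a spring omega_k^2 on each orthogonalized
# coordinate, and omega_ext^2 on the 6-dimensional external complement
# (standing in for the surface tether), gives
# H = M^(1/2) (sum_k w_k^2 e_k e_k^T + w_ext^2 P_ext) M^(1/2)
# with exact eigenfrequencies by construction.
.glycinate_hessian <- function(B, mdof, targets, tether_wavenumber) {
  G <- t(B) / sqrt(mdof)                   # mass-weighted internal directions
  S <- crossprod(G)
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-8)
    stop("infeasible local-mode basis: rank-deficient at this geometry")
  E <- G %*% (es$vectors %*% (t(es$vectors) / sqrt(es$values)))
  sv <- svd(E, nu = nrow(E))
  Q <- sv$u[, (ncol(E) + 1):nrow(E), drop = FALSE]   # external complement
  om2 <- wavenumber_to_omega(targets)^2
  if (any(om2 <= 0)) stop("infeasible frequency set")
  omx2 <- wavenumber_to_omega(tether_wavenumber)^2
  D <- E %*% (om2 * t(E)) + Q %*% (omx2 * t(Q))
  H <- sqrt(mdof) * t(sqrt(mdof) * t(D))
  H <- (H + t(H)) / 2
  assoc <- abs(colSums(G * E)) / sqrt(colSums(G^2))
  # verify: recover achieved frequencies by participation-weighted matching
  W <- H / sqrt(outer(mdof, mdof))
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  nu <- omega_to_wavenumber(sqrt(pmax(e$values, 0)))
  P <- (B %*% (e$vectors / sqrt(mdof)))^2
  achieved <- nu[apply(P / rowSums(P), 1, which.max)]
  names(achieved) <- names(targets)
  names(assoc) <- names(targets)
  list(H = H, achieved = achieved, association = assoc)
}

#' Glycinate-like harmonic toy model with prescribed mode frequencies
#'
#' Builds a 9-atom (or exactly glide-symmetric 18-atom) adsorbate model whose
#' normal-mode frequencies reproduce the requested 21 local-mode targets: a
#' spring of the target frequency is placed on each symmetrically
#' orthogonalized mass-weighted local-mode coordinate, so the normal-mode
#' analysis of the model returns the requested wavenumbers essentially
#' exactly, each normal mode dominantly of its parent local-mode character.
#' Surface binding is represented by a restoring term on the six external
#' (rigid-body) degrees of freedom at `tether_wavenumber`, placing the
#' frustrated translations/rotations in the sub-250 cm^-1 phonon band. The
#' glide-pair layout duplicates the molecule under mirror(y) + half-cell
#' translation along x inside a fixed periodic cell, optionally over a
#' glide-consistent fixed Cu substrate.
#'
#' @param frequencies named 21-vector of target wavenumbers (cm^-1), names
#'   from [local_mode_names()]; default [glycinate_default_frequencies()]
#' @param layout "single" or "glide_pair"
#' @param tether_wavenumber characteristic tether frequency, cm^-1
#' @param substrate include fixed Cu substrate atoms (default: only for the
#'   glide pair)
#' @return a `glycinate_toy` list: `model` (a `force_model` with Hessian),
#'   `topology`, `basis`, `selections` (adsorbate / per-molecule /
#'   substrate-layer `atom_selection`s), `glide` (a `glide_operation`, pair
#'   layout only), `target_frequencies`, `achieved_frequencies`
#' @export
glycinate_toy <- function(frequencies = glycinate_default_frequencies(),
                          layout = c("single", "glide_pair"),
                          tether_wavenumber = 80,
                          substrate = (layout == "glide_pair")) {
  layout <- match.arg(layout)
  substrate <- isTRUE(substrate)
  topo <- glycinate_topology()
  basis <- build_local_mode_basis(topo)
  nm_names <- vapply(basis, `[[`, "", "name")
  if (is.null(names(frequencies)) && length(frequencies) == 21)
    names(frequencies) <- nm_names
  if (!setequal(names(frequencies), nm_names))
    stop("frequencies must be named by the 21 local-mode labels")
  targets <- frequencies[nm_names]
  if (any(targets <= 0)) stop("target frequencies must be positive")
  x0 <- .glycinate_geometry()
  offset <- c(2.55, 1.80, 0.60)
  x0 <- sweep(x0, 2, offset, "+")
  species <- unname(.glycinate_elements[rownames(x0)])
  masses <- element_masses(species)
  mdof <- rep(masses, 3)
  B <- .glycinate_bmatrix(x0, basis)
  cal <- .glycinate_hessian(B, mdof, targets, tether_wavenumber)
  spring_ia <- lapply(seq_along(basis), function(k)
    list(type = "localmode_spring", name = nm_names[k],
         omega2 = unname(wavenumber_to_omega(targets[k])^2)))
  cell <- diag(c(10.2, 7.2, 25))
  mirror_y <- function(p) {
    p[, 2] <- -p[, 2]
    sweep(p, 2, c(5.1, 0, 0), "+")
  }
  sub_pos <- NULL
  if (substrate) {
    top <- as.matrix(expand.grid(x = c(0, 2.55, 5.1, 7.65),
                                 y = c(1.8, -1.8), z = 0))
    second <- as.matrix(expand.grid(x = c(1.275, 3.825, 6.375, 8.925),
                                    y = c(0, 3.6), z = -1.28))
    sub_pos <- rbind(top, second)
  }
  if (layout == "single") {
    pos <- x0
    H <- cal$H
    fixed <- rep(FALSE, 9)
    interactions <- spring_ia
    selections <- list(adsorbate = atom_selection(1:9, "adsorbate"))
    glide <- NULL
    topo_list <- list(topo)
  } else {
    x2 <- mirror_y(x0)
    pos <- rbind(x0, x2)
    species <- c(species, species)
    masses <- c(masses, masses)
    fixed <- rep(FALSE, 18)
    # embed the per-molecule Hessians (component-major over 9 atoms) into
    # the component-major stacking over 18 mobile atoms
    sflip <- rep(c(1, -1, 1), each = 9)
    H2 <- (sflip %o% sflip) * cal$H
    H <- matrix(0, 54, 54)
    ix1 <- as.vector(outer(1:9, (0:2) * 18, "+"))
    ix2 <- as.vector(outer(10:18, (0:2) * 18, "+"))
    H[ix1, ix1] <- cal$H
    H[ix2, ix2] <- H2
    interactions <- spring_ia
    selections <- list(adsorbate = atom_selection(1:18, "adsorbate"),
                       molecule1 = atom_selection(1:9, "molecule1"),
                       molecule2 = atom_selection(10:18, "molecule2"))
    sigma <- c(10:18, 1:9)
    if (!is.null(sub_pos)) {
      nsub <- nrow(sub_pos)
      pos <- rbind(pos, sub_pos)
      species <- c(species, rep("Cu", nsub))
      masses <- c(masses, rep(element_masses("Cu"), nsub))
      fixed <- c(fixed, rep(TRUE, nsub))
      selections$top_layer <- atom_selection(19:26, "top-layer Cu")
      selections$second_layer <- atom_selection(27:34, "second-layer Cu")
      # substrate permutation under the glide, by nearest image
      img <- mirror_y(sub_pos)
      sig_sub <- vapply(seq_len(nsub), function(i) {
        d <- .wrap_min_image(sub_pos - matrix(img[i, ], nsub, 3, byrow = TRUE),
                             cell)
        which.min(rowSums(d^2))
      }, integer(1))
      sigma <- c(sigma, sig_sub + 18L)
    }
    glide <- glide_operation(diag(c(1, -1, 1)), c(5.1, 0, 0), sigma,
                             species = species)
    topo2 <- glycinate_topology(stats::setNames(10:18, .glycinate_roles))
    topo_list <- list(topo, topo2)
  }
  model <- force_model(species, pos, interactions = interactions,
                       fixed = fixed, hessian = H, cell = cell,
                       masses = masses)
  structure(list(model = model, topology = topo_list, basis = basis,
                 selections = selections, glide = glide,
                 target_frequencies = targets,
                 achieved_frequencies = cal$achieved,
                 association = cal$association),
            class = "glycinate_toy")
}
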