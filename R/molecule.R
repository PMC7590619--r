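#' Rigid-molecule building block
#'
#' A molecule whose internal geometry is frozen during the search; only its
#' rigid-body pose over the surface varies. The ordered pair `center_atoms`
#' flags the two atoms whose midpoint is the centre of rotation.
#'
#' @param elements Character vector of chemical symbols.
#' @param coords n x 3 numeric matrix of Cartesian coordinates (Angstrom),
#'   in the molecule's body frame.
#' @param center_atoms Ordered pair of distinct 1-based atom indices.
#' @return An object of class `rigid_molecule`.
#' @export
rigid_molecule <- function(elements, coords, center_atoms) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) abort("coords must be an n x 3 matrix")
  if (length(elements) != nrow(coords)) {
    abort("elements and coords disagree on atom count")
  }
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  center_atoms <- as.integer(center_atoms)
  if (length(center_atoms) != 2 ||
      any(center_atoms < 1) || any(center_atoms > nrow(coords)) ||
      center_atoms[1] == center_atoms[2]) {
    abort("center_atoms must be two distinct valid atom indices")
  }
  dimnames(coords) <- NULL
  structure(
    list(elements = as.character(elements), coords = coords,
         center_atoms = center_atoms),
    class = "rigid_molecule"
  )
}

#' @export
print.rigid_molecule <- function(x, ...) {
  comp <- paste(names(table(x$elements)), table(x$elements),
                sep = "", collapse = "")
  cat(sprintf("<rigid_molecule> %s (%d atoms), rotation centre between atoms %d and %d\n",
              comp, nrow(x$coords), x$center_atoms[1], x$center_atoms[2]))
  invisible(x)
}

#' Tidy atomic coordinates
#'
#' Return the atoms of a molecule, slab or assembled configuration as a
#' tibble with one row per atom.
#'
#' @param x A `rigid_molecule`, `slab_model` or `configuration`.
#' @param ... Unused.
#' @return A tibble with columns `element`, `x`, `y`, `z`.
#' @export
tidy.rigid_molecule <- function(x, ...) {
  tibble(element = x$elements,
         x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3])
}

#' Centre of rotation of a rigid molecule
#'
#' The midpoint of the two flagged atoms.
#'
#' @param molecule A [rigid_molecule()].
#' @return Length-3 numeric vector (Angstrom).
#' @export
rotation_center <- function(molecule) {
  stopifnot(inherits(molecule, "rigid_molecule"))
  i <- molecule$center_atoms
  as.numeric((molecule$coords[i[1], ] + molecule$coords[i[2], ]) / 2)
}

# Intrinsic rotation Rz(gamma) %*% Ry(beta) %*% Rx(alpha), angles in degrees.
rotation_matrix <- function(alpha, beta, gamma) {
  d <- pi / 180
  ca <- cos(alpha * d); sa <- sin(alpha * d)
  cb <- cos(beta * d);  sb <- sin(beta * d)
  cg <- cos(gamma * d); sg <- sin(gamma * d)
  Rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  Ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  Rz <- rbind(c(cg, -sg, 0), c(sg, cg, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Assemble a molecule-on-slab configuration from a 6D pose
#'
#' Rotates the molecule rigidly about its rotation centre by the composed
#' rotation `Rz(gamma) Ry(beta) Rx(alpha)` (axes fixed in the lab frame,
#' aligned with the surface cell), then translates it so the centre sits at
#' fractional `(x, y)` of the orthogonal surface cell at height `z` above
#' the topmost atomic plane.
#'
#' @param molecule A [rigid_molecule()].
#' @param pose Named numeric vector or one-row data frame with entries
#'   `x`, `y` (fractional), `z` (Angstrom), `alpha`, `beta`, `gamma`
#'   (degrees).
#' @param slab A [build_slab()] model.
#' @return An object of class `configuration`: `elements`, `coords`,
#'   `cell`, plus `molecule_atoms` (index range of the molecule, listed
#'   first) and `top_layer_z`.
#' @export
place_molecule <- function(molecule, pose, slab) {
  stopifnot(inherits(molecule, "rigid_molecule"), inherits(slab, "slab_model"))
  p <- as_pose(pose)
  oc <- orthogonal_cell(slab$spec$lattice)
  R <- rotation_matrix(p[["alpha"]], p[["beta"]], p[["gamma"]])
  ctr <- rotation_center(molecule)
  target <- c(p[["x"]] * oc[["a_prime"]],
              p[["y"]] * oc[["b_prime"]],
              slab$top_layer_z + p[["z"]])
  shifted <- sweep(molecule$coords, 2, ctr)
  rotated <- shifted %*% t(R)
  mol_coords <- sweep(rotated, 2, target, "+")
  structure(
    list(
      elements = c(molecule$elements, slab$elements),
      coords = rbind(mol_coords, slab$coords),
      cell = slab$cell,
      molecule_atoms = seq_len(nrow(molecule$coords)),
      top_layer_z = slab$top_layer_z
    ),
    class = "configuration"
  )
}

#' @rdname tidy.rigid_molecule
#' @export
tidy.configuration <- function(x, ...) {
  tibble(
    element = x$elements,
    x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3],
    part = ifelse(seq_along(x$elements) %in% x$molecule_atoms,
                  "molecule", "slab")
  )
}

as_pose <- function(pose) {
  if (is.data.frame(pose)) pose <- unlist(pose[1, , drop = TRUE])
  need <- c("x", "y", "z", "alpha", "beta", "gamma")
  if (is.null(names(pose))) {
    if (length(pose) != 6) abort("pose must have six components")
    names(pose) <- need
  }
  if (!all(need %in% names(pose))) {
    abort(paste0("pose must name ", paste(need, collapse = ", ")))
  }
  pose[need]
}

#' Species and height of the molecule atom closest to the surface
#'
#' Used to classify adsorbates by the bonding species nearest the surface
#' (e.g. oxygen-down versus hydrogen-down families). Ties in height are
#' broken by the lowest atom index.
#'
#' @param config A [place_molecule()] configuration.
#' @param molecule_atoms Indices of the molecule atoms; defaults to the
#'   range recorded in the configuration.
#' @return List with `element`, `height` (Angstrom above the top layer) and
#'   `atom` (index).
#' @export
lowest_atom <- function(config, molecule_atoms = config$molecule_atoms) {
  if (length(molecule_atoms) == 0) abort("molecule atom range is empty")
  z <- config$coords[molecule_atoms, 3]
  i <- which.min(z)  # which.min returns the first index on ties
  list(element = config$elements[molecule_atoms[i]],
       height = unname(z[i] - config$top_layer_z),
       atom = molecule_atoms[i])
}

#' Normalize methyl C-H bond lengths and angles
#'
#' Idealizes the listed methyl groups so that within each group every C-H
#' bond has the group-average length and the H-C-H angles are equal: each
#' hydrogen keeps its azimuthal order about the local threefold axis (the
#' mean C-H direction), polar angles are set to the group mean and azimuths
#' are spaced uniformly around their mean. After normalization the listed
#' bond lengths and angles have zero spread, giving the molecule exact
#' 120-degree rotational periodicity per methyl group.
#'
#' @param molecule A [rigid_molecule()].
#' @param groups List of integer matrices (or two-column data frames), one
#'   per methyl group, each row a `(C, H)` bonded pair sharing the same
#'   carbon.
#' @return The normalized [rigid_molecule()].
#' @export
methyl_normalize <- function(molecule, groups) {
  stopifnot(inherits(molecule, "rigid_molecule"))
  coords <- molecule$coords
  for (g in groups) {
    g <- as.matrix(g)
    if (nrow(g) == 0) abort("empty methyl group")
    cidx <- unique(g[, 1])
    if (length(cidx) != 1) abort("a methyl group must share one carbon")
    hidx <- g[, 2]
    C <- coords[cidx, ]
    vecs <- sweep(coords[hidx, , drop = FALSE], 2, C)
    lens <- sqrt(rowSums(vecs^2))
    units <- vecs / lens
    axis <- colMeans(units)
    axis <- axis / sqrt(sum(axis^2))
    # orthonormal frame about the local C3 axis
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * axis) * axis
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    ax_comp <- units %*% axis
    polar <- acos(pmin(pmax(ax_comp, -1), 1))
    az <- atan2(units %*% e2, units %*% e1)
    mean_len <- mean(lens)
    mean_polar <- mean(polar)
    # uniform azimuthal spacing anchored at the first hydrogen, preserving
    # the circular order (a fixed point for already-uniform groups)
    n <- length(az)
    rank_az <- rank(az, ties.method = "first")
    new_az <- az[1] + 2 * pi * ((rank_az - rank_az[1]) %% n) / n
    for (k in seq_len(n)) {
      dirk <- cos(mean_polar) * axis +
        sin(mean_polar) * (cos(new_az[k]) * e1 + sin(new_az[k]) * e2)
      coords[hidx[k], ] <- C + mean_len * dirk
    }
  }
  rigid_molecule(molecule$elements, coords, molecule$center_atoms)
}

#' Structural deviation between two geometries
#'
#' Root-mean-square deviation of atomic positions in the common frame (no
#' superposition; pre- and post-relaxation structures share the slab frame)
#' and the mean absolute deviation of the listed bond lengths.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices with matching atom
#'   order.
#' @param bonds Two-column integer matrix of bonded atom pairs; may be
#'   `NULL` to skip the bond metric.
#' @return Named numeric vector `c(rmsd, mean_bond_dev)` in Angstrom
#'   (`mean_bond_dev` is `NA` when no bonds are given).
#' @export
structure_deviation <- function(coords_a, coords_b, bonds = NULL) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) {
    abort("coordinate sets must have matching dimensions")
  }
  rmsd <- sqrt(mean(rowSums((coords_a - coords_b)^2)))
  mbd <- NA_real_
  if (!is.null(bonds) && nrow(bonds <- as.matrix(bonds)) > 0) {
    len <- function(cc) sqrt(rowSums((cc[bonds[, 1], , drop = FALSE] -
                                        cc[bonds[, 2], , drop = FALSE])^2))
    mbd <- mean(abs(len(coords_a) - len(coords_b)))
  }
  c(rmsd = rmsd, mean_bond_dev = mbd)
}
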