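#' Cubic fcc lattice specification
#'
#' @param lattice_constant Conventional cubic cell parameter in Angstrom
#'   (e.g. 3.632 for bulk copper).
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(lattice_constant) {
  if (!is.numeric(lattice_constant) || length(lattice_constant) != 1 ||
      !is.finite(lattice_constant) || lattice_constant <= 0) {
    abort("lattice_constant must be a single positive number")
  }
  structure(list(lattice_constant = as.numeric(lattice_constant)),
            class = "lattice_spec")
}

as_lattice <- function(x) {
  if (inherits(x, "lattice_spec")) x else lattice_spec(x)
}

#' Orthogonal surface cell of the fcc(111) plane
#'
#' The hexagonal (111) surface lattice of an fcc crystal admits a rectangular
#' two-atom cell with vectors `a' = a / sqrt(2)` (the nearest-neighbour
#' distance) and `b' = a * sqrt(3) / sqrt(2)`, so that `b'/a' = sqrt(3)`
#' exactly. Fractional pose coordinates `x`, `y` refer to this cell.
#'
#' @param lattice A [lattice_spec()] or a bare lattice constant in Angstrom.
#' @return Named numeric vector `c(a_prime, b_prime)` in Angstrom.
#' @examples
#' orthogonal_cell(3.632)  # c(2.568..., 4.448...)
#' @export
orthogonal_cell <- function(lattice) {
  a <- as_lattice(lattice)$lattice_constant
  c(a_prime = a / sqrt(2), b_prime = a * sqrt(3) / sqrt(2))
}

#' Bulk interlayer spacing of fcc(111)
#'
#' The distance between adjacent (111) planes of an fcc crystal,
#' `a / sqrt(3)`.
#'
#' @inheritParams orthogonal_cell
#' @return Spacing in Angstrom.
#' @examples
#' bulk_layer_spacing(3.632)  # 2.097...
#' @export
bulk_layer_spacing <- function(lattice) {
  a <- as_lattice(lattice)$lattice_constant
  unname(a / sqrt(3))
}

#' Slab specification for an fcc(111) surface model
#'
#' @param lattice A [lattice_spec()] or lattice constant in Angstrom.
#' @param n_layers Number of atomic layers (>= 1).
#' @param repeats Integer pair `(nx, ny)`: supercell repeats of the
#'   orthogonal surface cell.
#' @param layer_spacings Optional numeric vector overriding the topmost
#'   interlayer distances, ordered from the surface down (first element is
#'   the gap between the top two layers). Remaining gaps use the bulk value.
#' @param vacuum Vacuum thickness in Angstrom appended along the surface
#'   normal.
#' @param element Chemical symbol of the substrate atoms.
#' @return An object of class `slab_spec`.
#' @export
slab_spec <- function(lattice, n_layers = 4, repeats = c(1, 1),
                      layer_spacings = NULL, vacuum = 50, element = "Cu") {
  lattice <- as_lattice(lattice)
  n_layers <- as.integer(n_layers)
  repeats <- as.integer(repeats)
  if (n_layers < 1) abort("n_layers must be >= 1")
  if (length(repeats) != 2 || any(repeats < 1)) {
    abort("repeats must be two integers >= 1")
  }
  if (!is.null(layer_spacings)) {
    if (length(layer_spacings) > n_layers - 1) {
      abort("more layer_spacings than interlayer gaps")
    }
    if (any(layer_spacings <= 0)) abort("layer spacings must be positive")
  }
  if (vacuum < 0) abort("vacuum must be non-negative")
  structure(
    list(lattice = lattice, n_layers = n_layers, repeats = repeats,
         layer_spacings = layer_spacings, vacuum = vacuum, element = element),
    class = "slab_spec"
  )
}

#' Build an fcc(111) slab in the orthogonal surface cell
#'
#' Stacks `n_layers` close-packed layers in ABC registry, two atoms per
#' orthogonal cell per layer (one at the cell origin, one at fractional
#' (1/2, 1/2)); successive layers are offset by the fractional stacking
#' vector (0, 1/3). Interlayer gaps default to the bulk (111) spacing and can
#' be overridden near the surface to represent a relaxed slab. Atoms are
#' ordered layer-major from the bottom layer up.
#'
#' @param spec A [slab_spec()].
#' @return An object of class `slab_model`: list with `elements`, `coords`
#'   (n x 3 Cartesian Angstrom), `cell` (3 x 3, rows are lattice vectors),
#'   `top_layer_z` and the originating `spec`.
#' @examples
#' slab <- build_slab(slab_spec(3.632, n_layers = 4, repeats = c(6, 4)))
#' nrow(slab$coords)  # 192
#' @export
build_slab <- function(spec) {
  stopifnot(inherits(spec, "slab_spec"))
  oc <- orthogonal_cell(spec$lattice)
  a_p <- oc[["a_prime"]]; b_p <- oc[["b_prime"]]
  nx <- spec$repeats[1]; ny <- spec$repeats[2]
  n_gaps <- spec$n_layers - 1

  gaps <- rep(bulk_layer_spacing(spec$lattice), max(n_gaps, 0))
  if (!is.null(spec$layer_spacings) && n_gaps > 0) {
    # overrides are listed surface-down; gaps vector runs bottom-up
    k <- length(spec$layer_spacings)
    gaps[n_gaps - seq_len(k) + 1] <- spec$layer_spacings
  }
  z_layers <- cumsum(c(0, gaps))

  basis <- rbind(c(0, 0), c(0.5, 0.5))      # two atoms of the orthogonal cell
  stack_shift <- c(0, 1 / 3)                # ABC registry per layer

  coords <- vector("list", spec$n_layers)
  for (l in seq_len(spec$n_layers)) {
    frac <- sweep(basis, 2, (l - 1) * stack_shift, "+")
    cells <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
    xy <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sweep(frac, 2, c(cells$ix[i], cells$iy[i]), "+")
    }))
    xy[, 1] <- (xy[, 1] %% nx) * a_p
    xy[, 2] <- (xy[, 2] %% ny) * b_p
    coords[[l]] <- cbind(xy, z_layers[l])
  }
  coords <- do.call(rbind, coords)
  dimnames(coords) <- NULL

  top_z <- z_layers[spec$n_layers]
  cell <- diag(c(nx * a_p, ny * b_p, top_z + spec$vacuum))
  structure(
    list(
      elements = rep(spec$element, nrow(coords)),
      coords = coords,
      cell = cell,
      top_layer_z = top_z,
      spec = spec
    ),
    class = "slab_model"
  )
}

#' @export
print.slab_model <- function(x, ...) {
  cat(sprintf(
    "<slab_model> %d x %s atoms, cell [%.2f, %.2f, %.2f] A, top layer z = %.3f A\n",
    nrow(x$coords), x$spec$element,
    x$cell[1, 1], x$cell[2, 2], x$cell[3, 3], x$top_layer_z
  ))
  invisible(x)
}

#' @rdname tidy.rigid_molecule
#' @export
tidy.slab_model <- function(x, ...) {
  tibble(
    element = x$elements,
    x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3]
  )
}
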