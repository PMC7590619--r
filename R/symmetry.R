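#' Surface symmetry operations on 6D pose points
#'
#' `twofold_translation()` applies the half-cell translation of the
#' orthogonal fcc(111) surface cell: `(x, y) -> (x + 1/2, y + 1/2)` modulo
#' the cell, all other coordinates unchanged. The two atoms of the
#' orthogonal cell are equivalent, so the surface energy is invariant under
#' this map.
#'
#' `threefold_rotation_top()` applies the +/-120 degree rotations about the
#' surface normal through the top-site atom at the cell origin: the in-plane
#' Cartesian displacement from the top site is rotated by +/-120 degrees and
#' the azimuthal angle `gamma` is shifted by the opposite amount, so the
#' molecule-surface registry is preserved.
#'
#' @param point Named numeric vector (or one-row data frame) of pose
#'   coordinates; must contain `x` and `y` (and `gamma` for the threefold
#'   map).
#' @param space The [search_space()] used for wrapping (defaults to the 6D
#'   [pose_space()]).
#' @return `twofold_translation()`: the mapped point.
#'   `threefold_rotation_top()`: a list of the two mapped points
#'   (+120 and -120 degrees).
#' @examples
#' twofold_translation(c(x = -0.05, y = -0.08, z = 5,
#'                       alpha = 0, beta = 0, gamma = 0))
#' @export
twofold_translation <- function(point, space = pose_space()) {
  p <- point_vector(point)
  p[["x"]] <- p[["x"]] + 0.5
  p[["y"]] <- p[["y"]] + 0.5
  wrap_named(space, p)
}

#' @rdname twofold_translation
#' @param lattice A [lattice_spec()] or lattice constant, fixing the aspect
#'   ratio of the orthogonal cell in which the rotation acts.
#' @export
threefold_rotation_top <- function(point, space = pose_space(),
                                   lattice = lattice_spec(3.632)) {
  p <- point_vector(point)
  oc <- orthogonal_cell(lattice)
  lapply(c(120, -120), function(ang) {
    th <- ang * pi / 180
    r <- c(p[["x"]] * oc[["a_prime"]], p[["y"]] * oc[["b_prime"]])
    rr <- c(cos(th) * r[1] - sin(th) * r[2],
            sin(th) * r[1] + cos(th) * r[2])
    q <- p
    q[["x"]] <- rr[1] / oc[["a_prime"]]
    q[["y"]] <- rr[2] / oc[["b_prime"]]
    if ("gamma" %in% names(q)) q[["gamma"]] <- q[["gamma"]] - ang
    wrap_named(space, q)
  })
}

point_vector <- function(point) {
  if (is.data.frame(point)) point <- unlist(point[1, , drop = TRUE])
  if (is.null(names(point))) abort("point must be named")
  point
}

wrap_named <- function(space, p) {
  idx <- match(space$name, names(p))
  has <- !is.na(idx)
  v <- p[idx[has]]
  sp <- space[has, ]
  per <- sp$periodic
  v[per] <- ((v[per] - sp$lower[per]) %% sp$period[per]) + sp$lower[per]
  hit <- per & (v >= sp$upper)
  v[hit] <- sp$lower[hit]
  p[idx[has]] <- v
  p
}

#' Augment a dataset with symmetry images
#'
#' Maps every record of a `(point, energy)` dataset under each symmetry
#' operation and appends the images with the original energy and provenance
#' `"symmetry-image"`. Images falling outside the search bounds after
#' wrapping are dropped with a warning; duplicates of retained points
#' (within a wrapped per-dimension tolerance) are collapsed, keeping the
#' first occurrence. Ordering is deterministic: originals first in input
#' order, then images in (record, op) order.
#'
#' @param dataset A tibble with one column per search dimension plus
#'   `energy` (eV); an optional `provenance` column is preserved.
#' @param ops List of symmetry maps. Each op takes a named point vector and
#'   returns a mapped point or a list of mapped points (as
#'   [threefold_rotation_top()] does).
#' @param space The [search_space()] of the dataset.
#' @param tol Deduplication tolerance in wrapped fractional/angular
#'   coordinates and Angstrom.
#' @return The augmented dataset tibble.
#' @export
augment_dataset <- function(dataset, ops, space = pose_space(), tol = 1e-6) {
  dataset <- as_tibble(dataset)
  if (!"energy" %in% names(dataset)) abort("dataset must have an energy column")
  if (!"provenance" %in% names(dataset)) dataset$provenance <- "scanned"
  if (length(ops) == 0) return(dataset)

  pts <- space_points(space, dataset)
  images <- list()
  dropped <- 0L
  for (i in seq_len(nrow(dataset))) {
    p <- setNames(pts[i, ], space$name)
    for (op in ops) {
      out <- op(p)
      if (!is.list(out)) out <- list(out)
      for (q in out) {
        qv <- as.numeric(q[space$name])
        if (!in_bounds(space, qv)) {
          dropped <- dropped + 1L
          next
        }
        images[[length(images) + 1L]] <-
          c(qv, energy = dataset$energy[i])
      }
    }
  }
  if (dropped > 0) {
    warn(sprintf("augment_dataset: dropped %d symmetry image(s) outside the search bounds",
                 dropped))
  }
  if (length(images) == 0) return(dataset)

  img <- do.call(rbind, images)
  img_tb <- points_tibble(space, img[, seq_len(space_dim(space)), drop = FALSE])
  img_tb$energy <- img[, "energy"]
  img_tb$provenance <- "symmetry-image"
  extra <- setdiff(names(dataset), names(img_tb))
  for (cn in extra) img_tb[[cn]] <- NA
  out <- dplyr::bind_rows(dataset, img_tb[names(dataset)])
  dedup_dataset(out, space, tol)
}

# Collapse records identical within `tol` in wrapped coordinates; first kept.
dedup_dataset <- function(dataset, space, tol = 1e-6) {
  pts <- space_points(space, dataset)
  n <- nrow(pts)
  if (n < 2) return(dataset)
  keep <- rep(TRUE, n)
  per <- space$periodic
  period <- space$period
  for (i in seq_len(n - 1)) {
    if (!keep[i]) next
    later <- which(keep)
    later <- later[later > i]
    if (!length(later)) break
    d <- sweep(pts[later, , drop = FALSE], 2, pts[i, ])
    for (k in which(per)) {
      d[, k] <- d[, k] - period[k] * round(d[, k] / period[k])
    }
    dup <- later[rowSums(abs(d) >= tol) == 0]
    if (length(dup)) keep[dup] <- FALSE
  }
  dataset[keep, ]
}
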