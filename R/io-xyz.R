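#' Read and write (extended) XYZ geometry files
#'
#' Plain XYZ with key=value metadata on the comment line, in the extended-XYZ
#' convention: `Lattice="ax ay az bx by bz cx cy cz"` carries the cell and
#' `center_atoms=i,j` flags the rotation-centre atom pair of a rigid
#' molecule. All lengths are Angstrom.
#'
#' @param path File path.
#' @return `read_xyz()` returns a [rigid_molecule()] when `center_atoms`
#'   metadata is present, otherwise a list with `elements`, `coords` and
#'   (if a `Lattice` entry exists) `cell`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("not an XYZ file: fewer than two lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) abort("not an XYZ file: first line must be the atom count")
  if (length(lines) < 2 + n) abort("XYZ file truncated")
  meta <- parse_xyz_comment(lines[2])
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  elements <- vapply(parts, `[[`, "", 1)
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  dimnames(coords) <- NULL
  if (!is.null(meta$center_atoms)) {
    ca <- as.integer(strsplit(meta$center_atoms, ",")[[1]])
    return(rigid_molecule(elements, coords, ca))
  }
  out <- list(elements = elements, coords = coords)
  if (!is.null(meta$Lattice)) {
    v <- as.numeric(strsplit(trimws(meta$Lattice), "\\s+")[[1]])
    out$cell <- matrix(v, 3, 3, byrow = TRUE)
  }
  out
}

parse_xyz_comment <- function(line) {
  meta <- list()
  pat <- "([A-Za-z_][A-Za-z0-9_]*)=(\"[^\"]*\"|\\S+)"
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(meta)
  for (tok in regmatches(line, gregexpr(pat, line, perl = TRUE))[[1]]) {
    kv <- regmatches(tok, regexec(pat, tok, perl = TRUE))[[1]]
    val <- kv[3]
    val <- sub('^"', "", sub('"$', "", val))
    meta[[kv[2]]] <- val
  }
  meta
}

#' @rdname read_xyz
#' @param x A `rigid_molecule`, `slab_model` or `configuration`.
#' @param comment Extra text appended to the comment line.
#' @export
write_xyz <- function(x, path, comment = "") {
  meta <- character(0)
  if (inherits(x, "rigid_molecule")) {
    meta <- c(meta, sprintf("center_atoms=%d,%d",
                            x$center_atoms[1], x$center_atoms[2]))
  }
  if (!is.null(x$cell)) {
    meta <- c(meta, sprintf('Lattice="%s"',
                            paste(format(t(x$cell), trim = TRUE, digits = 12),
                                  collapse = " ")))
  }
  meta <- c(meta, 'Properties=species:S:1:pos:R:3')
  header <- trimws(paste(paste(meta, collapse = " "), comment))
  body <- sprintf("%-2s %18.10f %18.10f %18.10f",
                  x$elements, x$coords[, 1], x$coords[, 2], x$coords[, 3])
  writeLines(c(as.character(nrow(x$coords)), header, body), path)
  invisible(path)
}
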