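#' Read a structured search configuration
#'
#' A single JSON (or YAML, if the `yaml` package is available) document
#' describing the search space, loop settings, backend and seed; it
#' round-trips with the command-line flags of the bundled CLI script. Keys:
#' `dimensions` (list of `name`, `lower`, `upper`, `periodic`), `budget`,
#' `init_n`, `seed`, `backend` (name of a bundled backend:
#' `toy_adsorption`, `morse_1d`, `two_well_2d`, `six_well_2d`), optional
#' `warm` (path to a CSV of warm-start records) and `symmetry`
#' (`"twofold"` to enable half-cell augmentation).
#'
#' @param path Configuration file path.
#' @return List with `settings` (a [search_settings()]) and `backend`
#'   (an [energy_backend()]).
#' @export
read_search_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configs need the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  dims <- as.data.frame(cfg$dimensions)
  space <- search_space(dims$name, dims$lower, dims$upper,
                        periodic = dims$periodic %||% FALSE)
  backend <- bundled_backend(cfg$backend %||% "toy_adsorption")
  warm <- NULL
  if (!is.null(cfg$warm)) {
    warm <- readr::read_csv(cfg$warm, show_col_types = FALSE)
  }
  ops <- list()
  if (identical(cfg$symmetry, "twofold")) {
    ops <- list(function(p) twofold_translation(p, space))
  }
  settings <- search_settings(
    space,
    budget = cfg$budget %||% 30,
    init_n = cfg$init_n %||% if (is.null(warm)) 5 else 0,
    warm = warm, sym_ops = ops,
    seed = cfg$seed %||% 0,
    track_minima = cfg$track_minima %||% TRUE
  )
  list(settings = settings, backend = backend, config = cfg)
}

#' @rdname read_search_config
#' @param name Bundled backend name.
#' @export
bundled_backend <- function(name) {
  switch(name,
    toy_adsorption = toy_adsorption_backend(),
    morse_1d = morse_backend(),
    two_well_2d = two_well_backend(),
    six_well_2d = six_well_backend(),
    abort(paste0("unknown bundled backend: ", name))
  )
}
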