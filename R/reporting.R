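#' Half-up decimal rounding
#'
#' Serialization rounding policy for reported tables: energies to 3
#' decimals, charges to 2, rounding half away from zero (so 0.0245 prints
#' as 0.025). Internal arithmetic is never rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' Difference columns of a results table
#'
#' `delta_E_D = E_D - E_B` (surrogate accuracy at the minimum) and
#' `delta_E_rel = E_rel - E_D` (energy change in the relaxation).
#'
#' @param E_B Predicted energies (eV).
#' @param E_D Backend energies at the mined locations (eV).
#' @param E_rel Energies after local relaxation (eV).
#' @return Tibble with columns `delta_E_D` and `delta_E_rel`.
#' @examples
#' delta_columns(-0.961, -0.933, -1.022)  # +0.028, -0.089
#' @export
delta_columns <- function(E_B, E_D, E_rel = NA_real_) {
  tibble(delta_E_D = E_D - E_B, delta_E_rel = E_rel - E_D)
}

#' Summarize mined minima into a results table
#'
#' One row per minimum with the standard column set (`E_B`, `sigma_B`,
#' `E_D`, `delta_E_D`, `E_rel`, `delta_E_rel`, and barriers `V_gamma`,
#' `V_xy` when present), sorted by class then energy, with the difference
#' columns recomputed exactly from their parents. Aggregates: mean
#' `sigma_B` over minima, mean relaxation change, and the `[min, max]`
#' range of predicted energies.
#'
#' @param records Minima tibble; must contain `E_B`, other columns
#'   optional.
#' @return List of class `results_summary` with `table` (tibble) and
#'   `aggregates` (one-row tibble: `mean_sigma_B`, `mean_delta_E_rel`,
#'   `E_B_min`, `E_B_max`, `n`). Aggregates are unrounded; use
#'   [round_half_up()] at serialization.
#' @export
summarize_minima <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) abort("summarize_minima: empty input")
  if (!"E_B" %in% names(records)) abort("records need an E_B column")
  tb <- records
  if (all(c("E_B", "E_D") %in% names(tb))) {
    tb$delta_E_D <- tb$E_D - tb$E_B
  }
  if (all(c("E_D", "E_rel") %in% names(tb))) {
    tb$delta_E_rel <- tb$E_rel - tb$E_D
  }
  if ("class" %in% names(tb)) {
    tb <- dplyr::arrange(tb, .data$class, .data$E_B)
  } else {
    tb <- dplyr::arrange(tb, .data$E_B)
  }
  agg <- tibble(
    mean_sigma_B = if ("sigma_B" %in% names(tb)) mean(tb$sigma_B) else NA_real_,
    mean_delta_E_rel = if ("delta_E_rel" %in% names(tb)) {
      mean(tb$delta_E_rel)
    } else NA_real_,
    E_B_min = min(tb$E_B), E_B_max = max(tb$E_B),
    n = nrow(tb)
  )
  structure(list(table = tb, aggregates = agg), class = "results_summary")
}

#' @export
print.results_summary <- function(x, ...) {
  cat(sprintf("<results_summary> %d minima, E_B in [%.3f, %.3f] eV\n",
              x$aggregates$n, x$aggregates$E_B_min, x$aggregates$E_B_max))
  if (is.finite(x$aggregates$mean_sigma_B)) {
    cat(sprintf("  mean sigma_B = %.3f eV\n",
                round_half_up(x$aggregates$mean_sigma_B, 3)))
  }
  if (is.finite(x$aggregates$mean_delta_E_rel)) {
    cat(sprintf("  mean relaxation change = %.2f eV\n",
                round_half_up(x$aggregates$mean_delta_E_rel, 2)))
  }
  print(x$table)
  invisible(x)
}

#' Per-element sums of partial charges
#'
#' Groups per-atom partial charges by element and sums them, plus the grand
#' total — the standard aggregation of a Mulliken population analysis used
#' to quantify molecule-to-surface charge transfer. Units: elementary
#' charge e.
#'
#' @param charges Numeric per-atom partial charges.
#' @param elements Chemical symbol per atom.
#' @return Tibble of class `charge_record` with one column per element
#'   (in order of first appearance) and `total`.
#' @export
mulliken_totals <- function(charges, elements) {
  if (length(charges) != length(elements)) {
    abort("charges and elements must have equal length")
  }
  sums <- tapply(charges, factor(elements, levels = unique(elements)), sum)
  out <- as_tibble(as.list(sums))
  out$total <- sum(charges)
  class(out) <- c("charge_record", class(out))
  out
}

#' HOMO-LUMO energy gap
#'
#' @param homo Highest occupied molecular orbital energy (eV).
#' @param lumo Lowest unoccupied molecular orbital energy (eV).
#' @return `lumo - homo` in eV.
#' @examples
#' energy_gap(-1.0, 2.9)  # 3.9
#' @export
energy_gap <- function(homo, lumo) {
  stopifnot(is.finite(homo), is.finite(lumo))
  lumo - homo
}

#' Boltzmann occupancy of an angular window in a hindered rotor
#'
#' For a periodic cosine well `V(phi) = (barrier / 2) (1 - cos(2 pi phi /
#' period))`, the thermal-equilibrium fraction of molecules found within
#' `|phi| <= half_window` of the minimum:
#' the Boltzmann integral of `exp(-V / kT)` over the window divided by the
#' integral over one period. The cosine shape is a declared model choice
#' for a symmetric hindered rotation (e.g. a methyl group with a 120-degree
#' period and a 0.1 eV barrier).
#'
#' @param barrier Barrier height in eV.
#' @param half_window Half-width of the angular window in degrees
#'   (`<= period / 2`).
#' @param period Potential period in degrees.
#' @param temperature Temperature in K (default 298.15, room temperature).
#' @return Fraction in `[0, 1]`.
#' @export
boltzmann_window_fraction <- function(barrier, half_window, period = 120,
                                      temperature = 298.15) {
  stopifnot(barrier >= 0, half_window > 0, period > 0,
            temperature > 0, half_window <= period / 2)
  kT <- .kB_eV * temperature
  dens <- function(phi) exp(-(barrier / 2) * (1 - cos(2 * pi * phi / period)) / kT)
  num <- integrate(dens, -half_window, half_window, rel.tol = 1e-10)$value
  den <- integrate(dens, -period / 2, period / 2, rel.tol = 1e-10)$value
  num / den
}

#' Write and read a results table
#'
#' CSV and JSON serializations of a results table with the declared
#' rounding policy (energies 3 decimals, charges 2, half-up); reading back
#' recovers the table to that precision. Decimal points are
#' locale-independent.
#'
#' @param table A results tibble (e.g. `summarize_minima(x)$table`).
#' @param path Output path; format chosen by extension (`.csv` or
#'   `.json`).
#' @param digits Decimal places for energy-like columns.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   the tibble.
#' @export
write_results <- function(table, path, digits = 3) {
  table <- as_tibble(table)
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], round_half_up, digits = digits)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         auto_unbox = FALSE, pretty = TRUE)
  } else {
    readr::write_csv(table, path)
  }
  invisible(path)
}

#' @rdname write_results
#' @param required_columns Columns that must be present when reading;
#'   missing ones raise an error naming the column.
#' @export
read_results <- function(path, required_columns = NULL) {
  tb <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  if (!is.null(required_columns)) {
    missing <- setdiff(required_columns, names(tb))
    if (length(missing)) {
      abort(paste0("results file ", path, " is missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  tb
}

#' Published reference energetics bundled with the package
#'
#' `reference_adsorbates()` returns the published adsorption energetics of
#' the eight stable camphor adsorbates on Cu(111) (predicted energy `E_B`
#' and its model standard deviation `sigma_B`, the density-functional
#' check `E_D` and difference `delta_E_D`, relaxed energy `E_rel` and
#' relaxation change `delta_E_rel`, and the rotation/translation barriers
#' `V_gamma`, `V_xy`, all in eV). `reference_charges()` returns the
#' corresponding per-element Mulliken partial-charge sums (units e). These
#' printed values exercise the table arithmetic; they are inputs, not
#' results of this package.
#'
#' @return A tibble.
#' @export
reference_adsorbates <- function() {
  readr::read_csv(system.file("extdata", "camphor_cu111_adsorbates.csv",
                              package = "surfsearch", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' @rdname reference_adsorbates
#' @export
reference_charges <- function() {
  readr::read_csv(system.file("extdata", "camphor_cu111_charges.csv",
                              package = "surfsearch", mustWork = TRUE),
                  show_col_types = FALSE)
}
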