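#' Plot a PES cross-section
#'
#' Raster heat map of the energy over the two free dimensions.
#'
#' @param object A [cross_section()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cross_section <- function(object, ...) {
  v <- object$values
  ggplot2::ggplot(v, ggplot2::aes(
    x = .data[[object$free_dims[1]]],
    y = .data[[object$free_dims[2]]],
    fill = .data$energy
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "E (eV)") +
    ggplot2::coord_fixed(ratio = diff(range(v[[object$free_dims[1]]])) /
                           diff(range(v[[object$free_dims[2]]]))) +
    ggplot2::labs(title = "PES cross-section")
}

#' Plot search progress
#'
#' Acquired energies and the running predicted global-minimum value per
#' iteration.
#'
#' @param object A [run_search()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surf_search <- function(object, ...) {
  h <- object$history
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$energy), shape = 1) +
    ggplot2::labs(x = "iteration", y = "energy (eV)",
                  title = "Active-learning search progress")
  if (any(is.finite(h$best_min_value))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$best_min_value),
                                colour = "firebrick")
  }
  p
}

#' Plot a rotational energy profile
#'
#' @param object A [rotation_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rotation_profile <- function(object, ...) {
  nm <- names(object$profile)[1]
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data[[nm]], y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(nm, " (deg)"), y = "energy (eV)",
                  title = sprintf("In-place rotation profile (barrier %.3f eV)",
                                  object$barrier))
}

#' Plot a minimum-energy path
#'
#' @param object A [neb_barrier()] path.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barrier_path <- function(object, ...) {
  ggplot2::ggplot(object$images,
                  ggplot2::aes(x = .data$image, y = .data$energy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "image", y = "energy (eV)",
                  title = sprintf("Minimum-energy path (barrier %.3f eV)",
                                  object$barrier))
}
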