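#' Quick-look plot of a profile across the slit
#'
#' @param profile Tibble whose first column is `z`; `value` picks the
#'   column to draw (default: the second column).
#' @param value Column name to plot against `z`.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, value = names(profile)[2L]) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$z, y = .data[[value]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = value) +
    ggplot2::theme_minimal()
}

#' Plot a radial distribution function
#'
#' @param rdf Output of [non_normalized_rdf()].
#' @param r0 Optional near/far split to mark with a vertical line (nm).
#' @return A ggplot object.
#' @export
plot_rdf <- function(rdf, r0 = 0.3) {
  p <- ggplot2::ggplot(rdf, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (nm)", y = "non-normalized RDF (beads/nm³)") +
    ggplot2::theme_minimal()
  if (!is.null(r0)) {
    p <- p + ggplot2::geom_vline(xintercept = r0, linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.coating_config <- function(object, ...) {
  ggplot2::ggplot(object$beads,
                  ggplot2::aes(x = .data$x, y = .data$z,
                               colour = factor(.data$chain))) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "x (nm)", y = "z (nm)",
                  title = sprintf("Grafted coating, N = %d", object$N)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.abead_fit <- function(object, ...) {
  obs <- dplyr::mutate(object$observed, which = "observed")
  fit <- dplyr::mutate(object$fitted, which = "NSB fit")
  ggplot2::ggplot(mapping = ggplot2::aes(x = .data$z, y = .data$u)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(shape = .data$which),
                        size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(data = fit, ggplot2::aes(linetype = .data$which),
                       colour = "red") +
    ggplot2::labs(x = "z (nm)", y = "u (m/s)", shape = NULL,
                  linetype = NULL,
                  title = sprintf("a_bead = %.4g nm", object$a_bead)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.shielding_kernel <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$theta,
                               fill = .data$a_bead)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "r (nm)", y = expression(theta[far] * " (deg)"),
                  fill = "a_bead (nm)") +
    ggplot2::theme_minimal()
}
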