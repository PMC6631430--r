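#' Polymer bead number-density profile across the slit
#'
#' For a generated coating, bins bead `z` coordinates into uniform cells
#' centred on the grid points and divides by the cell volume, so that the
#' profile conserves the total bead count:
#' \eqn{\int n(z)\, A\, dz = } number of beads (A the lateral box area).
#'
#' @param x A `coating_config`.
#' @param n_grid Number of uniform grid points spanning `[0, w]`.
#' @param ... Unused.
#'
#' @return A tibble with columns `z` (nm) and `n` (beads/nm^3).
#' @export
#' @examples
#' cfg <- generate_grafted_coating(N = 2, n_chains_per_wall = 4, seed = 1)
#' prof <- bead_density_profile(cfg, n_grid = 201)
bead_density_profile <- function(x, ...) UseMethod("bead_density_profile")

#' @rdname bead_density_profile
#' @export
bead_density_profile.coating_config <- function(x, n_grid = 2001L, ...) {
  if (nrow(x$beads) == 0L) stop("empty configuration")
  w <- x$geometry$w
  h <- w / (n_grid - 1L)
  # cells [z_i - h/2, z_i + h/2) tile the slit; no beads sit outside it
  idx <- pmin(pmax(floor(x$beads$z / h + 0.5), 0), n_grid - 1L)
  counts <- tabulate(idx + 1L, nbins = n_grid)
  area <- x$box[1L] * x$box[2L]
  tibble::tibble(z = seq(0, w, length.out = n_grid),
                 n = counts / (area * h))
}

#' Parametric bead-density profiles
#'
#' Idealized coating density profiles applied symmetrically from both
#' walls: a parabolic brush, \eqn{n(z) = n_0 (1 - (z/h)^2)} for `z <= h`
#' (the classical self-consistent-field brush shape), or a Gaussian
#' mushroom, \eqn{n(z) = n_0 \exp(-z^2 / 2h^2)}.
#'
#' @param form `"parabolic_brush"` or `"gaussian_mushroom"`.
#' @param height Profile height scale `h` (nm).
#' @param amplitude Contact density `n_0` (beads/nm^3).
#' @param w Slit width (nm).
#' @param n_grid Number of uniform grid points spanning `[0, w]`.
#'
#' @return A tibble with columns `z` (nm) and `n` (beads/nm^3).
#' @seealso [brush_amplitude()] to set `amplitude` from the grafted bead
#'   coverage.
#' @export
parametric_density <- function(form = c("parabolic_brush", "gaussian_mushroom"),
                               height, amplitude, w = 20, n_grid = 2001L) {
  form <- match.arg(form)
  stopifnot(height > 0, amplitude >= 0, w > 0, n_grid >= 3L)
  z <- seq(0, w, length.out = n_grid)
  shape <- switch(form,
    parabolic_brush = function(d) pmax(0, 1 - (d / height)^2),
    gaussian_mushroom = function(d) exp(-d^2 / (2 * height^2))
  )
  tibble::tibble(z = z, n = amplitude * (shape(z) + shape(w - z)))
}

#' Contact density of a parabolic brush from bead coverage
#'
#' For a parabolic brush of height `h`, \eqn{\int_0^h n_0 (1 - (z/h)^2) dz
#' = 2 n_0 h / 3}, so conserving a grafted coverage of `beads_per_area`
#' beads per nm^2 per wall requires \eqn{n_0 = 3\Gamma / (2h)}.
#'
#' @param beads_per_area Grafted beads per unit wall area (nm^-2), e.g.
#'   `(3 * N + 2) / graft_a^2`.
#' @param height Brush height (nm).
#' @return Contact density `n_0` (beads/nm^3).
#' @export
brush_amplitude <- function(beads_per_area, height) {
  stopifnot(beads_per_area >= 0, height > 0)
  3 * beads_per_area / (2 * height)
}

#' Gyration-radius scaling model for grafted chains
#'
#' Power-law model \eqn{R_g(N) = R_{ref} (N/N_{ref})^\gamma} calibrated so
#' that the brush/mushroom crossover (gyration radius equal to the grafting
#' separation, 2.5 nm by default) falls at `N_ref = 14`.
#'
#' @param N Degree(s) of polymerization.
#' @param gamma Scaling exponent.
#' @param rg_ref Gyration radius (nm) at `N_ref`.
#' @param N_ref Reference degree of polymerization.
#' @return Gyration radii (nm).
#' @export
rg_scaling_model <- function(N, gamma = 0.65, rg_ref = 2.5, N_ref = 14) {
  stopifnot(all(N > 0), gamma > 0)
  rg_ref * (N / N_ref)^gamma
}
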