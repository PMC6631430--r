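#' Infer the effective bead radius by velocity-profile matching
#'
#' Treats the Stokes radius `a_bead` of the Navier-Stokes-Brinkman drag
#' term as the single adjustable parameter and minimizes the unweighted L2
#' mismatch between the solved and the observed velocity profile over the
#' half-slit grid, by bounded scalar minimization ([stats::optimize()]).
#' If the interior optimum is not below both bound residuals, the better
#' bound is returned and flagged as a boundary solution.
#'
#' @param observed Velocity tibble with columns `z` (nm) and `u` (m/s); if
#'   its grid differs from the solver grid it is linearly resampled.
#' @param profiles NSB coefficient table (see [assemble_nsb_profiles()]).
#' @param params An [nsb_params()]; its `a_bead` entry is ignored.
#' @param bounds Search interval for `a_bead` (nm); defaults to
#'   `[0, a0]`.
#' @param tol Absolute convergence tolerance on `a_bead` (nm).
#' @param mask_wall Exclude grid points with `z < mask_wall` (nm) from the
#'   mismatch, e.g. to ignore wall-layering artifacts; 0 disables.
#'
#' @return An object of class `abead_fit` with [tidy()] and [glance()]
#'   methods; fields include `a_bead` (nm), `residual_rms` (m/s),
#'   `evaluations`, `bounds`, `relative` (`a_bead/a0`) and `boundary`.
#' @export
fit_abead <- function(observed, profiles, params,
                      bounds = c(0, params$a0), tol = 1e-8,
                      mask_wall = 0) {
  stopifnot(inherits(params, "nsb_params"),
            all(c("z", "u") %in% names(observed)),
            length(bounds) == 2L, bounds[1L] < bounds[2L], mask_wall >= 0)
  if (bounds[1L] < 0 || bounds[2L] > params$a0) {
    stop("bounds must lie within [0, a0]")
  }

  probe <- solve_nsb(profiles, .with_abead(params, bounds[1L]))
  same_grid <- nrow(observed) == nrow(probe) &&
    max(abs(observed$z - probe$z)) < 1e-9 * max(probe$z)
  u_obs <- if (same_grid) observed$u else
    approx(observed$z, observed$u, xout = probe$z, rule = 2)$y
  keep <- probe$z <= params$w / 2 + 1e-9 & probe$z >= mask_wall
  n_keep <- sum(keep)

  n_eval <- 0L
  sse <- function(a) {
    n_eval <<- n_eval + 1L
    sol <- solve_nsb(profiles, .with_abead(params, a))
    sum((sol$u[keep] - u_obs[keep])^2)
  }
  opt <- optimize(sse, interval = bounds, tol = tol)
  sse_lo <- sse(bounds[1L]); sse_hi <- sse(bounds[2L])
  boundary <- FALSE
  a_hat <- opt$minimum; sse_hat <- opt$objective
  if (min(sse_lo, sse_hi) < sse_hat) {
    boundary <- TRUE
    if (sse_lo <= sse_hi) { a_hat <- bounds[1L]; sse_hat <- sse_lo }
    else { a_hat <- bounds[2L]; sse_hat <- sse_hi }
  }
  fitted <- solve_nsb(profiles, .with_abead(params, a_hat))
  structure(
    list(a_bead = a_hat, residual_rms = sqrt(sse_hat / n_keep),
         evaluations = n_eval, bounds = bounds,
         relative = a_hat / params$a0, boundary = boundary,
         observed = tibble::tibble(z = probe$z, u = u_obs),
         fitted = fitted, params = params, mask_wall = mask_wall),
    class = "abead_fit"
  )
}

.with_abead <- function(params, a) {
  params$a_bead <- a
  params
}

#' @exportS3Method base::print
print.abead_fit <- function(x, ...) {
  cat("<abead_fit>\n")
  cat(sprintf("  a_bead = %.6g nm (%.4g a0)%s\n", x$a_bead, x$relative,
              if (x$boundary) " [boundary solution]" else ""))
  cat(sprintf("  residual RMS = %.4g m/s after %d solver calls\n",
              x$residual_rms, x$evaluations))
  invisible(x)
}

#' @export
tidy.abead_fit <- function(x, ...) {
  tibble::tibble(term = "a_bead", estimate = x$a_bead,
                 relative_a0 = x$relative)
}

#' @export
glance.abead_fit <- function(x, ...) {
  tibble::tibble(a_bead = x$a_bead, relative_a0 = x$relative,
                 residual_rms = x$residual_rms,
                 evaluations = x$evaluations,
                 bound_lower = x$bounds[1L], bound_upper = x$bounds[2L],
                 boundary = x$boundary)
}

#' Stokes radius from drag-force / ambient-velocity tables
#'
#' Converts measured drag forces to hydrodynamic radii through Stokes' law,
#' \eqn{a(\theta) = F(\theta) / (6\pi\mu v(\theta))}. Forces are accepted
#' in the MD convention kJ/(mol nm) and converted to newtons per molecule
#' via Avogadro's number.
#'
#' @param data Data frame with columns `theta_deg`, `F_kJ_mol_nm`,
#'   `v_m_s`, `mu_Pa_s` (and optionally `role`), as read by
#'   [read_drag_table()].
#' @return The input with an added column `a_bead_nm`.
#' @export
#' @examples
#' stokes_radius_from_drag(tibble::tibble(
#'   theta_deg = 90, F_kJ_mol_nm = 4.7, v_m_s = 1, mu_Pa_s = 1e-3))
stokes_radius_from_drag <- function(data) {
  need <- c("theta_deg", "F_kJ_mol_nm", "v_m_s", "mu_Pa_s")
  stopifnot(all(need %in% names(data)))
  if (any(data$v_m_s == 0)) stop("undefined radius: ambient velocity is zero")
  if (any(data$mu_Pa_s <= 0)) stop("viscosity must be positive")
  force_N <- data$F_kJ_mol_nm * 1e3 / (.const$avogadro * .const$nm)
  a_m <- force_N / (6 * pi * data$mu_Pa_s * abs(data$v_m_s))
  dplyr::mutate(tibble::as_tibble(data), a_bead_nm = a_m / .const$nm)
}

#' Orientation-averaged hydrodynamic radius
#'
#' Averages a tabulated `a_bead(theta)` over orientation by trapezoidal
#' quadrature with a normalized weight: `"sphere"` uses the hemisphere
#' measure \eqn{\sin\theta\, d\theta} (orientations uniform on the
#' sphere), `"uniform"` weights all angles equally.
#'
#' @param data Data frame with columns `theta_deg` (covering `[0, 90]`)
#'   and `a_bead_nm`.
#' @param weight `"sphere"` (default) or `"uniform"`.
#' @return The weighted mean radius (nm).
#' @export
average_radius_over_orientation <- function(data,
                                            weight = c("sphere", "uniform")) {
  weight <- match.arg(weight)
  stopifnot(all(c("theta_deg", "a_bead_nm") %in% names(data)))
  if (nrow(data) == 0L) stop("empty orientation table")
  data <- dplyr::arrange(tibble::as_tibble(data), .data$theta_deg)
  th <- data$theta_deg * pi / 180
  wgt <- switch(weight, sphere = sin(th), uniform = rep(1, length(th)))
  den <- .trapz(th, wgt)
  if (den == 0) stop("degenerate weight: single quadrature node")
  .trapz(th, data$a_bead_nm * wgt) / den
}

#' Read a drag-measurement table
#'
#' CSV with header `theta_deg,F_kJ_mol_nm,v_m_s,mu_Pa_s,role`, one row per
#' orientation/role combination.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_drag_table <- function(path) {
  tab <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("theta_deg", "F_kJ_mol_nm", "v_m_s", "mu_Pa_s")
  if (!all(need %in% names(tab))) {
    stop("drag table must have columns ", paste(need, collapse = ", "))
  }
  tab
}
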