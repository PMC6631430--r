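#' Parameters of the Navier-Stokes-Brinkman model
#'
#' Physical constants and numerical controls for the one-dimensional
#' Navier-Stokes-Brinkman (NSB) balance
#' \deqn{\frac{d}{dz}\mu(z)\frac{du}{dz} - 6\pi\mu(z) n(z) a_{bead}
#'   K(\phi(z))\, u + \rho_e(z) E_{ext} = 0,}
#' i.e. viscous stress, distributed Stokes drag of the polymer beads, and
#' the electric body force on the double-layer charge.
#'
#' @param a_bead Effective (Stokes) bead radius (nm), in `[0, a0]`.
#' @param a0 Physical bead radius (nm).
#' @param mu0 Bulk solvent viscosity (Pa s).
#' @param Eext Applied field along the slit (V/nm).
#' @param w Slit width (nm).
#' @param hindrance Hindered-drag correction `K(phi)`: `"kim_russel"`
#'   (default) or `"none"` (dilute limit, K = 1). See [hindrance_K()].
#' @param noslip_offset Distance of the hydrodynamic no-slip plane from the
#'   wall (nm, `>= 0`).
#'
#' @return An object of class `nsb_params`.
#' @export
#' @examples
#' nsb_params(a_bead = 0.019)
nsb_params <- function(a_bead, a0 = 0.156, mu0 = 0.85e-3, Eext = 1.6e-2,
                       w = 20, hindrance = c("kim_russel", "none"),
                       noslip_offset = 0) {
  hindrance <- match.arg(hindrance)
  stopifnot(is.numeric(a_bead), length(a_bead) == 1L,
            a0 > 0, mu0 > 0, w > 0, noslip_offset >= 0)
  if (a_bead < 0 || a_bead > a0) {
    stop("a_bead must lie in [0, a0]")
  }
  structure(
    list(a_bead = a_bead, a0 = a0, mu0 = mu0, Eext = Eext, w = w,
         hindrance = hindrance, noslip_offset = noslip_offset),
    class = "nsb_params"
  )
}

#' @exportS3Method base::print
print.nsb_params <- function(x, ...) {
  cat("<nsb_params>\n")
  cat(sprintf("  a_bead = %g nm (a0 = %g nm, ratio %.3g)\n",
              x$a_bead, x$a0, x$a_bead / x$a0))
  cat(sprintf("  mu0 = %g Pa s, Eext = %g V/nm, w = %g nm\n",
              x$mu0, x$Eext, x$w))
  cat(sprintf("  hindrance = %s, no-slip offset = %g nm\n",
              x$hindrance, x$noslip_offset))
  invisible(x)
}

#' Polymer bead volume fraction
#'
#' \eqn{\phi(z) = (4\pi/3) a_0^3 n(z)} with `a0` and `n` in nm units.
#' Warns when the packing exceeds random close packing (0.64).
#'
#' @param density Tibble with columns `z` (nm) and `n` (beads/nm^3).
#' @param a0 Physical bead radius (nm).
#' @return A tibble with columns `z` and `phi`.
#' @export
volume_fraction <- function(density, a0) {
  stopifnot(all(c("z", "n") %in% names(density)), a0 > 0)
  if (any(density$n < 0)) stop("negative bead density")
  phi <- (4 * pi / 3) * a0^3 * density$n
  if (max(phi) > 0.64) {
    warning(sprintf("max volume fraction %.3g exceeds close packing (0.64)",
                    max(phi)))
  }
  tibble::tibble(z = density$z, phi = phi)
}

#' Einstein-relation viscosity profile
#'
#' Dilute-suspension viscosity \eqn{\mu(z) = \mu_0 (1 + 2.5\,\phi(z))}.
#'
#' @param phi Tibble with columns `z` and `phi` (volume fraction in
#'   `[0, 1)`).
#' @param mu0 Bulk solvent viscosity (Pa s).
#' @return A tibble with columns `z` and `mu` (Pa s).
#' @export
viscosity_profile <- function(phi, mu0) {
  stopifnot(all(c("z", "phi") %in% names(phi)), mu0 > 0)
  if (any(phi$phi < 0) || any(phi$phi >= 1)) {
    stop("volume fraction must lie in [0, 1)")
  }
  tibble::tibble(z = phi$z, mu = mu0 * (1 + 2.5 * phi$phi))
}

#' Hindered-drag correction K(phi)
#'
#' Correction to the single-sphere Stokes drag accounting for hydrodynamic
#' correlations among homogeneously distributed spheres at volume fraction
#' `phi`. The default is the Kim-Russel fixed-bed expansion
#' \deqn{K(\phi) = 1 + \tfrac{3}{\sqrt 2}\phi^{1/2} +
#'   \tfrac{135}{64}\phi\ln\phi + 16.456\,\phi,}
#' which satisfies `K(0) = 1` and increases on `[0, 0.64]`; `"none"` gives
#' the dilute limit `K = 1`.
#'
#' @param phi Volume fraction(s) in `[0, 0.64]`.
#' @param model `"kim_russel"` or `"none"`.
#' @return `K(phi)`, vectorized over `phi`.
#' @export
#' @examples
#' hindrance_K(c(0, 0.1, 0.2))
hindrance_K <- function(phi, model = c("kim_russel", "none")) {
  model <- match.arg(model)
  if (any(phi < 0) || any(phi > 0.64)) {
    stop("phi out of range [0, 0.64]")
  }
  if (model == "none") return(rep(1, length(phi)))
  k <- 1 + (3 / sqrt(2)) * sqrt(phi) + 16.456 * phi
  pos <- phi > 0
  k[pos] <- k[pos] + (135 / 64) * phi[pos] * log(phi[pos])
  k
}

#' Ionic charge density profile
#'
#' \eqn{\rho_e(z) = F \sum_i z_i c_i(z)} with signed valences, the driving
#' charge for the electro-osmotic body force.
#'
#' @param ions Tibble with a `z` column and one concentration column per
#'   species (e.g. the output of [gouy_chapman_profiles()]).
#' @param valences Named numeric vector mapping concentration columns to
#'   valences, e.g. `c(c_plus = 1, c_minus = -1)`.
#' @param conc_unit Unit of the concentration columns, `"mol/L"` (default)
#'   or `"mol/m3"`.
#' @return A tibble with columns `z` and `rho_e` (C/m^3).
#' @export
charge_density <- function(ions, valences = c(c_plus = 1, c_minus = -1),
                           conc_unit = c("mol/L", "mol/m3")) {
  conc_unit <- match.arg(conc_unit)
  stopifnot("z" %in% names(ions), length(valences) >= 1L,
            !is.null(names(valences)))
  missing <- setdiff(names(valences), names(ions))
  if (length(missing)) {
    stop("species columns absent from `ions` (grid/profile mismatch): ",
         paste(missing, collapse = ", "))
  }
  scale <- if (conc_unit == "mol/L") 1000 else 1
  rho <- rep(0, nrow(ions))
  for (sp in names(valences)) {
    rho <- rho + valences[[sp]] * ions[[sp]] * scale
  }
  tibble::tibble(z = ions$z, rho_e = .const$faraday * rho)
}

#' Assemble NSB coefficient profiles on a common grid
#'
#' Combines a bead-density profile and ion-concentration profiles into the
#' coefficient table consumed by [solve_nsb()]: volume fraction, Einstein
#' viscosity and charge density, all on the shared `z` grid.
#'
#' @param density Tibble with columns `z`, `n` (beads/nm^3).
#' @param ions Tibble with `z` and species concentration columns (mol/L).
#' @param params An [nsb_params()].
#' @param valences Passed to [charge_density()].
#' @return A tibble with columns `z`, `n`, `phi`, `mu`, `rho_e`.
#' @export
assemble_nsb_profiles <- function(density, ions, params,
                                  valences = c(c_plus = 1, c_minus = -1)) {
  stopifnot(inherits(params, "nsb_params"))
  if (nrow(density) != nrow(ions) ||
      max(abs(density$z - ions$z)) > 1e-9 * max(abs(ions$z))) {
    stop("density and ion profiles must share one z grid")
  }
  phi <- volume_fraction(density, params$a0)
  mu <- viscosity_profile(phi, params$mu0)
  rho <- charge_density(ions, valences)
  tibble::tibble(z = density$z, n = density$n, phi = phi$phi,
                 mu = mu$mu, rho_e = rho$rho_e)
}

#' Solve the 1D Navier-Stokes-Brinkman equation
#'
#' Conservative-flux, second-order finite-difference solution of the linear
#' two-point boundary-value problem
#' \deqn{\frac{d}{dz}\mu\frac{du}{dz} - 6\pi\mu n a_{bead} K(\phi) u +
#'   \rho_e E_{ext} = 0}
#' on the half slit, with `u = 0` at the no-slip plane and the mirror
#' symmetry condition `du/dz = 0` at mid-slit; the returned profile covers
#' the full slit by reflection. Inputs are in nm-based units (see
#' [nsb_params()]); the velocity is returned in m/s.
#'
#' @param profiles Coefficient table with columns `z` (uniform grid, nm),
#'   `mu` (Pa s), `n` (beads/nm^3), `phi`, `rho_e` (C/m^3), covering either
#'   `[0, w/2]` or the full slit `[0, w]` (the grid must contain `w/2`).
#' @param params An [nsb_params()].
#' @return A tibble with columns `z` (nm) and `u` (m/s) over the full slit.
#' @export
solve_nsb <- function(profiles, params) {
  stopifnot(inherits(params, "nsb_params"),
            all(c("z", "mu", "n", "phi", "rho_e") %in% names(profiles)))
  z <- profiles$z
  if (length(z) < 3L) stop("grid too short (need >= 3 points)")
  if (!.is_uniform_grid(z)) stop("z grid must be strictly increasing and uniform")
  if (anyNA(profiles[c("z", "mu", "n", "phi", "rho_e")])) stop("NaN in profiles")
  if (any(profiles$mu <= 0)) stop("singular system: non-positive viscosity")
  if (any(profiles$n < 0)) stop("negative bead density")
  w <- params$w
  h <- z[2L] - z[1L]
  full_input <- abs(max(z) - w) < h / 100
  if (full_input) {
    half <- which(z <= w / 2 + h / 100)
    z_half <- z[half]
  } else {
    if (abs(max(z) - w / 2) > h / 100) {
      stop("grid must cover [0, w/2] or [0, w] and contain w/2")
    }
    half <- seq_along(z)
    z_half <- z
  }
  if (abs(z_half[length(z_half)] - w / 2) > h / 100) {
    stop("grid does not contain the mid-slit point w/2")
  }

  mu <- profiles$mu[half]
  n_si <- profiles$n[half] * 1e27                       # 1/m^3
  K <- hindrance_K(profiles$phi[half], params$hindrance)
  beta <- 6 * pi * mu * n_si * (params$a_bead * .const$nm) * K  # Pa s/m^2
  f <- profiles$rho_e[half] * params$Eext * 1e9         # N/m^3
  h_si <- h * .const$nm
  m <- length(z_half)

  # no-slip plane: nearest grid point to the configured offset
  i0 <- which.min(abs(z_half - params$noslip_offset))
  if (i0 >= m - 1L) stop("no-slip offset leaves no interior domain")

  idx <- (i0 + 1L):m      # unknowns
  nun <- length(idx)
  # harmonic-mean flux coefficients: conservative across viscosity jumps
  harm <- function(a, b) 2 * a * b / (a + b)
  mu_half_lo <- harm(mu[idx], mu[idx - 1L])             # mu_{i-1/2}
  mu_half_hi <- c(harm(mu[idx[-nun]], mu[idx[-nun] + 1L]), NA) # mu_{i+1/2}

  lower <- mu_half_lo / h_si^2                          # couples to u_{i-1}
  upper <- mu_half_hi / h_si^2                          # couples to u_{i+1}
  diagm <- numeric(nun)
  diagm[-nun] <- -(lower[-nun] + upper[-nun]) - beta[idx[-nun]]
  # mirror-symmetry row at mid-slit: ghost point u_{m+1} = u_{m-1}
  diagm[nun] <- -2 * mu_half_lo[nun] / h_si^2 - beta[m]
  lower[nun] <- 2 * mu_half_lo[nun] / h_si^2
  rhs <- -f[idx]

  A <- Matrix::bandSparse(nun, nun, k = c(-1L, 0L, 1L),
                          diagonals = list(lower[-1L], diagm, upper[-nun]))
  u_unknown <- as.numeric(Matrix::solve(A, rhs))
  u_half <- numeric(m)
  u_half[idx] <- u_unknown

  # reflect across mid-slit to the full profile
  z_full <- c(z_half, w - rev(z_half[-m]))
  u_full <- c(u_half, rev(u_half[-m]))
  tibble::tibble(z = z_full, u = u_full)
}
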