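#' Electrolyte specification
#'
#' Physical description of the (by default 1:1) electrolyte filling the
#' slit: bulk concentration, ion valences, wall surface-charge density,
#' solvent dielectric constant and temperature.
#'
#' @param c0 Bulk salt concentration (mol/L). For a 1:1 electrolyte this
#'   equals the ionic strength.
#' @param valences Integer valences of the two ionic species.
#' @param sigma_s Surface charge density of each wall (C/m^2).
#' @param eps_r Relative dielectric constant of the solvent.
#' @param temperature Temperature (K).
#'
#' @return An object of class `electrolyte_spec`.
#' @export
#' @examples
#' electrolyte_spec()
#' debye_length(electrolyte_spec())  # about 1.65 nm
electrolyte_spec <- function(c0 = 0.034, valences = c(1L, -1L),
                             sigma_s = 3.28e-2, eps_r = 78,
                             temperature = 300) {
  stopifnot(c0 > 0, length(valences) == 2L, eps_r > 0, temperature > 0)
  structure(
    list(c0 = c0, valences = as.integer(valences), sigma_s = sigma_s,
         eps_r = eps_r, temperature = temperature),
    class = "electrolyte_spec"
  )
}

#' @exportS3Method base::print
print.electrolyte_spec <- function(x, ...) {
  cat("<electrolyte_spec>\n")
  cat(sprintf("  c0 = %g mol/L, valences (%+d, %+d)\n",
              x$c0, x$valences[1L], x$valences[2L]))
  cat(sprintf("  sigma_s = %g C/m^2, eps_r = %g, T = %g K\n",
              x$sigma_s, x$eps_r, x$temperature))
  cat(sprintf("  Debye length = %.4g nm\n", debye_length(x)))
  invisible(x)
}

#' @rdname electrolyte_spec
#' @param spec An `electrolyte_spec`.
#' @return `debye_length()`: the Debye screening length in nm.
#' @export
debye_length <- function(spec) {
  # both species at c0 for the symmetric electrolyte: I = c0 for 1:1
  ionic_strength <- 0.5 * spec$c0 * sum(spec$valences^2)
  kT <- .const$kB * spec$temperature
  ld <- sqrt(spec$eps_r * .const$eps0 * kT /
               (2 * .const$avogadro * .const$e^2 * 1000 * ionic_strength))
  ld / .const$nm
}

#' Gouy-Chapman double-layer profiles across a slit
#'
#' Closed-form Gouy-Chapman (nonlinear Poisson-Boltzmann, single charged
#' plane) potential for each wall, superposed symmetrically across the slit,
#' with Boltzmann ion concentrations
#' \eqn{c_\pm(z) = c_0 \exp(\mp e\psi(z)/kT)}. The superposition is accurate
#' when the slit is several Debye lengths wide; mid-slit concentrations then
#' relax to the bulk value. Only 1:1 electrolytes are supported.
#'
#' @param spec An [electrolyte_spec()] with valences `(+1, -1)`.
#' @param w Slit width (nm).
#' @param n_grid Number of uniform grid points spanning `[0, w]`
#'   (`n_grid >= 3`).
#'
#' @return A tibble with columns `z` (nm), `psi` (V), `c_plus` and
#'   `c_minus` (mol/L), carrying the spec and the Debye length (nm) as
#'   attributes `"spec"` and `"debye_length"`.
#' @export
#' @examples
#' gc <- gouy_chapman_profiles(electrolyte_spec(), w = 20, n_grid = 401)
#' head(gc)
gouy_chapman_profiles <- function(spec, w = 20, n_grid = 2001L) {
  stopifnot(inherits(spec, "electrolyte_spec"), w > 0, n_grid >= 3L)
  if (!setequal(spec$valences, c(1L, -1L))) {
    stop("unsupported configuration: Gouy-Chapman profiles require a 1:1 electrolyte")
  }
  kT <- .const$kB * spec$temperature
  z <- seq(0, w, length.out = n_grid)
  if (spec$sigma_s == 0) {
    psi <- rep(0, n_grid)
  } else {
    n0 <- .const$avogadro * 1000 * spec$c0 # per-species number density [1/m^3]
    # Grahame equation for the single-wall surface potential
    psi0 <- (2 * kT / .const$e) *
      asinh(spec$sigma_s / sqrt(8 * spec$eps_r * .const$eps0 * kT * n0))
    gam <- tanh(.const$e * psi0 / (4 * kT))
    ld <- debye_length(spec) # nm
    wall_psi <- function(d) (4 * kT / .const$e) * atanh(gam * exp(-d / ld))
    psi <- wall_psi(z) + wall_psi(w - z)
  }
  u <- .const$e * psi / kT
  tibble::tibble(z = z, psi = psi,
                 c_plus = spec$c0 * exp(-u),
                 c_minus = spec$c0 * exp(u)) |>
    structure(spec = spec, debye_length = debye_length(spec))
}
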