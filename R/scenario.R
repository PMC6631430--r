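#' Synthetic electro-osmotic flow scenario
#'
#' Bundles everything needed to manufacture a full synthetic observation:
#' the coating (through a parabolic-brush density model calibrated to the
#' grafting geometry), the electrolyte, the applied field, a planted
#' effective bead radius, and the velocity noise level. The seed fully
#' determines every stochastic output built from the scenario.
#'
#' The default brush height is twice the model gyration radius
#' [rg_scaling_model()] at the given `N`, capped at the half slit, and the
#' brush amplitude conserves the grafted bead count `(3N + 2)` per lattice
#' cell ([brush_amplitude()]).
#'
#' @param N Degree of polymerization.
#' @param a_bead Planted effective bead radius (nm).
#' @param Eext Applied field (V/nm).
#' @param noise_sd Standard deviation of i.i.d. Gaussian velocity noise
#'   (m/s, `>= 0`).
#' @param seed Integer seed governing the noise.
#' @param electrolyte An [electrolyte_spec()].
#' @param geometry A [coating_geometry()].
#' @param brush_height Brush height (nm); default `2 * rg_scaling_model(N)`.
#' @param n_grid Grid points across the slit.
#' @param hindrance Passed to [nsb_params()].
#'
#' @return An object of class `synthetic_scenario`.
#' @export
#' @examples
#' sc <- synthetic_scenario(N = 14, a_bead = 0.019, seed = 1)
synthetic_scenario <- function(N = 14, a_bead = 0.019, Eext = 1.6e-2,
                               noise_sd = 0, seed = 1L,
                               electrolyte = electrolyte_spec(),
                               geometry = coating_geometry(),
                               brush_height = NULL, n_grid = 1601L,
                               hindrance = "kim_russel") {
  stopifnot(noise_sd >= 0, n_grid >= 3L)
  brush_height <- brush_height %||%
    min(2 * rg_scaling_model(N), geometry$w / 2)
  structure(
    list(N = N, a_bead = a_bead, Eext = Eext, noise_sd = noise_sd,
         seed = as.integer(seed), electrolyte = electrolyte,
         geometry = geometry, brush_height = brush_height,
         n_grid = as.integer(n_grid), hindrance = hindrance),
    class = "synthetic_scenario"
  )
}

#' @exportS3Method base::print
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario>\n")
  cat(sprintf("  N = %g, planted a_bead = %g nm, Eext = %g V/nm\n",
              x$N, x$a_bead, x$Eext))
  cat(sprintf("  brush height = %.3g nm, noise sd = %g m/s, seed = %d\n",
              x$brush_height, x$noise_sd, x$seed))
  invisible(x)
}

#' @rdname synthetic_scenario
#' @param scenario A `synthetic_scenario`.
#' @return `scenario_params()`: the matching [nsb_params()].
#' @export
scenario_params <- function(scenario) {
  nsb_params(a_bead = scenario$a_bead, a0 = scenario$geometry$a0,
             Eext = scenario$Eext, w = scenario$geometry$w,
             hindrance = scenario$hindrance)
}

#' @rdname synthetic_scenario
#' @return `scenario_profiles()`: the assembled NSB coefficient table
#'   (see [assemble_nsb_profiles()]) for the scenario.
#' @export
scenario_profiles <- function(scenario) {
  geo <- scenario$geometry
  coverage <- (3 * scenario$N + 2) / geo$graft_a^2
  density <- parametric_density("parabolic_brush",
                                height = scenario$brush_height,
                                amplitude = brush_amplitude(coverage, scenario$brush_height),
                                w = geo$w, n_grid = scenario$n_grid)
  ions <- gouy_chapman_profiles(scenario$electrolyte, w = geo$w,
                                n_grid = scenario$n_grid)
  assemble_nsb_profiles(density, ions, scenario_params(scenario))
}

#' Forward-solve a synthetic velocity profile
#'
#' Runs the NSB solver with the scenario's planted bead radius and adds
#' i.i.d. Gaussian noise of standard deviation `noise_sd` under the
#' scenario seed. With `noise_sd = 0` the solver output is returned
#' unchanged (bit-identical), and the random number generator is not
#' touched.
#'
#' @param scenario A [synthetic_scenario()].
#' @param profiles Optional precomputed [scenario_profiles()] table.
#' @return A tibble with columns `z` (nm) and `u` (m/s).
#' @export
synthesize_velocity <- function(scenario, profiles = NULL) {
  profiles <- profiles %||% scenario_profiles(scenario)
  sol <- solve_nsb(profiles, scenario_params(scenario))
  if (scenario$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(scenario$seed)
    sol$u <- sol$u + rnorm(nrow(sol), mean = 0, sd = scenario$noise_sd)
  }
  sol
}

#' Reference end-to-end pipeline at N = 14
#'
#' Runs the whole analysis chain on synthetic data at the brush/mushroom
#' crossover (`N = 14`): grows a grafted coating, computes its
#' non-normalized RDF and gyration statistics, forward-solves the NSB
#' velocity profile with the planted bead radius, refits the radius from
#' that profile, and evaluates the far-bead shielding average with the
#' coating's exposed far-bead distribution on a parametric kernel.
#' Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param N Degree of polymerization.
#' @param a_bead Planted effective bead radius (nm).
#' @param n_chains_per_wall Chains per wall for the structural statistics.
#' @param n_grid Solver grid points.
#' @return A list with elements `scenario`, `coating`, `rdf`, `rdf_peaks`,
#'   `gyration`, `velocity`, `fit`, and `shielding`.
#' @export
demo_n14 <- function(seed = 1L, N = 14, a_bead = 0.019,
                     n_chains_per_wall = 9L, n_grid = 1201L) {
  scenario <- synthetic_scenario(N = N, a_bead = a_bead, seed = seed,
                                 n_grid = n_grid)
  coating <- generate_grafted_coating(N = N,
                                      n_chains_per_wall = n_chains_per_wall,
                                      geometry = scenario$geometry,
                                      seed = seed)
  rdf <- non_normalized_rdf(coating, r_max = 1, bin_width = 0.005,
                            r_min = 0.05)
  gyr <- chain_gyration(coating) |>
    dplyr::mutate(conformation = classify_conformation(
      .data$rg, scenario$geometry$graft_a))
  profiles <- scenario_profiles(scenario)
  velocity <- synthesize_velocity(scenario, profiles)
  fit <- fit_abead(velocity, profiles, scenario_params(scenario))
  nf <- exposed_far_beads(coating, reference_z = 1)
  kern <- parametric_kernel(a_near = 0.18 * scenario$geometry$a0)
  shielding <- effective_radius(kern, build_pfar(nf, kern),
                                a0 = scenario$geometry$a0)
  list(scenario = scenario, coating = coating, rdf = rdf,
       rdf_peaks = rdf_peaks(rdf), gyration = gyr, velocity = velocity,
       fit = fit, shielding = shielding)
}
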