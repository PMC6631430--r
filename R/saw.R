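#' Pivot-algorithm ensemble of free polymer chains
#'
#' Samples free (ungrafted) chains on the simple cubic lattice. With
#' excluded volume the sampler is the pivot algorithm for self-avoiding
#' walks: a random octahedral symmetry is applied to the chain segment
#' beyond a random pivot site and the move is accepted when the result is
#' self-avoiding. Configurations are recorded every `thin` accepted pivots
#' after discarding `equil_factor * N` accepted equilibration moves from a
#' rod start. With `excluded_volume = FALSE`, independent ideal random
#' walks are generated instead, whose gyration radius scales as
#' \eqn{N^{1/2}}.
#'
#' Gyration radii are reported in lattice (bond-length) units; the scaling
#' exponent is unit-free.
#'
#' @param N Chain lengths (beads), each `>= 10`.
#' @param n_samples Configurations recorded per chain length.
#' @param seed Optional integer seed.
#' @param excluded_volume Self-avoiding (`TRUE`) or ideal (`FALSE`) chains.
#' @param equil_factor Accepted equilibration pivots per bead.
#' @param thin Accepted pivots between recorded samples.
#'
#' @return A tibble with columns `N`, `sample`, `rg` (lattice units).
#' @seealso [scaling_exponent()] to estimate the gyration exponent.
#' @export
#' @examples
#' ens <- pivot_saw_ensemble(N = c(20, 40, 80), n_samples = 100, seed = 1)
#' scaling_exponent(ens)
pivot_saw_ensemble <- function(N, n_samples = 2000L, seed = NULL,
                               excluded_volume = TRUE, equil_factor = 10,
                               thin = 10L) {
  stopifnot(all(N >= 10), all(N == round(N)), n_samples >= 1,
            equil_factor >= 0, thin >= 1)
  if (any(N > 2000)) stop("chain lengths above 2000 beads are not supported")
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(as.integer(N), function(nn) {
    rg <- if (excluded_volume) {
      saw_pivot_rg_cpp(nn, as.integer(n_samples),
                       as.integer(ceiling(equil_factor * nn)),
                       as.integer(thin))
    } else {
      ideal_walk_rg_cpp(nn, as.integer(n_samples))
    }
    tibble::tibble(N = nn, sample = seq_along(rg), rg = rg)
  })
}
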