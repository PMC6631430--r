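# Shared fixtures built in code at test time.

small_scenario <- function(a_bead = 0.019, N = 14, n_grid = 401L,
                           seed = 1L, noise_sd = 0) {
  synthetic_scenario(N = N, a_bead = a_bead, seed = seed,
                     noise_sd = noise_sd, n_grid = n_grid)
}

# a random piecewise-constant NSB instance on [0, L] (three segments);
# segment boundaries sit on cell interfaces of the solver grid, where the
# conservative scheme represents coefficient jumps exactly
random_piecewise_instance <- function(L = 10, n_grid = 4001L) {
  h <- L / (n_grid - 1L)
  cuts <- sort(sample(floor(0.2 * n_grid):floor(0.8 * n_grid), 2L)) * h + h / 2
  breaks <- c(0, cuts, L)
  mu_seg <- runif(3L, 0.5e-3, 2e-3)
  n_seg <- c(runif(2L, 0, 3), 0) # outer segment polymer-free
  rho_seg <- runif(3L, -3e7, 3e7)
  a_bead <- runif(1L, 0.005, 0.1)
  list(breaks = breaks, mu_seg = mu_seg, n_seg = n_seg, rho_seg = rho_seg,
       a_bead = a_bead, Eext = 1.6e-2,
       profiles = piecewise_profiles(breaks, mu_seg, n_seg, rho_seg, n_grid),
       params = nsb_params(a_bead = a_bead, Eext = 1.6e-2, w = 2 * L,
                           hindrance = "none"))
}

.scale_a <- function(params, a) { params$a_bead <- a; params }

# synthetic drag table with the qualitative shape of a three-bead complex:
# central drag rising roughly linearly with theta
synthetic_drag_table <- function(n = 10L, mu = 0.85e-3) {
  theta <- seq(0, 90, length.out = n)
  tibble::tibble(
    theta_deg = theta,
    F_kJ_mol_nm = 0.04 + 0.6 * theta / 90,
    v_m_s = rep(1.2, n),
    mu_Pa_s = mu,
    role = "central"
  )
}
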