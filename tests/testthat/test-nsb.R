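test_that("volume fraction follows (4pi/3) a0^3 n and is linear in n", {
  d <- tibble::tibble(z = 0:2, n = c(0, 10, 20))
  phi <- volume_fraction(d, a0 = 0.156)
  expect_equal(phi$phi[1], 0)
  expect_equal(phi$phi[2], (4 * pi / 3) * 0.156^3 * 10)
  expect_equal(phi$phi[2], 0.159, tolerance = 2e-3)
  expect_equal(phi$phi[3], 2 * phi$phi[2])
  expect_error(volume_fraction(tibble::tibble(z = 0, n = -1), 0.156),
               "negative")
  expect_warning(volume_fraction(tibble::tibble(z = 0, n = 200), 0.156),
                 "close packing")
})

test_that("Einstein viscosity is mu0 (1 + 2.5 phi) and monotone", {
  p <- tibble::tibble(z = 0:2, phi = c(0, 0.1, 0.3))
  mu <- viscosity_profile(p, mu0 = 1e-3)
  expect_equal(mu$mu[1], 1e-3)
  expect_equal(mu$mu[2], 1.25e-3)
  expect_true(all(diff(mu$mu) > 0))
  expect_error(viscosity_profile(tibble::tibble(z = 0, phi = 1), 1e-3))
})

test_that("hindrance correction has unit dilute limit and increases", {
  expect_equal(hindrance_K(0), 1)
  expect_gt(hindrance_K(0.1), 1)
  expect_gt(hindrance_K(0.2), hindrance_K(0.1))
  phis <- seq(0, 0.64, by = 0.01)
  expect_true(all(diff(hindrance_K(phis)) > 0))
  expect_error(hindrance_K(0.7), "range")
  expect_equal(hindrance_K(c(0, 0.3), model = "none"), c(1, 1))
})

test_that("no driving force or no net charge gives zero flow", {
  sc <- small_scenario()
  pr <- scenario_profiles(sc)
  p0 <- scenario_params(sc); p0$Eext <- 0
  expect_true(all(solve_nsb(pr, p0)$u == 0))

  pr2 <- pr; pr2$rho_e <- 0
  expect_true(all(solve_nsb(pr2, scenario_params(sc))$u == 0))
})

test_that("solver matches the exact piecewise-constant oracle", {
  withr::with_seed(2024, {
    worst <- 0
    for (k in 1:20) {
      inst <- random_piecewise_instance()
      sol <- solve_nsb(inst$profiles, inst$params)
      half <- sol$z <= 10 + 1e-9
      u_ref <- oracle_nsb_piecewise(inst$breaks, inst$mu_seg, inst$n_seg,
                                    inst$rho_seg, inst$a_bead, inst$Eext,
                                    sol$z[half])
      scale <- max(abs(u_ref))
      if (scale == 0) next
      worst <- max(worst, max(abs(sol$u[half] - u_ref)) / scale)
    }
    expect_lt(worst, 1e-4)
  })
})

test_that("grid refinement converges at second order", {
  params <- nsb_params(a_bead = 0.05, w = 20)
  solve_at <- function(n_grid) {
    density <- parametric_density("gaussian_mushroom", height = 2,
                                  amplitude = 2, w = 20, n_grid = n_grid)
    ions <- gouy_chapman_profiles(electrolyte_spec(), w = 20,
                                  n_grid = n_grid)
    solve_nsb(assemble_nsb_profiles(density, ions, params), params)
  }
  ref <- solve_at(8001L)
  err_at <- function(n_grid) {
    sol <- solve_at(n_grid)
    stride <- 8000L / (n_grid - 1L)
    max(abs(sol$u - ref$u[seq(1, 8001, by = stride)])) / max(abs(ref$u))
  }
  e1 <- err_at(1001L)
  e2 <- err_at(2001L)
  expect_gt(e1 / e2, 2.5) # ~4x per halving for a second-order scheme
})

test_that("thin-double-layer polymer-free flow reaches the Helmholtz-Smoluchowski plateau", {
  spec <- electrolyte_spec(c0 = 0.1) # Debye length ~ 1 nm << w/2
  gc <- gouy_chapman_profiles(spec, w = 20, n_grid = 4001)
  zeta <- gc$psi[1]
  density <- tibble::tibble(z = gc$z, n = 0)
  params <- nsb_params(a_bead = 0.02, w = 20)
  prof <- assemble_nsb_profiles(density, gc, params)
  sol <- solve_nsb(prof, params)
  u_mid <- sol$u[which.min(abs(sol$z - 10))]
  u_hs <- -78 * 8.8541878128e-12 * zeta * (params$Eext * 1e9) / params$mu0
  expect_equal(u_mid, u_hs, tolerance = 0.05)
})

test_that("the flow is exactly linear in the applied field", {
  sc <- small_scenario()
  pr <- scenario_profiles(sc)
  p1 <- scenario_params(sc)
  p2 <- p1; p2$Eext <- 2 * p1$Eext
  expect_equal(solve_nsb(pr, p2)$u, 2 * solve_nsb(pr, p1)$u,
               tolerance = 1e-12)
})

test_that("mid-slit speed decreases with bead radius and coating density", {
  sc <- small_scenario()
  pr <- scenario_profiles(sc)
  base <- scenario_params(sc)
  mid_speed <- function(profiles, params) {
    sol <- solve_nsb(profiles, params)
    abs(sol$u[which.min(abs(sol$z - params$w / 2))])
  }
  speeds_a <- vapply(c(0.005, 0.019, 0.05, 0.1), function(a)
    mid_speed(pr, .scale_a(base, a)), 0)
  expect_true(all(diff(speeds_a) < 0))

  speeds_n <- vapply(c(0.5, 1, 2, 4), function(s) {
    pr2 <- pr
    pr2$n <- pr2$n * s
    pr2$phi <- pr2$phi * s
    pr2$mu <- base$mu0 * (1 + 2.5 * pr2$phi)
    mid_speed(pr2, base)
  }, 0)
  expect_true(all(diff(speeds_n) < 0))
})

test_that("degenerate solver inputs are rejected", {
  sc <- small_scenario()
  pr <- scenario_profiles(sc)
  bad <- pr; bad$mu[5] <- -1
  expect_error(solve_nsb(bad, scenario_params(sc)), "viscosity")
  bad2 <- pr[sample(nrow(pr)), ]
  expect_error(solve_nsb(bad2, scenario_params(sc)), "uniform")
})
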