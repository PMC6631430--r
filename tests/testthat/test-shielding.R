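test_that("the far-bead weight is separable and halves the sine integral", {
  kern <- parametric_kernel(a_near = 0.028, theta = seq(0, 90, by = 2),
                            dr = 0.02)
  nf <- tibble::tibble(r = c(0.3, 1, 2, 3), n_far = c(0.5, 2, 1, 0.2))
  pf <- build_pfar(nf, kern)
  expect_true(all(pf$p_far >= 0))
  # per-radius theta integral equals n_far(r) / 2
  per_r <- pf |>
    dplyr::group_by(r) |>
    dplyr::summarise(mass = {
      th <- theta * pi / 180
      sum(diff(th) * (p_far[-1] + p_far[-length(p_far)]) / 2)
    })
  nf_interp <- approx(nf$r, nf$n_far, xout = per_r$r, yleft = 0,
                      yright = 0)$y
  expect_equal(per_r$mass, nf_interp / 2, tolerance = 2e-4)

  expect_true(all(build_pfar(tibble::tibble(r = 1, n_far = 0), kern)$p_far == 0))
  expect_error(build_pfar(tibble::tibble(r = 1, n_far = -1), kern),
               "nonnegative")
})

test_that("zero far-bead weight returns the near-bead radius exactly", {
  a0 <- 0.156
  kern <- parametric_kernel(a_near = 0.18 * a0)
  pf <- build_pfar(tibble::tibble(r = numeric(), n_far = numeric()), kern)
  res <- effective_radius(kern, pf, a0 = a0)
  expect_identical(res$a_bead_nm, 0.18 * a0)
  expect_identical(res$a_bead_rel, 0.18)
})

test_that("a saturated kernel is insensitive to any weight", {
  a_near <- 0.03
  kern <- parametric_kernel(a_near = a_near, A = 0) # kernel == a_near
  expect_true(all(kern$a_bead == a_near))
  nf <- tibble::tibble(r = c(0.5, 1.5), n_far = c(0.3, 0.5))
  res <- effective_radius(kern, build_pfar(nf, kern), a0 = 0.156)
  expect_equal(res$a_bead_nm, a_near, tolerance = 1e-12)
})

test_that("a single-cell weight reproduces the hand quadrature", {
  a_near <- 0.03
  r_grid <- seq(0.3, 1.3, by = 0.1)
  th_grid <- seq(0, 90, by = 10)
  kern_tbl <- tidyr::expand_grid(r = r_grid, theta = th_grid) |>
    dplyr::mutate(a_bead = 0.01)
  kern <- brushflow:::new_shielding_kernel(kern_tbl, a_near = a_near,
                                           r0 = 0.3)
  # weight nonzero at one interior grid node (r*, theta*)
  wt <- tidyr::expand_grid(r = r_grid, theta = th_grid) |>
    dplyr::mutate(p_far = as.numeric(r == 0.8 & theta == 40))
  # trapezoid mass of a unit spike: dr * dtheta(rad)
  m <- 0.1 * (10 * pi / 180)
  res <- effective_radius(kern, wt, a0 = 0.156)
  expect_equal(res$a_bead_nm, a_near - m * (a_near - 0.01),
               tolerance = 1e-12)
  expect_equal(res$pfar_mass, m, tolerance = 1e-12)
})

test_that("the shielding deficit is additive over disjoint weights", {
  kern <- parametric_kernel(a_near = 0.028)
  r_grid <- sort(unique(kern$r))
  nf1 <- tibble::tibble(r = r_grid,
                        n_far = ifelse(r_grid < 1.5, 0.3, 0))
  nf2 <- tibble::tibble(r = r_grid,
                        n_far = ifelse(r_grid >= 1.5, 0.8, 0))
  nf12 <- tibble::tibble(r = r_grid, n_far = nf1$n_far + nf2$n_far)
  d1 <- effective_radius(kern, build_pfar(nf1, kern))$deficit_nm
  d2 <- effective_radius(kern, build_pfar(nf2, kern))$deficit_nm
  d12 <- effective_radius(kern, build_pfar(nf12, kern))$deficit_nm
  expect_equal(d12, d1 + d2, tolerance = 1e-12)
})

test_that("excess weight warns and extreme weight clamps at zero", {
  kern <- parametric_kernel(a_near = 0.028, A = 1)
  nf <- tibble::tibble(r = sort(unique(kern$r)), n_far = 10)
  w0 <- testthat::capture_warnings(
    res <- effective_radius(kern, build_pfar(nf, kern)))
  expect_match(w0, "additive", all = FALSE)
  nf2 <- tibble::tibble(r = sort(unique(kern$r)), n_far = 500)
  w <- testthat::capture_warnings(
    res2 <- effective_radius(kern, build_pfar(nf2, kern)))
  expect_match(w, "additive", all = FALSE)
  expect_match(w, "clamped", all = FALSE)
  expect_identical(res2$a_bead_nm, 0)
})

test_that("the parametric kernel family behaves as specified", {
  a_near <- 0.028
  expect_error(parametric_kernel(a_near, lambda = 0), "lambda")
  k0 <- parametric_kernel(a_near, A = 0)
  expect_true(all(k0$a_bead == a_near))
  k <- parametric_kernel(a_near, A = 0.8, lambda = 0.3, r_max = 0.3 + 20 * 0.3)
  # monotone increasing in r at every theta
  mono <- k |>
    dplyr::group_by(theta) |>
    dplyr::summarise(ok = all(diff(a_bead[order(r)]) >= 0))
  expect_true(all(mono$ok))
  # exponential tail: saturated to 1e-6 at r0 + 20 lambda
  far <- dplyr::filter(k, r == max(r))
  expect_true(all(abs(far$a_bead - a_near) < 1e-6 * a_near))
})

test_that("the shielding radius inverts the parametric kernel analytically", {
  a_near <- 0.03; A <- 0.9; lambda <- 0.25; tol <- 0.05
  g <- function(th) cos(th * pi / 360)
  kern <- parametric_kernel(a_near, A = A, lambda = lambda, r0 = 0.3,
                            r_max = 2.5, dr = 0.002,
                            theta = c(0, 30, 60, 90), g = g)
  rs <- shielding_radius(kern, tol = tol)
  r_exact <- 0.3 + lambda * log(A * g(rs$theta) / tol)
  expect_equal(rs$r_s, r_exact, tolerance = 0.01)
  # decreasing g: far beads perpendicular to the flow stop mattering sooner
  expect_true(all(diff(rs$r_s) <= 0))

  const <- parametric_kernel(a_near, A = 0)
  rs0 <- shielding_radius(const, tol = tol)
  expect_true(all(rs0$r_s == min(const$r)))

  slow <- parametric_kernel(a_near, A = 1, lambda = 50, r_max = 1)
  expect_warning(rs_bad <- shielding_radius(slow, tol = 0.01), "settle")
  expect_true(all(rs_bad$r_s == max(slow$r)))
})

test_that("quadrature refinement leaves the shielded radius unchanged", {
  a_near <- 0.028
  nf_fun <- function(r) 1.5 * exp(-(r - 0.3) / 0.5)
  res_at <- function(dr, dth) {
    kern <- parametric_kernel(a_near, dr = dr,
                              theta = seq(0, 90, by = dth))
    nf <- tibble::tibble(r = sort(unique(kern$r)),
                         n_far = nf_fun(sort(unique(kern$r))))
    effective_radius(kern, build_pfar(nf, kern))$a_bead_nm
  }
  coarse <- res_at(0.02, 2)
  fine <- res_at(0.01, 1)
  expect_lt(abs(coarse - fine) / fine, 1e-4)
})

test_that("radius vs N decreases when far beads accumulate", {
  kern <- parametric_kernel(a_near = 0.028)
  r_grid <- sort(unique(kern$r))
  tab <- purrr::map_dfr(c(2, 8, 14, 20), function(nn) {
    tibble::tibble(N = nn, r = r_grid,
                   n_far = 0.1 * nn * exp(-(r_grid - 0.3)))
  })
  res <- radius_vs_N(kern, tab)
  expect_equal(nrow(res), 4L)
  expect_true(all(diff(res$a_bead_nm) < 0))
  expect_true(attr(res, "monotone_nonincreasing"))

  same <- purrr::map_dfr(c(5, 10), function(nn)
    tibble::tibble(N = nn, r = r_grid, n_far = 0.2))
  res2 <- radius_vs_N(kern, same)
  expect_equal(res2$a_bead_nm[1], res2$a_bead_nm[2])

  # two-N case against directly composed quadratures
  direct <- vapply(c(5, 10), function(nn) {
    nf <- dplyr::filter(same, N == nn)
    effective_radius(kern, build_pfar(nf, kern))$a_bead_nm
  }, 0)
  expect_equal(res2$a_bead_nm, direct)
})

test_that("kernel CSV round trip preserves the table", {
  kern <- parametric_kernel(a_near = 0.03, dr = 0.25, theta = c(0, 45, 90))
  path <- withr::local_tempfile(fileext = ".csv")
  write_kernel_csv(kern, path)
  back <- read_kernel_csv(path, a_near = 0.03, r0 = 0.3)
  expect_equal(back$a_bead, kern$a_bead, tolerance = 1e-6)
  expect_equal(attr(back, "a_near"), 0.03)
})
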