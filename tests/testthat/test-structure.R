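test_that("a single bonded pair fills exactly one RDF bin at the bond length", {
  beads <- tibble::tibble(x = c(0, 0.15), y = 0, z = 1)
  rdf <- non_normalized_rdf(beads, r_max = 0.5, bin_width = 0.01)
  nz <- which(rdf$g > 0)
  expect_length(nz, 1L)
  expect_lt(abs(rdf$r[nz] - 0.15), 0.01)
})

test_that("RDF pair counts are conserved against a brute-force histogram", {
  withr::with_seed(31, {
    xyz <- cbind(runif(120, 0, 5), runif(120, 0, 5), runif(120, 0, 5))
  })
  df <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  rdf <- non_normalized_rdf(df, r_max = 2, bin_width = 0.1,
                            box = c(5, 5, 5))
  ref <- oracle_pair_hist(xyz, 5, 5, 0, 2, 20)
  counts_back <- rdf$g * nrow(df) * 4 * pi * rdf$r^2 * 0.1 / 2
  expect_equal(counts_back, ref, tolerance = 1e-9)
})

test_that("an ideal-gas configuration gives a flat RDF at its density", {
  withr::with_seed(8, {
    n_pts <- 500; L <- 10
    df <- tibble::tibble(x = runif(n_pts, 0, L), y = runif(n_pts, 0, L),
                         z = runif(n_pts, 0, L))
  })
  rho <- n_pts / L^3
  rdf <- non_normalized_rdf(df, r_max = 1.2, bin_width = 0.1, r_min = 0.2,
                            box = c(L, L, L))
  # periodic in x, y only; z shells truncated near the boundaries reduce
  # counts slightly, so compare the plateau mean loosely
  expect_equal(mean(rdf$g), rho, tolerance = 0.15)
  expect_lt(sd(rdf$g) / mean(rdf$g), 0.25)
})

test_that("coating RDF peaks first at the bond length", {
  cfg <- generate_grafted_coating(N = 6, n_chains_per_wall = 6, seed = 21)
  rdf <- non_normalized_rdf(cfg, r_max = 1, bin_width = 0.005, r_min = 0.05)
  pk <- rdf_peaks(rdf)
  expect_lt(abs(pk$r[1] - cfg$geometry$bond_b), 0.005)
  # second peak at the next-nearest intra-chain separation 2b sin(54.75 deg)
  expect_lt(abs(pk$r[2] - 2 * 0.15 * sin(54.75 * pi / 180)), 0.01)
})

test_that("aligned neighbour displacements give all mass at theta = 0", {
  beads <- tibble::tibble(x = seq(0, 1.5, by = 0.15), y = 2, z = 2)
  od <- orientation_distribution(beads, r = 0.15, tol = 0.01, plane = "xz",
                                 bins = 9, slab_half_width = 0.078)
  # both pair directions are histogrammed, so the mass sits at 0 and 180
  expect_gt(od$f[1], 0)
  expect_equal(od$f[1], od$f[9])
  expect_true(all(od$f[2:8] == 0))
  expect_equal(mean(od$f), 1) # normalization is exact by construction
})

test_that("isotropic neighbour directions give a flat orientation distribution", {
  withr::with_seed(12, {
    n_dir <- 8000
    v <- matrix(rnorm(3 * n_dir), ncol = 3)
    v <- 0.15 * v / sqrt(rowSums(v^2))
  })
  # isolated two-bead pairs with isotropic separations
  centers <- 1e3 * seq_len(n_dir)
  beads <- tibble::tibble(
    x = c(centers, centers + v[, 1]),
    y = c(rep(0, n_dir), v[, 2]),
    z = c(rep(0, n_dir), v[, 3]))
  od <- orientation_distribution(beads, r = 0.15, tol = 0.01, plane = "xz",
                                 bins = 8, slab_half_width = 0.078)
  expect_true(all(abs(od$f - 1) < 0.05))
})

test_that("exposure flags match the exhaustive O(n^3) oracle", {
  # trivial cases first
  two <- tibble::tibble(x = c(0, 1), y = 0, z = 0)
  expect_true(exposed_pairs(two, d_occ = 0.3)$exposed)
  blocked <- tibble::tibble(x = c(0, 1, 0.5), y = c(0, 0, 0), z = 0)
  ep <- exposed_pairs(blocked, d_occ = 0.3)
  on_segment <- ep$i == 1 & ep$j == 2
  expect_false(ep$exposed[on_segment])

  withr::with_seed(77, {
    xyz <- cbind(runif(50, 0, 2), runif(50, 0, 2), runif(50, 0, 2))
  })
  df <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  # under periodic images the segment test is well-posed for r < box/2
  got <- exposed_pairs(df, d_occ = 0.31, r_max = 0.9, box = c(2, 2, 10))
  ref <- mapply(function(i, j) oracle_exposed(xyz, i, j, 0.31, c(2, 2)),
                got$i, got$j)
  expect_equal(got$exposed, unname(ref))

  # symmetry: the flag does not depend on the pair order
  got_rev <- mapply(function(i, j) oracle_exposed(xyz, j, i, 0.31, c(2, 2)),
                    got$i, got$j)
  expect_equal(unname(ref), unname(got_rev))
})

test_that("far-bead counts respond to occlusion and slab selection", {
  # two exposed far beads around a reference at z = 1
  beads <- tibble::tibble(
    x = c(0, 0.6, -0.6, 0.3),
    y = c(0, 0, 0, 0),
    z = c(1, 1, 1, 1))
  cfg <- structure(list(
    beads = dplyr::mutate(beads, chain = 1L, bead = dplyr::row_number(),
                          wall = 1L),
    box = c(100, 100, 20), wall_z = c(0, 20),
    geometry = coating_geometry(), N = 1L, n_chains = 1L),
    class = "coating_config")
  nf <- exposed_far_beads(cfg, reference_z = 1, slab_half_width = 0.05,
                          r_max = 1, bin_width = 0.1, r0 = 0.3)
  # bead 4 occludes the (1,2) line of sight; pairs (1,3), (2,3) blocked by 1?
  # just check totals against the exposure table
  ep <- exposed_pairs(cfg, r_min = 0.3, r_max = 1)
  expect_equal(sum(nf$n_far) * attr(nf, "n_ref"), 2 * sum(ep$exposed))
  expect_error(exposed_far_beads(cfg, reference_z = 15), "reference")
})

test_that("gyration radius handles degenerate and dumbbell geometries", {
  same <- tibble::tibble(x = rep(1, 4), y = 2, z = 3)
  expect_equal(gyration_radius(same), 0)
  pair <- tibble::tibble(x = c(0, 1), y = 0, z = 0)
  expect_equal(gyration_radius(pair), 0.5)
})

test_that("scaling exponent is exact on noiseless power laws", {
  N <- c(5, 10, 14, 20, 30, 40)
  dat <- tibble::tibble(N = N, rg = 0.45 * N^0.65)
  fit <- scaling_exponent(dat)
  expect_equal(fit$gamma, 0.65, tolerance = 1e-10)
  expect_equal(fit$prefactor, 0.45, tolerance = 1e-10)
  expect_error(scaling_exponent(dat[1:2, ]), "three")
})

test_that("planted-exponent ensembles recover gamma = 0.65 under noise", {
  N <- c(5, 10, 14, 20, 30, 40)
  withr::with_seed(99, {
    gammas <- vapply(1:20, function(k) {
      rg <- rg_scaling_model(N) * exp(rnorm(length(N), 0, 0.02))
      scaling_exponent(tibble::tibble(N = N, rg = rg))$gamma
    }, 0)
  })
  expect_lt(abs(mean(gammas) - 0.65), 0.01)
})

test_that("conformation classification flips at the calibrated crossover", {
  expect_equal(classify_conformation(1, 2.5), "mushroom")
  expect_equal(classify_conformation(3, 2.5), "brush")
  expect_equal(classify_conformation(2.5, 2.5), "crossover")
  # with Rg(N) calibrated so Rg(14) = 2.5 nm the flip happens at N = 14
  cls <- classify_conformation(rg_scaling_model(c(10, 13, 14, 15, 20)), 2.5)
  expect_equal(cls, c("mushroom", "mushroom", "crossover", "brush", "brush"))
})

test_that("chain gyration summarises every chain of a coating", {
  cfg <- generate_grafted_coating(N = 4, n_chains_per_wall = 3, seed = 15)
  gy <- chain_gyration(cfg)
  expect_equal(nrow(gy), cfg$n_chains)
  expect_true(all(gy$n_beads == 14))
  expect_true(all(gy$rg > 0))
})
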