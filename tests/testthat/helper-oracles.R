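# Independent oracles used to cross-check the package implementations.
# They deliberately avoid the code paths they verify.

# --- exact transfer-matrix solution of the NSB balance with
# --- piecewise-constant coefficients: d/dz(mu u') - beta u + f = 0,
# --- u(0) = 0, u'(L) = 0. All lengths in nm here, SI internally.
oracle_nsb_piecewise <- function(breaks, mu_seg, n_seg, rho_seg, a_bead,
                                 Eext, z_eval) {
  nm <- 1e-9
  S <- length(mu_seg)
  stopifnot(length(breaks) == S + 1L)
  beta <- 6 * pi * mu_seg * (n_seg * 1e27) * (a_bead * nm)
  f <- rho_seg * Eext * 1e9

  prop <- function(state, mu, bet, ff, d) { # d in metres
    if (bet > 0) {
      kap <- sqrt(bet / mu)
      up <- ff / bet
      ch <- cosh(kap * d); sh <- sinh(kap * d)
      c(up + (state[1L] - up) * ch + state[2L] / (mu * kap) * sh,
        (state[1L] - up) * mu * kap * sh + state[2L] * ch)
    } else {
      c(state[1L] + (state[2L] * d - ff * d^2 / 2) / mu,
        state[2L] - ff * d)
    }
  }

  # states at the start of each segment for the particular (forced, u=q=0
  # at 0) and homogeneous (unforced, u=0, q=1 at 0) solutions
  starts_p <- matrix(0, nrow = S + 1L, ncol = 2L)
  starts_h <- matrix(0, nrow = S + 1L, ncol = 2L); starts_h[1L, 2L] <- 1
  for (k in seq_len(S)) {
    d <- (breaks[k + 1L] - breaks[k]) * nm
    starts_p[k + 1L, ] <- prop(starts_p[k, ], mu_seg[k], beta[k], f[k], d)
    starts_h[k + 1L, ] <- prop(starts_h[k, ], mu_seg[k], beta[k], 0, d)
  }
  cc <- -starts_p[S + 1L, 2L] / starts_h[S + 1L, 2L]

  vapply(z_eval, function(z) {
    k <- findInterval(z, breaks, rightmost.closed = TRUE)
    k <- min(max(k, 1L), S)
    d <- (z - breaks[k]) * nm
    up <- prop(starts_p[k, ], mu_seg[k], beta[k], f[k], d)[1L]
    uh <- prop(starts_h[k, ], mu_seg[k], beta[k], 0, d)[1L]
    up + cc * uh
  }, 0)
}

# profile table for a piecewise-constant instance on a uniform grid over
# [0, L]; grid nodes exactly on a break take the right segment's value
piecewise_profiles <- function(breaks, mu_seg, n_seg, rho_seg, n_grid) {
  L <- breaks[length(breaks)]
  z <- seq(0, L, length.out = n_grid)
  k <- pmin(pmax(findInterval(z, breaks, rightmost.closed = TRUE), 1L),
            length(mu_seg))
  tibble::tibble(z = z, n = n_seg[k], phi = 0, mu = mu_seg[k],
                 rho_e = rho_seg[k])
}

# --- brute-force O(n^2) pair histogram (no binning tricks)
oracle_pair_hist <- function(xyz, Lx = NULL, Ly = NULL, r_min, r_max,
                             nbins) {
  n <- nrow(xyz)
  db <- (r_max - r_min) / nbins
  counts <- numeric(nbins)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- xyz[j, 1L] - xyz[i, 1L]
      dy <- xyz[j, 2L] - xyz[i, 2L]
      dz <- xyz[j, 3L] - xyz[i, 3L]
      if (!is.null(Lx)) dx <- dx - Lx * round(dx / Lx)
      if (!is.null(Ly)) dy <- dy - Ly * round(dy / Ly)
      d <- sqrt(dx^2 + dy^2 + dz^2)
      if (d < r_min || d >= r_max) next
      b <- min(nbins, floor((d - r_min) / db) + 1L)
      counts[b] <- counts[b] + 1
    }
  }
  counts
}

# --- O(n^3) exhaustive line-of-sight exposure test
oracle_exposed <- function(xyz, i, j, d_occ, box = NULL) {
  mi <- function(v) {
    if (!is.null(box)) {
      v[1L] <- v[1L] - box[1L] * round(v[1L] / box[1L])
      v[2L] <- v[2L] - box[2L] * round(v[2L] / box[2L])
    }
    v
  }
  vij <- mi(xyz[j, ] - xyz[i, ])
  r2 <- sum(vij^2)
  for (k in seq_len(nrow(xyz))) {
    if (k == i || k == j) next
    vik <- mi(xyz[k, ] - xyz[i, ])
    t <- sum(vik * vij) / r2
    if (t <= 0 || t >= 1) next
    perp2 <- sum(vik^2) - t^2 * r2
    if (perp2 < d_occ^2) return(FALSE)
  }
  TRUE
}

# --- dense trapezoid quadrature of the linear interpolant of (x, y)
oracle_dense_quad <- function(x, y, n_fine = 20001L) {
  xf <- seq(min(x), max(x), length.out = n_fine)
  yf <- approx(x, y, xout = xf)$y
  sum(diff(xf) * (yf[-1L] + yf[-n_fine]) / 2)
}

# --- brute-force grid search for the bead-radius fit
oracle_grid_search_abead <- function(observed, profiles, params, bounds,
                                     n_grid = 50L) {
  grid <- seq(bounds[1L], bounds[2L], length.out = n_grid)
  sse <- vapply(grid, function(a) {
    p <- params; p$a_bead <- a
    sol <- solve_nsb(profiles, p)
    keep <- sol$z <= params$w / 2 + 1e-9
    u_obs <- approx(observed$z, observed$u, xout = sol$z, rule = 2)$y
    sum((sol$u[keep] - u_obs[keep])^2)
  }, 0)
  list(a = grid[which.min(sse)], step = diff(grid)[1L])
}
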