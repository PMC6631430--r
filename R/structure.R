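.coords_and_box <- function(x, box = NULL) {
  if (inherits(x, "coating_config")) {
    list(xyz = as.matrix(x$beads[, c("x", "y", "z")]),
         box = x$box, a0 = x$geometry$a0)
  } else {
    df <- tibble::as_tibble(x)
    stopifnot(all(c("x", "y", "z") %in% names(df)))
    list(xyz = as.matrix(df[, c("x", "y", "z")]), box = box, a0 = NULL)
  }
}

#' Non-normalized radial distribution function
#'
#' Histogram of all bead-bead pair distances (minimum image in the
#' periodic `x`, `y` directions), divided by the number of reference beads
#' and the shell volume \eqn{4\pi r^2 \Delta r} -- but *not* by a bulk
#' density, which is ill-defined for the strongly inhomogeneous bead
#' distribution of a grafted coating. Units are therefore beads/nm^3.
#'
#' @param x A `coating_config`, or a data frame of coordinates with
#'   columns `x`, `y`, `z`.
#' @param r_max Histogram upper edge (nm).
#' @param bin_width Bin width (nm, `> 0`).
#' @param r_min Histogram lower edge (nm).
#' @param box Optional `c(Lx, Ly, Lz)` for plain coordinate input;
#'   `NULL` disables the minimum-image convention.
#'
#' @return A tibble with columns `r` (bin centres, nm) and `g`
#'   (beads/nm^3), with attributes `normalization = "non-normalized"` and
#'   `bin_width`. See [rdf_peaks()] for peak locations.
#' @export
non_normalized_rdf <- function(x, r_max = 1, bin_width = 0.005, r_min = 0,
                               box = NULL) {
  if (bin_width <= 0) stop("bin width must be positive")
  cb <- .coords_and_box(x, box)
  if (nrow(cb$xyz) < 2L) stop("need at least two beads")
  nbins <- as.integer(round((r_max - r_min) / bin_width))
  counts <- pair_dist_hist_cpp(cb$xyz,
                               if (is.null(cb$box)) -1 else cb$box[1L],
                               if (is.null(cb$box)) -1 else cb$box[2L],
                               !is.null(cb$box), r_min, r_max, nbins)
  r <- r_min + (seq_len(nbins) - 0.5) * bin_width
  n_ref <- nrow(cb$xyz)
  g <- 2 * counts / (n_ref * 4 * pi * r^2 * bin_width)
  structure(tibble::tibble(r = r, g = g),
            normalization = "non-normalized", bin_width = bin_width)
}

#' Peak locations of a radial distribution function
#'
#' @param rdf Output of [non_normalized_rdf()].
#' @param n_peaks Number of leading local maxima to report.
#' @return A tibble with columns `rank`, `r`, `g`, ordered by increasing
#'   `r`.
#' @export
rdf_peaks <- function(rdf, n_peaks = 2L) {
  g <- rdf$g
  n <- length(g)
  is_peak <- g > 0 &
    g >= c(-Inf, g[-n]) & g >= c(g[-1L], -Inf) &
    (g > c(-Inf, g[-n]) | g > c(g[-1L], -Inf))
  peaks <- which(is_peak)
  peaks <- peaks[seq_len(min(n_peaks, length(peaks)))]
  tibble::tibble(rank = seq_along(peaks), r = rdf$r[peaks], g = g[peaks])
}

#' Planar orientation distribution of bead neighbours
#'
#' For every bead, takes the directions to neighbours at shell distance
#' `|d - r| <= tol`, keeps those whose out-of-plane offset is within a slab
#' of half-width `slab_half_width`, projects them into the chosen plane and
#' histograms the angle to the flow direction (`+x`), folded to
#' `[0, 180]` degrees. The distribution is normalized by its mean, so a
#' structureless coating gives `f = 1` in every bin.
#'
#' @param x A `coating_config` or coordinate data frame.
#' @param r Shell radius (nm, `> 0`).
#' @param tol Shell half-thickness (nm).
#' @param plane `"xz"` (perpendicular to the walls) or `"xy"` (parallel).
#' @param bins Number of angular bins on `[0, 180]`.
#' @param slab_half_width Out-of-plane slab half-width (nm); defaults to
#'   `0.5 * a0` for a `coating_config`.
#' @param box As in [non_normalized_rdf()].
#' @return A tibble with columns `theta` (bin centres, degrees) and `f`
#'   (mean-normalized surface density); attribute `n_pairs` records the
#'   number of contributing neighbour directions.
#' @export
orientation_distribution <- function(x, r = 0.15, tol = 0.02,
                                     plane = c("xz", "xy"), bins = 12L,
                                     slab_half_width = NULL, box = NULL) {
  plane <- match.arg(plane)
  if (r <= 0) stop("shell radius must be positive")
  cb <- .coords_and_box(x, box)
  slab_half_width <- slab_half_width %||%
    (if (!is.null(cb$a0)) 0.5 * cb$a0 else stop("slab_half_width required"))
  pd <- pair_disp_cpp(cb$xyz,
                      if (is.null(cb$box)) -1 else cb$box[1L],
                      if (is.null(cb$box)) -1 else cb$box[2L],
                      !is.null(cb$box), max(0, r - tol), r + tol)
  # both directions of every unordered pair
  disp <- rbind(pd[, c("dx", "dy", "dz"), drop = FALSE],
                -pd[, c("dx", "dy", "dz"), drop = FALSE])
  out_axis <- if (plane == "xz") 2L else 3L # y for (x,z), z for (x,y)
  in_axis <- if (plane == "xz") 3L else 2L
  keep <- abs(disp[, out_axis]) <= slab_half_width
  disp <- disp[keep, , drop = FALSE]
  edges <- seq(0, 180, length.out = bins + 1L)
  centres <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  if (nrow(disp) == 0L) {
    warning("no neighbours found in the shell: empty distribution")
    return(structure(tibble::tibble(theta = centres, f = NA_real_),
                     plane = plane, r = r, n_pairs = 0L))
  }
  px <- disp[, 1L]; py <- disp[, in_axis]
  theta <- acos(pmin(1, pmax(-1, px / sqrt(px^2 + py^2)))) * 180 / pi
  idx <- pmin(bins, pmax(1L, ceiling(theta / 180 * bins)))
  counts <- tabulate(idx, nbins = bins)
  structure(tibble::tibble(theta = centres, f = counts / mean(counts)),
            plane = plane, r = r, n_pairs = nrow(disp))
}

# Is the segment between beads i and j (displacement vij from i) free of
# occluding beads? occ: matrix of displacements from i to candidate
# occluders. Blocked when a bead's perpendicular distance to the open
# segment is below d_occ with its projection strictly inside the segment.
.segment_exposed <- function(vij, occ, d_occ) {
  if (is.null(occ) || nrow(occ) == 0L) return(TRUE)
  r2 <- sum(vij^2)
  t <- (occ %*% vij) / r2
  perp2 <- rowSums(occ^2) - t^2 * r2
  !any(t > 0 & t < 1 & perp2 < d_occ^2)
}

#' Pairwise line-of-sight exposure between beads
#'
#' A pair of beads is *exposed* when no third bead lies within a bead
#' diameter of the open segment joining them (perpendicular distance below
#' `d_occ` with the projection strictly between the endpoints). The test
#' is symmetric in the pair.
#'
#' @param x A `coating_config` or coordinate data frame.
#' @param d_occ Occlusion diameter (nm); defaults to `2 * a0` for a
#'   `coating_config`.
#' @param r_min,r_max Only pairs with distance in `[r_min, r_max]` are
#'   examined; under a periodic box keep `r_max` below half the box side,
#'   where the minimum-image segment is well defined.
#' @param box As in [non_normalized_rdf()].
#' @return A tibble with columns `i`, `j`, `r`, `exposed`.
#' @export
exposed_pairs <- function(x, d_occ = NULL, r_min = 0, r_max = Inf,
                          box = NULL) {
  cb <- .coords_and_box(x, box)
  d_occ <- d_occ %||%
    (if (!is.null(cb$a0)) 2 * cb$a0 else stop("d_occ required"))
  n <- nrow(cb$xyz)
  if (n < 2L) stop("need at least two beads")
  r_hi <- if (is.finite(r_max)) r_max else
    sqrt(sum((apply(cb$xyz, 2L, max) - apply(cb$xyz, 2L, min))^2))
  pd <- pair_disp_cpp(cb$xyz,
                      if (is.null(cb$box)) -1 else cb$box[1L],
                      if (is.null(cb$box)) -1 else cb$box[2L],
                      !is.null(cb$box), r_min, r_hi)
  if (nrow(pd) == 0L) {
    return(tibble::tibble(i = integer(), j = integer(),
                          r = numeric(), exposed = logical()))
  }
  # displacements from every bead to all others (for occluder lookups)
  exposed <- logical(nrow(pd))
  for (k in seq_len(nrow(pd))) {
    i <- pd[k, "i"]; j <- pd[k, "j"]
    vij <- pd[k, c("dx", "dy", "dz")]
    occ <- .displacements_from(cb$xyz, i, cb$box)
    occ <- occ[-c(i, j), , drop = FALSE]
    exposed[k] <- .segment_exposed(vij, occ, d_occ)
  }
  tibble::tibble(i = as.integer(pd[, "i"]), j = as.integer(pd[, "j"]),
                 r = pd[, "r"], exposed = exposed)
}

# displacements from bead i to all beads (minimum image in x, y when a box
# is given); row i is zero
.displacements_from <- function(xyz, i, box = NULL) {
  d <- sweep(xyz, 2L, xyz[i, ])
  if (!is.null(box)) {
    for (ax in 1:2) {
      L <- box[ax]
      d[, ax] <- d[, ax] - L * round(d[, ax] / L)
    }
  }
  d
}

#' Exposed far-bead distribution
#'
#' The mean number of *far* beads (pair distance beyond the near/far split
#' `r0`) directly exposed to a reference bead, as a function of pair
#' distance. Reference beads are those in a slab around `reference_z`;
#' every bead of the configuration can occlude. See [exposed_pairs()] for
#' the line-of-sight criterion.
#'
#' @param config A `coating_config`.
#' @param reference_z Height of the reference slab above the bottom wall
#'   (nm).
#' @param slab_half_width Half-width of the reference slab (nm).
#' @param r_max Largest pair distance considered (nm).
#' @param bin_width Distance bin width (nm).
#' @param r0 Near/far split distance (nm).
#' @param d_occ Occlusion diameter (nm); default `2 * a0`.
#' @return A tibble with columns `r` (bin centres) and `n_far` (exposed
#'   far beads per reference bead per bin), with attributes `n_ref`,
#'   `reference_z`, `d_occ` and `N`.
#' @export
exposed_far_beads <- function(config, reference_z = 1,
                              slab_half_width = 0.25, r_max = 1.5,
                              bin_width = 0.05, r0 = 0.3, d_occ = NULL) {
  stopifnot(inherits(config, "coating_config"), bin_width > 0,
            r_max > r0)
  xyz <- as.matrix(config$beads[, c("x", "y", "z")])
  d_occ <- d_occ %||% (2 * config$geometry$a0)
  refs <- which(abs(xyz[, 3L] - reference_z) <= slab_half_width)
  if (length(refs) == 0L) stop("no reference beads in the slab")
  # occluders can only matter within r_max + d_occ of a reference bead
  nbins <- as.integer(round((r_max - r0) / bin_width))
  counts <- numeric(nbins)
  for (i in refs) {
    d <- .displacements_from(xyz, i, config$box)
    rr <- sqrt(rowSums(d^2))
    cand <- which(rr >= r0 & rr <= r_max & seq_len(nrow(xyz)) != i)
    if (!length(cand)) next
    occ_rows <- which(rr < r_max + d_occ & seq_len(nrow(xyz)) != i)
    for (j in cand) {
      occ <- d[setdiff(occ_rows, j), , drop = FALSE]
      if (.segment_exposed(d[j, ], occ, d_occ)) {
        b <- min(nbins, max(1L, ceiling((rr[j] - r0) / bin_width)))
        counts[b] <- counts[b] + 1
      }
    }
  }
  structure(
    tibble::tibble(r = r0 + (seq_len(nbins) - 0.5) * bin_width,
                   n_far = counts / length(refs)),
    n_ref = length(refs), reference_z = reference_z, d_occ = d_occ,
    N = config$N)
}

#' Gyration radius of a set of beads
#'
#' \eqn{R_g^2} is the mean squared distance of the beads from their
#' centroid.
#'
#' @param coords Data frame with columns `x`, `y`, `z` (nm), at least two
#'   rows.
#' @return `R_g` in nm.
#' @export
#' @examples
#' gyration_radius(data.frame(x = c(0, 1), y = 0, z = 0))  # 0.5
gyration_radius <- function(coords) {
  stopifnot(all(c("x", "y", "z") %in% names(coords)))
  m <- as.matrix(coords[, c("x", "y", "z")])
  if (nrow(m) < 2L) stop("need at least two beads")
  ctr <- colMeans(m)
  sqrt(mean(rowSums(sweep(m, 2L, ctr)^2)))
}

#' Per-chain gyration radii of a coating
#'
#' @param config A `coating_config`.
#' @return A tibble with columns `chain`, `wall`, `n_beads`, `rg`.
#' @export
chain_gyration <- function(config) {
  config$beads |>
    dplyr::group_by(.data$chain, .data$wall) |>
    dplyr::summarise(
      n_beads = dplyr::n(),
      rg = gyration_radius(dplyr::pick(dplyr::everything())),
      .groups = "drop")
}

#' Gyration-radius scaling exponent
#'
#' Least-squares slope of `log(Rg)` against `log(N)`; replicate rows at
#' the same `N` are averaged before fitting. On noiseless power-law data
#' the estimate is exact.
#'
#' @param data Data frame with columns `N` and `rg`.
#' @return A one-row tibble with `gamma`, `gamma_se`, `prefactor`
#'   (the fitted `Rg` at `N = 1`), `r_squared` and `n_levels`.
#' @export
scaling_exponent <- function(data) {
  stopifnot(all(c("N", "rg") %in% names(data)))
  means <- tibble::as_tibble(data) |>
    dplyr::group_by(.data$N) |>
    dplyr::summarise(rg = mean(.data$rg), .groups = "drop")
  if (nrow(means) < 3L) {
    stop("need at least three distinct N values for a scaling fit")
  }
  if (any(means$rg <= 0) || any(means$N <= 0)) stop("N and rg must be positive")
  fit <- lm(log(rg) ~ log(N), data = means)
  s <- suppressWarnings(summary(fit)) # exact power laws fit perfectly
  tibble::tibble(gamma = unname(coef(fit)[2L]),
                 gamma_se = s$coefficients[2L, 2L],
                 prefactor = exp(unname(coef(fit)[1L])),
                 r_squared = s$r.squared,
                 n_levels = nrow(means))
}

#' Classify a grafted chain as mushroom or brush
#'
#' Mushroom when the gyration radius is below the grafting separation,
#' brush when above, `"crossover"` at equality.
#'
#' @param rg Gyration radius (nm), vectorized.
#' @param graft_a Grafting lattice constant (nm).
#' @return Character vector of `"mushroom"`, `"brush"` or `"crossover"`.
#' @export
#' @examples
#' classify_conformation(c(1, 3), graft_a = 2.5)
classify_conformation <- function(rg, graft_a) {
  stopifnot(all(rg > 0), graft_a > 0)
  dplyr::case_when(rg > graft_a ~ "brush",
                   rg < graft_a ~ "mushroom",
                   TRUE ~ "crossover")
}
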