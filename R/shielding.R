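#' Parametric far-bead shielding kernel
#'
#' Fixture family for the tabulated central-bead hydrodynamic radius
#' \eqn{a_{bead}(r, \theta_{far})} of a three-bead complex flanked by two
#' far beads at distance `r` and orientation `theta_far`:
#' \deqn{a(r,\theta) = a^{near} [1 - A\, e^{-(r - r_0)/\lambda} g(\theta)],}
#' clipped at zero. The kernel rises with `r` and saturates at the
#' near-bead radius `a_near`; a decreasing angular profile `g` makes far
#' beads perpendicular to the flow less effective, so the shielding radius
#' shrinks with `theta`.
#'
#' @param a_near Near-bead saturation radius (nm, `> 0`).
#' @param A Shielding depth in `[0, 1]`.
#' @param lambda Radial decay length (nm, `> 0`).
#' @param r0 Near/far split radius (nm); the grid starts here.
#' @param r_max Largest tabulated `r` (nm).
#' @param dr Radial grid step (nm).
#' @param theta Orientation grid (degrees, covering `[0, 90]`).
#' @param g Angular profile, a function of degrees decreasing on
#'   `[0, 90]`; default `cos(theta / 2)`.
#'
#' @return A `shielding_kernel`: tibble with columns `r`, `theta`,
#'   `a_bead` (nm) and attributes `a_near` and `r0`.
#' @export
#' @examples
#' kern <- parametric_kernel(a_near = 0.028)
parametric_kernel <- function(a_near, A = 0.8, lambda = 0.3, r0 = 0.3,
                              r_max = 3, dr = 0.05,
                              theta = seq(0, 90, by = 5), g = NULL) {
  if (lambda <= 0) stop("decay length lambda must be positive")
  stopifnot(a_near > 0, A >= 0, A <= 1, r_max > r0, dr > 0)
  g <- g %||% function(th) cos(th * pi / 360)
  grid <- tidyr::expand_grid(r = seq(r0, r_max, by = dr),
                             theta = sort(unique(theta)))
  a <- a_near * (1 - A * exp(-(grid$r - r0) / lambda) * g(grid$theta))
  new_shielding_kernel(tibble::tibble(r = grid$r, theta = grid$theta,
                                      a_bead = pmax(0, a)),
                       a_near = a_near, r0 = r0)
}

new_shielding_kernel <- function(tbl, a_near, r0) {
  stopifnot(all(c("r", "theta", "a_bead") %in% names(tbl)))
  if (any(tbl$a_bead < 0) || any(tbl$a_bead > a_near + 1e-12)) {
    stop("kernel values must lie in [0, a_near]")
  }
  structure(tbl, a_near = a_near, r0 = r0,
            class = c("shielding_kernel", class(tbl)))
}

#' Read a shielding kernel from CSV
#'
#' CSV with header `r_nm,theta_deg,a_bead_nm` tabulating the central-bead
#' radius on an `(r, theta)` grid.
#'
#' @param path CSV file path.
#' @param a_near Near-bead saturation radius (nm); defaults to the largest
#'   tabulated kernel value.
#' @param r0 Near/far split radius (nm); defaults to the smallest
#'   tabulated `r`.
#' @return A `shielding_kernel`.
#' @export
read_kernel_csv <- function(path, a_near = NULL, r0 = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("r_nm", "theta_deg", "a_bead_nm")
  if (!all(need %in% names(tab))) {
    stop("kernel CSV must have columns ", paste(need, collapse = ", "))
  }
  tbl <- tibble::tibble(r = tab$r_nm, theta = tab$theta_deg,
                        a_bead = tab$a_bead_nm)
  new_shielding_kernel(dplyr::arrange(tbl, .data$r, .data$theta),
                       a_near = a_near %||% max(tbl$a_bead),
                       r0 = r0 %||% min(tbl$r))
}

#' Write a shielding kernel to CSV
#'
#' @param kernel A `shielding_kernel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  write.csv(data.frame(r_nm = kernel$r, theta_deg = kernel$theta,
                       a_bead_nm = kernel$a_bead),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Far-bead weight on a kernel grid
#'
#' The separable far-bead distribution
#' \eqn{P_{far}(r, \theta; N) = \tfrac12 n_{far}(r) \sin\theta}
#' evaluated on the kernel's `(r, theta)` grid; `n_far` is linearly
#' interpolated onto the kernel's radial grid (zero outside its tabulated
#' range).
#'
#' @param n_far Tibble with columns `r` and `n_far` (see
#'   [exposed_far_beads()]).
#' @param kernel A `shielding_kernel` supplying the grid.
#' @return A tibble with columns `r`, `theta`, `p_far`.
#' @export
build_pfar <- function(n_far, kernel) {
  stopifnot(all(c("r", "n_far") %in% names(n_far)),
            inherits(kernel, "shielding_kernel"))
  if (any(n_far$n_far < 0)) stop("n_far must be nonnegative")
  r_grid <- sort(unique(kernel$r))
  nf <- if (nrow(n_far) == 0L || all(n_far$n_far == 0)) {
    rep(0, length(r_grid))
  } else if (nrow(n_far) == 1L) {
    ifelse(abs(r_grid - n_far$r) < 1e-12, n_far$n_far, 0)
  } else {
    approx(n_far$r, n_far$n_far, xout = r_grid, yleft = 0, yright = 0)$y
  }
  th_grid <- sort(unique(kernel$theta))
  grid <- tidyr::expand_grid(r = r_grid, theta = th_grid)
  tibble::tibble(r = grid$r, theta = grid$theta,
                 p_far = 0.5 * rep(nf, each = length(th_grid)) *
                   sin(grid$theta * pi / 180))
}

# trapezoidal double quadrature of `values` tabulated on the (r, theta)
# grid of `tbl` (theta in degrees, integrated in radians)
.double_trapz <- function(r, theta, values) {
  rs <- sort(unique(r)); ths <- sort(unique(theta))
  m <- matrix(values[order(r, theta)], nrow = length(ths), ncol = length(rs))
  inner <- apply(m, 2L, function(col) .trapz(ths * pi / 180, col))
  .trapz(rs, inner)
}

.check_same_grid <- function(kernel, weight) {
  if (nrow(kernel) != nrow(weight) ||
      !isTRUE(all.equal(sort(unique(kernel$r)), sort(unique(weight$r)))) ||
      !isTRUE(all.equal(sort(unique(kernel$theta)),
                        sort(unique(weight$theta))))) {
    stop("kernel and weight must share one (r, theta) grid")
  }
}

#' Additive far-bead shielding average
#'
#' The effective bead radius under additive far-bead shielding:
#' \deqn{a_{bead}(N) = a^{near} - \int_0^{\pi/2}\! d\theta \int_0^\infty\!
#'   dr\, [a^{near} - a_{bead}(r,\theta)]\, P_{far}(r, \theta; N),}
#' evaluated by trapezoidal double quadrature on the tabulated grid. The
#' degenerate limit of zero far-bead weight returns the near-bead radius
#' exactly. A total far-bead mass above one strains the additivity
#' assumption and triggers a warning; negative outputs are clamped to zero
#' with a model-validity warning.
#'
#' @param kernel A `shielding_kernel`.
#' @param weight A far-bead weight table from [build_pfar()], on the same
#'   grid.
#' @param a0 Physical bead radius (nm) used to express the result in
#'   units of `a0`.
#' @return A one-row tibble with `a_bead_nm`, `a_bead_rel`
#'   (`a_bead / a0`), `a_near_nm`, `deficit_nm` and `pfar_mass`.
#' @export
effective_radius <- function(kernel, weight, a0 = 0.156) {
  stopifnot(inherits(kernel, "shielding_kernel"),
            all(c("r", "theta", "p_far") %in% names(weight)))
  .check_same_grid(kernel, weight)
  a_near <- attr(kernel, "a_near")
  kern <- dplyr::arrange(tibble::as_tibble(kernel), .data$r, .data$theta)
  wt <- dplyr::arrange(tibble::as_tibble(weight), .data$r, .data$theta)
  deficit <- .double_trapz(kern$r, kern$theta,
                           (a_near - kern$a_bead) * wt$p_far)
  mass <- .double_trapz(wt$r, wt$theta, wt$p_far)
  if (mass > 1) {
    warning(sprintf(
      "total far-bead weight %.3g > 1: additive-shielding assumption strained",
      mass))
  }
  a <- a_near - deficit
  if (a < 0) {
    warning("shielding average below zero: clamped to 0 (model validity)")
    a <- 0
  }
  tibble::tibble(a_bead_nm = a, a_bead_rel = a / a0, a_near_nm = a_near,
                 deficit_nm = deficit, pfar_mass = mass)
}

#' Shielding radius of a kernel
#'
#' For each orientation, the smallest tabulated distance beyond which the
#' kernel stays within a relative tolerance of its near-bead saturation
#' value -- the distance at which far beads stop mattering.
#'
#' @param kernel A `shielding_kernel`.
#' @param tol Relative tolerance (`> 0`).
#' @return A tibble with columns `theta`, `r_s` and `converged`; when the
#'   criterion is never met on the grid, `r_s` is the largest tabulated
#'   `r`, `converged` is `FALSE`, and a warning is issued.
#' @export
shielding_radius <- function(kernel, tol = 0.05) {
  stopifnot(inherits(kernel, "shielding_kernel"), tol > 0)
  a_near <- attr(kernel, "a_near")
  out <- tibble::as_tibble(kernel) |>
    dplyr::group_by(.data$theta) |>
    dplyr::arrange(.data$r, .by_group = TRUE) |>
    dplyr::summarise(
      r_s = {
        ok <- abs(.data$a_bead - a_near) <= tol * a_near
        bad <- which(!ok)
        if (length(bad) == 0L) .data$r[1L]
        else if (max(bad) == length(ok)) .data$r[length(ok)]
        else .data$r[max(bad) + 1L]
      },
      converged = {
        ok <- abs(.data$a_bead - a_near) <= tol * a_near
        length(ok) > 0L && ok[length(ok)] &&
          !(length(which(!ok)) > 0L && max(which(!ok)) == length(ok))
      },
      .groups = "drop")
  if (any(!out$converged)) {
    warning("kernel never settles within tolerance for some orientations")
  }
  out
}

#' Shielded radius as a function of polymer length
#'
#' Applies the additive shielding average ([effective_radius()]) to one
#' far-bead distribution per degree of polymerization.
#'
#' @param kernel A `shielding_kernel`.
#' @param n_far_by_N Tibble with columns `N`, `r`, `n_far`.
#' @param a0 Physical bead radius (nm).
#' @return A tibble with one row per `N`: `N`, `a_bead_nm`, `a_bead_rel`,
#'   `pfar_mass`; the attribute `monotone_nonincreasing` records whether
#'   the radius decreases with `N`.
#' @export
radius_vs_N <- function(kernel, n_far_by_N, a0 = 0.156) {
  stopifnot(all(c("N", "r", "n_far") %in% names(n_far_by_N)))
  Ns <- sort(unique(n_far_by_N$N))
  if (length(Ns) < 2L) stop("need at least two N values")
  rows <- purrr::map_dfr(Ns, function(nn) {
    nf <- dplyr::filter(n_far_by_N, .data$N == nn)
    res <- effective_radius(kernel, build_pfar(nf, kernel), a0 = a0)
    tibble::tibble(N = nn, a_bead_nm = res$a_bead_nm,
                   a_bead_rel = res$a_bead_rel, pfar_mass = res$pfar_mass)
  })
  structure(rows,
            monotone_nonincreasing = all(diff(rows$a_bead_nm) <= 1e-12))
}
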