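#' Slit and grafting geometry for a polymer coating
#'
#' Collects the geometric parameters of a polymer-coated nanoslit: the slit
#' width, the square grafting lattice on the two walls, and the bead-spring
#' parameters of the united-atom chains. The coordinate origin `z = 0` is the
#' centre of the innermost layer of the bottom wall; the top wall sits at
#' `z = w`.
#'
#' @param w Slit width (nm), distance between the two innermost wall layers.
#' @param graft_a Grafting lattice constant (nm) of the square lattice on
#'   each wall.
#' @param bond_b Intra-chain bead-bead bond length (nm).
#' @param a0 Physical (Lennard-Jones) bead radius (nm).
#' @param bond_angle Bond angle between consecutive bonds (degrees).
#'
#' @return An object of class `coating_geometry`.
#' @export
#' @examples
#' coating_geometry()
coating_geometry <- function(w = 20, graft_a = 2.5, bond_b = 0.15,
                             a0 = 0.156, bond_angle = 109.5) {
  stopifnot(w > 0, graft_a > 0, bond_b > 0, a0 > 0,
            bond_angle > 0, bond_angle < 180)
  structure(
    list(w = w, graft_a = graft_a, bond_b = bond_b, a0 = a0,
         bond_angle = bond_angle),
    class = "coating_geometry"
  )
}

#' @exportS3Method base::print
print.coating_geometry <- function(x, ...) {
  cat("<coating_geometry>\n")
  cat(sprintf("  slit width w        : %g nm\n", x$w))
  cat(sprintf("  grafting lattice a  : %g nm (density %.3g nm^-2)\n",
              x$graft_a, 1 / x$graft_a^2))
  cat(sprintf("  bond length b       : %g nm\n", x$bond_b))
  cat(sprintf("  bead radius a0      : %g nm\n", x$a0))
  cat(sprintf("  bond angle          : %g deg\n", x$bond_angle))
  invisible(x)
}

# unit vector orthogonal pair spanning the plane normal to u
.ortho_basis <- function(u) {
  a <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2L] * e1[3L] - u[3L] * e1[2L],
          u[3L] * e1[1L] - u[1L] * e1[3L],
          u[1L] * e1[2L] - u[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}

# TRUE if point p (x, y, z) comes closer than dmin to any row of `others`
# under the minimum-image convention in x and y
.too_close <- function(p, others, Lx, Ly, dmin) {
  if (is.null(others) || nrow(others) == 0L) return(FALSE)
  dx <- abs(others[, 1L] - p[1L]); dx <- pmin(dx, Lx - dx)
  dy <- abs(others[, 2L] - p[2L]); dy <- pmin(dy, Ly - dy)
  dz <- others[, 3L] - p[3L]
  any(dx * dx + dy * dy + dz * dz < dmin * dmin)
}

#' Generate a grafted polymer coating
#'
#' Grows bead-spring polymer chains grafted on square lattices on both walls
#' of a nanoslit. Each chain carries `3N + 2` free beads (the united-atom
#' counting rule for a PEG-like chain of degree of polymerization `N` whose
#' first two backbone beads anchor it to the wall). Chains are grown as
#' freely-rotating walks with fixed bond length and bond angle, a random
#' dihedral at every step, and hard-core excluded volume: any two beads
#' separated by more than two bonds along a chain, or belonging to different
#' chains, must be at least one bead diameter `2 a0` apart. Growth uses
#' rejection sampling with chain restarts; an overcrowded specification
#' raises an error naming the chain that could not be placed.
#'
#' The box is periodic in `x` and `y` (side lengths set by the grafting
#' lattice) and bounded by the walls in `z`; every bead lies strictly
#' between the walls.
#'
#' @param N Degree of polymerization (number of free monomers), `N >= 1`.
#' @param n_chains_per_wall Number of chains grafted on each wall; placed on
#'   the first `n_chains_per_wall` sites of a near-square lattice.
#' @param geometry A [coating_geometry()].
#' @param seed Optional integer seed; the same (arguments, seed) pair
#'   reproduces the configuration exactly.
#' @param max_bead_retries Dihedral redraws allowed per bead before the
#'   chain is restarted.
#' @param max_chain_restarts Restarts allowed per chain before failing.
#'
#' @return An object of class `coating_config`: a list with elements
#'   `beads` (tibble with columns `chain`, `bead`, `x`, `y`, `z`, `wall`),
#'   `box` (`c(Lx, Ly, Lz)` in nm), `wall_z`, `graft_sites`, `geometry`,
#'   and `N`.
#' @export
#' @examples
#' cfg <- generate_grafted_coating(N = 1, n_chains_per_wall = 1, seed = 1)
#' nrow(cfg$beads)  # 3 * 1 + 2 = 5 free beads
generate_grafted_coating <- function(N, n_chains_per_wall = 16,
                                     geometry = coating_geometry(),
                                     seed = NULL,
                                     max_bead_retries = 200L,
                                     max_chain_restarts = 100L) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1, N == round(N),
            n_chains_per_wall >= 1)
  if (!is.null(seed)) set.seed(seed)

  w <- geometry$w; a <- geometry$graft_a; b <- geometry$bond_b
  a0 <- geometry$a0
  n_beads <- 3L * as.integer(N) + 2L
  nx <- ceiling(sqrt(n_chains_per_wall))
  ny <- ceiling(n_chains_per_wall / nx)
  Lx <- nx * a; Ly <- ny * a
  sites <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  sites <- sites[seq_len(n_chains_per_wall), , drop = FALSE]

  # angle between consecutive bond vectors for a fixed bond angle
  alpha <- pi - geometry$bond_angle * pi / 180
  ca <- cos(alpha); sa <- sin(alpha)
  dmin <- 2 * a0

  n_chains <- 2L * n_chains_per_wall
  walls <- rep(1:2, each = n_chains_per_wall)
  anchors <- rbind(
    cbind(sites$ix * a, sites$iy * a, b),
    cbind(sites$ix * a, sites$iy * a, w - b)
  )
  # all beads in one matrix; rows (c-1)*n_beads + i hold bead i of chain c
  coords <- matrix(NA_real_, nrow = n_chains * n_beads, ncol = 3L)
  row_of <- function(c, i) (c - 1L) * n_beads + i
  for (c in seq_len(n_chains)) coords[row_of(c, 1L), ] <- anchors[c, ]
  if (n_chains > 1L) {
    for (c in seq_len(n_chains)) {
      others <- coords[setdiff(which(!is.na(coords[, 1L])), row_of(c, 1L)), ,
                       drop = FALSE]
      if (.too_close(anchors[c, ], others, Lx, Ly, dmin)) {
        stop(sprintf("chain %d: grafting sites closer than one bead diameter",
                     c))
      }
    }
  }

  # grow all chains concurrently, one bead per chain per sweep, so that no
  # mushroom can smother an ungrown grafting site; on a dead end a chain
  # backtracks one bead and redraws it
  grown <- rep(1L, n_chains)
  place_bead <- function(c, i) {
    inward <- if (walls[c] == 1L) 1 else -1
    r1 <- row_of(c, 1L)
    prior_rows <- which(!is.na(coords[, 1L]))
    # exclude own beads i-1, i-2 (separations fixed by the bond geometry)
    drop_rows <- row_of(c, max(1L, i - 2L):(i - 1L))
    occ <- coords[setdiff(prior_rows, c(drop_rows, row_of(c, i))), ,
                  drop = FALSE]
    prev_pos <- coords[row_of(c, i - 1L), ]
    for (try in seq_len(max_bead_retries)) {
      if (i == 2L) {
        # first bond: uniform on the inward-facing hemisphere
        v <- rnorm(3L); v <- v / sqrt(sum(v^2))
        if (v[3L] * inward < 0) v[3L] <- -v[3L]
        dir <- v
      } else {
        prev <- (prev_pos - coords[row_of(c, i - 2L), ]) / b
        basis <- .ortho_basis(prev)
        phi <- runif(1L, 0, 2 * pi)
        dir <- ca * prev + sa * (cos(phi) * basis$e1 + sin(phi) * basis$e2)
      }
      pos <- prev_pos + b * dir
      if (pos[3L] <= 0 || pos[3L] >= w) next
      if (.too_close(pos, occ, Lx, Ly, dmin)) next
      coords[row_of(c, i), ] <<- pos
      return(TRUE)
    }
    FALSE
  }

  budget <- max_chain_restarts * n_beads
  spent <- rep(0L, n_chains)
  stuck <- rep(0L, n_chains) # consecutive dead ends -> deeper backtracking
  for (sweep in 2:n_beads) {
    for (c in seq_len(n_chains)) {
      while (grown[c] < sweep) {
        i <- grown[c] + 1L
        if (place_bead(c, i)) {
          grown[c] <- i
          if (i >= sweep) stuck[c] <- 0L
        } else {
          spent[c] <- spent[c] + 1L
          stuck[c] <- stuck[c] + 1L
          depth <- min(i - 2L, stuck[c])
          if (depth >= 1L && spent[c] <= budget) {
            rows <- row_of(c, (i - depth):(i - 1L))
            coords[rows, ] <- NA_real_
            grown[c] <- grown[c] - depth
          } else {
            stop(sprintf(
              "failed to grow chain %d (wall %d) at bead %d: specification too crowded",
              c, walls[c], i))
          }
        }
      }
    }
  }

  beads <- tibble::tibble(
    chain = rep(seq_len(n_chains), each = n_beads),
    bead = rep(seq_len(n_beads), times = n_chains),
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    wall = rep(walls, each = n_beads)
  )
  structure(
    list(beads = beads, box = c(Lx, Ly, w), wall_z = c(0, w),
         graft_sites = tibble::tibble(x = sites$ix * a, y = sites$iy * a),
         geometry = geometry, N = as.integer(N),
         n_chains = 2L * n_chains_per_wall),
    class = "coating_config"
  )
}

#' @exportS3Method base::print
print.coating_config <- function(x, ...) {
  cat("<coating_config>\n")
  cat(sprintf("  N = %d (%d free beads/chain), %d chains, %d beads\n",
              x$N, 3L * x$N + 2L, x$n_chains, nrow(x$beads)))
  cat(sprintf("  box %g x %g x %g nm (periodic x,y; walls at z = %g, %g)\n",
              x$box[1L], x$box[2L], x$box[3L], x$wall_z[1L], x$wall_z[2L]))
  invisible(x)
}

#' @export
as_tibble.coating_config <- function(x, ...) x$beads

#' Check the structural invariants of a coating configuration
#'
#' Verifies the united-atom counting rule (every chain has `3N + 2` beads),
#' the fixed bond length, strict confinement between the walls, and
#' anchoring of the first bead of each chain on the grafting lattice.
#'
#' @param config A `coating_config`.
#' @param tol Bond-length tolerance (nm).
#' @return `TRUE` invisibly; errors describe any violated invariant.
#' @export
validate_coating <- function(config, tol = 1e-6) {
  beads <- config$beads
  n_expect <- 3L * config$N + 2L
  counts <- dplyr::count(beads, .data$chain)
  if (any(counts$n != n_expect)) {
    stop(sprintf("chains with bead count != 3N+2 = %d", n_expect))
  }
  bonds <- beads |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(
      max_dev = if (dplyr::n() > 1L)
        max(abs(sqrt(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2) -
                  config$geometry$bond_b)) else 0,
      .groups = "drop")
  if (any(bonds$max_dev > tol)) stop("bond lengths deviate from b")
  if (any(beads$z <= config$wall_z[1L] | beads$z >= config$wall_z[2L])) {
    stop("beads outside the slit")
  }
  anchors <- beads |>
    dplyr::filter(.data$bead == 1L) |>
    dplyr::mutate(
      off = pmin(.data$x %% config$geometry$graft_a,
                 config$geometry$graft_a - .data$x %% config$geometry$graft_a) +
            pmin(.data$y %% config$geometry$graft_a,
                 config$geometry$graft_a - .data$y %% config$geometry$graft_a))
  if (any(anchors$off > 1e-9)) stop("chain anchors off the grafting lattice")
  invisible(TRUE)
}

#' Write bead coordinates as an XYZ file
#'
#' One-frame XYZ with element tag `"C"` for every bead; coordinates are
#' written in nanometres (noted on the comment line) at full precision.
#'
#' @param x A `coating_config` or a data frame with columns `x`, `y`, `z`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  beads <- if (inherits(x, "coating_config")) x$beads else tibble::as_tibble(x)
  stopifnot(all(c("x", "y", "z") %in% names(beads)))
  lines <- c(
    as.character(nrow(beads)),
    "brushflow coating; units: nm",
    sprintf("C %s %s %s",
            formatC(beads$x, format = "g", digits = 17),
            formatC(beads$y, format = "g", digits = 17),
            formatC(beads$z, format = "g", digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read bead coordinates from an XYZ file
#'
#' @param path Path to a one-frame XYZ file (coordinates in nm).
#' @return A tibble with columns `element`, `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("XYZ file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("XYZ line 1: expected an atom count")
  if (length(lines) < 2L + n) stop("XYZ file truncated")
  rows <- strsplit(trimws(lines[3:(2L + n)]), "\\s+")
  bad <- which(vapply(rows, length, 1L) < 4L)
  if (length(bad)) stop(sprintf("XYZ parse error at line %d", bad[1L] + 2L))
  num <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", k)))
    if (anyNA(v)) stop(sprintf("XYZ non-numeric coordinate at line %d",
                               which(is.na(v))[1L] + 2L))
    v
  }
  tibble::tibble(element = vapply(rows, `[[`, "", 1L),
                 x = num(2L), y = num(3L), z = num(4L))
}

#' Read bead coordinates from a GRO file
#'
#' Minimal fixed-width reader for Gromacs `.gro` coordinate files
#' (positions already in nm). Velocities, if present, are ignored.
#'
#' @param path Path to a `.gro` file.
#' @return A tibble with columns `resid`, `atom`, `x`, `y`, `z`.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("GRO file too short")
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n)) stop("GRO line 2: expected an atom count")
  if (length(lines) < 2L + n) stop("GRO file truncated")
  body <- lines[3:(2L + n)]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(body, from, to)))
    if (anyNA(v)) stop(sprintf("GRO non-numeric %s at line %d", what,
                               which(is.na(v))[1L] + 2L))
    v
  }
  tibble::tibble(
    resid = trimws(substr(body, 1L, 10L)),
    atom = trimws(substr(body, 11L, 15L)),
    x = num(21L, 28L, "x"), y = num(29L, 36L, "y"), z = num(37L, 44L, "z")
  )
}
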