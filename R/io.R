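#' Read a two-column profile file
#'
#' Plain-text profiles over the slit coordinate: two whitespace-separated
#' numeric columns, with `#` and xvg-style `@` comment lines ignored. The
#' `z` grid must be strictly increasing and uniform.
#'
#' @param path File path.
#' @param value_name Name for the second column in the returned tibble.
#' @return A tibble with columns `z` and `value_name`.
#' @export
read_profile <- function(path, value_name = "value") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  if (!length(line_no)) stop("no data rows in ", path)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  for (k in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[k]][1:2]))
    if (length(rows[[k]]) < 2L || anyNA(v)) {
      stop(sprintf("parse error at line %d of %s: expected two numeric columns",
                   line_no[k], path))
    }
  }
  z <- vapply(rows, function(r) as.numeric(r[1L]), 0)
  val <- vapply(rows, function(r) as.numeric(r[2L]), 0)
  if (any(diff(z) <= 0)) {
    stop("z column must be strictly increasing")
  }
  if (!.is_uniform_grid(z)) {
    stop("non-uniform z grid: resample onto a uniform grid before use")
  }
  out <- tibble::tibble(z = z, value = val)
  names(out)[2L] <- value_name
  out
}

#' Write a two-column profile file
#'
#' Writes `# z[nm] <name>[unit]` followed by the data at full double
#' precision, so that a write/read round trip preserves the values
#' exactly.
#'
#' @param profile Tibble whose first column is `z` and whose second column
#'   holds the values.
#' @param path Output file path.
#' @param unit Unit label for the header.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, unit = "") {
  stopifnot(ncol(profile) >= 2L, names(profile)[1L] == "z")
  vname <- names(profile)[2L]
  header <- sprintf("# z[nm] %s%s", vname,
                    if (nzchar(unit)) sprintf("[%s]", unit) else "")
  body <- sprintf("%s %s",
                  formatC(profile$z, format = "g", digits = 17),
                  formatC(profile[[2L]], format = "g", digits = 17))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Save / load a synthetic scenario as JSON
#'
#' @param scenario A [synthetic_scenario()].
#' @param path JSON file path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns the reconstructed `synthetic_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  payload <- list(
    N = scenario$N, a_bead = scenario$a_bead, Eext = scenario$Eext,
    noise_sd = scenario$noise_sd, seed = scenario$seed,
    brush_height = scenario$brush_height, n_grid = scenario$n_grid,
    hindrance = scenario$hindrance,
    electrolyte = unclass(scenario$electrolyte),
    geometry = unclass(scenario$geometry)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_scenario(
    N = p$N, a_bead = p$a_bead, Eext = p$Eext, noise_sd = p$noise_sd,
    seed = p$seed,
    electrolyte = do.call(electrolyte_spec, as.list(p$electrolyte)),
    geometry = do.call(coating_geometry, as.list(p$geometry)),
    brush_height = p$brush_height, n_grid = p$n_grid,
    hindrance = p$hindrance
  )
}
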