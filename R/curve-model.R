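#' Cantilever description
#'
#' Metadata for the AFM cantilever used to record a force curve. Defaults
#' correspond to a soft colloidal probe commonly used for live-cell
#' indentation: a ~6 um diameter spherical tip (radius 3 um) on a 0.08 N/m
#' lever, approached at ~4 um/s.
#'
#' @param spring_constant Cantilever spring constant in N/m; must be > 0.
#' @param tip_radius Spherical tip radius in m; must be > 0.
#' @param approach_velocity Tip approach/retraction speed in um/s.
#' @return An object of class `cantilever_spec`.
#' @examples
#' cantilever_spec()
#' cantilever_spec(spring_constant = 0.1, tip_radius = 2.5e-6)
#' @export
cantilever_spec <- function(spring_constant = 0.08,
                            tip_radius = 3e-6,
                            approach_velocity = 4) {
  if (!is.numeric(spring_constant) || length(spring_constant) != 1 ||
      !is.finite(spring_constant) || spring_constant <= 0) {
    abort("`spring_constant` must be a single positive number (N/m).")
  }
  if (!is.numeric(tip_radius) || length(tip_radius) != 1 ||
      !is.finite(tip_radius) || tip_radius <= 0) {
    abort("`tip_radius` must be a single positive number (m).")
  }
  structure(
    list(
      spring_constant = spring_constant,
      tip_radius = tip_radius,
      approach_velocity = approach_velocity
    ),
    class = "cantilever_spec"
  )
}

#' @export
print.cantilever_spec <- function(x, ...) {
  cat(sprintf(
    "<cantilever_spec> k = %g N/m, R = %g um, v = %g um/s\n",
    x$spring_constant, x$tip_radius * 1e6, x$approach_velocity
  ))
  invisible(x)
}

new_force_curve <- function(approach, retraction, cantilever,
                            label = "", grid_position = NULL) {
  structure(
    list(
      approach = as_tibble(approach),
      retraction = as_tibble(retraction),
      cantilever = cantilever,
      label = label,
      grid_position = grid_position
    ),
    class = "force_curve"
  )
}

check_segment <- function(seg, name, direction, curve_label = "") {
  where <- if (nzchar(curve_label)) sprintf(" in curve '%s'", curve_label) else ""
  if (!all(c("z_nm", "deflection_nm") %in% names(seg))) {
    abort(sprintf("malformed segment: %s%s lacks z_nm/deflection_nm columns", name, where))
  }
  if (nrow(seg) < 16) {
    abort(sprintf("malformed segment: %s%s has fewer than 16 samples", name, where))
  }
  dz <- diff(seg$z_nm)
  ok <- if (direction > 0) all(dz > 0) else all(dz < 0)
  if (!ok) {
    abort(sprintf("malformed segment: z not strictly monotone on %s%s", name, where))
  }
  if (!all(is.finite(seg$deflection_nm))) {
    abort(sprintf("malformed segment: non-finite deflection on %s%s", name, where))
  }
  invisible(TRUE)
}

#' A single approach/retraction force curve
#'
#' The atomic record of force spectroscopy: cantilever deflection versus piezo
#' displacement for the tip's approach to and retraction from the surface.
#' The z axis increases toward the sample, so the approach segment has
#' strictly increasing z and the retraction strictly decreasing z. Force is
#' always derived, never stored: `force_pN = spring_constant * deflection_nm * 1000`.
#'
#' @param approach,retraction Data frames with columns `z_nm` and
#'   `deflection_nm`, at least 16 samples each, z strictly monotone
#'   (increasing on approach, decreasing on retraction), finite deflections.
#' @param cantilever A [cantilever_spec()].
#' @param label Free-text identifier used in error messages and output tables.
#' @param grid_position Optional integer `c(row, col)` when the curve belongs
#'   to a force-volume map.
#' @param validate Set `FALSE` to skip invariant checks (internal use, e.g.
#'   constructing deliberately malformed fixtures).
#' @return An object of class `force_curve`.
#' @seealso [curve_force()], [force_volume_map()]
#' @export
force_curve <- function(approach, retraction, cantilever = cantilever_spec(),
                        label = "", grid_position = NULL, validate = TRUE) {
  if (!inherits(cantilever, "cantilever_spec")) {
    abort("`cantilever` must be a cantilever_spec object.")
  }
  fc <- new_force_curve(approach, retraction, cantilever, label, grid_position)
  if (validate) {
    check_segment(fc$approach, "approach", +1, label)
    check_segment(fc$retraction, "retraction", -1, label)
  }
  fc
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "<force_curve%s> approach %d samples, retraction %d samples, k = %g N/m\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    nrow(x$approach), nrow(x$retraction), x$cantilever$spring_constant
  ))
  invisible(x)
}

#' Forces of a curve segment
#'
#' Returns one segment of a force curve as a tibble with the derived force
#' column appended (`force_pN = spring_constant * deflection_nm * 1000`).
#'
#' @param curve A [force_curve()].
#' @param segment `"approach"` or `"retraction"`.
#' @return A tibble with columns `z_nm`, `deflection_nm`, `force_pN`.
#' @export
curve_force <- function(curve, segment = c("approach", "retraction")) {
  segment <- match.arg(segment)
  seg <- curve[[segment]]
  k <- curve$cantilever$spring_constant
  mutate(seg, force_pN = k * .data$deflection_nm * PN_PER_NM_DEFLECTION)
}

#' Force-volume map
#'
#' A rectangular grid of force curves acquired over one cell, one curve per
#' pixel, all sharing a cantilever.
#'
#' @param curves List of [force_curve()] objects in row-major order
#'   (row 1 col 1, row 1 col 2, ...); length must equal `n_rows * n_cols`.
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param pixel_size Pixel edge length in um, stored verbatim.
#' @param label Free-text map identifier (e.g. a cell id).
#' @return An object of class `force_volume_map`.
#' @examples
#' p <- mechanical_preset("pc3")
#' m <- generate_force_volume(p, seed = 1)
#' m$n_rows * m$n_cols
#' @export
force_volume_map <- function(curves, n_rows, n_cols, pixel_size, label = "") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (length(curves) == 0 || n_rows < 1 || n_cols < 1) abort("empty map")
  if (length(curves) != n_rows * n_cols) {
    abort(sprintf(
      "grid mismatch: %d curves for a %d x %d map", length(curves), n_rows, n_cols
    ))
  }
  if (!all(vapply(curves, inherits, logical(1), "force_curve"))) {
    abort("`curves` must be a list of force_curve objects.")
  }
  k <- vapply(curves, function(cv) cv$cantilever$spring_constant, numeric(1))
  r <- vapply(curves, function(cv) cv$cantilever$tip_radius, numeric(1))
  if (length(unique(k)) != 1 || length(unique(r)) != 1) {
    abort("all curves in a force-volume map must share one cantilever spec")
  }
  structure(
    list(
      curves = curves, n_rows = n_rows, n_cols = n_cols,
      pixel_size = pixel_size, cantilever = curves[[1]]$cantilever,
      label = label
    ),
    class = "force_volume_map"
  )
}

#' @export
print.force_volume_map <- function(x, ...) {
  cat(sprintf(
    "<force_volume_map%s> %d x %d pixels (%g um/px), %d curves\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    x$n_rows, x$n_cols, x$pixel_size, length(x$curves)
  ))
  invisible(x)
}

#' Extract one curve from a force-volume map
#'
#' @param map A [force_volume_map()].
#' @param row,col 1-based pixel indices.
#' @return The [force_curve()] at that pixel.
#' @export
fv_curve <- function(map, row, col) {
  stopifnot(inherits(map, "force_volume_map"))
  if (row < 1 || row > map$n_rows || col < 1 || col > map$n_cols) {
    abort("pixel index out of range")
  }
  map$curves[[(row - 1) * map$n_cols + col]]
}

# Canonical tabular form of a map's samples, used for round-trip comparisons.
fv_samples <- function(map) {
  purrr::imap(map$curves, function(cv, i) {
    bind_rows(
      mutate(cv$approach, segment = "approach"),
      mutate(cv$retraction, segment = "retraction")
    ) %>% mutate(curve = i)
  }) %>%
    bind_rows() %>%
    dplyr::select("curve", "segment", "z_nm", "deflection_nm")
}
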