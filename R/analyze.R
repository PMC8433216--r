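#' Quality control for one force curve
#'
#' A curve fails QC when any of the following holds: a segment is malformed
#' (non-monotone z, too short), the baseline residual SD exceeds five times
#' the configured noise scale (an "unclear" curve), no contact is detected,
#' or the Hertz fit R^2 falls below `qc_min_fit_r2`. The first failing check
#' is recorded as the reason; QC-failed curves carry no modulus or
#' deformation downstream.
#'
#' @param curve A [force_curve()].
#' @param config An [analysis_config()].
#' @return A list with `qc_pass` (logical) and `qc_reason` (text, `"ok"` on
#'   pass).
#' @export
qc_curve <- function(curve, config = analysis_config()) {
  res <- analyze_force_curve(curve, config)
  list(qc_pass = res$qc_pass, qc_reason = res$qc_reason)
}

#' Analyze one force curve
#'
#' Runs the full per-curve chain: baseline estimation, QC, contact-point
#' detection, indentation, Hertz fit of the Young's modulus, deformation at
#' maximum load, adhesion-event detection on the retraction, and work of
#' detachment. Failures are recorded in the QC columns rather than raised.
#'
#' @param curve A [force_curve()].
#' @param config An [analysis_config()].
#' @param cell Optional cell label copied into the output row.
#' @return A one-row tibble with columns `cell`, `row`, `col`, `E_Pa`, `D_nm`,
#'   `n_events`, `max_adhesion_pN`, `WD_aJ`, `r_squared`, `contact_z_nm`,
#'   `qc_pass`, `qc_reason`.
#' @export
analyze_force_curve <- function(curve, config = analysis_config(), cell = "") {
  pos <- curve$grid_position %||% c(NA_integer_, NA_integer_)
  out <- tibble(
    cell = cell, row = pos[1], col = pos[2],
    E_Pa = NA_real_, D_nm = NA_real_,
    n_events = NA_integer_, max_adhesion_pN = NA_real_, WD_aJ = NA_real_,
    r_squared = NA_real_, contact_z_nm = NA_real_,
    qc_pass = FALSE, qc_reason = "ok"
  )
  fail <- function(reason) { out$qc_reason <- reason; out }

  ok <- tryCatch({
    check_segment(curve$approach, "approach", +1, curve$label)
    check_segment(curve$retraction, "retraction", -1, curve$label)
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(fail("malformed segment"))

  app <- curve_force(curve, "approach")
  bl <- estimate_baseline(app$z_nm, app$force_pN, config$baseline_fraction)
  if (bl$residual_sd_pN > 5 * config$noise_scale_pN) {
    return(fail("excessive baseline noise"))
  }

  z0 <- tryCatch(detect_contact_point(curve, config),
                 error = function(e) NA_real_)
  if (is.na(z0)) return(fail("no contact detected"))
  out$contact_z_nm <- z0

  ind <- compute_indentation(curve, z0, config)
  fit <- tryCatch(fit_hertz(ind, curve$cantilever$tip_radius, config),
                  error = function(e) conditionMessage(e))
  if (is.character(fit)) return(fail(fit))
  out$r_squared <- fit$r_squared

  # Retraction quantities are computed regardless of the elastic-fit QC.
  ret <- curve_force(curve, "retraction")
  blr <- estimate_baseline(ret$z_nm, ret$force_pN, config$baseline_fraction,
                           far = "last")
  f_ret <- ret$force_pN - blr$line(ret$z_nm)
  k <- curve$cantilever$spring_constant
  sep <- (z0 - ret$z_nm) - f_ret / (PN_PER_NM_DEFLECTION * k)
  events <- detect_adhesion_events(f_ret, sep, config)
  out$n_events <- nrow(events)
  out$max_adhesion_pN <- if (nrow(events)) max(events$force_magnitude_pN) else 0
  past <- ret$z_nm <= z0
  out$WD_aJ <- if (sum(past) >= 2) {
    compute_work_of_detachment(sep[past], f_ret[past])
  } else 0

  if (fit$r_squared < config$qc_min_fit_r2) {
    return(fail(sprintf("poor Hertz fit (R^2 = %.3f)", fit$r_squared)))
  }

  out$E_Pa <- fit$E_Pa
  out$D_nm <- measure_deformation(ind)
  out$qc_pass <- TRUE
  out
}

#' Analyze every pixel of a force-volume map
#'
#' Applies [analyze_force_curve()] to each pixel. Per-pixel failures are
#' recorded in the QC columns, never raised; QC-failed pixels carry `NA`
#' modulus and deformation and should be excluded from population statistics.
#'
#' @param map A [force_volume_map()].
#' @param config An [analysis_config()].
#' @return A tibble with one row per pixel (row-major order), columns as in
#'   [analyze_force_curve()].
#' @examples
#' m <- generate_force_volume(mechanical_preset("pc3"), seed = 3)
#' res <- analyze_force_volume(m, analysis_config(fit_range_nm = c(100, 400)))
#' mean(res$E_Pa[res$qc_pass])
#' @export
analyze_force_volume <- function(map, config = analysis_config()) {
  if (!inherits(map, "force_volume_map")) abort("`map` must be a force_volume_map")
  if (length(map$curves) == 0) abort("empty map")
  bind_rows(lapply(map$curves, analyze_force_curve,
                   config = config, cell = map$label))
}

#' Analyze a population of cells
#'
#' @param maps A list of [force_volume_map()] objects (e.g. from
#'   [generate_cell_population()]).
#' @param config An [analysis_config()].
#' @return A tibble of per-pixel rows across all cells; the `cell` column
#'   carries each map's label (or `cell_##` when unlabelled).
#' @export
analyze_cells <- function(maps, config = analysis_config()) {
  stopifnot(is.list(maps), length(maps) >= 1)
  bind_rows(lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    if (!nzchar(m$label)) m$label <- sprintf("cell_%02d", i)
    analyze_force_volume(m, config)
  }))
}
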