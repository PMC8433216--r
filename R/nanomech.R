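#' Analysis configuration for per-curve nanomechanics
#'
#' @param fit_range_nm Indentation window (min, max) in nm used for the Hertz
#'   fit; the elastic region. Typical choices: 100-200 nm for stiff captured
#'   cells, up to 400 nm for soft cultured cells.
#' @param nu Poisson ratio, default 0.5 (incompressible cell).
#' @param adhesion_cutoff_pN Minimum dip magnitude (below the zero-force line)
#'   for an adhesion event; default 10 pN, chosen against measurement noise.
#' @param neighbor_window A retraction sample is an adhesion minimum iff it is
#'   strictly less than each of this many samples on both sides; default 5.
#' @param baseline_fraction Fraction of samples, farthest from the surface,
#'   used to fit the zero-force line; default 0.1.
#' @param qc_min_fit_r2 Minimum Hertz-fit R^2 for a curve to pass QC.
#' @param noise_scale_pN Expected baseline noise RMS; a curve whose baseline
#'   residual SD exceeds five times this is rejected as unclear.
#' @param contact_threshold_factor Contact is declared where the
#'   baseline-corrected approach force first exceeds this multiple of the
#'   baseline residual SD and stays above it.
#' @param contact_sustain Number of consecutive samples that must stay above
#'   the threshold for a crossing to count.
#' @param contact_refine Refine the threshold crossing by regressing
#'   `F^(2/3)` on tip height minus deflection above the threshold and
#'   extrapolating to zero force (exact for noiseless Hertzian contact);
#'   removes the systematic late-detection bias of the bare threshold rule.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(fit_range_nm = c(100, 200),
                            nu = 0.5,
                            adhesion_cutoff_pN = 10,
                            neighbor_window = 5L,
                            baseline_fraction = 0.1,
                            qc_min_fit_r2 = 0.90,
                            noise_scale_pN = 5,
                            contact_threshold_factor = 3,
                            contact_sustain = 10L,
                            contact_refine = TRUE) {
  if (length(fit_range_nm) != 2 || fit_range_nm[1] >= fit_range_nm[2]) {
    abort("`fit_range_nm` must be an increasing pair")
  }
  if (!(nu >= 0 && nu < 0.5 + 1e-9)) abort("`nu` must be in [0, 0.5]")
  if (neighbor_window < 1) abort("`neighbor_window` must be >= 1")
  if (!(baseline_fraction > 0 && baseline_fraction < 0.5)) {
    abort("`baseline_fraction` must be in (0, 0.5)")
  }
  structure(
    list(
      fit_range_nm = fit_range_nm, nu = nu,
      adhesion_cutoff_pN = adhesion_cutoff_pN,
      neighbor_window = as.integer(neighbor_window),
      baseline_fraction = baseline_fraction,
      qc_min_fit_r2 = qc_min_fit_r2,
      noise_scale_pN = noise_scale_pN,
      contact_threshold_factor = contact_threshold_factor,
      contact_sustain = as.integer(contact_sustain),
      contact_refine = contact_refine
    ),
    class = "analysis_config"
  )
}

#' Zero-force baseline of a segment
#'
#' Least-squares line through the far-from-surface fraction of a segment's
#' force samples; subtracting it defines the zero-force line used by every
#' downstream step.
#'
#' @param z_nm,force_pN Segment samples, ordered along the segment.
#' @param baseline_fraction Fraction of samples used, taken from the
#'   far-from-surface end.
#' @param far Which end of the segment is far from the surface: `"first"`
#'   (approach segments) or `"last"` (retraction segments ordered from the
#'   surface outward).
#' @return A list with `offset_pN` (force at z = 0), `slope_pN_per_um`,
#'   `residual_sd_pN`, and `line(z_nm)`, the fitted baseline evaluator.
#' @examples
#' b <- estimate_baseline(1:100, rep(3, 100))
#' c(b$offset_pN, b$slope_pN_per_um)
#' @export
estimate_baseline <- function(z_nm, force_pN, baseline_fraction = 0.1,
                              far = c("first", "last")) {
  far <- match.arg(far)
  n <- length(z_nm)
  if (n < 16 || length(force_pN) != n) abort("segment too short")
  m <- max(4L, floor(n * baseline_fraction))
  idx <- if (far == "first") seq_len(m) else seq(n - m + 1L, n)
  zb <- z_nm[idx]; fb <- force_pN[idx]
  zc <- zb - mean(zb)
  slope <- if (sum(zc^2) > 0) sum(zc * fb) / sum(zc^2) else 0
  intercept <- mean(fb) - slope * mean(zb)
  res <- fb - (intercept + slope * zb)
  list(
    offset_pN = intercept,
    slope_pN_per_um = slope * 1000,
    residual_sd_pN = if (m > 2) sqrt(sum(res^2) / (m - 2)) else 0,
    line = function(z) intercept + slope * z
  )
}

#' Detect the tip-sample contact point
#'
#' Finds the z position where the baseline-corrected approach force first
#' exceeds a noise threshold (`contact_threshold_factor` times the baseline
#' residual SD) and remains above it for `contact_sustain` samples. With
#' `contact_refine = TRUE` (default) the crossing is then refined by a
#' Hertzian back-extrapolation: for spherical contact, F^(2/3) is linear in
#' u = z - corrected deflection, so regressing F^(2/3) on u over the
#' above-threshold points inside the fit window and extrapolating to zero
#' force recovers the contact point exactly on noiseless data and without the
#' late bias a bare threshold incurs on soft samples.
#'
#' @param curve A [force_curve()].
#' @param config An [analysis_config()].
#' @return Contact point z in nm (scalar).
#' @export
detect_contact_point <- function(curve, config = analysis_config()) {
  app <- curve_force(curve, "approach")
  bl <- estimate_baseline(app$z_nm, app$force_pN, config$baseline_fraction)
  f <- app$force_pN - bl$line(app$z_nm)
  thr <- max(config$contact_threshold_factor * bl$residual_sd_pN, 1e-9)

  above <- f > thr
  n <- length(f)
  sustain <- max(1L, config$contact_sustain)
  cross <- NA_integer_
  cand <- which(above)
  for (i in cand) {
    j <- seq(i, min(n, i + sustain - 1L))
    if (all(above[j]) && (i + sustain - 1L) <= n) { cross <- i; break }
  }
  if (is.na(cross)) abort("no contact detected")
  z_cross <- app$z_nm[cross]

  if (!isTRUE(config$contact_refine)) return(z_cross)

  k <- curve$cantilever$spring_constant
  u <- app$z_nm - f / (PN_PER_NM_DEFLECTION * k)
  sel <- which(above & seq_len(n) >= cross &
                 (u - u[cross]) <= config$fit_range_nm[2])
  if (length(sel) >= 5) {
    y <- f[sel]^(2 / 3)
    x <- u[sel]
    xc <- x - mean(x)
    b <- sum(xc * y) / sum(xc^2)
    if (is.finite(b) && b > 0) {
      a <- mean(y) - b * mean(x)
      z0 <- -a / b
      # accept only a physically sensible refinement near the crossing
      if (is.finite(z0) && z0 <= z_cross &&
          z0 >= z_cross - config$fit_range_nm[2]) {
        return(z0)
      }
    }
  }
  z_cross
}

#' Indentation curve from an approach segment
#'
#' Converts the approach segment to (indentation, force) pairs:
#' `delta = (z - z0) - corrected deflection`, clipped at zero, with force
#' corrected by the fitted baseline. On a rigid surface (deflection tracking z
#' one-to-one) the indentation is identically zero.
#'
#' @param curve A [force_curve()].
#' @param contact_point_z Contact point in nm, from [detect_contact_point()].
#' @param config An [analysis_config()] (baseline fraction).
#' @return A tibble with `delta_nm` (>= 0) and `force_pN`.
#' @export
compute_indentation <- function(curve, contact_point_z,
                                config = analysis_config()) {
  app <- curve_force(curve, "approach")
  if (contact_point_z < min(app$z_nm) || contact_point_z > max(app$z_nm)) {
    abort("contact point outside the approach z range")
  }
  bl <- estimate_baseline(app$z_nm, app$force_pN, config$baseline_fraction)
  f <- app$force_pN - bl$line(app$z_nm)
  k <- curve$cantilever$spring_constant
  d <- f / (PN_PER_NM_DEFLECTION * k)
  delta <- (app$z_nm - contact_point_z) - d
  tibble(delta_nm = pmax(delta, 0), force_pN = f)
}

#' Fit the Hertz contact model to an indentation curve
#'
#' Linearised least-squares fit of force against indentation^(3/2) through
#' the origin, restricted to the configured indentation window (the elastic
#' region). The through-origin slope maps to the Young's modulus via
#' `E = slope * (3/4) * (1 - nu^2) / sqrt(R)` with the contact point fixed
#' beforehand, not co-fitted.
#'
#' @param indentation A tibble from [compute_indentation()] (`delta_nm`,
#'   `force_pN`).
#' @param R_m Tip radius in m.
#' @param config An [analysis_config()] (fit range, Poisson ratio).
#' @return An object of class `hertz_fit` with elements `E_Pa`, `nu`, `R_m`,
#'   `fit_range_nm`, `r_squared`, `n`, `slope_pN_nm32`. Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' p <- mechanical_preset("ctc_localized", noise_rms_pN = 0,
#'                        baseline_slope_pN_per_um = 0)
#' cv <- generate_force_curve(10e3, p, seed = 1)
#' ind <- compute_indentation(cv, detect_contact_point(cv))
#' fit_hertz(ind, R_m = 3e-6)$E_Pa  # ~10000
#' @export
fit_hertz <- function(indentation, R_m, config = analysis_config()) {
  d <- indentation$delta_nm
  f <- indentation$force_pN
  sel <- d >= config$fit_range_nm[1] & d <= config$fit_range_nm[2]
  if (sum(sel) < 8) abort("fit range empty")
  x <- d[sel]^1.5
  y <- f[sel]
  slope <- sum(x * y) / sum(x^2)
  if (!is.finite(slope) || slope <= 0) abort("non-physical fit")
  yhat <- slope * x
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - yhat)^2) / ss_tot else 1
  structure(
    list(
      E_Pa = hertz_E_from_slope(slope, R_m, config$nu),
      nu = config$nu, R_m = R_m,
      fit_range_nm = config$fit_range_nm,
      r_squared = r2, n = sum(sel), slope_pN_nm32 = slope
    ),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "<hertz_fit> E = %.4g kPa (nu = %g, R = %g um), R^2 = %.4f, n = %d in [%g, %g] nm\n",
    x$E_Pa / 1e3, x$nu, x$R_m * 1e6, x$r_squared, x$n,
    x$fit_range_nm[1], x$fit_range_nm[2]
  ))
  invisible(x)
}

#' Deformation at maximum load
#'
#' The surface deformation D is the indentation reached at the maximum
#' applied force on the approach segment.
#'
#' @param indentation A tibble from [compute_indentation()].
#' @return D in nm.
#' @export
measure_deformation <- function(indentation) {
  if (nrow(indentation) == 0) abort("empty indentation curve")
  indentation$delta_nm[which.max(indentation$force_pN)]
}
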