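#' Cell capture efficiency
#'
#' The fraction of captured cells with respect to the number of cells loaded
#' into the device, as a percentage. Vectorised, so it drops straight into
#' `dplyr::mutate()` over a table of capture experiments.
#'
#' @param n_captured,n_spiked Non-negative counts; `n_spiked` must be > 0.
#' @return Percentage(s) in \[0, 100\].
#' @examples
#' capture_efficiency(895, 1000)  # 89.5
#' @export
capture_efficiency <- function(n_captured, n_spiked) {
  if (any(n_spiked <= 0)) abort("undefined efficiency: n_spiked must be > 0")
  if (any(n_captured < 0)) abort("argument error: negative capture count")
  100 * n_captured / n_spiked
}

#' Capture purity
#'
#' The ratio of captured target cells to the total number of captured cells
#' including white blood cells, as a percentage.
#'
#' @param n_target,n_wbc Non-negative counts; their sum must be > 0.
#' @return Percentage(s) in \[0, 100\].
#' @examples
#' purity(28, 72)  # 28
#' @export
purity <- function(n_target, n_wbc) {
  if (any(n_target < 0) || any(n_wbc < 0)) abort("argument error: negative count")
  if (any(n_target + n_wbc == 0)) abort("undefined purity: no captured cells")
  100 * n_target / (n_target + n_wbc)
}

#' White-blood-cell background density
#'
#' Captured WBCs per mm^2 of channel area.
#'
#' @param n_wbc Non-negative count(s).
#' @param channel_area_mm2 Channel area(s) in mm^2, > 0.
#' @return WBCs per mm^2.
#' @export
background_density <- function(n_wbc, channel_area_mm2) {
  if (any(channel_area_mm2 <= 0)) abort("argument error: channel area must be > 0")
  if (any(n_wbc < 0)) abort("argument error: negative count")
  n_wbc / channel_area_mm2
}

#' Spike-in recovery regression
#'
#' Ordinary least-squares line of captured versus spiked cell counts on
#' log10-log10 axes, the standard way spike-in dose response is recorded. A
#' slope of 1 with high r^2 indicates equal capture response across cell
#' loads.
#'
#' @param spiked,captured Paired positive counts, >= 3 points.
#' @return A one-row tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @examples
#' spike_recovery_regression(c(100, 500, 1000), c(90, 450, 900))
#' @export
spike_recovery_regression <- function(spiked, captured) {
  if (length(spiked) < 3 || length(captured) != length(spiked)) {
    abort("need >= 3 paired points")
  }
  if (any(spiked <= 0) || any(captured <= 0)) {
    abort("domain error: counts must be positive for log regression")
  }
  fit <- lm(log10(captured) ~ log10(spiked))
  # summary.lm warns on exactly collinear (perfect-recovery) fixtures
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n = length(spiked)
  )
}

#' CTCs per millilitre of blood, aggregated across patients
#'
#' For each qualifying patient computes `count / blood_ml` for the requested
#' capture antibody and reports the arithmetic mean and sample SD across
#' patients (each patient weighted equally). Patients without a count for the
#' antibody are excluded. With one qualifying patient the SD is reported as 0
#' and flagged (`n1 = TRUE`). `pooled = TRUE` instead divides the pooled count
#' by the pooled blood volume.
#'
#' @param records Patient records: a data frame with columns `patient_id`,
#'   `group`, `blood_ml` and one count column per antibody (NA = not assayed).
#'   See [ctc_patient_counts()] for the bundled clinical table.
#' @param antibody Name of the count column (e.g. `"epcam"`, `"psa"`,
#'   `"psma"`).
#' @param group Optional group filter (e.g. `"localized"`).
#' @param pooled Use pooled counts / pooled volume instead of per-patient
#'   averaging.
#' @return A one-row tibble with `antibody`, `group`, `n_patients`,
#'   `mean_ctcs_per_ml`, `sd_ctcs_per_ml`, `n1`.
#' @examples
#' ctcs_per_ml(ctc_patient_counts(), "psa", "localized")
#' @export
ctcs_per_ml <- function(records, antibody, group = NULL, pooled = FALSE) {
  if (!antibody %in% names(records)) {
    abort(sprintf("no data: no column '%s' in records", antibody))
  }
  r <- records
  if (!is.null(group)) r <- dplyr::filter(r, .data$group == !!group)
  r <- r[!is.na(r[[antibody]]), ]
  if (nrow(r) == 0) abort("no data: no qualifying records")
  if (any(r$blood_ml <= 0)) abort("argument error: blood_ml must be > 0")
  per_patient <- r[[antibody]] / r$blood_ml
  tibble(
    antibody = antibody,
    group = group %||% "all",
    n_patients = nrow(r),
    mean_ctcs_per_ml = if (pooled) sum(r[[antibody]]) / sum(r$blood_ml)
                       else mean(per_patient),
    sd_ctcs_per_ml = if (nrow(r) > 1 && !pooled) sd(per_patient) else 0,
    n1 = nrow(r) == 1
  )
}

#' Clinical per-patient CTC capture counts
#'
#' The bundled table of CTC counts captured from whole blood of six prostate
#' cancer patients (four with localized disease under active surveillance,
#' two metastatic), per capture antibody (anti-EpCAM, anti-PSA, anti-PSMA;
#' NA where an antibody was not assayed), with blood volumes in mL. All
#' captures were run at 20 uL/min with 10 ug/mL antibody.
#'
#' @return A tibble with columns `patient_id`, `age`, `gleason`, `psa_ng_ml`,
#'   `group`, `blood_ml`, `epcam`, `psa`, `psma`.
#' @examples
#' ctc_patient_counts()
#' @export
ctc_patient_counts <- function() {
  path <- system.file("extdata", "prostate_ctc_counts.csv", package = "ctcforce")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = "c", age = "i", gleason = "c",
                    psa_ng_ml = "c", group = "c", blood_ml = "d",
                    epcam = "d", psa = "d", psma = "d"
                  ))
}
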