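#' Detect adhesion rupture events on a retraction segment
#'
#' A retraction sample is an adhesion event iff its baseline-corrected force
#' is strictly less than the force of every one of the `neighbor_window`
#' samples on each side (samples with fewer neighbors on a side are
#' ineligible; ties disqualify), the force lies below the zero-force line,
#' and the dip magnitude is at least `adhesion_cutoff_pN`.
#'
#' @param force_pN Baseline-corrected retraction forces, ordered along the
#'   segment; must have at least `2 * neighbor_window + 1` samples.
#' @param separation_nm Optional tip-sample separation per sample, carried
#'   into the output.
#' @param config An [analysis_config()] (`neighbor_window`,
#'   `adhesion_cutoff_pN`).
#' @return A tibble, one row per event in order of position, with
#'   `sample_index`, `force_magnitude_pN` (positive dip depth) and
#'   `separation_nm` (NA when not supplied).
#' @examples
#' f <- rep(0, 40); f[15] <- -50
#' detect_adhesion_events(f)
#' @export
detect_adhesion_events <- function(force_pN, separation_nm = NULL,
                                   config = analysis_config()) {
  w <- config$neighbor_window
  n <- length(force_pN)
  if (n < 2 * w + 1) abort("segment too short")
  is_min <- rep(TRUE, n)
  for (kk in seq_len(w)) {
    left <- c(rep(NA, kk), force_pN[seq_len(n - kk)])
    right <- c(force_pN[-seq_len(kk)], rep(NA, kk))
    is_min <- is_min & !is.na(left) & !is.na(right) &
      force_pN < left & force_pN < right
  }
  idx <- which(is_min & force_pN < 0 & abs(force_pN) >= config$adhesion_cutoff_pN)
  tibble(
    sample_index = idx,
    force_magnitude_pN = -force_pN[idx],
    separation_nm = if (is.null(separation_nm)) NA_real_ else separation_nm[idx]
  )
}

#' Work of detachment
#'
#' Trapezoidal integral of the area confined between the zero-force line and
#' the retraction curve (only the region below the zero-force line
#' contributes), over tip-sample separation. Reported in attojoules
#' (1 aJ = 1000 pN nm).
#'
#' @param separation_nm Tip-sample separation per retraction sample.
#' @param force_pN Baseline-corrected retraction forces.
#' @return Work of detachment in aJ (>= 0).
#' @examples
#' s <- seq(0, 200, by = 10)
#' f <- -pmax(0, 100 - abs(100 - s))  # triangular dip, 100 pN deep, 200 nm base
#' compute_work_of_detachment(s, f)   # 10 aJ
#' @export
compute_work_of_detachment <- function(separation_nm, force_pN) {
  if (length(separation_nm) != length(force_pN) || length(force_pN) < 2) {
    abort("need paired separation/force samples")
  }
  o <- order(separation_nm)
  below <- pmax(0, -force_pN[o])
  abs(pracma::trapz(separation_nm[o], below)) / 1000
}
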