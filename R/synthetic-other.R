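#' Generate a synthetic fluorescence image
#'
#' Builds a flat-field raster at the background level with a brighter sample
#' region and additive Gaussian noise, plus the disjoint masks needed for
#' corrected-total-fluorescence quantification. The default geometry is a
#' centred square sample region and a two-pixel border frame as background.
#'
#' @param mean_signal Mean gray value inside the sample region; must satisfy
#'   `mean_signal >= background >= 0`.
#' @param background Mean gray value elsewhere.
#' @param dim Image dimension `c(rows, cols)`.
#' @param sample_mask,background_mask Optional logical matrices overriding the
#'   default geometry; must be disjoint.
#' @param noise_sd Gaussian noise SD (gray values).
#' @param seed Integer seed; the raster is a pure function of its arguments.
#' @return A [fluor_image()].
#' @examples
#' img <- generate_fluorescence_image(5, 2, noise_sd = 0, seed = 1)
#' corrected_total_fluorescence(img)
#' @export
generate_fluorescence_image <- function(mean_signal, background,
                                        dim = c(32L, 32L),
                                        sample_mask = NULL,
                                        background_mask = NULL,
                                        noise_sd = 0, seed = 1) {
  if (!(mean_signal >= background && background >= 0)) {
    abort("argument error: need mean_signal >= background >= 0")
  }
  nr <- dim[1]; nc <- dim[2]
  if (is.null(sample_mask)) {
    sample_mask <- matrix(FALSE, nr, nc)
    side <- max(2L, floor(min(nr, nc) / 3))
    r0 <- floor((nr - side) / 2); c0 <- floor((nc - side) / 2)
    sample_mask[r0 + seq_len(side), c0 + seq_len(side)] <- TRUE
  }
  if (is.null(background_mask)) {
    background_mask <- matrix(FALSE, nr, nc)
    background_mask[c(1, 2, nr - 1, nr), ] <- TRUE
    background_mask[, c(1, 2, nc - 1, nc)] <- TRUE
  }
  if (any(sample_mask & background_mask)) abort("argument error: overlapping masks")
  px <- withr::with_seed(as.integer(seed), {
    base <- matrix(background, nr, nc)
    base[sample_mask] <- mean_signal
    if (noise_sd > 0) base <- base + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    base
  })
  fluor_image(px, sample_mask, background_mask)
}

#' Generate a synthetic spike-in capture experiment
#'
#' Emulates one microfluidic spike-in run: the captured-cell count is
#' binomial in the number of spiked cells with per-cell capture probability
#' `p_capture`, and the captured white-blood-cell background is Poisson with
#' mean `n_wbc_background`.
#'
#' @param p_capture Per-cell capture probability in \[0, 1\].
#' @param n_spiked Number of spiked cells.
#' @param n_wbc_background Expected number of contaminating WBCs.
#' @param seed Integer seed.
#' @param flow_rate_ul_min,matrix,channel_area_mm2,storage_h Annotations
#'   carried through to the output record.
#' @return A one-row tibble (a capture-experiment record) with columns
#'   `n_spiked`, `n_captured`, `n_wbc_captured`, `flow_rate_ul_min`,
#'   `matrix`, `channel_area_mm2`, `storage_h`.
#' @examples
#' generate_capture_experiment(0.895, 1000, 60, seed = 1)
#' @export
generate_capture_experiment <- function(p_capture, n_spiked, n_wbc_background,
                                        seed,
                                        flow_rate_ul_min = 20,
                                        matrix = c("medium", "blood"),
                                        channel_area_mm2 = 100,
                                        storage_h = 0) {
  if (!is.numeric(p_capture) || p_capture < 0 || p_capture > 1) {
    abort("argument error: `p_capture` must be in [0, 1]")
  }
  matrix <- match.arg(matrix)
  withr::with_seed(as.integer(seed), {
    tibble(
      n_spiked = as.integer(n_spiked),
      n_captured = rbinom(1, as.integer(n_spiked), p_capture),
      n_wbc_captured = rpois(1, n_wbc_background),
      flow_rate_ul_min = flow_rate_ul_min,
      matrix = matrix,
      channel_area_mm2 = channel_area_mm2,
      storage_h = storage_h
    )
  })
}
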