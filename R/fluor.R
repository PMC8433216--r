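#' Fluorescence image with quantification masks
#'
#' A single-channel intensity raster together with a disjoint sample mask
#' (the selection to quantify, e.g. an antibody-coated region) and background
#' mask. All corrected-total-fluorescence arithmetic is defined on gray
#' values, so multi-channel images must be split before use.
#'
#' @param pixels Numeric matrix of gray values.
#' @param sample_mask,background_mask Logical matrices of the same dimension
#'   as `pixels`; must be disjoint and each non-empty.
#' @return An object of class `fluor_image`.
#' @export
fluor_image <- function(pixels, sample_mask, background_mask) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix")
  }
  for (m in list(sample_mask, background_mask)) {
    if (!is.matrix(m) || !is.logical(m) || !identical(dim(m), dim(pixels))) {
      abort("masks must be logical matrices with the same dimension as `pixels`")
    }
  }
  if (any(sample_mask & background_mask)) {
    abort("argument error: overlapping masks")
  }
  if (!any(sample_mask)) abort("empty selection")
  if (!any(background_mask)) abort("empty background")
  structure(
    list(pixels = pixels, sample_mask = sample_mask,
         background_mask = background_mask),
    class = "fluor_image"
  )
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf(
    "<fluor_image> %d x %d px, sample %d px, background %d px\n",
    nrow(x$pixels), ncol(x$pixels), sum(x$sample_mask), sum(x$background_mask)
  ))
  invisible(x)
}

#' Mean/SD intensity transfer
#'
#' Rescales an image so its global pixel mean and standard deviation match a
#' reference image: `out = a * pixels + b` with `a = sd_ref / sd_in` and
#' `b = mean_ref - a * mean_in`. This is the linear color-transfer
#' normalisation used to put fluorescence images acquired in different
#' sessions on a common intensity scale before quantification. The operation
#' is idempotent: applying it twice with the same reference equals applying
#' it once.
#'
#' @param image,reference [fluor_image()] objects; `reference` must have
#'   nonzero pixel SD, and a constant `image` cannot be rescaled.
#' @return A [fluor_image()] with transformed pixels and unchanged masks.
#' @export
transfer_mean_sd <- function(image, reference) {
  stopifnot(inherits(image, "fluor_image"), inherits(reference, "fluor_image"))
  sd_in <- sd(as.vector(image$pixels))
  sd_ref <- sd(as.vector(reference$pixels))
  if (!is.finite(sd_in) || sd_in == 0) abort("degenerate input: zero pixel SD")
  if (!is.finite(sd_ref) || sd_ref == 0) abort("degenerate input: reference has zero pixel SD")
  a <- sd_ref / sd_in
  b <- mean(reference$pixels) - a * mean(image$pixels)
  fluor_image(a * image$pixels + b, image$sample_mask, image$background_mask)
}

#' Integrated density of the sample selection
#'
#' `IntDen = Area x MGVsample`: the pixel count of the sample mask times the
#' mean gray value over it (algebraically, the sum of the masked pixels).
#'
#' @param image A [fluor_image()].
#' @return A single number.
#' @export
integrated_density <- function(image) {
  stopifnot(inherits(image, "fluor_image"))
  if (!any(image$sample_mask)) abort("empty selection")
  area <- sum(image$sample_mask)
  area * mean(image$pixels[image$sample_mask])
}

#' Corrected total fluorescence
#'
#' `CTF = IntDen - Area x MGVbackground = Area x (MGVsample - MGVbackground)`:
#' the integrated density of the selection minus the background contribution
#' scaled to the selection area. May be negative; reported as computed.
#'
#' @param image A [fluor_image()].
#' @return A single number.
#' @seealso [ctf_table()] for the full quantification row.
#' @export
corrected_total_fluorescence <- function(image) {
  stopifnot(inherits(image, "fluor_image"))
  if (!any(image$sample_mask)) abort("empty selection")
  if (!any(image$background_mask)) abort("empty background")
  area <- sum(image$sample_mask)
  mgv_s <- mean(image$pixels[image$sample_mask])
  mgv_b <- mean(image$pixels[image$background_mask])
  area * (mgv_s - mgv_b)
}

#' Full fluorescence quantification row
#'
#' @param image A [fluor_image()].
#' @param reference Optional [fluor_image()]; when given, [transfer_mean_sd()]
#'   is applied before quantification.
#' @return A one-row tibble with `area_px`, `mgv_sample`, `mgv_background`,
#'   `int_den`, `ctf`.
#' @export
ctf_table <- function(image, reference = NULL) {
  if (!is.null(reference)) image <- transfer_mean_sd(image, reference)
  area <- sum(image$sample_mask)
  mgv_s <- mean(image$pixels[image$sample_mask])
  mgv_b <- mean(image$pixels[image$background_mask])
  tibble(
    area_px = area, mgv_sample = mgv_s, mgv_background = mgv_b,
    int_den = area * mgv_s, ctf = area * (mgv_s - mgv_b)
  )
}

#' Antibody saturation summary
#'
#' Fits a one-site binding (rectangular hyperbola) curve
#' `CTF(c) = CTFmax * c / (K + c)` to corrected-total-fluorescence readings
#' across antibody concentrations and reports the smallest tested
#' concentration whose predicted CTF reaches 95% of the fitted plateau.
#'
#' @param concentrations Antibody concentrations, ug/mL (>= 4 points).
#' @param ctf_values Corresponding CTF readings.
#' @return A one-row tibble with `ctf_max`, `K_ug_ml`,
#'   `saturating_concentration`, `nonmonotone` (gross non-monotonicity flag).
#' @export
saturation_summary <- function(concentrations, ctf_values) {
  if (length(concentrations) < 4 || length(ctf_values) != length(concentrations)) {
    abort("insufficient points: need >= 4 paired concentration/CTF values")
  }
  o <- order(concentrations)
  conc <- concentrations[o]; ctf <- ctf_values[o]
  nonmono <- sd(ctf) > 0 && stats::cor(conc, ctf, method = "spearman") < 0
  if (isTRUE(nonmono)) {
    warn("CTF response is grossly non-monotone in concentration; fit returned anyway")
  }
  # flat responses push K to its boundary at 0; the optimizer warns there
  fit <- suppressWarnings(minpack.lm::nlsLM(
    ctf ~ ctf_max * conc / (K + conc),
    start = list(ctf_max = max(ctf), K = max(median(conc), 1e-6)),
    lower = c(ctf_max = 0, K = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ))
  est <- coef(fit)
  pred <- est[["ctf_max"]] * conc / (est[["K"]] + conc)
  sat <- conc[pred >= 0.95 * est[["ctf_max"]]]
  tibble(
    ctf_max = est[["ctf_max"]],
    K_ug_ml = est[["K"]],
    saturating_concentration = if (length(sat)) sat[1] else NA_real_,
    nonmonotone = isTRUE(nonmono)
  )
}
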