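#' Tidy a Hertz fit
#'
#' @param x A `hertz_fit` from [fit_hertz()].
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter.
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(
    term = c("E_Pa", "slope_pN_nm32"),
    estimate = c(x$E_Pa, x$slope_pN_nm32)
  )
}

#' @rdname tidy.hertz_fit
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n, nu = x$nu, R_m = x$R_m)
}

#' Tidy a density fit
#'
#' @param x A `density_fit` from [fit_density()].
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter.
#' @export
tidy.density_fit <- function(x, ...) {
  tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @rdname tidy.density_fit
#' @export
glance.density_fit <- function(x, ...) {
  tibble(family = x$family, logLik = x$loglik, nobs = x$n)
}
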