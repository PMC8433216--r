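#' Summarise a population of per-pixel measurements
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of one
#' measured quantity, with a Freedman-Diaconis histogram attached for
#' plotting.
#'
#' @param values Numeric measurements (n >= 2 after dropping NA).
#' @param quantity Tag for the quantity: `"E"`, `"D"`, `"F"`, `"WD"`, or any
#'   label.
#' @return A one-row tibble with `quantity`, `n`, `mean`, `sd`, `bin_width`;
#'   the full `histogram` (from [graphics::hist()], not plotted) is attached
#'   as an attribute.
#' @examples
#' summarize_population(c(1, 2, 3), "E")
#' @export
summarize_population <- function(values, quantity = "value") {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("insufficient data")
  h <- graphics::hist(values, breaks = "FD", plot = FALSE)
  out <- tibble(
    quantity = quantity,
    n = length(values),
    mean = mean(values),
    sd = sd(values),
    bin_width = h$breaks[2] - h$breaks[1]
  )
  attr(out, "histogram") <- h
  out
}

#' Summarise all four nanomechanical quantities per group
#'
#' Convenience wrapper over [summarize_population()] for per-pixel result
#' tables from [analyze_cells()]: summarises the Young's modulus E (kPa),
#' deformation D (nm), maximum adhesion force F (nN) and work of detachment
#' WD (aJ) of QC-passing pixels, optionally per group.
#'
#' @param results Per-pixel results with columns `E_Pa`, `D_nm`,
#'   `max_adhesion_pN`, `WD_aJ`, `qc_pass`, and optionally a grouping column.
#' @param group Name of the grouping column, or `NULL` for a single group.
#' @return A tibble with one row per group x quantity.
#' @export
summarize_quantities <- function(results, group = NULL) {
  pull_groups <- if (is.null(group)) list(all = results) else {
    split(results, results[[group]])
  }
  bind_rows(lapply(names(pull_groups), function(g) {
    r <- dplyr::filter(pull_groups[[g]], .data$qc_pass)
    qs <- list(
      E_kPa = r$E_Pa / 1e3, D_nm = r$D_nm,
      F_nN = r$max_adhesion_pN / 1e3, WD_aJ = r$WD_aJ
    )
    bind_rows(lapply(names(qs), function(q) {
      summarize_population(qs[[q]], q)
    })) %>% mutate(group = g, .before = 1)
  }))
}

#' Maximum-likelihood density fit (lognormal or Gaussian)
#'
#' Fits a probability density to measured values by maximum likelihood, the
#' way single-cell mechanics histograms are usually modelled. With
#' `family = "auto"` both candidates are fitted and the higher log-likelihood
#' wins (ties go to the Gaussian); the lognormal requires strictly positive
#' values.
#'
#' @param values Numeric measurements (n >= 8).
#' @param family `"lognormal"`, `"gauss"`, or `"auto"`.
#' @return An object of class `density_fit`: `family`, `estimate` (named
#'   parameter vector), `loglik`, `n`. Has [tidy()] and [glance()] methods.
#' @examples
#' x <- rlnorm(500, 1, 0.3)
#' fit_density(x, "auto")$family
#' @export
fit_density <- function(values, family = c("auto", "lognormal", "gauss")) {
  family <- match.arg(family)
  values <- values[!is.na(values)]
  if (length(values) < 8) abort("insufficient data")

  fit_one <- function(fam) {
    if (fam == "lognormal" && any(values <= 0)) {
      abort("domain error: lognormal fit requires positive values")
    }
    dist <- if (fam == "lognormal") "lnorm" else "norm"
    f <- fitdistrplus::fitdist(values, dist, method = "mle")
    structure(
      list(family = fam, estimate = f$estimate,
           loglik = f$loglik, n = length(values)),
      class = "density_fit"
    )
  }

  if (family != "auto") return(fit_one(family))
  gauss <- fit_one("gauss")
  if (any(values <= 0)) return(gauss)
  lnorm <- fit_one("lognormal")
  if (lnorm$loglik > gauss$loglik) lnorm else gauss
}

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf(
    "<density_fit %s> %s, logLik = %.2f, n = %d\n",
    x$family,
    paste(sprintf("%s = %.4g", names(x$estimate), x$estimate), collapse = ", "),
    x$loglik, x$n
  ))
  invisible(x)
}

#' Two-sample t test between groups
#'
#' Welch's unequal-variance two-sample t test (the safer default when group
#' variances differ; set `var_equal = TRUE` for the pooled test). Degenerate
#' input where both groups have zero variance is not an error: identical
#' constant groups return p = 1 by convention and are flagged.
#'
#' @param a,b Numeric measurements, n >= 2 each.
#' @param alpha Significance level; default 0.05.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return A one-row tibble with `t`, `df`, `p_value`, `significant`,
#'   `mean_a`, `mean_b`, `degenerate`.
#' @examples
#' two_sample_t_test(rnorm(20), rnorm(20, 1))
#' @export
two_sample_t_test <- function(a, b, alpha = 0.05, var_equal = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs n >= 2")
  if (sd(a) == 0 && sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble(
      t = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
      df = NA_real_,
      p_value = if (same) 1 else 0,
      significant = !same,
      mean_a = mean(a), mean_b = mean(b),
      degenerate = TRUE
    ))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < alpha,
    mean_a = mean(a), mean_b = mean(b),
    degenerate = FALSE
  )
}

#' Compare two groups on all four nanomechanical quantities
#'
#' Runs [two_sample_t_test()] on QC-passing per-pixel values of E, D, maximum
#' adhesion force and work of detachment between two groups of a per-pixel
#' results table.
#'
#' @param results Per-pixel results with a grouping column.
#' @param group Name of the grouping column (must have exactly two levels).
#' @param alpha Significance level.
#' @return A tibble with one row per quantity.
#' @export
compare_groups <- function(results, group = "group", alpha = 0.05) {
  lv <- unique(results[[group]])
  if (length(lv) != 2) abort("`group` must have exactly two levels")
  r <- dplyr::filter(results, .data$qc_pass)
  qs <- c(E_kPa = "E_Pa", D_nm = "D_nm", F_nN = "max_adhesion_pN", WD_aJ = "WD_aJ")
  scale <- c(E_kPa = 1e-3, D_nm = 1, F_nN = 1e-3, WD_aJ = 1)
  bind_rows(lapply(names(qs), function(q) {
    a <- r[[qs[[q]]]][r[[group]] == lv[1]] * scale[[q]]
    b <- r[[qs[[q]]]][r[[group]] == lv[2]] * scale[[q]]
    two_sample_t_test(a, b, alpha) %>%
      mutate(quantity = q, group_a = lv[1], group_b = lv[2], .before = 1)
  }))
}
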