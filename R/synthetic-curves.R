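#' Generate a synthetic force curve
#'
#' Simulates one approach/retraction force-distance record for a cell of
#' Young's modulus `E_Pa` probed by the preset's cantilever. The approach is
#' a zero-force baseline (with drift `baseline_slope_pN_per_um` and Gaussian
#' noise `noise_rms_pN`) up to the contact point, followed by Hertzian
#' loading to a setpoint drawn uniformly from `load_range_nN`. The retraction
#' unloads elastically along the same Hertz branch and then shows K sawtooth
#' adhesion dips below the zero-force line (K drawn from
#' `adhesion_event_count_range`): a linear ramp to the rupture force followed
#' by an instantaneous jump back to baseline, dips separated by more than six
#' samples. Noiseless curves satisfy the Hertz relation exactly beyond the
#' contact point; z sample spacing never exceeds `z_spacing_nm` (<= 2 nm).
#'
#' The generated object carries a `truth` attribute (contact z, modulus,
#' load, dip depths) used by recovery tests.
#'
#' @param E_Pa Young's modulus of the simulated cell surface, Pa.
#' @param preset A [mechanical_preset()].
#' @param seed Integer seed; the curve is a pure function of
#'   `(E_Pa, preset, seed)`.
#' @param label,grid_position Passed to [force_curve()].
#' @return A [force_curve()].
#' @examples
#' p <- mechanical_preset("ctc_localized", noise_rms_pN = 0)
#' cv <- generate_force_curve(23.9e3, p, seed = 1)
#' attr(cv, "truth")$contact_z_nm
#' @export
generate_force_curve <- function(E_Pa, preset, seed,
                                 label = "", grid_position = NULL) {
  stopifnot(inherits(preset, "mechanical_preset"), E_Pa > 0)
  withr::with_seed(as.integer(seed), {
    k <- preset$cantilever$spring_constant
    R <- preset$cantilever$tip_radius
    pref <- hertz_prefactor_pN_nm32(E_Pa, R, preset$nu)

    load_pN <- runif(1, preset$load_range_nN[1], preset$load_range_nN[2]) * 1000
    delta_max <- (load_pN / pref)^(2 / 3)
    d_max <- load_pN / (PN_PER_NM_DEFLECTION * k)
    z0 <- preset$baseline_span_nm
    if (z0 + delta_max + d_max > preset$max_z_travel_nm) {
      abort(sprintf(
        "travel exceeded: load %.3g nN needs %.0f nm of z travel (max %.0f nm)",
        load_pN / 1000, z0 + delta_max + d_max, preset$max_z_travel_nm
      ))
    }

    sp <- preset$z_spacing_nm
    # In contact, dz = ddelta * (1 + d(deflection)/d(delta)); shrink the
    # indentation step so z spacing stays below the configured cap.
    slope_max <- 1.5 * pref * sqrt(delta_max) / (PN_PER_NM_DEFLECTION * k)
    ddelta <- sp / (1 + slope_max)
    n_contact <- max(2L, ceiling(delta_max / ddelta) + 1L)
    delta <- seq(0, delta_max, length.out = n_contact)
    f_hertz <- pref * delta^1.5
    z_contact <- z0 + delta + f_hertz / (PN_PER_NM_DEFLECTION * k)

    z_base <- seq(0, z0 - sp, by = sp)
    z_app <- c(z_base, z_contact)
    f_app <- c(rep(0, length(z_base)), f_hertz)

    # Retraction: elastic unload on the same branch, then adhesion dips.
    adh <- build_adhesion_profile(preset)
    z_adh <- z0 - sp * seq_len(length(adh))
    z_ret <- c(rev(z_contact), z_adh)
    f_ret <- c(rev(f_hertz), adh)

    drift <- function(z) preset$baseline_slope_pN_per_um * z / 1000
    noise <- function(n) if (preset$noise_rms_pN > 0) {
      rnorm(n, 0, preset$noise_rms_pN)
    } else {
      numeric(n)
    }
    to_defl <- function(f) f / (PN_PER_NM_DEFLECTION * k)

    approach <- tibble(
      z_nm = z_app,
      deflection_nm = to_defl(f_app + drift(z_app) + noise(length(z_app)))
    )
    retraction <- tibble(
      z_nm = z_ret,
      deflection_nm = to_defl(f_ret + drift(z_ret) + noise(length(z_ret)))
    )

    out <- force_curve(approach, retraction,
                       cantilever = preset$cantilever,
                       label = label, grid_position = grid_position)
    attr(out, "truth") <- list(
      E_Pa = E_Pa, load_pN = load_pN, contact_z_nm = z0,
      delta_max_nm = delta_max,
      dip_depths_pN = attr(adh, "depths"),
      n_dips = length(attr(adh, "depths"))
    )
    out
  })
}

# Sawtooth adhesion profile (force in pN, one value per retraction sample
# past the contact point). Consumes RNG draws; call inside with_seed().
build_adhesion_profile <- function(preset,
                                   n_ramp = 30L, n_gap = 10L, n_tail = 120L) {
  # n_tail keeps the far-from-surface baseline window (baseline_fraction of
  # the whole retraction) clear of the last rupture event.
  cr <- preset$adhesion_event_count_range
  K <- if (cr[1] == cr[2]) cr[1] else sample(seq(cr[1], cr[2]), 1)
  depths <- numeric(0)
  if (K >= 1) {
    first <- max(rnorm(1, preset$adhesion_mean_pN, preset$adhesion_sd_pN), 50)
    rest <- if (K > 1) pmax(first * runif(K - 1, 0.2, 0.8), 30) else numeric(0)
    depths <- c(first, rest)
  }
  prof <- rep(0, n_gap)
  for (d in depths) {
    ramp <- -seq(d / n_ramp, d, length.out = n_ramp)
    prof <- c(prof, ramp, rep(0, n_gap))
  }
  prof <- c(prof, rep(0, n_tail))
  attr(prof, "depths") <- depths
  prof
}

draw_modulus <- function(mean_Pa, sd_Pa, distribution) {
  if (distribution == "lognormal") {
    s2 <- log(1 + (sd_Pa / mean_Pa)^2)
    rlnorm(1, log(mean_Pa) - s2 / 2, sqrt(s2))
  } else {
    e <- rnorm(1, mean_Pa, sd_Pa)
    while (e <= 0) e <- rnorm(1, mean_Pa, sd_Pa)
    e
  }
}

#' Generate a synthetic force-volume map
#'
#' Draws one cell-level Young's modulus from the preset distribution and one
#' loading setpoint (constant across the map, as in force-volume acquisition),
#' applies small per-pixel lognormal jitter (`pixel_jitter` relative SD,
#' mean-one) around the cell modulus, and generates one curve per pixel.
#'
#' @param preset A [mechanical_preset()].
#' @param seed Integer seed; the map is a pure function of `(preset, seed)`.
#' @param label Map label (e.g. a cell id).
#' @return A [force_volume_map()] with a `truth` attribute
#'   (cell modulus, per-pixel moduli, load).
#' @examples
#' m <- generate_force_volume(mechanical_preset("ctc_metastatic"), seed = 7)
#' length(m$curves)  # 64
#' @export
generate_force_volume <- function(preset, seed, label = "") {
  stopifnot(inherits(preset, "mechanical_preset"))
  n <- preset$grid[1] * preset$grid[2]
  withr::with_seed(as.integer(seed), {
    E_cell <- draw_modulus(preset$E_mean_Pa, preset$E_sd_Pa, preset$E_distribution)
    load_nN <- runif(1, preset$load_range_nN[1], preset$load_range_nN[2])
    s2 <- log(1 + preset$pixel_jitter^2)
    E_px <- E_cell * rlnorm(n, -s2 / 2, sqrt(s2))
    subseeds <- sample.int(.Machine$integer.max - 1L, n)
  })
  fixed <- preset
  fixed$load_range_nN <- c(load_nN, load_nN)
  curves <- lapply(seq_len(n), function(i) {
    row <- (i - 1) %/% preset$grid[2] + 1
    col <- (i - 1) %% preset$grid[2] + 1
    generate_force_curve(E_px[i], fixed, subseeds[i],
                         label = sprintf("%s_r%d_c%d", label, row, col),
                         grid_position = c(row, col))
  })
  out <- force_volume_map(curves, preset$grid[1], preset$grid[2],
                          preset$pixel_size_um, label = label)
  attr(out, "truth") <- list(E_cell_Pa = E_cell, E_pixel_Pa = E_px,
                             load_nN = load_nN)
  out
}

#' Generate a population of synthetic cells
#'
#' Each cell is an independent force-volume map with its own cell-level
#' modulus draw. Sub-seeds are derived deterministically from `seed`, so with
#' `n_cells = 1` the result is identical to a single
#' [generate_force_volume()] call with the derived sub-seed.
#'
#' @param preset A [mechanical_preset()].
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed.
#' @return A list of [force_volume_map()] objects labelled `cell_01`, ...
#' @export
generate_cell_population <- function(preset, n_cells, seed) {
  if (!is.numeric(n_cells) || n_cells < 1) {
    abort("argument error: `n_cells` must be >= 1")
  }
  n_cells <- as.integer(n_cells)
  subseeds <- withr::with_seed(as.integer(seed),
                               sample.int(.Machine$integer.max - 1L, n_cells))
  lapply(seq_len(n_cells), function(i) {
    generate_force_volume(preset, subseeds[i], label = sprintf("cell_%02d", i))
  })
}
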