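# Shared fixtures and independent oracles.

# Preset without noise, drift or adhesion events: curves satisfy the contact
# model exactly beyond the contact point.
quiet_preset <- function(name = "ctc_localized", ...) {
  mechanical_preset(name,
                    noise_rms_pN = 0, baseline_slope_pN_per_um = 0,
                    adhesion_event_count_range = c(0L, 0L), ...)
}

# Exhaustive O(n * w) neighbor scan: the independent oracle for the
# adhesion-event detector (strictly-less than every sample within `w` on both
# sides, below zero, magnitude >= cutoff).
brute_force_minima <- function(f, w = 5L, cutoff = 10) {
  n <- length(f)
  idx <- integer(0)
  for (i in seq_len(n)) {
    if (i <= w || i > n - w) next
    nb <- f[c((i - w):(i - 1), (i + 1):(i + w))]
    if (all(f[i] < nb) && f[i] < 0 && abs(f[i]) >= cutoff) idx <- c(idx, i)
  }
  idx
}

# Random retraction-like force trace with planted dips, for property tests.
random_retraction <- function(seed, n = 300) {
  withr::with_seed(seed, {
    f <- rnorm(n, 0, 5)
    k <- sample(0:4, 1)
    if (k > 0) {
      pos <- sort(sample(seq(20, n - 20), k))
      pos <- pos[c(TRUE, diff(pos) > 12)]
      f[pos] <- f[pos] - runif(length(pos), 15, 200)
    }
    f
  })
}

# A flat baseline-only curve (never contacts the surface).
baseline_only_curve <- function(n = 200, k = 0.08) {
  z <- seq(0, by = 2, length.out = n)
  force_curve(
    approach = data.frame(z_nm = z, deflection_nm = rep(0, n)),
    retraction = data.frame(z_nm = rev(z), deflection_nm = rep(0, n)),
    cantilever = cantilever_spec(spring_constant = k)
  )
}
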