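#' Write a force-volume map to a curve container
#'
#' The on-disk container is a directory holding one tab-separated table per
#' curve (columns `segment`, `z_nm`, `deflection_nm`) plus a human-readable
#' YAML sidecar (`metadata.yaml`) with the cantilever spec, grid geometry and
#' units. Numbers are serialised with 17 significant digits so a write/read
#' round trip reproduces every double exactly, and output is byte-stable for
#' identical input.
#'
#' @param map A [force_volume_map()].
#' @param path Directory to create (or reuse) for the container.
#' @return `path`, invisibly.
#' @seealso [read_curve_container()]
#' @export
write_curve_container <- function(map, path) {
  if (!inherits(map, "force_volume_map")) abort("`map` must be a force_volume_map")
  if (length(map$curves) == 0) abort("empty map")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("I/O error: cannot create '%s'", path))

  meta <- list(
    format = "ctcforce-curve-container",
    version = 1L,
    label = map$label,
    n_rows = map$n_rows,
    n_cols = map$n_cols,
    pixel_size_um = map$pixel_size,
    cantilever = list(
      spring_constant_N_per_m = map$cantilever$spring_constant,
      tip_radius_m = map$cantilever$tip_radius,
      approach_velocity_um_per_s = map$cantilever$approach_velocity
    ),
    units = list(z = "nm", deflection = "nm", pixel_size = "um"),
    curve_labels = vapply(map$curves, function(cv) cv$label, character(1))
  )
  yaml::write_yaml(meta, file.path(path, "metadata.yaml"), precision = 17)

  for (i in seq_along(map$curves)) {
    cv <- map$curves[[i]]
    row <- (i - 1) %/% map$n_cols + 1
    col <- (i - 1) %% map$n_cols + 1
    tab <- bind_rows(
      mutate(cv$approach, segment = "approach"),
      mutate(cv$retraction, segment = "retraction")
    )
    lines <- c(
      "segment\tz_nm\tdeflection_nm",
      sprintf("%s\t%.17g\t%.17g", tab$segment, tab$z_nm, tab$deflection_nm)
    )
    f <- file(file.path(path, sprintf("curve_r%03d_c%03d.tsv", row, col)),
              open = "wb")
    writeLines(lines, f, sep = "\n")
    close(f)
  }
  invisible(path)
}

#' Read a curve container into a force-volume map
#'
#' Inverse of [write_curve_container()]. Units are checked against the sidecar
#' and normalised to the package-internal system (nm, N/m); a sidecar without
#' a `units` block is rejected rather than silently assumed.
#'
#' @param path Container directory written by [write_curve_container()].
#' @return A [force_volume_map()] with all invariants enforced.
#' @export
read_curve_container <- function(path) {
  meta_path <- file.path(path, "metadata.yaml")
  if (!dir.exists(path) || !file.exists(meta_path)) {
    abort(sprintf("metadata error: no metadata.yaml under '%s'", path))
  }
  meta <- yaml::read_yaml(meta_path)
  for (fld in c("n_rows", "n_cols", "pixel_size_um", "cantilever")) {
    if (is.null(meta[[fld]])) abort(sprintf("metadata error: missing field '%s'", fld))
  }
  cl <- meta$cantilever
  if (is.null(cl$spring_constant_N_per_m) || is.null(cl$tip_radius_m)) {
    abort("metadata error: cantilever spring_constant/tip_radius missing")
  }
  u <- meta$units
  if (is.null(u) || is.null(u$z) || is.null(u$deflection)) {
    abort("unit error: sidecar lacks a complete units block")
  }
  if (!identical(u$z, "nm") || !identical(u$deflection, "nm")) {
    abort(sprintf("unit error: unsupported units z='%s', deflection='%s'", u$z, u$deflection))
  }

  cant <- cantilever_spec(
    spring_constant = cl$spring_constant_N_per_m,
    tip_radius = cl$tip_radius_m,
    approach_velocity = cl$approach_velocity_um_per_s %||% NA_real_
  )
  n_rows <- meta$n_rows; n_cols <- meta$n_cols
  labels <- meta$curve_labels %||% rep("", n_rows * n_cols)

  curves <- vector("list", n_rows * n_cols)
  for (i in seq_len(n_rows * n_cols)) {
    row <- (i - 1) %/% n_cols + 1
    col <- (i - 1) %% n_cols + 1
    f <- file.path(path, sprintf("curve_r%03d_c%03d.tsv", row, col))
    if (!file.exists(f)) abort(sprintf("metadata error: missing curve table '%s'", f))
    tab <- utils::read.delim(f, colClasses = c("character", "numeric", "numeric"))
    app <- tab[tab$segment == "approach", c("z_nm", "deflection_nm")]
    ret <- tab[tab$segment == "retraction", c("z_nm", "deflection_nm")]
    curves[[i]] <- force_curve(
      app, ret, cantilever = cant,
      label = if (length(labels) >= i) labels[[i]] else "",
      grid_position = c(row, col)
    )
  }
  force_volume_map(curves, n_rows, n_cols, meta$pixel_size_um,
                   label = meta$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
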