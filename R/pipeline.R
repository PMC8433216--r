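#' Pipeline configuration
#'
#' @param groups Named list of groups, each a list with `preset` (a preset
#'   name or [mechanical_preset()]) and `n_cells`.
#' @param seed Master seed; every stage derives its sub-seeds from it
#'   deterministically, so one seed fixes the whole run.
#' @param analysis Named list of [analysis_config()] overrides applied on top
#'   of each preset's fit range and noise scale.
#' @param write_containers Write each generated cell to a curve container and
#'   analyze the re-read copy (exercises the on-disk format end to end).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(groups = list(
                              localized = list(preset = "ctc_localized", n_cells = 3),
                              metastatic = list(preset = "ctc_metastatic", n_cells = 2)
                            ),
                            seed = 1,
                            analysis = list(),
                            write_containers = TRUE) {
  if (length(groups) == 0 || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("config error: `groups` must be a named list")
  }
  for (g in names(groups)) {
    if (is.null(groups[[g]]$preset)) {
      abort(sprintf("config error: group '%s' is missing the field 'preset'", g))
    }
    if (is.null(groups[[g]]$n_cells)) {
      abort(sprintf("config error: group '%s' is missing the field 'n_cells'", g))
    }
  }
  structure(
    list(groups = groups, seed = as.integer(seed), analysis = analysis,
         write_containers = write_containers),
    class = "pipeline_config"
  )
}

resolve_preset <- function(x) {
  if (inherits(x, "mechanical_preset")) return(x)
  if (is.character(x) && length(x) == 1) return(mechanical_preset(x))
  abort("config error: 'preset' must be a preset name or mechanical_preset")
}

#' Run the simulate / analyze / summarize pipeline
#'
#' Generates the configured synthetic cell populations, optionally round-trips
#' every cell through the curve-container format, analyzes every pixel,
#' summarises each group, compares the two groups (Welch t tests on E, D,
#' maximum adhesion force and work of detachment) when exactly two groups are
#' configured, and writes all tables plus a reproducibility manifest under
#' `out_dir`. Identical config and seed produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `results` (per-pixel tibble), `summary`,
#'   `tests` (or NULL), and `out_dir`.
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(seed = 7), tempfile("run"))
#' run$tests
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  group_names <- names(config$groups)
  group_seeds <- withr::with_seed(
    config$seed,
    sample.int(.Machine$integer.max - 1L, length(group_names))
  )
  names(group_seeds) <- group_names

  results <- bind_rows(lapply(group_names, function(g) {
    spec <- config$groups[[g]]
    preset <- resolve_preset(spec$preset)
    cfg_args <- utils::modifyList(
      list(fit_range_nm = preset$fit_range_nm,
           noise_scale_pN = max(preset$noise_rms_pN, 1)),
      config$analysis
    )
    cfg <- do.call(analysis_config, cfg_args)
    pop <- generate_cell_population(preset, spec$n_cells, group_seeds[[g]])
    if (isTRUE(config$write_containers)) {
      pop <- lapply(seq_along(pop), function(i) {
        path <- file.path(out_dir, "containers", g, sprintf("cell_%02d", i))
        write_curve_container(pop[[i]], path)
        read_curve_container(path)
      })
    }
    analyze_cells(pop, cfg) %>% mutate(group = g, .before = 1)
  }))

  summary <- summarize_quantities(results, group = "group")
  tests <- if (length(group_names) == 2) compare_groups(results) else NULL

  readr::write_csv(results, file.path(out_dir, "per_pixel_results.csv"))
  readr::write_csv(summary, file.path(out_dir, "group_summaries.csv"))
  if (!is.null(tests)) readr::write_csv(tests, file.path(out_dir, "group_tests.csv"))

  manifest <- list(
    package = "ctcforce",
    version = as.character(utils::packageVersion("ctcforce")),
    seed = config$seed,
    group_seeds = as.list(group_seeds),
    groups = lapply(config$groups, function(s) {
      list(preset = if (is.character(s$preset)) s$preset else s$preset$name,
           n_cells = s$n_cells)
    }),
    analysis_overrides = config$analysis,
    config_hash = rlang::hash(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(results = results, summary = summary, tests = tests,
                 out_dir = out_dir))
}
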