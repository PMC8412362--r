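#' Run configuration: YAML file plus overrides
#'
#' Resolves a run configuration from (in increasing precedence)
#' documented defaults, an optional YAML file, and programmatic or
#' command-line overrides. Unknown keys are rejected with a
#' nearest-match hint; the resolved configuration is fully serializable
#' so every run can write its effective settings next to its outputs.
#'
#' Recognized sections and keys:
#' * `params`: any argument of [wb_params()].
#' * `run`: `water_year` (logical), `spin_up` (integer cycles),
#'   `output` (`"daily"`/`"annual"`).
#' * `analysis`: `trend_years`, `mean_years`, `period1`, `period2`
#'   (year vectors), `n_zones`.
#' * `fixtures`: `scenario`, `seed`, `nrow`, `ncol`, `years`.
#'
#' @param path Optional YAML file.
#' @param overrides Named list of `section$key` values overriding the
#'   file, e.g. `list(params = list(whc = 150))`.
#' @return A list of class `wb_config` with the four sections resolved.
#' @export
wb_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    params = list(),
    run = list(water_year = FALSE, spin_up = 0L, output = "annual"),
    analysis = list(trend_years = NULL, mean_years = NULL,
                    period1 = 1980:1999, period2 = 2000:2019,
                    n_zones = 9L),
    fixtures = list(scenario = "drying_west", seed = 1L,
                    nrow = 12L, ncol = 12L, years = 1980:2019)
  )
  from_file <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- defaults
  merge_section <- function(cfg, new, where) {
    bad_sections <- setdiff(names(new), names(cfg))
    if (length(bad_sections) > 0) {
      abort(paste0("Unknown config section(s) in ", where, ": ",
                   paste(bad_sections, collapse = ", ")))
    }
    for (sec in names(new)) {
      # an explicitly null key (YAML "~") means "use the default"
      new[[sec]] <- new[[sec]][!vapply(new[[sec]], is.null, logical(1))]
      if (sec == "params") {
        # key validation (incl. nearest-match) happens in as_wb_params
        cfg$params <- utils::modifyList(cfg$params, new$params)
        next
      }
      bad <- setdiff(names(new[[sec]]), names(cfg[[sec]]))
      if (length(bad) > 0) {
        hints <- vapply(bad, function(k) {
          cand <- names(cfg[[sec]])
          cand[which.min(utils::adist(k, cand))]
        }, character(1))
        abort(sprintf("Unknown key(s) in [%s] (%s): %s. Did you mean: %s?",
                      sec, where, paste(bad, collapse = ", "),
                      paste(hints, collapse = ", ")))
      }
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], new[[sec]])
    }
    cfg
  }
  cfg <- merge_section(cfg, from_file, where = path %||% "file")
  cfg <- merge_section(cfg, overrides, where = "overrides")
  as_wb_params(cfg$params)  # validate early
  structure(cfg, class = "wb_config")
}

#' @rdname wb_config
#' @param config A `wb_config` object.
#' @export
write_wb_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records provenance for a run: the effective configuration, package
#' version, timestamp, input description and any scalar diagnostics
#' (e.g. the run's maximum mass-balance residual), as JSON.
#'
#' @param path Output JSON path.
#' @param config A `wb_config`.
#' @param inputs Named list describing inputs (paths, grid shape, span).
#' @param diagnostics Named list of scalar diagnostics.
#' @return `path`, invisibly.
#' @export
wb_manifest <- function(path, config, inputs = list(),
                        diagnostics = list()) {
  manifest <- list(
    package = "waterbal",
    version = as.character(utils::packageVersion("waterbal")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config),
    inputs = inputs,
    diagnostics = diagnostics
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
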