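# Package-wide defaults and YAML configuration.

#' Analysis defaults
#'
#' One place for every tunable threshold used across the toolkit, with
#' the values used throughout the documentation: `onset_frac` 0.05
#' (upstroke-foot threshold, fraction of peak flow), `es_window_frac`
#' 0.6 (end-systole search window, fraction of cycle), `zc_upstroke_frac`
#' 0.95 (upper end of the early-systolic impedance window),
#' `smooth_span` 0.125 and `ramp_len` 0.6 (normalized time units),
#' `apex_fraction` 0.25 (Tri25), `coverage` 0.5 (sample-volume fraction
#' of the minimum effective diameter), `tau_n` 1000 and `tau_range`
#' (-0.3, 2.5) for the common normalized-time grid, and `n_samples` 128
#' per beat.
#'
#' @return Named list of defaults.
#' @export
ws_defaults <- function() {
  list(onset_frac = 0.05, es_window_frac = 0.6, zc_upstroke_frac = 0.95,
       smooth_span = 0.125, ramp_len = 0.6, apex_fraction = 0.25,
       coverage = 0.5, tau_n = 1000, tau_range = c(-0.3, 2.5),
       n_samples = 128, seed = 1L)
}

#' Load configuration, optionally overriding defaults from YAML
#'
#' @param path Optional YAML file; keys replace entries of
#'   [ws_defaults()]. Unknown keys are rejected.
#' @return Named list of settings.
#' @export
ws_config <- function(path = NULL) {
  cfg <- ws_defaults()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) {
    ws_stop(paste("unknown configuration keys:", paste(bad, collapse = ", ")),
            "ws_usage_error")
  }
  utils::modifyList(cfg, user)
}
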