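# Pipeline configuration: defaults mirror the recording/analysis protocol
# (rejection thresholds 200 uV / 50 uV / 0.7, five CV folds, 1000 label
# permutations, 15-s online timeout). YAML files may override any key;
# unknown keys are rejected rather than silently ignored.

#' Default pipeline configuration
#'
#' @return Nested list with `thresholds`, `cv_folds`, `n_permutations`,
#'   `windows`, `online` (see [online_config()]), `simulation` (see
#'   [sim_config()] for the meaning of its keys) and `seed`.
#' @export
pipeline_config <- function() {
  list(
    thresholds = default_thresholds(),
    cv_folds = 5,
    n_permutations = 1000,
    windows = default_windows(),
    online = unclass(online_config()),
    simulation = list(erd_depth = 0.5, ers_gain = 0.3,
                      n_trials_per_class = 45,
                      artifact_rates = c(blink = 0, clipping = 0, emg = 0)),
    seed = 1L)
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    if (is.list(base[[key]]) && is.list(override[[key]]))
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    else base[[key]] <- override[[key]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [pipeline_config()] defaults; unknown keys are
#' an error.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  over <- yaml::read_yaml(path)
  if (is.null(over)) return(cfg)
  merge_config(cfg, over)
}
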