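#' Default experiment configuration
#'
#' Mirrors the study protocol: an ultrasound cohort of 6 and an MRI cohort of
#' 7, the bundled tMCAO scenario, a 60-component clutter filter, a 0.15
#' coefficient-of-variation mask, 3x flash rejection, bolus injection at the
#' 180th image and CBV integration truncated at the 400th.
#'
#' @param seed master seed; per-subject, per-stage streams are derived from
#'   it with a counter scheme.
#' @return nested configuration list (`ExperimentConfig`).
#' @export
default_config <- function(seed = 1L) {
  list(
    scenario = "paper_tmcao",
    seed = as.integer(seed),
    n_uus = 6L,
    n_dsc = 7L,
    out_dir = NULL,
    phantom = list(nx = 64, ny = 64, nz = 21, lesion_frac = 0.15),
    uus_params = list(),
    uus = list(
      schedule = c(-30, -22, -15, 20, 45, 75, 100, 130, 150, 180, 210, 270),
      baseline_window = c(-30, -15),
      n_remove = 60L,
      cov_threshold = 0.15,
      flash_factor = 3,
      report_times = c(45, 100, 150, 210, 270)),
    ulm_params = list(),
    ulm = list(
      times = c(-20, 45, 110, 270),
      n_remove = 4L,
      det_threshold = 12,
      v_max = 50,
      min_len = 4L,
      upsample = 8),
    dsc_params = list(),
    dsc = list(
      times = c(45, 150, 210, 270),
      truncation = 400L,
      lambda = 0.10,
      aif_n = 5L,
      baseline_window = c(50, 170)),
    t2_params = list()
  )
}

#' Load and validate an experiment configuration
#'
#' Reads JSON (or YAML when the `yaml` package is available and the file ends
#' in `.yml`/`.yaml`), fills every unspecified field with its default, and
#' rejects unknown keys by name. Parameter blocks are validated against the
#' module preconditions before any computation runs.
#'
#' @param path configuration file; an empty file yields the full default
#'   configuration.
#' @param seed default master seed when the file does not set one.
#' @return validated `ExperimentConfig`.
#' @export
load_config <- function(path, seed = 1L) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (!nzchar(trimws(txt))) list()
  else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("YAML config requires the 'yaml' package")
    yaml::yaml.load(txt) %||% list()
  } else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  merged <- merge_config(default_config(seed), cfg, path = "")
  validate_config(merged)
}

merge_config <- function(def, user, path) {
  if (!length(user)) return(def)
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stopf("unknown configuration key%s: %s",
          if (length(unknown) > 1) "s" else "",
          paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]])) && is.list(user[[k]])) {
      def[[k]] <- merge_config(def[[k]], user[[k]], paste0(path, ".", k))
    } else if (k %in% c("uus_params", "ulm_params", "dsc_params", "t2_params")) {
      # free-form parameter blocks: keys checked against the constructor
      ctor <- switch(k, uus_params = uus_params, ulm_params = ulm_params,
                     dsc_params = dsc_params, t2_params = t2_params)
      bad <- setdiff(names(user[[k]]), names(formals(ctor)))
      if (length(bad)) stopf("unknown configuration key: %s.%s", k, bad[1])
      def[[k]] <- user[[k]]
    } else def[[k]] <- user[[k]]
  }
  def
}

validate_config <- function(cfg) {
  up <- do.call(uus_params, cfg$uus_params)
  if (cfg$uus$n_remove >= up$n_frames)
    stopf("uus.n_remove (%d) must be below the stack frame count (%d)",
          cfg$uus$n_remove, up$n_frames)
  if (cfg$uus$cov_threshold < 0) stopf("uus.cov_threshold must be >= 0")
  if (cfg$uus$flash_factor <= 0) stopf("uus.flash_factor must be positive")
  dp <- do.call(dsc_params, cfg$dsc_params)
  if (cfg$dsc$truncation > dp$n_images)
    stopf("dsc.truncation (%d) exceeds the image count (%d)",
          cfg$dsc$truncation, dp$n_images)
  if (cfg$dsc$baseline_window[2] >= dp$injection_index)
    stopf("dsc.baseline_window must end before the injection index")
  if (cfg$n_uus < 0 || cfg$n_dsc < 0) stopf("cohort sizes must be >= 0")
  do.call(ulm_params, cfg$ulm_params)
  do.call(t2_params, cfg$t2_params)
  cfg
}
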