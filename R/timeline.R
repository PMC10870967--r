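#' Build a hemodynamic scenario timeline
#'
#' A timeline is an ordered, contiguous set of epochs, each carrying the
#' ground-truth hemodynamic state relative to baseline: the ultrasound CBV
#' factor (ipsi- and contralesional), absolute CBFv (mm/s, both hemispheres),
#' and the DSC-MRI CBV and CBF factors (the occlusion-phase CBV deficit
#' measured by DSC differs from the Doppler one, so the two modalities carry
#' separate truth columns). A recanalization transient (overshoot intercept +
#' linear decay, minutes) and declared no-acquisition gaps complete the
#' scenario.
#'
#' Two scenarios are bundled:
#' \describe{
#'   \item{`"paper_tmcao"`}{90-min filament occlusion with baseline, occlusion,
#'     recanalization transient, and post-recanalization epochs whose factors
#'     are the study's group-mean ground truth (see
#'     `system.file("extdata/scenario_paper_tmcao.json", package = "perfusim")`).}
#'   \item{`"null"`}{identical span with every factor at its baseline value;
#'     used for symmetry and conservation checks.}
#' }
#'
#' @param spec `"paper_tmcao"`, `"null"`, or a data frame of epochs with
#'   columns `name, t_start, t_end, cbv_ipsi, cbv_contra, cbfv_ipsi,
#'   cbfv_contra, dsc_cbv_ipsi, dsc_cbv_contra, dsc_cbf_ipsi, dsc_cbf_contra`
#'   (times in minutes).
#' @param transient optional list `(intercept, slope_per_min, duration_min)`
#'   describing the ipsilesional CBV overshoot at recanalization; applied over
#'   the epoch named `"transient"` when present.
#' @param gaps optional list of `c(start, end)` no-acquisition windows (min).
#' @return An object of class `perf_timeline`.
#' @export
build_scenario <- function(spec = "paper_tmcao", transient = NULL, gaps = NULL) {
  if (is.character(spec)) {
    sc <- load_bundled_scenario(match.arg(spec, c("paper_tmcao", "null")))
    epochs <- sc$epochs
    transient <- transient %||% sc$transient
    gaps <- gaps %||% sc$gaps
  } else if (is.data.frame(spec)) {
    epochs <- spec
  } else stopf("spec must be a scenario name or an epoch data frame")

  req <- c("name", "t_start", "t_end", "cbv_ipsi", "cbv_contra",
           "cbfv_ipsi", "cbfv_contra", "dsc_cbv_ipsi", "dsc_cbv_contra",
           "dsc_cbf_ipsi", "dsc_cbf_contra")
  miss <- setdiff(req, names(epochs))
  if (length(miss)) stopf("epoch table lacks columns: %s", paste(miss, collapse = ", "))
  epochs <- epochs[order(epochs$t_start), , drop = FALSE]
  if (any(epochs$t_end <= epochs$t_start)) stopf("epochs must have positive duration")
  if (nrow(epochs) > 1) {
    joins <- epochs$t_start[-1] - epochs$t_end[-nrow(epochs)]
    if (any(joins > 1e-9)) stopf("epochs are not contiguous (gap in epoch list)")
    if (any(joins < -1e-9)) stopf("epochs overlap")
  }
  fac <- as.matrix(epochs[, setdiff(req, c("name", "t_start", "t_end"))])
  if (any(fac < 0)) stopf("all hemodynamic factors must be >= 0")

  structure(list(epochs = epochs, transient = transient, gaps = gaps,
                 t_start = min(epochs$t_start), t_end = max(epochs$t_end)),
            class = "perf_timeline")
}

load_bundled_scenario <- function(name) {
  path <- system.file("extdata",
                      sprintf("scenario_%s.json", name), package = "perfusim")
  if (!nzchar(path)) stopf("bundled scenario '%s' not found", name)
  raw <- jsonlite::fromJSON(path)
  ep <- as.data.frame(raw$epochs, stringsAsFactors = FALSE)
  gaps <- if (is.matrix(raw$gaps) && nrow(raw$gaps) > 0)
    lapply(seq_len(nrow(raw$gaps)), function(i) as.numeric(raw$gaps[i, ]))
  else NULL
  list(epochs = ep, transient = raw$transient, gaps = gaps)
}

#' Ground-truth hemodynamic state at a time point
#'
#' Looks up the epoch containing `t_min` and returns its factors; inside the
#' recanalization transient the ipsilesional CBV factor follows the configured
#' line `intercept + slope * (t - t_transient_start)`.
#'
#' @param timeline a `perf_timeline`.
#' @param t_min time in minutes.
#' @return named list of factors plus the epoch name.
#' @export
epoch_factors <- function(timeline, t_min) {
  ep <- timeline$epochs
  if (t_min < timeline$t_start || t_min > timeline$t_end)
    stopf("t = %g min is outside the timeline [%g, %g]",
          t_min, timeline$t_start, timeline$t_end)
  i <- findInterval(t_min, ep$t_start, rightmost.closed = TRUE)
  i <- max(1L, min(i, nrow(ep)))
  out <- as.list(ep[i, ])
  if (identical(out$name, "transient") && !is.null(timeline$transient)) {
    tr <- timeline$transient
    out$cbv_ipsi <- max(0, tr$intercept + tr$slope_per_min * (t_min - ep$t_start[i]))
  }
  out
}

in_gap <- function(timeline, t_min) {
  if (is.null(timeline$gaps)) return(FALSE)
  any(vapply(timeline$gaps, function(g) t_min >= g[1] && t_min < g[2], logical(1)))
}

#' @export
print.perf_timeline <- function(x, ...) {
  cat(sprintf("perfusim timeline: %g to %g min, %d epochs\n",
              x$t_start, x$t_end, nrow(x$epochs)))
  print(x$epochs, row.names = FALSE)
  invisible(x)
}
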