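#' ROI means, contralesional reference and normalized ratio at one time point
#'
#' Averages a map over the ipsi- and contralesional ROIs and forms the
#' normalized ratio (ipsi/contra). For ultrasound data a flash-rejection
#' factor can be supplied: ROI values exceeding `flash_factor` times the ROI
#' mean at this time point are rejected before averaging (the Doppler flash
#' artifact rule; not applied to MRI data).
#'
#' @param map numeric array (or vector) of voxel values.
#' @param lesion,contra logical masks (or index vectors), disjoint, nonempty.
#' @param flash_factor optional rejection multiple (3 for ultrasound).
#' @return one-row data frame: `ipsi, contra, ratio, n_ipsi, n_contra`.
#'   `ratio` is `NA` when the contralesional mean is non-positive.
#' @export
roi_timecourse <- function(map, lesion, contra, flash_factor = NULL) {
  iv <- map[lesion]; cv <- map[contra]
  iv <- iv[is.finite(iv)]; cv <- cv[is.finite(cv)]
  if (!length(iv) || !length(cv)) stopf("empty ROI after masking")
  if (is.logical(lesion) && is.logical(contra) && any(lesion & contra))
    stopf("ROIs overlap")
  if (!is.null(flash_factor)) {
    iv <- flash_reject(iv, flash_factor)
    cv <- flash_reject(cv, flash_factor)
  }
  ipsi <- mean(iv); contra_m <- mean(cv)
  data.frame(ipsi = ipsi, contra = contra_m,
             ratio = if (contra_m > 0) ipsi / contra_m else NA_real_,
             n_ipsi = length(iv), n_contra = length(cv))
}

#' Pixel-wise linear intercept fit at recanalization
#'
#' Fits `y = a + b t` by ordinary least squares per pixel over the fit
#' window, with the time origin at filament retraction: the intercept `a`
#' estimates rCBV immediately upon recanalization, before the fast decay.
#'
#' @param series samples x pixels matrix of rCBV values.
#' @param times_s sample times in seconds, 0 at retraction.
#' @param window `c(start, end)` seconds of data used.
#' @return list of class `perf_intercept`: `intercept`, `slope` per pixel,
#'   `times_s` used.
#' @export
recanalization_intercept_fit <- function(series, times_s, window = c(0, 300)) {
  sel <- which(times_s >= window[1] & times_s <= window[2])
  if (length(sel) < 3) stopf("need at least 3 samples in the fit window")
  t <- times_s[sel]
  Y <- series[sel, , drop = FALSE]
  tm <- mean(t)
  st2 <- sum((t - tm)^2)
  slope <- unname(colSums((t - tm) * Y) / st2)
  intercept <- unname(colMeans(Y)) - slope * tm
  structure(list(intercept = intercept, slope = slope, times_s = t),
            class = "perf_intercept")
}

#' Paired t-test on ipsi- vs contralesional summary values
#'
#' Two-sided paired t-test (one value per subject and hemisphere), as used to
#' compare mean ROI intercepts at recanalization.
#'
#' @param ipsi,contra equal-length numeric vectors, `n >= 2`.
#' @return list: `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(ipsi, contra) {
  if (length(ipsi) != length(contra)) stopf("paired samples must have equal length")
  if (length(ipsi) < 2) stopf("need at least 2 pairs")
  d <- ipsi - contra
  if (stats::sd(d) == 0)
    stopf("zero-variance differences: the paired t statistic is undefined")
  ht <- stats::t.test(ipsi, contra, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}

#' Cohort summary table (mean and SD per cell)
#'
#' Aggregates per-subject ROI tables into the final report: arithmetic mean
#' and sample standard deviation of each measure per (time point, modality)
#' cell. Cells with fewer than two subjects are omitted with a warning.
#'
#' @param tables data frame with columns `subject, time_min, modality,
#'   measure, value` (rbind of per-subject rows).
#' @return data frame `time_min, modality, measure, mean, sd, n`.
#' @export
group_summary <- function(tables) {
  req <- c("subject", "time_min", "modality", "measure", "value")
  miss <- setdiff(req, names(tables))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  key <- interaction(tables$time_min, tables$modality, tables$measure, drop = TRUE)
  out <- lapply(split(tables, key), function(df) {
    v <- df$value[is.finite(df$value)]
    if (length(v) < 2) {
      warning(sprintf("cell (%s, %s, t=%s) has < 2 subjects; omitted",
                      df$modality[1], df$measure[1], df$time_min[1]))
      return(NULL)
    }
    data.frame(time_min = df$time_min[1], modality = df$modality[1],
               measure = df$measure[1], mean = mean(v), sd = stats::sd(v),
               n = length(v))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(time_min = numeric(), modality = character(),
                      measure = character(), mean = numeric(), sd = numeric(),
                      n = integer()))
  out <- out[order(out$modality, out$measure, out$time_min), ]
  rownames(out) <- NULL
  out
}
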