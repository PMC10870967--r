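#' Whole-brain ultrasound pipeline for one subject
#'
#' Simulates whole-brain acquisitions over the experimental schedule, then
#' runs the full processing chain: SVD clutter filtering, power-Doppler
#' computation, volume assembly, interpolation to the one-minute common
#' timeline (with linear extrapolation into declared acquisition gaps),
#' baseline-median normalization to rCBV, coefficient-of-variation vessel
#' masking and flash rejection, and ROI extraction at the report time points.
#'
#' @param phantom a `perf_phantom`.
#' @param timeline a `perf_timeline`.
#' @param params a `uus_params`.
#' @param seed subject seed.
#' @param schedule acquisition times (min); the default covers baseline,
#'   occlusion and the post-recanalization hours while avoiding the
#'   scenario's declared gaps.
#' @param grid common timeline (min), one-minute resolution.
#' @param baseline_window minutes used for the baseline median.
#' @param n_remove singular values removed by the clutter filter.
#' @param cov_threshold coefficient-of-variation mask threshold.
#' @param flash_factor flash-rejection multiple.
#' @param report_times ROI report time points (min).
#' @param ipsi_scale subject-level scaling of the ipsilesional deviation from
#'   baseline (between-animal severity of the insult).
#' @return list: `rcbv`, `valid` mask, `roi` (long-format rows), `truth`.
#' @export
uus_subject_pipeline <- function(phantom, timeline, params = uus_params(),
                                 seed = 1L,
                                 schedule = c(-30, -22, -15, 20, 45, 75,
                                              100, 130, 150, 180, 210, 270),
                                 grid = NULL,
                                 baseline_window = c(-30, -15),
                                 n_remove = 60L, cov_threshold = 0.15,
                                 flash_factor = 3,
                                 report_times = c(45, 100, 150, 210, 270),
                                 ipsi_scale = 1) {
  grid <- grid %||% seq(timeline$t_start, timeline$t_end - 30, by = 1)
  bad <- vapply(schedule, function(t) in_gap(timeline, t), logical(1))
  if (any(bad)) stopf("schedule enters a declared acquisition gap at t = %s",
                      paste(schedule[bad], collapse = ", "))
  vols <- vector("list", length(schedule))
  truths <- vector("list", length(schedule))
  for (i in seq_along(schedule)) {
    t <- schedule[i]
    acq <- simulate_uus_acquisition(phantom, timeline, t, params,
                                    seed = derive_seed(seed, stage = STAGE[["uus"]],
                                                       counter = i),
                                    ipsi_scale = ipsi_scale)
    pd <- lapply(acq$stacks, function(s)
      power_doppler(svd_clutter_filter(s, n_remove)))
    vols[[i]] <- assemble_wb_volume(pd)
    vols[[i]]$t_min <- t                 # nominal acquisition time
    truths[[i]] <- acq$truth$factors
  }
  series <- build_timeline_series(vols, times = schedule, grid = grid,
                                  gaps = timeline$gaps)
  vmask <- cov_mask(series, cov_threshold)
  rcbv <- relative_cbv(series, baseline_window)
  valid <- vmask & rcbv$valid

  lesion <- as.vector(phantom_mask(phantom, "lesion"))
  contra <- as.vector(phantom_mask(phantom, "contra"))
  rows <- list()
  for (t in report_times) {
    gi <- which.min(abs(grid - t))
    vals <- rcbv$series[gi, ]
    r <- roi_timecourse(vals, lesion & valid, contra & valid, flash_factor)
    rows[[length(rows) + 1L]] <- data.frame(
      time_min = t, modality = "uus",
      measure = c("rcbv_ipsi", "rcbv_contra", "ncbv_ratio"),
      value = c(r$ipsi, r$contra, r$ratio),
      n_vox = c(r$n_ipsi, r$n_contra, NA))
  }
  list(rcbv = rcbv, valid = valid, roi = do.call(rbind, rows),
       truth = truths, schedule = schedule)
}

#' ULM pipeline for one subject
#'
#' For each requested time point: simulate a microbubble sequence, clutter
#' filter, detect and localize bubbles, link them into tracks, accumulate
#' velocity/density maps on the refined grid, and average CBFv over
#' non-zero ROI pixels.
#'
#' @param phantom,timeline phantom and scenario.
#' @param params a `ulm_params`.
#' @param seed subject seed.
#' @param times acquisition times (min): baseline, occlusion, early
#'   post-recanalization and 3 h in the default protocol.
#' @param n_remove singular values removed before detection.
#' @param det_threshold detection threshold on filtered magnitude.
#' @param v_max,max_gap,min_len tracking parameters.
#' @param upsample map refinement factor.
#' @param speed_scale subject-level speed multiplier.
#' @return list: `roi` rows, per-time results (`maps`, counts).
#' @export
ulm_subject_pipeline <- function(phantom, timeline, params = ulm_params(),
                                 seed = 1L, times = c(-20, 45, 110, 270),
                                 n_remove = 4L, det_threshold = 12,
                                 v_max = 50, max_gap = 1L, min_len = 4L,
                                 upsample = 8, speed_scale = 1) {
  rows <- list(); per_time <- list()
  for (i in seq_along(times)) {
    t <- times[i]
    sim <- simulate_ulm_sequence(phantom, timeline, t, params,
                                 seed = derive_seed(seed, stage = STAGE[["ulm"]],
                                                    counter = i),
                                 speed_scale = speed_scale)
    filt <- svd_clutter_filter(sim$stack, n_remove)
    locs <- detect_bubbles(filt, det_threshold)
    tracks <- link_tracks(locs, v_max = v_max, max_gap = max_gap,
                          min_len = min_len)
    map <- accumulate_maps(tracks, dim_px = sim$stack$dim_px,
                           pixel_mm = sim$stack$pixel_mm, upsample = upsample)
    les <- kron_upsample(sim$lesion_px, upsample)
    con <- kron_upsample(sim$contra_px, upsample)
    ri <- roi_cbfv(map, les)
    rc <- roi_cbfv(map, con)
    rows[[i]] <- data.frame(
      time_min = t, modality = "ulm",
      measure = c("cbfv_ipsi", "cbfv_contra", "zero_frac_ipsi"),
      value = c(ri$mean_cbfv, rc$mean_cbfv, ri$zero_fraction),
      n_vox = c(ri$n_used, rc$n_used, NA))
    per_time[[i]] <- list(map = map, n_tracks = length(tracks),
                          n_locs = nrow(locs), factors = sim$factors)
  }
  list(roi = do.call(rbind, rows), detail = per_time, times = times)
}

#' DSC-MRI pipeline for one subject
#'
#' Fits the T2 map from a simulated multi-echo acquisition, segments the
#' edematous lesion and mirrors it into the contralesional homologue, then
#' for each bolus experiment converts signal to concentration, integrates
#' the truncated curve into a CBV-weighted map, selects the contralesional
#' arterial reference, deconvolves for the CBF-weighted map, and extracts
#' normalized ipsi/contralesional ratios.
#'
#' @param phantom,timeline phantom and scenario.
#' @param params a `dsc_params`; `t2p` a `t2_params`.
#' @param seed subject seed.
#' @param times bolus time points (min).
#' @param truncation CBV integration cut-off (image index).
#' @param lambda deconvolution singular-value threshold fraction.
#' @param aif_n arterial voxels averaged.
#' @param baseline_window pre-bolus images for S0.
#' @param ipsi_scale subject-level multiplier on ipsilesional factors.
#' @param t2p multi-echo simulation parameters.
#' @return list: `roi` rows, `lesion_mask`, `contra_mask`, `t2map`, per-time
#'   detail (AIF QC).
#' @export
dsc_subject_pipeline <- function(phantom, timeline, params = dsc_params(),
                                 seed = 1L, times = c(45, 150, 210, 270),
                                 truncation = 400L, lambda = 0.10,
                                 aif_n = 5L, baseline_window = c(50, 170),
                                 ipsi_scale = 1, t2p = t2_params()) {
  me <- simulate_multiecho_t2(phantom, t2p, seed = seed)
  brain <- phantom_mask(phantom, "brain")
  t2map <- fit_t2_map(me, mask = brain)
  d <- phantom$dim
  xs <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d)
  contra_hemi <- brain & xs < phantom$midline
  lesion_mask <- segment_lesion(t2map, contra_hemi, k = 2)
  lesion_mask <- lesion_mask & xs > phantom$midline   # lesion is ipsilesional
  if (!any(lesion_mask)) lesion_mask <- phantom_mask(phantom, "lesion")
  contra_mask <- mirror_roi(lesion_mask, phantom$midline) & brain

  core <- which(lesion_mask | contra_mask | phantom_mask(phantom, "artery"))
  rest <- setdiff(which(brain), core)
  extra <- with_seed(derive_seed(seed, stage = STAGE[["dsc"]], counter = 500L),
                     sample(rest, min(length(rest), 800L)))
  voxels <- sort(c(core, extra))

  rows <- list(); detail <- list()
  for (i in seq_along(times)) {
    t <- times[i]
    dsc <- simulate_dsc_series(phantom, timeline, t, params,
                               seed = derive_seed(seed, stage = STAGE[["dsc"]],
                                                  counter = i),
                               voxels = voxels, ipsi_scale = ipsi_scale)
    conc <- signal_to_concentration(dsc, baseline_window)
    cbv <- compute_cbv_map(conc, truncation)
    in_contra_hemi <- contra_hemi[voxels]
    aif <- select_aif(conc, in_contra_hemi, n = aif_n)
    cbf <- compute_cbf_map(conc, aif, lambda)
    les_v <- lesion_mask[voxels]
    con_v <- contra_mask[voxels]
    rv <- roi_timecourse(cbv, les_v, con_v)
    rf <- roi_timecourse(cbf$cbf, les_v, con_v)
    rows[[i]] <- data.frame(
      time_min = t, modality = "dsc",
      measure = c("cbv_ratio", "cbf_ratio"),
      value = c(rv$ratio, rf$ratio),
      n_vox = c(rv$n_ipsi, rf$n_ipsi))
    detail[[i]] <- list(aif_qc = aif$qc,
                        aif_voxels_arterial =
                          all(phantom$labels[voxels[aif$voxels]] == 4L),
                        truth = dsc$truth[c("factors", "injection_factor")])
  }
  list(roi = do.call(rbind, rows), lesion_mask = lesion_mask,
       contra_mask = contra_mask, t2map = t2map, detail = detail,
       times = times)
}

#' Run the full two-cohort experiment
#'
#' Simulates the ultrasound cohort (whole-brain Doppler + ULM + single-slice
#' recanalization imaging) and the MRI cohort (multi-echo T2 + DSC bolus
#' series), processes every subject with the full pipelines, and writes
#' per-subject ROI tables, the cohort summary, the recanalization intercept
#' comparison, and a ground-truth-vs-recovered comparison file.
#'
#' @param config an `ExperimentConfig` list from [load_config()] /
#'   [default_config()].
#' @return (invisibly) list with `roi` (all rows), `summary`, `recovery`
#'   comparison, `intercept` test, and the output directory.
#' @export
run_experiment <- function(config = default_config()) {
  config <- validate_config(config)
  timeline <- build_scenario(config$scenario)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  all_rows <- list()
  ss_i <- numeric(0); ss_c <- numeric(0)
  uusp <- do.call(uus_params, config$uus_params)
  for (s in seq_len(config$n_uus)) {
    sseed <- derive_seed(config$seed, subject = s, stage = STAGE[["subject"]])
    ph <- do.call(build_phantom, c(config$phantom, list(seed = sseed)))
    eff <- with_seed(derive_seed(sseed, stage = 8L),
                     stats::rlnorm(2, -c(0.08, 0.05)^2 / 2, c(0.08, 0.05)))
    u <- uus_subject_pipeline(ph, timeline, uusp, seed = sseed,
                              schedule = config$uus$schedule,
                              baseline_window = config$uus$baseline_window,
                              n_remove = config$uus$n_remove,
                              cov_threshold = config$uus$cov_threshold,
                              flash_factor = config$uus$flash_factor,
                              report_times = config$uus$report_times,
                              ipsi_scale = eff[1])
    m <- ulm_subject_pipeline(ph, timeline,
                              do.call(ulm_params, config$ulm_params),
                              seed = sseed, times = config$ulm$times,
                              n_remove = config$ulm$n_remove,
                              det_threshold = config$ulm$det_threshold,
                              v_max = config$ulm$v_max,
                              min_len = config$ulm$min_len,
                              upsample = config$ulm$upsample,
                              speed_scale = eff[2])
    ss_rows <- NULL
    if (!is.null(timeline$transient)) {
      ss <- simulate_ss_doppler(ph, timeline, seed = sseed)
      fit <- recanalization_intercept_fit(ss$rcbv, ss$times_s)
      ss_i[s] <- mean(fit$intercept[as.vector(ss$lesion_px)])
      ss_c[s] <- mean(fit$intercept[as.vector(ss$contra_px)])
      ss_rows <- data.frame(time_min = 90, modality = "ss_uus",
                            measure = c("intercept_ipsi", "intercept_contra"),
                            value = c(ss_i[s], ss_c[s]), n_vox = NA)
    }
    rows <- rbind(u$roi, m$roi, ss_rows)
    rows$subject <- sprintf("A%02d", s)
    all_rows[[length(all_rows) + 1L]] <- rows
  }
  for (s in seq_len(config$n_dsc)) {
    sseed <- derive_seed(config$seed, subject = 100L + s,
                         stage = STAGE[["subject"]])
    ph <- do.call(build_phantom, c(config$phantom, list(seed = sseed)))
    eff <- with_seed(derive_seed(sseed, stage = 8L),
                     stats::rlnorm(1, -0.06^2 / 2, 0.06))
    dsc <- dsc_subject_pipeline(ph, timeline,
                                do.call(dsc_params, config$dsc_params),
                                seed = sseed, times = config$dsc$times,
                                truncation = config$dsc$truncation,
                                lambda = config$dsc$lambda,
                                aif_n = config$dsc$aif_n,
                                baseline_window = config$dsc$baseline_window,
                                ipsi_scale = eff,
                                t2p = do.call(t2_params, config$t2_params))
    rows <- dsc$roi
    rows$subject <- sprintf("B%02d", s)
    all_rows[[length(all_rows) + 1L]] <- rows
  }
  roi <- do.call(rbind, all_rows)
  roi <- roi[, c("subject", "time_min", "modality", "measure", "value", "n_vox")]
  summ <- group_summary(roi)
  itest <- if (length(ss_i) >= 2) paired_t(ss_i, ss_c) else NULL
  recovery <- recovery_table(roi, timeline, config)

  if (!is.null(out_dir)) {
    utils::write.csv(roi, file.path(out_dir, "roi_table.csv"), row.names = FALSE)
    utils::write.csv(summ, file.path(out_dir, "group_summary.csv"), row.names = FALSE)
    utils::write.csv(recovery, file.path(out_dir, "recovery_comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = summ, intercept_test = itest),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(roi = roi, summary = summ, recovery = recovery,
                 intercept = itest, out_dir = out_dir))
}

# cohort means vs configured scenario truth at the report time points
recovery_table <- function(roi, timeline, config) {
  summ <- group_summary(roi)
  pick <- function(modality, measure, t) {
    r <- summ[summ$modality == modality & summ$measure == measure &
                summ$time_min == t, ]
    if (nrow(r)) r$mean[1] else NA_real_
  }
  truthv <- function(t, what) {
    f <- epoch_factors(timeline, t)
    f[[what]]
  }
  rows <- list()
  for (t in config$uus$report_times)
    rows[[length(rows) + 1L]] <- data.frame(
      modality = "uus", measure = "rcbv_ipsi", time_min = t,
      truth = truthv(t, "cbv_ipsi"), recovered = pick("uus", "rcbv_ipsi", t))
  for (t in config$ulm$times) {
    f <- epoch_factors(timeline, t)
    rows[[length(rows) + 1L]] <- data.frame(
      modality = "ulm", measure = "cbfv_ipsi", time_min = t,
      truth = f$cbfv_ipsi, recovered = pick("ulm", "cbfv_ipsi", t))
  }
  for (t in config$dsc$times) {
    f <- epoch_factors(timeline, t)
    rows[[length(rows) + 1L]] <- data.frame(
      modality = "dsc", measure = "cbv_ratio", time_min = t,
      truth = f$dsc_cbv_ipsi / f$dsc_cbv_contra,
      recovered = pick("dsc", "cbv_ratio", t))
    rows[[length(rows) + 1L]] <- data.frame(
      modality = "dsc", measure = "cbf_ratio", time_min = t,
      truth = f$dsc_cbf_ipsi / f$dsc_cbf_contra,
      recovered = pick("dsc", "cbf_ratio", t))
  }
  out <- do.call(rbind, rows)
  out$rel_error <- (out$recovered - out$truth) / out$truth
  out
}
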