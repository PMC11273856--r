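#' Pipeline configuration
#'
#' Tunables of the per-subject analysis chain (enhancement, registration,
#' segmentation, quality control, HRV windowing).
#'
#' @param diffusion list of [anisotropic_diffusion()] parameters.
#' @param compensation list of [adaptive_compensation()] parameters.
#' @param segmentation a [segmentation_params()].
#' @param registration list of [estimate_rigid()] options.
#' @param qc_max_invalid maximum tolerated invalid-A-scan fraction before a
#'   scan is replaced by its same-condition alternate (mirroring the
#'   poor-quality substitution rule of the acquisition protocol).
#' @param snap_to_grid round the estimated inter-session translation to
#'   whole voxels (and drop the sub-degree rotation) before resampling.
#'   Integer-shift resampling is an exact copy, so both sessions are
#'   segmented after an identical processing chain; the remaining
#'   misalignment (at most half a voxel, a fraction of a degree) is
#'   negligible for fovea-centred thickness, whereas sub-voxel interpolation
#'   smooths one arm only and inflates the between-session noise severalfold.
#' @param hrv_window_s HRV window length, seconds.
#' @export
pipeline_config <- function(diffusion = list(n_iter = 20L, kappa = 0.07, lambda = 0.2),
                            compensation = list(n = 2, take_root = TRUE),
                            segmentation = segmentation_params(),
                            registration = list(refine_interp = FALSE,
                                                maxit_coarse = 300L,
                                                maxit_fine = 80L),
                            qc_max_invalid = 0.2,
                            snap_to_grid = TRUE,
                            hrv_window_s = 20) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Specification of one simulated subject
#'
#' Parameters from which [simulate_subject()] deterministically materialises
#' one paired-session subject: the eye geometry, the stress effect (choroidal
#' thickening plus a small rigid motion), and per-condition RR statistics.
#'
#' @param id subject identifier.
#' @param seed per-subject RNG seed.
#' @param geometry an [eye_geometry_config()].
#' @param delta_ct_um between-session choroidal thickening, um.
#' @param rigid_shift_px,rigid_rot_deg rigid inter-session motion.
#' @param baseline_hr_bpm,stress_hr_bpm per-condition mean heart rate.
#' @param baseline_rmssd_ms,stress_rmssd_ms per-condition RMSSD targets
#'   (converted to the AR marginal SD via `sd = rmssd / sqrt(2 (1 - ar))`).
#' @param ar_coef RR lag-1 autocorrelation.
#' @export
subject_spec <- function(id, seed, geometry = eye_geometry_config(),
                         delta_ct_um = 3.326,
                         rigid_shift_px = c(0, 0, 0), rigid_rot_deg = 0,
                         baseline_hr_bpm = 77.029, stress_hr_bpm = 86.727,
                         baseline_rmssd_ms = 36.871, stress_rmssd_ms = 25.502,
                         ar_coef = 0.4) {
  stopifnot(inherits(geometry, "eye_geometry_config"),
            baseline_hr_bpm > 0, stress_hr_bpm > 0,
            baseline_rmssd_ms >= 0, stress_rmssd_ms >= 0)
  structure(as.list(environment()), class = "subject_spec")
}

rmssd_to_sd <- function(rmssd_ms, ar_coef) rmssd_ms / sqrt(2 * (1 - ar_coef))

#' Materialise a simulated subject
#'
#' Renders two baseline scans (same ground truth, independent speckle), the
#' stress scan (thickened choroid plus rigid motion, independent speckle)
#' and a two-segment RR recording with acquisition-end events
#' `baseline_1`, `baseline_2`, `stress_1`, `stress_2`.
#'
#' @param spec a [subject_spec()].
#' @param noise a [noise_config()] template (its seed is re-derived per scan).
#' @return a `subject_bundle` list.
#' @export
simulate_subject <- function(spec, noise = noise_config()) {
  stopifnot(inherits(spec, "subject_spec"))
  cs <- function(k) child_seed(spec$seed, k)
  truth_base <- generate_eye(spec$geometry, seed = cs(1))
  nz <- function(k) { n <- noise; n$seed <- cs(k); n }
  vol_base1 <- render_volume(truth_base, nz(2))
  vol_base2 <- render_volume(truth_base, nz(3))
  effect <- stress_effect_config(spec$delta_ct_um, spec$rigid_shift_px,
                                 spec$rigid_rot_deg)
  truth_stress <- apply_stress_effect(truth_base, effect)
  vol_stress <- render_volume(truth_stress, nz(4))
  # RR recording: ~125 s per condition, acquisitions ending mid-segment and
  # just before the segment end
  seg <- function(hr, rmssd, k) {
    mean_rr <- 60000 / hr
    sd_rr <- min(rmssd_to_sd(rmssd, spec$ar_coef), mean_rr / 3.2)
    n <- ceiling(125000 / mean_rr)
    generate_rr_series(mean_rr, sd_rr, n, seed = cs(k), ar_coef = spec$ar_coef)
  }
  rr_b <- seg(spec$baseline_hr_bpm, spec$baseline_rmssd_ms, 5)
  rr_s <- seg(spec$stress_hr_bpm, spec$stress_rmssd_ms, 6)
  t1 <- rr_b$t_end_ms[length(rr_b$t_end_ms)]
  t2 <- rr_s$t_end_ms[length(rr_s$t_end_ms)]
  events <- c(baseline_1 = 0.5 * t1, baseline_2 = t1 - 1000,
              stress_1 = t1 + 0.5 * t2, stress_2 = t1 + t2 - 1000)
  rr <- rr_series(c(rr_b$rr_ms, rr_s$rr_ms), events = events)
  structure(list(id = spec$id, spec = spec,
                 axial_length_mm = spec$geometry$axial_length_mm,
                 orientation = spec$geometry$orientation,
                 truth_base = truth_base, truth_stress = truth_stress,
                 vol_base1 = vol_base1, vol_base2 = vol_base2,
                 vol_stress = vol_stress, rr = rr),
            class = "subject_bundle")
}

#' Draw the specifications of a simulated study cohort
#'
#' Per-subject parameters are drawn at the study's published scale: axial
#' length N(25.563, 1.242) mm; choroidal thickening
#' N(`delta_ct_mean`, `delta_ct_sd`) um (defaults 3.326 and 6.143); small
#' rigid inter-session motion; baseline HR N(77.029, 12.305) bpm with a
#' stress rise of N(9.698, 5) bpm; baseline RMSSD N(36.871, 17.149) ms with
#' a stress fall of N(11.369, 8) ms (both truncated to stay positive).
#'
#' @param n cohort size.
#' @param seed cohort RNG seed.
#' @param delta_ct_mean,delta_ct_sd distribution of the per-subject
#'   choroidal thickening, um.
#' @param geometry an [eye_geometry_config()] template (axial length is
#'   overwritten per subject).
#' @return list of [subject_spec()] objects; the drawn thickening is
#'   attached as attribute `delta_ct_um`.
#' @export
simulate_cohort_specs <- function(n = 33, seed = 1L,
                                  delta_ct_mean = 3.326, delta_ct_sd = 6.143,
                                  geometry = eye_geometry_config()) {
  draws <- with_seed(seed, {
    list(al = stats::rnorm(n, 25.563, 1.242),
         dct = stats::rnorm(n, delta_ct_mean, delta_ct_sd),
         shift = matrix(stats::rnorm(3 * n, 0, 0.5), n, 3),
         rot = clamp(stats::rnorm(n, 0, 0.3), -2, 2),
         hr_b = pmax(stats::rnorm(n, 77.029, 12.305), 45),
         dhr = stats::rnorm(n, 9.698, 5),
         rmssd_b = pmax(stats::rnorm(n, 36.871, 17.149), 8),
         drmssd = stats::rnorm(n, 11.369, 8))
  })
  specs <- lapply(seq_len(n), function(i) {
    g <- geometry
    g$axial_length_mm <- clamp(draws$al[i], 22, 29)
    subject_spec(
      id = sprintf("sim%02d", i), seed = child_seed(seed, 100 + i),
      geometry = g,
      delta_ct_um = draws$dct[i],
      rigid_shift_px = draws$shift[i, ], rigid_rot_deg = draws$rot[i],
      baseline_hr_bpm = draws$hr_b[i],
      stress_hr_bpm = draws$hr_b[i] + draws$dhr[i],
      baseline_rmssd_ms = draws$rmssd_b[i],
      stress_rmssd_ms = pmax(draws$rmssd_b[i] - draws$drmssd[i], 5)
    )
  })
  attr(specs, "delta_ct_um") <- draws$dct
  specs
}

#' Run the full analysis for one subject
#'
#' Enhancement (diffusion then adaptive compensation) of both conditions,
#' rigid registration of the enhanced stress volume to the enhanced analysis
#' baseline and resampling onto its grid, segmentation of all scans,
#' morphometry (the stress volume reuses the baseline fovea, made comparable
#' by registration), and event-anchored HRV for both conditions. If the
#' analysis baseline fails segmentation quality control the alternate
#' baseline scan is substituted; if both fail the subject errors out (for
#' exclusion by [run_cohort()]).
#'
#' @param subject a `subject_bundle` (from [simulate_subject()] or
#'   [load_subject_manifest()]).
#' @param config a [pipeline_config()].
#' @return list with `morph_baseline`, `morph_baseline_alt`, `morph_stress`,
#'   `hrv_baseline`, `hrv_stress`, `transform`, `qc`.
#' @export
run_subject <- function(subject, config = pipeline_config()) {
  stopifnot(inherits(subject, "subject_bundle"), inherits(config, "pipeline_config"))
  enh <- function(v) do.call(enhance_volume, c(list(v), config$diffusion,
                                               config$compensation))
  seg <- function(v) segment_volume(v, config$segmentation)
  e_b1 <- enh(subject$vol_base1)
  e_b2 <- enh(subject$vol_base2)
  s_b1 <- seg(e_b1)
  s_b2 <- seg(e_b2)
  swapped <- FALSE
  # QC substitution: analysis baseline is the second scan unless it fails QC
  if (attr(s_b2, "invalid_fraction") > config$qc_max_invalid) {
    if (attr(s_b1, "invalid_fraction") > config$qc_max_invalid)
      stop("subject excluded: both baseline scans fail segmentation QC")
    tmp <- e_b1; e_b1 <- e_b2; e_b2 <- tmp
    tmp <- s_b1; s_b1 <- s_b2; s_b2 <- tmp
    swapped <- TRUE
  }
  # transform estimated on enhanced intensities, but applied to the raw
  # stress volume; enhancement then runs on the resampled grid so both
  # conditions are segmented after an identical processing chain
  e_st <- enh(subject$vol_stress)
  tr <- estimate_rigid(e_st, e_b2, config$registration)
  tr_apply <- tr
  if (isTRUE(config$snap_to_grid)) {
    pitchf <- voxel_pitch_mm(e_b2)
    tr_apply <- rigid_transform(c(0, 0, 0),
                                round(tr$translation_mm / pitchf) * pitchf,
                                tr$center_mm)
  }
  res_st <- enh(resample_to_grid(subject$vol_stress, tr_apply, subject$vol_stress))
  s_st <- seg(res_st)
  if (attr(s_st, "invalid_fraction") > config$qc_max_invalid)
    stop("subject excluded: stress scan fails segmentation QC")
  cal <- volume_calibration(e_b2)
  fov <- locate_fovea(s_b2)
  morph_baseline <- measure_volume(s_b2, cal, fov, subject$orientation)
  morph_stress <- measure_volume(s_st, cal, fov, subject$orientation)
  morph_baseline_alt <- measure_volume(s_b1, cal, NULL, subject$orientation)
  ev <- subject$rr$events
  hrv_baseline <- hrv_metrics(subject$rr, ev[["baseline_2"]], config$hrv_window_s)
  hrv_stress <- hrv_metrics(subject$rr, ev[["stress_1"]], config$hrv_window_s)
  list(id = subject$id,
       morph_baseline = morph_baseline,
       morph_baseline_alt = morph_baseline_alt,
       morph_stress = morph_stress,
       hrv_baseline = hrv_baseline, hrv_stress = hrv_stress,
       transform = tr, transform_applied = tr_apply,
       qc = list(swapped_baseline = swapped,
                 invalid_baseline = attr(s_b2, "invalid_fraction"),
                 invalid_stress = attr(s_st, "invalid_fraction"),
                 registration_status = attr(tr, "status")))
}

morph_params <- c("rt_1mm_um", "rt_3mm_um", "ct_1mm_um", "ct_3mm_um",
                  "r0_mm", "r45_mm", "r90_mm", "r135_mm")

#' Run the study analysis over a cohort
#'
#' Processes every subject with [run_subject()] (subjects failing quality
#' control are excluded with a recorded reason; at least 3 processable
#' subjects are required), then computes the study battery: normality-gated
#' paired comparisons per endpoint (morphometry plus mean HR and RMSSD),
#' Bland-Altman repeatability from the two baseline scans, and the
#' correlations of choroidal change with axial length and with HR change,
#' and of baseline RMSSD with baseline choroidal thickness.
#'
#' @param subjects list of [subject_spec()] objects (materialised on demand,
#'   keeping one subject in memory at a time) and/or `subject_bundle`s.
#' @param config a [pipeline_config()].
#' @param noise a [noise_config()] template for simulated subjects.
#' @param progress print per-subject progress lines.
#' @return a `study_report` list: `table` (endpoint summary in the layout of
#'   the published cohort table), `comparisons`, `bland_altman`,
#'   `correlations`, `subjects` (per-subject values), `exclusions`,
#'   `n_processed`.
#' @export
run_cohort <- function(subjects, config = pipeline_config(),
                       noise = noise_config(), progress = FALSE) {
  stopifnot(length(subjects) >= 3)
  results <- list()
  exclusions <- data.frame(id = character(), reason = character())
  for (i in seq_along(subjects)) {
    sub <- subjects[[i]]
    res <- tryCatch({
      bundle <- if (inherits(sub, "subject_spec")) simulate_subject(sub, noise)
                else sub
      run_subject(bundle, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      id <- if (!is.null(sub$id)) as.character(sub$id) else sprintf("subject%d", i)
      exclusions <- rbind(exclusions,
                          data.frame(id = id, reason = conditionMessage(res)))
    } else {
      results[[length(results) + 1L]] <- res
    }
    if (progress)
      message(sprintf("[%d/%d] processed=%d excluded=%d", i, length(subjects),
                      length(results), nrow(exclusions)))
  }
  if (length(results) < 3)
    stop("fewer than 3 processable subjects")
  val <- function(field, p) vapply(results, function(r) r[[field]][[p]], numeric(1))
  subj_df <- data.frame(id = vapply(results, `[[`, character(1), "id"))
  for (p in morph_params) {
    subj_df[[paste0("baseline_", p)]] <- val("morph_baseline", p)
    subj_df[[paste0("baseline_alt_", p)]] <- val("morph_baseline_alt", p)
    subj_df[[paste0("stress_", p)]] <- val("morph_stress", p)
  }
  subj_df$baseline_mean_hr_bpm <- vapply(results, function(r) r$hrv_baseline$mean_hr_bpm, numeric(1))
  subj_df$stress_mean_hr_bpm <- vapply(results, function(r) r$hrv_stress$mean_hr_bpm, numeric(1))
  subj_df$baseline_rmssd_ms <- vapply(results, function(r) r$hrv_baseline$rmssd_ms, numeric(1))
  subj_df$stress_rmssd_ms <- vapply(results, function(r) r$hrv_stress$rmssd_ms, numeric(1))
  all_params <- c(morph_params, "mean_hr_bpm", "rmssd_ms")
  comparisons <- lapply(all_params, function(p) {
    paired_compare(subj_df[[paste0("baseline_", p)]],
                   subj_df[[paste0("stress_", p)]], parameter = p)
  })
  names(comparisons) <- all_params
  table <- do.call(rbind, lapply(comparisons, function(pc) {
    data.frame(parameter = pc$parameter,
               baseline_mean = pc$mean_baseline, baseline_sd = pc$sd_baseline,
               stress_mean = pc$mean_condition, stress_sd = pc$sd_condition,
               diff_mean = pc$mean_diff, diff_sd = pc$sd_diff,
               test = pc$test_used, p_value = pc$p_value,
               significant = !is.na(pc$p_value) & pc$p_value < 0.05)
  }))
  rownames(table) <- NULL
  ba <- lapply(morph_params[1:4], function(p) {
    bland_altman(subj_df[[paste0("baseline_alt_", p)]],
                 subj_df[[paste0("baseline_", p)]])
  })
  names(ba) <- morph_params[1:4]
  correlations <- list()
  dct1 <- subj_df$stress_ct_1mm_um - subj_df$baseline_ct_1mm_um
  dct3 <- subj_df$stress_ct_3mm_um - subj_df$baseline_ct_3mm_um
  dhr <- subj_df$stress_mean_hr_bpm - subj_df$baseline_mean_hr_bpm
  safe_cor <- function(x, y) tryCatch(correlate(x, y), error = function(e) NULL)
  # axial length comes from the matching spec/bundle
  al <- vapply(seq_len(nrow(subj_df)), function(i) {
    s <- subjects[[match(subj_df$id[i], vapply(subjects, function(x)
      as.character(x$id %||% ""), character(1)))]]
    if (inherits(s, "subject_spec")) s$geometry$axial_length_mm
    else s$axial_length_mm %||% NA_real_
  }, numeric(1))
  subj_df$axial_length_mm <- al
  correlations$dct1_vs_axial_length <- safe_cor(dct1, al)
  correlations$dct3_vs_axial_length <- safe_cor(dct3, al)
  correlations$dct1_vs_dhr <- safe_cor(dct1, dhr)
  correlations$dct3_vs_dhr <- safe_cor(dct3, dhr)
  correlations$baseline_rmssd_vs_ct1 <- safe_cor(subj_df$baseline_rmssd_ms,
                                                 subj_df$baseline_ct_1mm_um)
  correlations$baseline_rmssd_vs_ct3 <- safe_cor(subj_df$baseline_rmssd_ms,
                                                 subj_df$baseline_ct_3mm_um)
  structure(list(table = table, comparisons = comparisons, bland_altman = ba,
                 correlations = correlations, subjects = subj_df,
                 exclusions = exclusions,
                 n_processed = length(results)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects processed, %d excluded\n",
              x$n_processed, nrow(x$exclusions)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Load a subject from a file manifest
#'
#' Reads a subject's scans and RR recording from disk: two baseline TIFF
#' volumes, one stress TIFF volume and a plain-text RR export with a JSON
#' event sidecar naming `baseline_1`, `baseline_2`, `stress_1`, `stress_2`.
#'
#' @param id subject identifier.
#' @param axial_length_mm axial length, mm (plausible range 15-40).
#' @param baseline1_path,baseline2_path,stress_path TIFF volume paths.
#' @param rr_path RR text file path (events in `<rr_path>.events.json`).
#' @param orientation eye orientation flag.
#' @return a `subject_bundle`.
#' @export
load_subject_manifest <- function(id, axial_length_mm, baseline1_path,
                                  baseline2_path, stress_path, rr_path,
                                  orientation = c("left", "right")) {
  orientation <- match.arg(orientation)
  stopifnot(axial_length_mm >= 15, axial_length_mm <= 40)
  for (p in c(baseline1_path, baseline2_path, stress_path, rr_path))
    if (!file.exists(p)) stop("manifest file not found: ", p)
  rd <- function(p) {
    v <- read_oct_volume(p)
    v$axial_length_mm <- axial_length_mm
    v$orientation <- orientation
    v
  }
  structure(list(id = id, axial_length_mm = axial_length_mm,
                 orientation = orientation,
                 vol_base1 = rd(baseline1_path), vol_base2 = rd(baseline2_path),
                 vol_stress = rd(stress_path),
                 rr = read_rr_series(rr_path)),
            class = "subject_bundle")
}
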