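# Forward simulation: ground-truth multivoxel patterns -> BOLD time series.

#' Simulation configuration
#'
#' Bundles the study-design constants and the simulator's free parameters.
#' Defaults mirror the study conditions: 26 subjects, 8 search runs of 16
#' trials at 75% scene validity, 4 one-back runs, TR 1.5 s, 3-mm isotropic
#' voxels, and a behavioral validity effect of dz = 0.678. The voxel grid
#' and ROI geometry are desk-scale stand-ins (a small grid with spherical
#' ROIs) since the analysis is insensitive to absolute brain size.
#'
#' @param n_subjects cohort size.
#' @param search_runs,trials_per_run,valid_fraction search-task design.
#' @param oneback_runs,oneback_iti 1-back design (ITI after the 8-s delay).
#' @param localizer_runs localizer design.
#' @param tr repetition time, seconds.
#' @param dim,voxel_size voxel grid shape and size (mm).
#' @param roi_specs named list of `list(center = c(i,j,k), radius_mm = r)`
#'   spheres.
#' @param information named list mapping ROI label to the cross-decoding
#'   signals it carries, each a subset of `c("cue_face", "cue_scene",
#'   "delay_face", "delay_scene")`. The default mirrors the study's headline
#'   pattern: cue-period face information in FFA, delay-period associated-
#'   scene information in PPA and IFJ, and an uninformative control ROI.
#' @param amplitude standard deviation of the condition-specific voxel
#'   patterns (response units, i.e., units of GLM betas).
#' @param noise_sd scan noise standard deviation (same units).
#' @param ar1 AR(1) coefficient of the scan noise (0 = white).
#' @param baseline constant baseline signal.
#' @param evoked_mean mean evoked response added to every task regressor in
#'   every voxel (univariate activation common to all conditions).
#' @param validity_effect `list(rois =, delta =)`: uniform extra activation
#'   of `display_invalid` over the named ROIs (scene-validity univariate
#'   effect; default none).
#' @param localizer_selectivity named list mapping ROI label to preferred
#'   localizer categories; those block regressors gain `localizer_boost` in
#'   that ROI.
#' @param localizer_boost selectivity amplitude for the localizer.
#' @param dz_behav behavioral scene-validity effect size (Cohen's dz).
#' @param behav RT model parameters: `rt_base`, `sd_trial` (trial-level RT
#'   noise, s), `sd_subject` (between-subject spread of the validity effect,
#'   s), `sd_base` (between-subject spread of mean RT, s), `acc_base` and
#'   `acc_effect` (accuracy validity effect at dz = 0.678, scaled linearly
#'   with `dz_behav`).
#' @param association a [association_map()].
#' @param seed master seed; all per-subject / per-stage streams derive from
#'   it.
#' @return an object of class `sim_config` (a list).
#' @export
sim_config <- function(n_subjects = 26,
                       search_runs = 8, trials_per_run = 16,
                       valid_fraction = 0.75,
                       oneback_runs = 4, oneback_iti = 9,
                       localizer_runs = 2,
                       tr = 1.5,
                       dim = c(14, 14, 10), voxel_size = 3,
                       roi_specs = list(
                         FFA  = list(center = c(4, 4, 3),  radius_mm = 6),
                         PPA  = list(center = c(11, 4, 3), radius_mm = 6),
                         IFJ  = list(center = c(4, 11, 8), radius_mm = 6),
                         CTRL = list(center = c(11, 11, 8), radius_mm = 6)),
                       information = list(FFA = "cue_face",
                                          PPA = "delay_scene",
                                          IFJ = "delay_scene"),
                       amplitude = 0.5,
                       noise_sd = 1,
                       ar1 = 0,
                       baseline = 100,
                       evoked_mean = 1,
                       validity_effect = list(rois = character(0), delta = 0),
                       localizer_selectivity = list(FFA = "faces",
                                                    PPA = c("houses", "corridors")),
                       localizer_boost = 1,
                       dz_behav = 0.678,
                       behav = list(rt_base = 0.8, sd_trial = 0.25,
                                    sd_subject = 0.05, sd_base = 0.1,
                                    acc_base = 0.935, acc_effect = 0.07),
                       association = association_map(),
                       seed = 1) {
  if (valid_fraction < 0 || valid_fraction > 1)
    stopf("valid_fraction must be in [0, 1]")
  if (tr <= 0) stopf("tr must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  geometry <- volume_geometry(dim, voxel_size)
  cfg <- list(n_subjects = n_subjects, search_runs = search_runs,
              trials_per_run = trials_per_run, valid_fraction = valid_fraction,
              oneback_runs = oneback_runs, oneback_iti = oneback_iti,
              localizer_runs = localizer_runs, tr = tr,
              geometry = geometry, roi_specs = roi_specs,
              information = information, amplitude = amplitude,
              noise_sd = noise_sd, ar1 = ar1, baseline = baseline,
              evoked_mean = evoked_mean, validity_effect = validity_effect,
              localizer_selectivity = localizer_selectivity,
              localizer_boost = localizer_boost,
              dz_behav = dz_behav, behav = behav,
              association = association, seed = seed)
  badi <- setdiff(unlist(information), CROSS_SCHEMES)
  if (length(badi)) stopf("unknown information signals: %s", paste(badi, collapse = ", "))
  for (nm in names(roi_specs)) {
    idx <- sphere_offsets_linear(roi_specs[[nm]]$center,
                                 roi_specs[[nm]]$radius_mm, geometry)
    if (length(idx) < 2) stopf("ROI '%s' does not fit inside the grid", nm)
  }
  structure(cfg, class = "sim_config")
}

#' ROI masks for a simulation configuration
#'
#' @param config a [sim_config()].
#' @return named list of `roi_mask` objects.
#' @export
sim_roi_masks <- function(config) {
  out <- list()
  for (nm in names(config$roi_specs)) {
    sp <- config$roi_specs[[nm]]
    out[[nm]] <- sphere_mask(config$geometry, sp$center, sp$radius_mm, label = nm)
  }
  out
}

#' Ground-truth condition patterns for one subject
#'
#' Draws the condition-specific multivoxel patterns that the simulator
#' injects and the decoder is meant to recover. Within each
#' information-bearing ROI there is one fixed Gaussian pattern per face
#' identity and/or scene category (standard deviation = `amplitude`). The
#' same face pattern drives the search-cue response and the 1-back face
#' sample, and the same scene pattern drives the search delay (keyed by the
#' cued face's associated scene) and the 1-back scene trials — this shared
#' code is what makes cross-task decoding possible.
#'
#' @param config a [sim_config()].
#' @param subject subject index (patterns are subject-specific, as in native
#'   space).
#' @return an object of class `ground_truth`.
#' @export
make_ground_truth <- function(config, subject = 1L) {
  set.seed(derive_seed(config$seed, "ground_truth", subject))
  rois <- list()
  for (nm in names(config$roi_specs)) {
    sp <- config$roi_specs[[nm]]
    vox <- sphere_offsets_linear(sp$center, sp$radius_mm, config$geometry)
    schemes <- config$information[[nm]] %||% character(0)
    need_face <- any(schemes %in% c("cue_face", "delay_face"))
    need_scene <- any(schemes %in% c("cue_scene", "delay_scene"))
    pat <- list()
    # draw both unconditionally so the RNG stream does not depend on the
    # information assignment
    face_pat <- matrix(rnorm(4 * length(vox), sd = config$amplitude), 4)
    scene_pat <- matrix(rnorm(4 * length(vox), sd = config$amplitude), 4)
    if (need_face) pat$face <- face_pat
    if (need_scene) pat$scene <- scene_pat
    rois[[nm]] <- list(voxels = vox, schemes = schemes, patterns = pat)
  }
  structure(list(subject = subject, rois = rois,
                 association = config$association,
                 amplitude = config$amplitude,
                 noise = list(sd = config$noise_sd, ar1 = config$ar1),
                 seed = config$seed),
            class = "ground_truth")
}

#' @noRd
infer_task <- function(events) {
  cond <- events$condition[1]
  if (startsWith(cond, "search")) "search"
  else if (startsWith(cond, "oneback")) "oneback"
  else if (startsWith(cond, "loc_")) "localizer"
  else stopf("cannot infer task from condition '%s'", cond)
}

#' @noRd
true_beta_matrix <- function(design, gt, config, task) {
  V <- prod(config$geometry$dim)
  cols <- colnames(design)
  B <- matrix(0, ncol(design), V, dimnames = list(cols, NULL))
  n_task <- attr(design, "n_task")
  B[seq_len(n_task), ] <- config$evoked_mean
  B["constant", ] <- config$baseline
  assoc <- gt$association
  for (nm in names(gt$rois)) {
    roi <- gt$rois[[nm]]
    vox <- roi$voxels
    for (sc in roi$schemes) {
      if (task == "search") {
        for (f in 1:4) {
          if (sc == "cue_face")
            B[paste0("cue_face", f), vox] <- B[paste0("cue_face", f), vox] +
              roi$patterns$face[f, ]
          if (sc == "cue_scene")
            B[paste0("cue_face", f), vox] <- B[paste0("cue_face", f), vox] +
              roi$patterns$scene[assoc[f], ]
          if (sc == "delay_face" && paste0("delay_face", f) %in% cols)
            B[paste0("delay_face", f), vox] <- B[paste0("delay_face", f), vox] +
              roi$patterns$face[f, ]
          if (sc == "delay_scene" && paste0("delay_face", f) %in% cols)
            B[paste0("delay_face", f), vox] <- B[paste0("delay_face", f), vox] +
              roi$patterns$scene[assoc[f], ]
        }
      } else if (task == "oneback") {
        for (f in 1:4) {
          if (sc == "cue_face")
            B[paste0("sample_face", f), vox] <- B[paste0("sample_face", f), vox] +
              roi$patterns$face[f, ]
          if (sc == "delay_face")
            B[paste0("delay_face", f), vox] <- B[paste0("delay_face", f), vox] +
              roi$patterns$face[f, ]
          if (sc == "cue_scene")
            B[paste0("sample_scene", f), vox] <- B[paste0("sample_scene", f), vox] +
              roi$patterns$scene[f, ]
          if (sc == "delay_scene")
            B[paste0("delay_scene", f), vox] <- B[paste0("delay_scene", f), vox] +
              roi$patterns$scene[f, ]
        }
      }
    }
    if (task == "search" && nm %in% config$validity_effect$rois &&
        "display_invalid" %in% cols)
      B["display_invalid", vox] <- B["display_invalid", vox] +
        config$validity_effect$delta
    if (task == "localizer") {
      cats <- config$localizer_selectivity[[nm]]
      for (ct in cats) {
        col <- paste0("loc_", ct)
        if (col %in% cols)
          B[col, vox] <- B[col, vox] + config$localizer_boost
      }
    }
  }
  B
}

#' Simulate multivoxel BOLD runs from ground truth
#'
#' Forward model: for every run, the same design matrix the analysis will
#' fit (canonical-HRF convolution of the events, motion nuisance columns,
#' constant) is multiplied by a true beta matrix assembled from the
#' ground-truth patterns, and Gaussian (optionally AR(1)) noise is added.
#' With `noise_sd = 0` the downstream GLM recovers the true betas exactly.
#'
#' @param events event table (all runs of one task); the task is inferred
#'   from the condition labels.
#' @param ground_truth a [make_ground_truth()] result.
#' @param config a [sim_config()].
#' @param seed optional integer; default derives from the config seed, the
#'   subject and the task.
#' @return list of `bold_run` objects (one per run), each with elements
#'   `bold` (scans x voxels), `design`, `true_beta`, `motion`, `events`,
#'   `geometry`.
#' @export
simulate_bold <- function(events, ground_truth, config, seed = NULL) {
  task <- infer_task(events)
  if (is.null(seed))
    seed <- derive_seed(config$seed, "bold", ground_truth$subject, task)
  if (config$noise_sd < 0) stopf("noise_sd must be >= 0")
  V <- prod(config$geometry$dim)
  runs <- sort(unique(events$run))
  out <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    set.seed(derive_seed(seed, ri))
    ev <- events[events$run == runs[ri], ]
    attr(ev, "run_duration") <- attr(events, "run_duration")
    n_scans <- events_n_scans(ev, config$tr)
    motion <- matrix(cumsum(rnorm(n_scans * 6, sd = 0.02)), n_scans, 6)
    design <- build_design_matrix(ev, n_scans, config$tr, motion = motion,
                                  scheme = task)
    B <- true_beta_matrix(design, ground_truth, config, task)
    noise <- matrix(rnorm(n_scans * V, sd = config$noise_sd), n_scans, V)
    if (config$ar1 != 0) {
      a <- config$ar1
      for (t in 2:n_scans)
        noise[t, ] <- a * noise[t - 1, ] + sqrt(1 - a^2) * noise[t, ]
    }
    Y <- unclass(design) %*% B + noise
    out[[ri]] <- structure(
      list(bold = Y, design = design, true_beta = B, motion = motion,
           events = ev, geometry = config$geometry, run = runs[ri]),
      class = "bold_run")
  }
  out
}

#' Mark error trials on a search event table
#'
#' Flags the display events of incorrect trials so the design matrix builder
#' routes them to the error-response regressor (the study's GLM models error
#' displays separately).
#'
#' @param events search `event_table`.
#' @param behavior rows of a [simulate_behavior()] table for one subject
#'   (columns `run`, `trial`, `correct`).
#' @return the event table with a logical `error` column.
#' @export
mark_error_trials <- function(events, behavior) {
  key_ev <- paste(events$run, events$trial)
  key_bh <- paste(behavior$run, behavior$trial)
  bad <- key_bh[!behavior$correct]
  events$error <- events$condition == "search_display" & key_ev %in% bad
  events
}

#' Simulate a complete subject (designs, ground truth, BOLD)
#'
#' @param config a [sim_config()].
#' @param subject subject index.
#' @param localizer also simulate the localizer task (default `FALSE`).
#' @param behavior optional behavioral table (its error trials are modeled
#'   in the search GLM).
#' @return list with `search` and `oneback` lists of `bold_run`s, the
#'   `ground_truth`, the event tables, and `label_map`.
#' @export
simulate_subject <- function(config, subject = 1L, localizer = FALSE,
                             behavior = NULL) {
  search_ev <- make_search_design(config$search_runs, config$trials_per_run,
                                  config$valid_fraction,
                                  seed = derive_seed(config$seed, "design_search", subject),
                                  association = config$association)
  oneback_ev <- make_oneback_design(config$oneback_runs,
                                    seed = derive_seed(config$seed, "design_oneback", subject),
                                    iti = config$oneback_iti)
  if (!is.null(behavior)) {
    bs <- behavior[behavior$subject_id == subject, ]
    if (nrow(bs)) search_ev <- mark_error_trials(search_ev, bs)
  }
  gt <- make_ground_truth(config, subject)
  out <- list(subject = subject,
              events = list(search = search_ev, oneback = oneback_ev),
              ground_truth = gt,
              label_map = config$association,
              search = simulate_bold(search_ev, gt, config),
              oneback = simulate_bold(oneback_ev, gt, config))
  if (localizer) {
    loc_ev <- make_localizer_design(config$localizer_runs,
                                    seed = derive_seed(config$seed, "design_localizer", subject))
    out$events$localizer <- loc_ev
    out$localizer <- simulate_bold(loc_ev, gt, config)
  }
  out
}

#' Simulate behavioral accuracy and response times
#'
#' Generates per-trial RTs and correctness with a scene-validity effect whose
#' across-subject standardized size (Cohen's dz of the per-subject
#' invalid-minus-valid RT difference) targets `dz_behav`. The population mean
#' difference is set to `dz_behav` times the predicted standard deviation of
#' per-subject differences (between-subject spread plus trial-sampling
#' noise), so the recovered dz is unbiased in expectation. Accuracy is higher
#' on valid trials by an amount scaled linearly with `dz_behav`.
#'
#' @param search_events a search `event_table` (defines trial counts and
#'   validity labels; all subjects share the trial structure).
#' @param dz_behav target effect size (study estimate: 0.678).
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @param behav RT model parameters, see [sim_config()].
#' @return a `behavioral_table` data frame: `subject_id, run, trial,
#'   validity, correct, rt`.
#' @export
simulate_behavior <- function(search_events, dz_behav = 0.678,
                              n_subjects = 26, seed = 1,
                              behav = list(rt_base = 0.8, sd_trial = 0.25,
                                           sd_subject = 0.05, sd_base = 0.1,
                                           acc_base = 0.935, acc_effect = 0.07)) {
  if (dz_behav < 0) stopf("dz_behav must be >= 0")
  if (n_subjects < 2)
    warnf("n_subjects < 2: group statistics are undefined downstream")
  disp <- search_events[search_events$condition == "search_display", ]
  n_val <- sum(disp$validity == "valid")
  n_inv <- sum(disp$validity == "invalid")
  sd_diff <- sqrt(behav$sd_subject^2 +
                  behav$sd_trial^2 * (1 / max(n_inv, 1) + 1 / max(n_val, 1)))
  mu_d <- dz_behav * sd_diff
  acc_delta <- behav$acc_effect * dz_behav / 0.678
  p_val <- min(behav$acc_base + acc_delta / 2, 1)
  p_inv <- max(behav$acc_base - acc_delta / 2, 0)
  set.seed(seed)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    base_s <- behav$rt_base + rnorm(1, sd = behav$sd_base)
    delta_s <- mu_d + rnorm(1, sd = behav$sd_subject)
    inv <- disp$validity == "invalid"
    rt <- base_s + ifelse(inv, delta_s, 0) +
      rnorm(nrow(disp), sd = behav$sd_trial)
    rt <- pmax(rt, 0.15)
    correct <- rbinom(nrow(disp), 1, ifelse(inv, p_inv, p_val)) == 1
    out[[s]] <- data.frame(subject_id = s, run = disp$run, trial = disp$trial,
                           validity = disp$validity, correct = correct,
                           rt = rt)
  }
  structure(do.call(rbind, out),
            class = c("behavioral_table", "data.frame"))
}
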