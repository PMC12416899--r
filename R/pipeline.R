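# End-to-end orchestration: simulate -> GLM -> decode -> infer -> map.

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults matching the study parameters (TR 1.5 s, searchlight
#' radius 9 mm, 10,000 permutations, SVM cost 1, chance level 0.5, all four
#' cross-classification schemes) and rejects contradictions with readable
#' errors.
#'
#' @param config a (possibly partial) named list: `sim` (a [sim_config()] or
#'   a list of its arguments), `schemes`, `rois`, `n_perm`, `alpha`,
#'   `bonferroni_family`, `chance`, `cost`, `radius_mm`, `smooth_fwhm`,
#'   `tfce` (a [tfce_params()]), `searchlight` (logical),
#'   `searchlight_schemes`, `seed`, `verbose`. May also be a path to a YAML
#'   or JSON file holding such a list.
#' @return a normalized `pipeline_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML/JSON path")
  cfg <- config
  if (is.null(cfg$sim)) cfg$sim <- sim_config()
  else if (!inherits(cfg$sim, "sim_config")) cfg$sim <- do.call(sim_config, cfg$sim)
  cfg$schemes <- cfg$schemes %||% CROSS_SCHEMES
  bad <- setdiff(cfg$schemes, CROSS_SCHEMES)
  if (length(bad))
    stopf("unknown scheme(s) %s; valid schemes are: %s",
          paste(bad, collapse = ", "), paste(CROSS_SCHEMES, collapse = ", "))
  cfg$rois <- cfg$rois %||% names(cfg$sim$roi_specs)
  bad <- setdiff(cfg$rois, names(cfg$sim$roi_specs))
  if (length(bad))
    stopf("unknown ROI(s): %s", paste(bad, collapse = ", "))
  cfg$n_perm <- cfg$n_perm %||% 10000L
  if (cfg$n_perm < 1) stopf("n_perm must be >= 1")
  cfg$alpha <- cfg$alpha %||% 0.05
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stopf("alpha must be in (0, 1)")
  cfg$bonferroni_family <- cfg$bonferroni_family %||% length(cfg$rois)
  cfg$chance <- cfg$chance %||% 0.5
  cfg$cost <- cfg$cost %||% 1
  if (cfg$cost <= 0) stopf("cost must be > 0")
  cfg$radius_mm <- cfg$radius_mm %||% 9
  cfg$smooth_fwhm <- cfg$smooth_fwhm %||% 4
  cfg$tfce <- if (is.null(cfg$tfce)) tfce_params()
              else if (inherits(cfg$tfce, "tfce_params")) cfg$tfce
              else do.call(tfce_params, cfg$tfce)
  cfg$searchlight <- isTRUE(cfg$searchlight)
  cfg$searchlight_schemes <- cfg$searchlight_schemes %||% cfg$schemes
  cfg$cluster_p <- cfg$cluster_p %||% 0.005
  cfg$min_cluster <- cfg$min_cluster %||% 50
  cfg$seed <- cfg$seed %||% cfg$sim$seed
  cfg$verbose <- cfg$verbose %||% TRUE
  structure(cfg, class = "pipeline_config")
}

#' @noRd
fit_task <- function(runs, ar1 = 0) lapply(runs, function(r) fit_glm(r, r$design, ar1 = ar1))

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates the cohort (per-subject task designs, behavior, ground-truth
#' patterns, BOLD), fits the first-level GLMs, runs ROI cross-classification
#' for every configured ROI x scheme, performs permutation group inference
#' with Bonferroni control, computes the behavioral validity statistics, and
#' (optionally) the group searchlight with TFCE correction. Deterministic
#' given the configuration.
#'
#' @param config a [validate_config()] input (list, path, or
#'   `pipeline_config`).
#' @param output_dir optional directory; when given, results tables and a
#'   provenance sidecar are written there.
#' @return a `report_bundle`: list with `decoding` (data frame: roi, scheme,
#'   accuracy, t, p_uncorrected, p_bonferroni, family, n_perm, seed),
#'   `subject_accuracy` (long data frame), `behavior` (data frame of paired
#'   tests), `searchlight` (per-scheme `tfce_result`s or `NULL`),
#'   `provenance` (config hash, master seed, package version).
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  cfg <- validate_config(config)
  sim <- cfg$sim
  say <- function(...) if (cfg$verbose) message(sprintf(...))

  # --- behavioral simulation (per-subject designs drive the trial lists) --
  say("simulating %d subjects (%d search runs, %d one-back runs)",
      sim$n_subjects, sim$search_runs, sim$oneback_runs)
  behavior <- vector("list", sim$n_subjects)
  fits <- vector("list", sim$n_subjects)
  for (s in seq_len(sim$n_subjects)) {
    search_ev <- make_search_design(sim$search_runs, sim$trials_per_run,
                                    sim$valid_fraction,
                                    seed = derive_seed(sim$seed, "design_search", s),
                                    association = sim$association)
    bh <- suppressWarnings(
      simulate_behavior(search_ev, sim$dz_behav, n_subjects = 1,
                        seed = derive_seed(sim$seed, "behavior", s),
                        behav = sim$behav))
    bh$subject_id <- s
    behavior[[s]] <- bh
    sub <- simulate_subject(sim, s, behavior = bh)
    fits[[s]] <- list(search = fit_task(sub$search),
                      oneback = fit_task(sub$oneback))
  }
  behavior <- do.call(rbind, behavior)
  masks <- sim_roi_masks(sim)

  # --- ROI decoding + permutation inference ------------------------------
  dec_rows <- list()
  subj_rows <- list()
  for (scheme in cfg$schemes) {
    for (roi in cfg$rois) {
      problems <- lapply(fits, function(f)
        decoding_problem(f$search, f$oneback, masks[[roi]], scheme,
                         label_map = sim$association))
      obs <- vapply(problems, decode_accuracy, numeric(1), cost = cfg$cost)
      null_seed <- derive_seed(cfg$seed, "null", scheme, roi)
      null <- permutation_null(problems, cfg$n_perm, seed = null_seed,
                               cost = cfg$cost, alpha = cfg$alpha)
      p_unc <- permutation_pvalue(mean(obs), null)
      gt_stat <- group_ttest_vs_chance(obs, cfg$chance, tails = 1)
      dec_rows[[length(dec_rows) + 1]] <- data.frame(
        roi = roi, scheme = scheme, accuracy = mean(obs),
        t = gt_stat$t, p_uncorrected = p_unc,
        p_bonferroni = bonferroni(p_unc, cfg$bonferroni_family),
        family = cfg$bonferroni_family, n_perm = cfg$n_perm,
        seed = null_seed)
      subj_rows[[length(subj_rows) + 1]] <- data.frame(
        subject = seq_along(obs), roi = roi, scheme = scheme, accuracy = obs)
      say("decoded %s in %s: %.3f (p = %.4g)", scheme, roi, mean(obs), p_unc)
    }
  }
  decoding <- do.call(rbind, dec_rows)
  subject_accuracy <- do.call(rbind, subj_rows)

  # --- behavioral validity statistics ------------------------------------
  agg <- function(field, val) {
    vapply(split(behavior, behavior$subject_id), function(b)
      mean(b[[field]][b$validity == val]), numeric(1))
  }
  rt_stat <- paired_t_cohens_d(agg("rt", "invalid"), agg("rt", "valid"))
  acc_stat <- paired_t_cohens_d(agg("correct", "valid"), agg("correct", "invalid"))
  behavior_stats <- data.frame(
    measure = c("rt_invalid_minus_valid", "accuracy_valid_minus_invalid"),
    mean_difference = c(rt_stat$mean, acc_stat$mean),
    t = c(rt_stat$t, acc_stat$t), df = c(rt_stat$df, acc_stat$df),
    p = c(rt_stat$p, acc_stat$p),
    cohens_dz = c(rt_stat$cohens_dz, acc_stat$cohens_dz))

  # --- optional searchlight ----------------------------------------------
  searchlight <- NULL
  if (cfg$searchlight) {
    mask <- array(TRUE, sim$geometry$dim)
    searchlight <- list()
    for (scheme in cfg$searchlight_schemes) {
      say("searchlight: %s", scheme)
      maps <- lapply(fits, function(f) {
        sl <- run_searchlight(f$search, f$oneback, scheme,
                              radius_mm = cfg$radius_mm,
                              geometry = sim$geometry, mask = mask,
                              label_map = sim$association, cost = cfg$cost)
        smooth_volume(sl$accuracy, cfg$smooth_fwhm, sim$geometry)
      })
      searchlight[[scheme]] <- tfce_corrected_pmap(
        maps, mask, cfg$tfce, n_perm = min(cfg$n_perm, 1000),
        seed = derive_seed(cfg$seed, "tfce", scheme), center = cfg$chance,
        cluster_p = cfg$cluster_p, min_cluster = cfg$min_cluster)
    }
  }

  provenance <- list(
    config_hash = object_hash(unclass(cfg)[order(names(cfg))]),
    seed = cfg$seed,
    n_subjects = sim$n_subjects,
    package_version = as.character(utils::packageVersion("crossdecode")))
  bundle <- structure(list(decoding = decoding,
                           subject_accuracy = subject_accuracy,
                           behavior = behavior_stats,
                           behavior_trials = behavior,
                           searchlight = searchlight,
                           provenance = provenance),
                      class = "report_bundle")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_tsv(decoding, file.path(output_dir, "decoding.tsv"))
    write_results_tsv(behavior_stats, file.path(output_dir, "behavior.tsv"))
    write_results_tsv(subject_accuracy,
                      file.path(output_dir, "subject_accuracy.tsv"))
    jsonlite::write_json(provenance, file.path(output_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n-------------\nROI decoding:\n")
  print(x$decoding, row.names = FALSE)
  cat("\nBehavior:\n")
  print(x$behavior, row.names = FALSE)
  cat(sprintf("\nprovenance: config %s, seed %d\n",
              x$provenance$config_hash, x$provenance$seed))
  invisible(x)
}
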