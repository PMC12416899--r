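# Task design generators: cued face search, face/scene 1-back, associative
# learning, and the category localizer. All counts are exact (not sampled),
# and trial orders are pseudorandomized from the seed.

SEARCH_CUE_DUR <- 1
SEARCH_DELAY_DUR <- 8
SEARCH_DISPLAY_DUR <- 0.25
SEARCH_ITI <- 8.75
ONEBACK_SAMPLE_DUR <- 1
ONEBACK_DELAY_DUR <- 8

#' Default face-to-scene association map
#'
#' The learned association between the four target faces and the four scene
#' categories is a bijection on 1..4. The default pairs face i with scene i;
#' pass a permutation to `permute` for other pairings.
#'
#' @param permute optional permutation of 1:4; `association[face]` is the
#'   scene category associated with that face.
#' @return an object of class `label_map`: integer vector of length 4 (scene
#'   per face) with the inverse map as attribute `face_for_scene`.
#' @export
association_map <- function(permute = 1:4) {
  if (!identical(sort(as.integer(permute)), 1:4))
    stopf("association must be a permutation of 1:4")
  assoc <- as.integer(permute)
  inv <- integer(4)
  inv[assoc] <- 1:4
  structure(assoc, face_for_scene = inv, class = "label_map")
}

#' @noRd
new_event_table <- function(df, run_duration = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("event_table", "data.frame"),
            run_duration = run_duration)
}

#' Generate a cued face-search task design
#'
#' Each trial is a 1-s face cue, an 8-s blank delay, a 0.25-s search display
#' and an 8.75-s inter-trial interval (18 s per trial). Per run, every one of
#' the four target faces is cued `trials_per_run / 4` times and the number of
#' scene-valid trials is exactly `trials_per_run * valid_fraction` (the
#' default design: 16 trials per run, 12 valid and 4 invalid). On valid
#' trials the target appears on its associated scene; on invalid trials on a
#' scene from one of the three unassociated categories. Validity is
#' counterbalanced across faces as evenly as the counts allow, and the trial
#' order within each run is shuffled from the seed.
#'
#' @param n_runs number of runs (study design: 8).
#' @param trials_per_run trials per run, divisible by 4 (study design: 16).
#' @param valid_fraction fraction of scene-valid trials;
#'   `trials_per_run * valid_fraction` must be an integer (study design: 0.75).
#' @param seed integer seed.
#' @param association a [association_map()].
#' @return an `event_table` with one cue, one delay and one display event per
#'   trial; columns `run, trial, onset, duration, condition, face_id,
#'   scene_category, validity, is_repeat`.
#' @export
make_search_design <- function(n_runs = 8, trials_per_run = 16,
                               valid_fraction = 0.75, seed = 1,
                               association = association_map()) {
  if (n_runs < 1) stopf("n_runs must be >= 1")
  if (trials_per_run %% 4 != 0)
    stopf("trials_per_run must be divisible by 4 to counterbalance the four faces")
  n_valid <- trials_per_run * valid_fraction
  if (abs(n_valid - round(n_valid)) > 1e-9)
    stopf("trials_per_run * valid_fraction must be an integer (got %.3f)", n_valid)
  n_valid <- as.integer(round(n_valid))
  per_face <- trials_per_run %/% 4L

  set.seed(seed)
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    faces <- rep(1:4, each = per_face)
    # distribute the valid quota as evenly as possible over faces
    base <- n_valid %/% 4L
    extra <- n_valid - 4L * base
    face_valid <- rep(base, 4) + as.integer(seq_len(4) %in% sample(1:4, extra))
    validity <- unlist(lapply(1:4, function(f)
      sample(rep(c("valid", "invalid"), c(face_valid[f], per_face - face_valid[f])))))
    ord <- sample(trials_per_run)
    faces <- faces[ord]
    validity <- validity[ord]
    scene <- integer(trials_per_run)
    for (t in seq_len(trials_per_run)) {
      scene[t] <- if (validity[t] == "valid") association[faces[t]]
                  else sample(setdiff(1:4, association[faces[t]]), 1)
    }
    t0 <- (seq_len(trials_per_run) - 1) *
      (SEARCH_CUE_DUR + SEARCH_DELAY_DUR + SEARCH_DISPLAY_DUR + SEARCH_ITI)
    mk <- function(cond, onset, dur, scn) data.frame(
      run = r, trial = seq_len(trials_per_run), onset = onset, duration = dur,
      condition = cond, face_id = faces, scene_category = scn,
      validity = validity, is_repeat = FALSE)
    ev <- rbind(
      mk("search_cue", t0, SEARCH_CUE_DUR, NA_integer_),
      mk("search_delay", t0 + SEARCH_CUE_DUR, SEARCH_DELAY_DUR, NA_integer_),
      mk("search_display", t0 + SEARCH_CUE_DUR + SEARCH_DELAY_DUR,
         SEARCH_DISPLAY_DUR, scene))
    out[[r]] <- ev[order(ev$onset), ]
  }
  new_event_table(do.call(rbind, out),
                  run_duration = trials_per_run *
                    (SEARCH_CUE_DUR + SEARCH_DELAY_DUR +
                     SEARCH_DISPLAY_DUR + SEARCH_ITI))
}

#' Generate a face and scene 1-back task design
#'
#' Per run: four trials for each of the four target faces and four trials for
#' each of the four scene categories (32 decoding trials), plus six 1-back
#' repeat trials in which the previous stimulus is shown again. Each trial is
#' a 1-s sample stimulus followed by an 8-s delay and an inter-trial interval
#' (`iti`, default 9 s). Repeat trials are flagged `is_repeat = TRUE`; they
#' are modeled by a dedicated regressor and excluded from decoding samples.
#' The four presentations of a scene category use four distinct exemplar
#' indices.
#'
#' @param n_runs number of runs (study design: 4).
#' @param seed integer seed.
#' @param iti inter-trial interval after the delay, seconds (default 9).
#' @param n_repeats repeat trials per run (study design: 6).
#' @return an `event_table` with one sample and one delay event per trial;
#'   scene trials carry an `exemplar` column.
#' @export
make_oneback_design <- function(n_runs = 4, seed = 1, iti = 9, n_repeats = 6L) {
  if (n_runs < 1) stopf("n_runs must be >= 1")
  set.seed(seed)
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    base <- data.frame(
      face_id = c(rep(1:4, each = 4), rep(NA_integer_, 16)),
      scene_category = c(rep(NA_integer_, 16), rep(1:4, each = 4)))
    # distinct exemplars for the four presentations of each scene category
    base$exemplar <- NA_integer_
    for (s in 1:4) {
      k <- which(!is.na(base$scene_category) & base$scene_category == s)
      base$exemplar[k] <- sample(1:16, length(k))
    }
    base <- base[sample(nrow(base)), ]
    base$is_repeat <- FALSE
    # insert repeat trials after distinct base positions
    pos <- sort(sample(seq_len(nrow(base)), n_repeats))
    rows <- vector("list", nrow(base))
    for (i in seq_len(nrow(base))) {
      rows[[i]] <- base[i, ]
      if (i %in% pos) {
        rpt <- base[i, ]
        rpt$is_repeat <- TRUE
        rows[[i]] <- rbind(rows[[i]], rpt)
      }
    }
    trials <- do.call(rbind, rows)
    n_tr <- nrow(trials)
    trials$trial <- seq_len(n_tr)
    t0 <- (trials$trial - 1) * (ONEBACK_SAMPLE_DUR + ONEBACK_DELAY_DUR + iti)
    mk <- function(cond, onset, dur) data.frame(
      run = r, trial = trials$trial, onset = onset, duration = dur,
      condition = cond, face_id = trials$face_id,
      scene_category = trials$scene_category,
      validity = "n/a", is_repeat = trials$is_repeat,
      exemplar = trials$exemplar)
    ev <- rbind(mk("oneback_sample", t0, ONEBACK_SAMPLE_DUR),
                mk("oneback_delay", t0 + ONEBACK_SAMPLE_DUR, ONEBACK_DELAY_DUR))
    out[[r]] <- ev[order(ev$onset), ]
  }
  n_tr <- 32L + as.integer(n_repeats)
  new_event_table(do.call(rbind, out),
                  run_duration = n_tr * (ONEBACK_SAMPLE_DUR + ONEBACK_DELAY_DUR + iti))
}

#' Generate the face-scene associative learning task design
#'
#' The pre-scan learning test: each of the four faces is tested on 18
#' scene-match trials (the face on exemplars of its associated category) and
#' 9 scene-nonmatch trials (three scenes from each of the three other
#' categories), 108 trials in total, in pseudorandom order. Match trials are
#' coded `validity = "valid"`, nonmatch `"invalid"`.
#'
#' @param seed integer seed.
#' @param association a [association_map()].
#' @return an `event_table` of 108 single-event rows.
#' @export
make_learning_design <- function(seed = 1, association = association_map()) {
  set.seed(seed)
  rows <- list()
  for (f in 1:4) {
    match_scene <- rep(association[f], 18)
    nonmatch_scene <- rep(setdiff(1:4, association[f]), each = 3)
    rows[[f]] <- data.frame(
      face_id = f,
      scene_category = c(match_scene, nonmatch_scene),
      validity = rep(c("valid", "invalid"), c(18, 9)))
  }
  df <- do.call(rbind, rows)
  df <- df[sample(nrow(df)), ]
  n <- nrow(df)
  trial_len <- 3  # decision display + feedback + ITI, nominal
  new_event_table(data.frame(
    run = 1L, trial = seq_len(n), onset = (seq_len(n) - 1) * trial_len,
    duration = 2, condition = "learning_trial",
    face_id = df$face_id, scene_category = df$scene_category,
    validity = df$validity, is_repeat = FALSE),
    run_duration = n * trial_len)
}

#' Generate a category-selective localizer design
#'
#' Block localizer with six stimulus categories (faces, houses, corridors,
#' cars, instruments, phase-scrambled) in 4-s mini-blocks, `blocks_per_run`
#' blocks per run evenly divided over the categories, order pseudorandomized
#' per run.
#'
#' @param n_runs number of runs (study design: 2).
#' @param seed integer seed.
#' @param blocks_per_run total blocks per run, divisible by 6 (study
#'   design: 54).
#' @param block_dur block duration, seconds (default 4).
#' @param rest gap between blocks, seconds (default 2).
#' @return an `event_table` with one event per block; `condition` is
#'   `loc_<category>`.
#' @export
make_localizer_design <- function(n_runs = 2, seed = 1, blocks_per_run = 54L,
                                  block_dur = 4, rest = 2) {
  if (blocks_per_run %% 6 != 0) stopf("blocks_per_run must be divisible by 6")
  set.seed(seed)
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cats <- sample(rep(LOCALIZER_CATEGORIES, blocks_per_run / 6))
    onset <- (seq_len(blocks_per_run) - 1) * (block_dur + rest)
    out[[r]] <- data.frame(
      run = r, trial = seq_len(blocks_per_run), onset = onset,
      duration = block_dur, condition = paste0("loc_", cats),
      face_id = NA_integer_, scene_category = NA_integer_,
      validity = "n/a", is_repeat = FALSE)
  }
  new_event_table(do.call(rbind, out),
                  run_duration = blocks_per_run * (block_dur + rest))
}
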