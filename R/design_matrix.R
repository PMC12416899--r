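# HRF-convolved design matrices for the three task GLMs.

# Regressor layouts per scheme (task columns, before nuisance + constant):
#  search:            4 cue + 4 delay + {valid, invalid[, error]} displays
#  search_delay_split: 4 cue + 8 half-delay + displays (exploratory split)
#  oneback:           4 face samples + 4 face delays + 4 scene samples +
#                     4 scene delays + 1 repeat-event regressor
#  localizer:         6 category block regressors
DESIGN_SCHEMES <- c("search", "search_delay_split", "oneback", "localizer")

LOCALIZER_CATEGORIES <- c("faces", "houses", "corridors", "cars",
                          "instruments", "scrambled")

#' Build an HRF-convolved design matrix for one run
#'
#' Turns an event table into a scans x regressors matrix: condition boxcars
#' are convolved with the canonical HRF on an oversampled grid, sampled at
#' scan onsets, and motion nuisance columns plus a constant are appended.
#'
#' The search scheme follows the task GLM of the study design: four 1-s cue
#' regressors (one per target face), four 8-s delay regressors, and 1-s
#' display regressors for scene-valid, scene-invalid and (when the event
#' table flags any) error-response trials. The display is modeled with a 1-s
#' duration regardless of its physical 0.25-s duration. The 1-back scheme has
#' 17 task regressors (4 face samples, 4 face delays, 4 scene samples, 4
#' scene delays, one repeat-event regressor); delay periods of repeat trials
#' are left unmodeled. `search_delay_split` splits each 8-s delay into two
#' 4-s halves for the early/late exploratory analysis.
#'
#' @param events event table for a single run (see [make_search_design()]).
#' @param n_scans number of volumes acquired in the run.
#' @param tr repetition time, seconds.
#' @param motion optional scans x 6 matrix/data frame of realignment
#'   parameters appended as nuisance regressors; if `NULL` a warning is
#'   issued and no nuisance columns are added.
#' @param scheme one of `"search"`, `"search_delay_split"`, `"oneback"`,
#'   `"localizer"`.
#' @param hrf an [canonical_hrf()] kernel; default built from `tr`.
#' @param display_model_duration modeled duration (s) of search display
#'   regressors (default 1).
#' @param drift number of cosine drift basis columns to append (default 0).
#' @return a `design_matrix`: numeric matrix with column names and
#'   attributes `tr`, `scheme`, `n_task`, `n_nuisance`.
#' @export
build_design_matrix <- function(events, n_scans, tr, motion = NULL,
                                scheme = c("search", "search_delay_split",
                                           "oneback", "localizer"),
                                hrf = NULL,
                                display_model_duration = 1,
                                drift = 0L) {
  scheme <- match.arg(scheme)
  if (length(unique(events$run)) > 1)
    stopf("build_design_matrix expects events from a single run")
  if (is.null(hrf)) hrf <- canonical_hrf(tr)
  run_dur <- n_scans * tr
  ends <- events$onset + events$duration
  if (any(ends > run_dur + 1e-9))
    stopf("events overrun the scan duration (%.2f s run, last event ends %.2f s)",
          run_dur, max(ends))

  spec <- switch(scheme,
    search = regressors_search(events, split_delay = FALSE,
                               display_dur = display_model_duration),
    search_delay_split = regressors_search(events, split_delay = TRUE,
                                           display_dur = display_model_duration),
    oneback = regressors_oneback(events),
    localizer = regressors_localizer(events))

  os <- hrf$params$oversampling
  dt <- hrf$dt
  n_fine <- n_scans * os
  B <- matrix(0, n_fine, length(spec))
  for (j in seq_along(spec)) {
    ons <- spec[[j]]$onset
    dur <- spec[[j]]$duration
    for (e in seq_along(ons)) {
      i0 <- floor(ons[e] / dt) + 1
      i1 <- ceiling((ons[e] + dur[e]) / dt)
      i1 <- min(i1, n_fine)
      if (i0 <= i1) B[i0:i1, j] <- 1
    }
  }
  # FFT convolution of all boxcars at once, padded to a 5-smooth length
  nh <- length(hrf$values)
  N <- stats::nextn(n_fine + nh - 1)
  H <- stats::fft(c(hrf$values, numeric(N - nh)))
  Bp <- rbind(B, matrix(0, N - n_fine, ncol(B)))
  conv <- Re(stats::mvfft(stats::mvfft(Bp) * H, inverse = TRUE)) / N * dt
  X <- conv[(seq_len(n_scans) - 1) * os + 1, , drop = FALSE]
  colnames(X) <- names(spec)
  n_task <- ncol(X)

  n_nuis <- 0L
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_scans)
      stopf("motion table has %d rows, expected %d scans", nrow(motion), n_scans)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    X <- cbind(X, motion)
    n_nuis <- ncol(motion)
  } else {
    warnf("no motion table supplied; design has no motion nuisance columns")
  }
  if (drift > 0) {
    s <- seq_len(n_scans) - 1
    D <- sapply(seq_len(drift), function(k)
      cos(pi * (2 * s + 1) * k / (2 * n_scans)))
    colnames(D) <- paste0("drift", seq_len(drift))
    X <- cbind(X, D)
    n_nuis <- n_nuis + drift
  }
  X <- cbind(X, constant = 1)

  structure(X, class = c("design_matrix", "matrix"),
            tr = tr, scheme = scheme,
            n_task = n_task, n_nuisance = n_nuis)
}

# onset/duration lists per regressor ------------------------------------

#' @noRd
regressors_search <- function(events, split_delay, display_dur) {
  spec <- list()
  for (f in 1:4) {
    cue <- events[events$condition == "search_cue" & events$face_id == f, ]
    spec[[paste0("cue_face", f)]] <-
      list(onset = cue$onset, duration = cue$duration)
  }
  for (f in 1:4) {
    del <- events[events$condition == "search_delay" & events$face_id == f, ]
    if (split_delay) {
      half <- del$duration / 2
      spec[[paste0("delay_face", f, "_h1")]] <-
        list(onset = del$onset, duration = half)
      spec[[paste0("delay_face", f, "_h2")]] <-
        list(onset = del$onset + half, duration = half)
    } else {
      spec[[paste0("delay_face", f)]] <-
        list(onset = del$onset, duration = del$duration)
    }
  }
  disp <- events[events$condition == "search_display", ]
  err <- if ("error" %in% names(disp)) disp$error %in% TRUE else rep(FALSE, nrow(disp))
  spec$display_valid <- list(
    onset = disp$onset[disp$validity == "valid" & !err],
    duration = rep(display_dur, sum(disp$validity == "valid" & !err)))
  spec$display_invalid <- list(
    onset = disp$onset[disp$validity == "invalid" & !err],
    duration = rep(display_dur, sum(disp$validity == "invalid" & !err)))
  if (any(err))
    spec$display_error <- list(onset = disp$onset[err],
                               duration = rep(display_dur, sum(err)))
  spec
}

#' @noRd
regressors_oneback <- function(events) {
  spec <- list()
  smp <- events[events$condition == "oneback_sample", ]
  del <- events[events$condition == "oneback_delay", ]
  for (f in 1:4) {
    k <- !is.na(smp$face_id) & smp$face_id == f & !smp$is_repeat
    spec[[paste0("sample_face", f)]] <-
      list(onset = smp$onset[k], duration = smp$duration[k])
  }
  for (f in 1:4) {
    k <- !is.na(del$face_id) & del$face_id == f & !del$is_repeat
    spec[[paste0("delay_face", f)]] <-
      list(onset = del$onset[k], duration = del$duration[k])
  }
  for (s in 1:4) {
    k <- !is.na(smp$scene_category) & smp$scene_category == s & !smp$is_repeat
    spec[[paste0("sample_scene", s)]] <-
      list(onset = smp$onset[k], duration = smp$duration[k])
  }
  for (s in 1:4) {
    k <- !is.na(del$scene_category) & del$scene_category == s & !del$is_repeat
    spec[[paste0("delay_scene", s)]] <-
      list(onset = del$onset[k], duration = del$duration[k])
  }
  rep_k <- smp$is_repeat
  spec$oneback_repeat <- list(onset = smp$onset[rep_k],
                              duration = smp$duration[rep_k])
  spec
}

#' @noRd
regressors_localizer <- function(events) {
  spec <- list()
  for (cat in LOCALIZER_CATEGORIES) {
    cond <- paste0("loc_", cat)
    k <- events$condition == cond
    spec[[cond]] <- list(onset = events$onset[k], duration = events$duration[k])
  }
  spec
}

#' Number of scans implied by an event table
#'
#' @param events event table (single run or several; the maximum end time
#'   plus the table's trailing interval attribute is used).
#' @param tr repetition time, seconds.
#' @return integer scan count covering all events for one run.
#' @export
events_n_scans <- function(events, tr) {
  total <- attr(events, "run_duration")
  if (is.null(total)) total <- max(events$onset + events$duration)
  as.integer(ceiling(total / tr - 1e-9))
}
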