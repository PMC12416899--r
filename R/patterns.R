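# Beta-pattern extraction into decoding-ready sample matrices.

PATTERN_PERIODS <- c("cue", "delay", "sample_face", "sample_scene",
                     "delay_face", "delay_scene", "delay_h1", "delay_h2")

#' @noRd
period_regex <- function(period) {
  switch(period,
    cue          = "^cue_face([1-4])$",
    delay        = "^delay_face([1-4])$",
    sample_face  = "^sample_face([1-4])$",
    sample_scene = "^sample_scene([1-4])$",
    delay_face   = "^delay_face([1-4])$",
    delay_scene  = "^delay_scene([1-4])$",
    delay_h1     = "^delay_face([1-4])_h1$",
    delay_h2     = "^delay_face([1-4])_h2$",
    stopf("unknown period '%s'", period))
}

#' Construct a pattern set
#'
#' A pattern set is the unit of all decoding: a samples x voxels matrix of
#' beta estimates with a condition label (1..4), run (chunk) id and period
#' tag per sample.
#'
#' @param X samples x voxels numeric matrix.
#' @param condition integer vector in 1..4, one per sample.
#' @param run integer run ids, one per sample.
#' @param period period tag string.
#' @param roi source ROI label.
#' @param voxels optional linear voxel indices of the columns.
#' @param geometry optional [volume_geometry()].
#' @return an object of class `pattern_set`.
#' @export
pattern_set <- function(X, condition, run, period, roi = "roi",
                        voxels = NULL, geometry = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(condition) || nrow(X) != length(run))
    stopf("condition/run labels must match the number of samples")
  if (anyNA(X)) stopf("pattern set contains missing values")
  if (!all(condition %in% 1:4)) stopf("conditions must be in 1..4")
  structure(list(X = X, condition = as.integer(condition),
                 run = as.integer(run), period = period, roi = roi,
                 voxels = voxels, geometry = geometry),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: %d samples x %d voxels, roi=%s, period=%s\n",
              nrow(x$X), ncol(x$X), x$roi, x$period))
  invisible(x)
}

#' Extract ROI beta patterns for decoding
#'
#' Pulls one beta pattern per (run x condition) for the requested trial
#' period out of per-run GLM fits, restricted to the ROI's voxels. Sample
#' order is deterministic: run-major, condition-minor.
#'
#' @param beta_maps list of [fit_glm()] results, one per run.
#' @param roi_mask an `roi_mask` (or logical array) on the fits' geometry.
#' @param period one of `"cue"`, `"delay"` (search task), `"sample_face"`,
#'   `"sample_scene"`, `"delay_face"`, `"delay_scene"` (1-back), or
#'   `"delay_h1"` / `"delay_h2"` (split-delay search GLM).
#' @return a [pattern_set()].
#' @export
extract_patterns <- function(beta_maps, roi_mask, period) {
  if (inherits(beta_maps, "beta_map")) beta_maps <- list(beta_maps)
  geometry <- beta_maps[[1]]$geometry
  if (!is.null(geometry) && !is.null(attr(roi_mask, "geometry"))) {
    if (!identical(geometry$dim, attr(roi_mask, "geometry")$dim))
      stopf("beta maps and ROI mask have different geometries")
  }
  vox <- which(as.logical(roi_mask))
  if (!length(vox)) stopf("ROI mask is empty")
  rx <- period_regex(period)
  rows <- list(); cond <- integer(0); run <- integer(0)
  for (bi in seq_along(beta_maps)) {
    bm <- beta_maps[[bi]]
    nm <- rownames(bm$beta)
    hit <- grep(rx, nm, value = TRUE)
    hit <- hit[order(as.integer(sub(rx, "\\1", hit)))]
    if (!length(hit))
      stopf("no regressors matching period '%s' in run %d", period, bi)
    for (h in hit) {
      rows[[length(rows) + 1]] <- bm$beta[h, vox]
      cond <- c(cond, as.integer(sub(rx, "\\1", h)))
      run <- c(run, bi)
    }
  }
  roi_label <- attr(roi_mask, "label") %||% "roi"
  pattern_set(do.call(rbind, rows), cond, run, period, roi = roi_label,
              voxels = vox, geometry = geometry)
}
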