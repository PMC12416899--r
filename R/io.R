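# Reading and writing the standard on-disk forms: BIDS-style events TSV,
# NIfTI volumes, results tables and JSON sidecars.

#' Write an event table as BIDS-style TSV
#'
#' Columns `onset`, `duration`, `trial_type` (from `condition`) first, then
#' the attribute columns.
#'
#' @param events an `event_table`.
#' @param path output file.
#' @export
write_events_tsv <- function(events, path) {
  df <- as.data.frame(events)
  df$trial_type <- df$condition
  lead <- c("onset", "duration", "trial_type")
  df <- df[, c(lead, setdiff(names(df), c(lead, "condition")))]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "n/a")
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' @param path file written by [write_events_tsv()] (or compatible).
#' @return an `event_table`.
#' @export
read_events_tsv <- function(path) {
  df <- read.delim(path, na.strings = c("n/a", "NA"))
  if ("trial_type" %in% names(df) && !"condition" %in% names(df))
    df$condition <- df$trial_type
  df$trial_type <- NULL
  if (!"run" %in% names(df)) df$run <- 1L
  if ("validity" %in% names(df)) df$validity[is.na(df$validity)] <- "n/a"
  new_event_table(df)
}

#' Write a volume as NIfTI-1
#'
#' @param vol numeric or logical array.
#' @param geometry a [volume_geometry()] (sets the voxel dimensions).
#' @param path output `.nii` / `.nii.gz` file.
#' @export
write_volume_nifti <- function(vol, geometry, path) {
  img <- RNifti::asNifti(array(as.numeric(vol), geometry$dim))
  RNifti::pixdim(img) <- geometry$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @return list with `vol` (array) and `geometry` (a [volume_geometry()]
#'   built from the header voxel dimensions).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim(img))
  vs <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  geom <- volume_geometry(dim(vol)[1:3], vs)
  list(vol = vol, geometry = geom)
}

#' Write a motion-parameter table as TSV
#'
#' @param motion scans x 6 matrix.
#' @param path output file.
#' @export
write_motion_tsv <- function(motion, path) {
  colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
  write.table(motion, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motion-parameter table
#'
#' @param path TSV with 6 columns.
#' @return numeric matrix.
#' @export
read_motion_tsv <- function(path) {
  as.matrix(read.delim(path))
}

#' Write a ground-truth JSON sidecar
#'
#' Records the seeds, association map, noise model and per-ROI information
#' assignment of a simulated subject (not the raw pattern values).
#'
#' @param ground_truth a [make_ground_truth()] result.
#' @param path output `.json` file.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  side <- list(
    subject = ground_truth$subject,
    seed = ground_truth$seed,
    association = as.integer(ground_truth$association),
    amplitude = ground_truth$amplitude,
    noise = ground_truth$noise,
    rois = lapply(ground_truth$rois, function(r)
      list(n_voxels = length(r$voxels), information = r$schemes)))
  jsonlite::write_json(side, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' @param df data frame (decoding or behavioral results).
#' @param path output file.
#' @export
write_results_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated BOLD run as 4-D NIfTI
#'
#' @param bold_run a `bold_run` from [simulate_bold()] (or a scans x voxels
#'   matrix plus `geometry`).
#' @param path output `.nii` / `.nii.gz` file.
#' @param geometry required when a bare matrix is given.
#' @export
write_bold_nifti <- function(bold_run, path, geometry = NULL) {
  if (inherits(bold_run, "bold_run")) {
    geometry <- bold_run$geometry
    bold <- bold_run$bold
  } else bold <- bold_run
  if (is.null(geometry)) stopf("geometry required")
  vol4 <- array(t(bold), c(geometry$dim, nrow(bold)))
  img <- RNifti::asNifti(vol4)
  RNifti::pixdim(img) <- c(geometry$voxel_size, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D BOLD NIfTI into a scans x voxels matrix
#'
#' @param path NIfTI file.
#' @return list with `bold` (scans x voxels), `geometry`.
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stopf("expected a 4-D volume")
  bold <- t(matrix(as.numeric(img), prod(d[1:3]), d[4]))
  vs <- RNifti::pixdim(img)[1:3]
  list(bold = bold, geometry = volume_geometry(d[1:3], vs))
}
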