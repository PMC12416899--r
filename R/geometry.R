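# Volume geometry, ROI masks, spheres and connected components.

#' Define a volume geometry
#'
#' Grid shape plus voxel size and an affine mapping 0-based voxel indices to
#' world mm coordinates. The default affine is diagonal scaling by the voxel
#' size with the origin at voxel (0,0,0).
#'
#' @param dim integer grid shape (i, j, k).
#' @param voxel_size voxel edge lengths in mm (length 1 or 3; default 3 mm
#'   isotropic).
#' @param origin world coordinate of voxel (0,0,0), mm.
#' @return an object of class `volume_geometry`.
#' @export
volume_geometry <- function(dim, voxel_size = c(3, 3, 3), origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  if (length(dim) != 3 || any(dim < 1)) stopf("dim must be 3 positive integers")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (any(voxel_size <= 0)) stopf("voxel sizes must be > 0")
  affine <- diag(c(voxel_size, 1))
  affine[1:3, 4] <- origin
  structure(list(dim = dim, voxel_size = voxel_size, affine = affine),
            class = "volume_geometry")
}

#' @noRd
voxel_to_world <- function(idx, geometry) {
  # idx: n x 3 matrix of 0-based voxel indices
  idx <- matrix(idx, ncol = 3)
  t(geometry$affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

#' @noRd
grid_index <- function(ijk, dim) {
  # 1-based (i,j,k) -> linear index
  (ijk[, 3] - 1) * dim[1] * dim[2] + (ijk[, 2] - 1) * dim[1] + ijk[, 1]
}

#' Create a spherical ROI mask
#'
#' @param geometry a [volume_geometry()].
#' @param center_voxel 1-based voxel index (i, j, k) of the sphere center.
#' @param radius_mm sphere radius in world mm.
#' @param label ROI label string.
#' @return an object of class `roi_mask`: logical array with attributes
#'   `label`, `geometry`, `n_voxels`.
#' @export
sphere_mask <- function(geometry, center_voxel, radius_mm, label = "roi") {
  vol <- array(FALSE, geometry$dim)
  vol[sphere_offsets_linear(center_voxel, radius_mm, geometry)] <- TRUE
  roi_mask(vol, geometry, label)
}

#' Construct an ROI mask from a logical volume
#'
#' @param vol logical array matching the geometry grid.
#' @param geometry a [volume_geometry()].
#' @param label ROI label string.
#' @return an `roi_mask`.
#' @export
roi_mask <- function(vol, geometry, label = "roi") {
  vol <- array(as.logical(vol), geometry$dim)
  n <- sum(vol)
  if (n < 1) stopf("ROI '%s' is empty", label)
  structure(vol, label = label, geometry = geometry, n_voxels = n,
            class = c("roi_mask", "array"))
}

#' @noRd
sphere_offsets_linear <- function(center_voxel, radius_mm, geometry) {
  vs <- geometry$voxel_size
  rad_vox <- floor(radius_mm / vs)
  off <- expand.grid(i = -rad_vox[1]:rad_vox[1],
                     j = -rad_vox[2]:rad_vox[2],
                     k = -rad_vox[3]:rad_vox[3])
  d2 <- (off$i * vs[1])^2 + (off$j * vs[2])^2 + (off$k * vs[3])^2
  off <- off[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  ijk <- cbind(center_voxel[1] + off$i, center_voxel[2] + off$j,
               center_voxel[3] + off$k)
  keep <- ijk[, 1] >= 1 & ijk[, 1] <= geometry$dim[1] &
          ijk[, 2] >= 1 & ijk[, 2] <= geometry$dim[2] &
          ijk[, 3] >= 1 & ijk[, 3] <= geometry$dim[3]
  grid_index(ijk[keep, , drop = FALSE], geometry$dim)
}

#' Voxels within a searchlight sphere
#'
#' Returns the linear indices of all in-mask voxels whose world-coordinate
#' Euclidean distance (via the geometry affine) to the center voxel is at
#' most `radius_mm`. Spheres are truncated at the mask boundary; the center
#' itself is always included.
#'
#' @param center_voxel 1-based voxel index (i, j, k); must be inside the mask.
#' @param radius_mm radius in mm (on a 3-mm isotropic grid a 9-mm sphere deep
#'   inside the mask holds 123 voxels).
#' @param geometry a [volume_geometry()].
#' @param mask logical array (analysis mask).
#' @return sorted integer vector of linear voxel indices.
#' @export
sphere_indices <- function(center_voxel, radius_mm, geometry, mask) {
  if (radius_mm < 0) stopf("radius_mm must be >= 0")
  ctr_lin <- grid_index(matrix(center_voxel, 1), geometry$dim)
  if (!mask[ctr_lin]) stopf("center voxel is outside the mask")
  lin <- sphere_offsets_linear(center_voxel, radius_mm, geometry)
  sort(lin[mask[lin]])
}

#' Label connected components of a logical volume
#'
#' @param vol logical array.
#' @param connectivity 6 or 26 (default 26).
#' @return integer array of component labels (0 = background), with the
#'   number of components as attribute `n_components`.
#' @export
connected_components <- function(vol, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L)) stopf("connectivity must be 6 or 26")
  d <- dim(vol)
  lab <- .label_components_cpp(as.logical(vol), as.integer(d),
                               as.integer(connectivity))
  structure(array(lab, d), n_components = max(lab))
}

#' Define a functional ROI from a localizer contrast
#'
#' Mirrors functional ROI definition from localizer contrasts: threshold the
#' contrast's t map (at an uncorrected p or a raw statistic value), intersect
#' with an anatomical search region, and keep the largest contiguous
#' suprathreshold cluster (26-connectivity). If nothing survives, a more
#' lenient threshold is tried before failing.
#'
#' @param contrast_map a `contrast_map` (see [contrast()]) carrying t values
#'   and degrees of freedom, or a numeric array of t values (then supply
#'   `df`).
#' @param threshold_mode `"p_uncorrected"` (threshold is a p value converted
#'   to a t cutoff via `df`) or `"statistic"` (threshold applied to the map
#'   directly).
#' @param threshold primary threshold (default p < 0.001 uncorrected).
#' @param search_region logical array restricting the search.
#' @param lenient fallback threshold used when the primary one yields no
#'   voxels (default p < 0.01).
#' @param geometry a [volume_geometry()] (taken from the contrast map if
#'   present).
#' @param df degrees of freedom for the p-to-t conversion.
#' @param label ROI label.
#' @param connectivity cluster connectivity (default 26).
#' @return an `roi_mask` of the winning cluster.
#' @export
define_functional_roi <- function(contrast_map,
                                  threshold_mode = c("p_uncorrected", "statistic"),
                                  threshold = 0.001,
                                  search_region,
                                  lenient = 0.01,
                                  geometry = NULL, df = NULL,
                                  label = "functional_roi",
                                  connectivity = 26L) {
  threshold_mode <- match.arg(threshold_mode)
  tmap <- if (inherits(contrast_map, "contrast_map")) contrast_map$t else contrast_map
  if (is.null(geometry) && inherits(contrast_map, "contrast_map"))
    geometry <- contrast_map$geometry
  if (is.null(df) && inherits(contrast_map, "contrast_map"))
    df <- contrast_map$df
  cutoff <- function(thr) {
    if (threshold_mode == "p_uncorrected") {
      if (is.null(df)) stopf("df required to convert a p threshold to t")
      qt(1 - thr, df)
    } else thr
  }
  pick_cluster <- function(thr) {
    supra <- array(tmap >= cutoff(thr), dim(tmap)) & search_region
    if (!any(supra)) return(NULL)
    lab <- connected_components(supra, connectivity)
    sizes <- tabulate(lab[lab > 0])
    best <- which.max(sizes)
    array(lab == best, dim(tmap))
  }
  win <- pick_cluster(threshold)
  if (is.null(win)) win <- pick_cluster(lenient)
  if (is.null(win))
    stopf("no suprathreshold voxels in the search region, even at the lenient threshold")
  roi_mask(win, geometry, label)
}
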