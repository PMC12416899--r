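# Whole-brain searchlight mapping, smoothing, TFCE and cluster correction.

#' Run a searchlight cross-classification map
#'
#' For every in-mask voxel, gathers the sphere of in-mask voxels within
#' `radius_mm` (world mm), z-scores each voxel with training statistics, and
#' runs the identical pairwise train/cross-test chain used for ROI decoding,
#' assigning the mean accuracy to the center voxel. Centers whose sphere has
#' fewer than 2 voxels are skipped (NA).
#'
#' @param search_fits,oneback_fits per-run [fit_glm()] lists for one subject.
#' @param scheme scheme name or [cross_scheme()].
#' @param radius_mm sphere radius (study analysis: 9 mm).
#' @param geometry a [volume_geometry()].
#' @param mask logical analysis-mask array.
#' @param label_map a [association_map()] (scene schemes).
#' @param cost SVM cost parameter.
#' @param tol SMO tolerance.
#' @return an object of class `searchlight_map`: list with `accuracy` (array,
#'   NA outside mask), `scheme`, `radius_mm`, `geometry`, `mask`.
#' @export
run_searchlight <- function(search_fits, oneback_fits, scheme, radius_mm = 9,
                            geometry, mask, label_map = NULL, cost = 1,
                            tol = 1e-3) {
  if (radius_mm <= 0) stopf("radius_mm must be > 0")
  if (!any(mask)) stopf("empty analysis mask")
  if (is.character(scheme)) scheme <- cross_scheme(scheme)
  whole <- roi_mask(mask, geometry, label = "wholebrain")
  train <- extract_patterns(search_fits, whole, scheme$train_period)
  test <- extract_patterns(oneback_fits, whole, scheme$test_period)
  yte <- map_test_labels(test, scheme$modality, label_map)
  vox <- train$voxels
  col_of <- integer(prod(geometry$dim))
  col_of[vox] <- seq_along(vox)
  dims <- geometry$dim
  centers <- vector("list", length(vox))
  for (ci in seq_along(vox)) {
    lin <- vox[ci] - 1L
    k <- lin %/% (dims[1] * dims[2])
    j <- (lin %% (dims[1] * dims[2])) %/% dims[1]
    i <- lin %% dims[1]
    sph <- sphere_indices(c(i, j, k) + 1L, radius_mm, geometry, mask)
    centers[[ci]] <- col_of[sph]
  }
  acc <- .searchlight_cpp(train$X, as.integer(train$condition),
                          test$X, as.integer(yte),
                          centers, 4L, cost, tol)
  vol <- array(NA_real_, dims)
  vol[vox] <- acc
  structure(list(accuracy = vol, scheme = scheme$name, radius_mm = radius_mm,
                 geometry = geometry, mask = mask),
            class = "searchlight_map")
}

#' Gaussian smoothing of a statistic volume
#'
#' Separable Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis in mm, converted to voxels by the geometry. `fwhm_mm = 0` is the
#' identity. NAs are treated as 0 and the original NA positions restored.
#'
#' @param vol numeric array (or `searchlight_map`).
#' @param fwhm_mm kernel full width at half maximum, mm.
#' @param geometry a [volume_geometry()].
#' @return smoothed array (or `searchlight_map` with smoothed accuracies).
#' @export
smooth_volume <- function(vol, fwhm_mm, geometry = NULL) {
  if (inherits(vol, "searchlight_map")) {
    vol$accuracy <- smooth_volume(vol$accuracy, fwhm_mm, vol$geometry)
    return(vol)
  }
  if (fwhm_mm < 0) stopf("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  if (is.null(geometry)) stopf("geometry required")
  nas <- is.na(vol)
  v <- vol
  v[nas] <- 0
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    sig_vox <- sigma_mm / geometry$voxel_size[ax]
    r <- max(1L, ceiling(3 * sig_vox))
    kern <- exp(-((-r:r)^2) / (2 * sig_vox^2))
    kern <- kern / sum(kern)
    v <- convolve_axis(v, kern, ax)
  }
  v[nas] <- NA_real_
  v
}

# zero-padded 1-D convolution along one array axis
#' @noRd
convolve_axis <- function(v, kern, axis) {
  d <- dim(v)
  r <- (length(kern) - 1) / 2
  perm <- c(axis, setdiff(1:3, axis))
  vp <- aperm(v, perm)
  m <- matrix(vp, nrow = d[axis])
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (o in -r:r) {
    w <- kern[o + r + 1]
    src <- (1:n) + o
    ok <- src >= 1 & src <= n
    out[ok, ] <- out[ok, ] + w * m[src[ok], ]
  }
  aperm(array(out, d[perm]), order(perm))
}

#' TFCE parameters
#'
#' @param E cluster-extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh integration step; `NULL` (default) means `max(map) / n_steps`.
#' @param n_steps number of integration steps when `dh` is `NULL`
#'   (default 100).
#' @param connectivity 6 or 26 (default 26).
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, n_steps = 100L,
                        connectivity = 26L) {
  if (E < 0 || H < 0) stopf("E and H must be >= 0")
  if (!is.null(dh) && dh <= 0) stopf("dh must be > 0")
  structure(list(E = E, H = H, dh = dh, n_steps = n_steps,
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' For each voxel p, integrates `e_h(p)^E * h^H * dh` over thresholds h from
#' `dh` up to the map maximum, where `e_h(p)` is the size of the connected
#' suprathreshold component containing p. With `two_sided = TRUE` the
#' transform is applied separately to the negated map and the result is
#' signed.
#'
#' @param stat_map numeric array of statistics.
#' @param params a [tfce_params()].
#' @param mask optional logical array; voxels outside are zeroed first.
#' @param two_sided enhance negative values too (default `FALSE`).
#' @return numeric array of TFCE scores.
#' @export
tfce <- function(stat_map, params = tfce_params(), mask = NULL,
                 two_sided = FALSE) {
  v <- stat_map
  if (!is.null(mask)) v[!mask] <- 0
  if (any(!is.finite(v))) stopf("stat map must be finite")
  d <- dim(v)
  run1 <- function(x) {
    mx <- max(x)
    if (mx <= 0) return(array(0, d))
    dh <- params$dh %||% (mx / params$n_steps)
    if (dh >= mx)
      warnf("dh >= map maximum; TFCE degenerates to a single step")
    array(.tfce_pos_cpp(as.numeric(x), as.integer(d), params$E, params$H,
                        dh, params$connectivity), d)
  }
  out <- run1(v)
  if (two_sided) out <- out - run1(-v)
  out
}

#' Group TFCE-corrected p map with sign-flip permutations
#'
#' Computes the group one-sample t map of the subject maps against `center`
#' (0 for contrasts, the chance level for accuracy maps), applies TFCE, and
#' builds a max-statistic null by randomly sign-flipping the centered
#' subject maps `n_perm` times. The corrected p per voxel is
#' `(#\{max null >= observed\} + 1) / (n_perm + 1)` (one-tailed, positive).
#' Clusters of voxels with corrected p below `cluster_p` are reported when
#' larger than `min_cluster` voxels.
#'
#' @param subject_maps list of per-subject arrays (e.g., smoothed
#'   searchlight accuracy maps), or a subjects x voxels matrix with
#'   `geometry`.
#' @param mask logical analysis mask.
#' @param params a [tfce_params()].
#' @param n_perm number of sign-flip iterations.
#' @param seed integer seed.
#' @param center value subtracted from every map before testing (0.5 for
#'   accuracy maps; default 0).
#' @param cluster_p corrected-p threshold for the cluster table
#'   (study threshold: 0.005).
#' @param min_cluster minimum cluster extent; clusters must exceed this many
#'   voxels (study threshold: 50).
#' @param geometry required when `subject_maps` is a matrix.
#' @return list of class `tfce_result`: `t_map`, `tfce_map`, `p_map`
#'   (corrected), `max_null`, `clusters` (data frame: cluster, n_voxels,
#'   peak_tfce, peak_i, peak_j, peak_k, p_corrected), `params`, `n_perm`,
#'   `seed`.
#' @export
tfce_corrected_pmap <- function(subject_maps, mask, params = tfce_params(),
                                n_perm = 1000, seed = 1, center = 0,
                                cluster_p = 0.005, min_cluster = 50,
                                geometry = NULL) {
  if (is.list(subject_maps)) {
    d <- dim(subject_maps[[1]])
    S <- do.call(rbind, lapply(subject_maps, function(m) as.numeric(m)[mask]))
  } else {
    if (is.null(geometry)) stopf("geometry required for matrix input")
    d <- geometry$dim
    S <- subject_maps[, as.logical(mask), drop = FALSE]
  }
  n <- nrow(S)
  if (n < 2) stopf("need >= 2 subject maps")
  if (1 / (n_perm + 1) > cluster_p)
    warnf("n_perm = %d cannot attain p < %.4f", n_perm, cluster_p)
  S <- S - center
  S[is.na(S)] <- 0
  ss <- colSums(S^2)   # invariant under sign flips
  t_of <- function(m) {
    va <- (ss - n * m^2) / (n - 1)
    ifelse(va > 1e-24, m / sqrt(va / n), 0)
  }
  to_vol <- function(x) { v <- array(0, d); v[mask] <- x; v }
  t_obs <- t_of(colMeans(S))
  # fix the integration step from the observed map so permuted maps are
  # enhanced on the same scale
  mx <- max(c(t_obs, 0))
  prm <- params
  if (is.null(prm$dh)) prm$dh <- if (mx > 0) mx / params$n_steps else 1
  tfce_obs <- tfce(to_vol(t_obs), prm)
  set.seed(derive_seed(seed, "signflip"))
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  m_perm <- (flips %*% S) / n
  max_null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    ti <- t_of(m_perm[i, ])
    max_null[i] <- max(.tfce_pos_cpp(as.numeric(to_vol(ti)), as.integer(d),
                                     prm$E, prm$H, prm$dh, prm$connectivity))
  }
  sorted_null <- sort(max_null)
  exceed <- length(max_null) - findInterval(as.numeric(tfce_obs) - 1e-12, sorted_null)
  p_map <- array((exceed + 1) / (n_perm + 1), d)
  p_map[!mask] <- NA_real_

  supra <- array(!is.na(p_map) & p_map < cluster_p, d)
  clusters <- data.frame(cluster = integer(0), n_voxels = integer(0),
                         peak_tfce = numeric(0), peak_i = integer(0),
                         peak_j = integer(0), peak_k = integer(0),
                         p_corrected = numeric(0))
  if (any(supra)) {
    lab <- connected_components(supra, prm$connectivity)
    keep <- 0L
    for (l in seq_len(attr(lab, "n_components"))) {
      vx <- which(lab == l)
      if (length(vx) <= min_cluster) next
      keep <- keep + 1L
      pk <- vx[which.max(tfce_obs[vx])]
      ijk <- arrayInd(pk, d)
      clusters <- rbind(clusters, data.frame(
        cluster = keep, n_voxels = length(vx),
        peak_tfce = max(tfce_obs[vx]),
        peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
        p_corrected = min(p_map[vx])))
    }
  }
  structure(list(t_map = to_vol(t_obs), tfce_map = tfce_obs, p_map = p_map,
                 max_null = max_null, clusters = clusters, params = prm,
                 n_perm = n_perm, seed = seed, center = center),
            class = "tfce_result")
}
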