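# Searchlight mapping, smoothing, TFCE and cluster correction.

test_that("searchlight center equals the ROI pipeline on a matched sphere", {
  cfg <- tiny_sim_config(seed = 31)
  f <- fit_subject(cfg, 1)
  g <- cfg$geometry
  ctr <- cfg$roi_specs$FFA$center
  rad <- cfg$roi_specs$FFA$radius_mm
  mask <- array(TRUE, g$dim)
  sl <- run_searchlight(f$search, f$oneback, "cue_face", radius_mm = rad,
                        geometry = g, mask = mask,
                        label_map = cfg$association)
  roi <- sphere_mask(g, ctr, rad, "sphere")
  pr <- decoding_problem(f$search, f$oneback, roi, "cue_face",
                         cfg$association)
  ctr_lin <- which(array(seq_len(prod(g$dim)), g$dim) ==
                     ((ctr[3] - 1) * g$dim[1] * g$dim[2] +
                        (ctr[2] - 1) * g$dim[1] + ctr[1]))
  expect_equal(sl$accuracy[ctr_lin], decode_accuracy(pr))
  # accuracies live in [0, 1] inside the mask
  expect_true(all(sl$accuracy[mask] >= 0 & sl$accuracy[mask] <= 1, na.rm = TRUE))
})

test_that("zero-information searchlight maps hover at chance", {
  cfg <- tiny_sim_config(seed = 32, information = list())
  mask <- array(FALSE, cfg$geometry$dim)
  mask[2:7, 2:7, 2:5] <- TRUE
  means <- vapply(1:3, function(s) {
    f <- fit_subject(cfg, s)
    sl <- run_searchlight(f$search, f$oneback, "cue_face", radius_mm = 6,
                          geometry = cfg$geometry, mask = mask)
    mean(sl$accuracy[mask], na.rm = TRUE)
  }, numeric(1))
  # per-subject map means spread with sd ~ 0.028 (spatially correlated
  # spheres); 3 sigma of the 3-subject mean
  expect_lt(abs(mean(means) - 0.5), 0.05)
})

test_that("Gaussian smoothing preserves DC, width, and the identity at 0", {
  g <- volume_geometry(c(15, 15, 15), 3)
  vol <- array(rnorm(prod(g$dim)), g$dim)
  expect_identical(smooth_volume(vol, 0, g), vol)
  cst <- array(2.5, g$dim)
  sm <- smooth_volume(cst, 4, g)
  expect_equal(sm[4:12, 4:12, 4:12], cst[4:12, 4:12, 4:12], tolerance = 1e-9)
  # measured FWHM of the smoothed delta matches the request within a voxel
  delta <- array(0, g$dim); delta[8, 8, 8] <- 1
  sd8 <- smooth_volume(delta, 8, g)
  prof <- sd8[, 8, 8]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  fwhm_meas <- (diff(above) + 1) * 3  # mm, quantized to voxels
  expect_lt(abs(fwhm_meas - 8), 3 + 1e-9)
})

test_that("TFCE of an isolated peak approaches the h^3/3 closed form", {
  vol <- array(0, c(7, 7, 7))
  h_max <- 2.4
  vol[4, 4, 4] <- h_max
  out <- tfce(vol, tfce_params(E = 0.5, H = 2, dh = h_max / 1000))
  expect_lt(abs(out[4, 4, 4] - h_max^3 / 3) / (h_max^3 / 3), 0.01)
  expect_equal(sum(out > 0), 1)
  # all-zero map maps to all zeros
  expect_equal(max(abs(tfce(array(0, c(5, 5, 5))))), 0)
})

test_that("TFCE matches a brute-force threshold enumeration in 1-D", {
  set.seed(41)
  v <- abs(rnorm(30))
  vol <- array(v, c(30, 1, 1))
  E <- 0.5; H <- 2
  dh <- max(v) / 200
  out <- tfce(vol, tfce_params(E = E, H = H, dh = dh))
  # brute force: enumerate runs of suprathreshold voxels at each step
  brute <- numeric(30)
  for (h in seq(dh, max(v), by = dh)) {
    supra <- v >= h
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (seg in which(r$values)) {
      ext <- r$lengths[seg]
      brute[starts[seg]:ends[seg]] <-
        brute[starts[seg]:ends[seg]] + ext^E * h^H * dh
    }
  }
  expect_lt(max(abs(as.numeric(out) - brute)) / max(brute), 1e-6)
})

test_that("TFCE is monotone and scales as c^(H+1)", {
  set.seed(42)
  v <- array(abs(rnorm(6 * 6 * 6)), c(6, 6, 6))
  v2 <- v + 0.3
  p <- tfce_params(dh = max(v2) / 500)  # shared integration grid
  out <- tfce(v, p)
  # pointwise-increasing input never decreases the output
  out2 <- tfce(v2, p)
  expect_true(all(out2 >= out - 1e-9))
  # scaling: c^(H+1) with H = 2 on a proportionally scaled grid
  cc <- 1.7
  out_base <- tfce(v, tfce_params(dh = max(v) / 500))
  out_sc <- tfce(cc * v, tfce_params(dh = cc * max(v) / 500))
  expect_equal(as.numeric(out_sc), as.numeric(out_base) * cc^3,
               tolerance = 5e-3)
})

test_that("sign-flip TFCE correction calibrates and reports clusters", {
  g <- volume_geometry(c(10, 10, 4), 3)
  mask <- array(TRUE, g$dim)
  set.seed(43)
  # informative blob in subjects' maps
  maps <- lapply(1:8, function(s) {
    m <- array(rnorm(prod(g$dim), 0.5, 0.05), g$dim)
    m[3:5, 3:5, 2:3] <- m[3:5, 3:5, 2:3] + 0.2
    m
  })
  res <- tfce_corrected_pmap(maps, mask, tfce_params(), n_perm = 300,
                             seed = 1, center = 0.5, cluster_p = 0.05,
                             min_cluster = 5)
  expect_true(nrow(res$clusters) >= 1)
  expect_true(all(res$clusters$n_voxels > 5))
  blob <- which(array(FALSE, g$dim) | {
    a <- array(FALSE, g$dim); a[3:5, 3:5, 2:3] <- TRUE; a })
  expect_lt(min(res$p_map[blob]), 0.05)
  # p floors at 1/(n_perm+1) and is valid in (0, 1]
  pm <- res$p_map[mask]
  expect_true(all(pm >= 1 / 301 & pm <= 1))
  # a 10-voxel suprathreshold cluster is filtered by min_cluster = 50
  res50 <- tfce_corrected_pmap(maps, mask, tfce_params(), n_perm = 300,
                               seed = 1, center = 0.5, cluster_p = 0.05,
                               min_cluster = 50)
  expect_true(all(res50$clusters$n_voxels > 50))
  # null maps rarely produce suprathreshold voxels
  null_maps <- lapply(1:8, function(s) array(rnorm(prod(g$dim), 0.5, 0.05), g$dim))
  res0 <- tfce_corrected_pmap(null_maps, mask, tfce_params(), n_perm = 300,
                              seed = 2, center = 0.5, cluster_p = 0.05,
                              min_cluster = 0)
  expect_equal(nrow(res0$clusters), 0)
})
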