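# Geometry, spheres, functional ROI definition, pattern extraction.

test_that("a 9 mm sphere on a 3 mm grid holds 123 voxels deep in the mask", {
  g <- volume_geometry(c(15, 15, 15), 3)
  mask <- array(TRUE, g$dim)
  idx <- sphere_indices(c(8, 8, 8), 9, g, mask)
  # lattice enumeration oracle: offsets with i^2+j^2+k^2 <= (9/3)^2
  expect_equal(length(idx), 123)
  expect_equal(length(sphere_indices(c(8, 8, 8), 0, g, mask)), 1)
})

test_that("edge spheres are the brute-force in-mask subset", {
  g <- volume_geometry(c(8, 8, 8), 3)
  mask <- array(TRUE, g$dim)
  ctr <- c(2, 2, 7)
  idx <- sphere_indices(ctr, 9, g, mask)
  # brute force over every voxel
  all_ijk <- as.matrix(expand.grid(i = 1:8, j = 1:8, k = 1:8))
  d <- sqrt(colSums((t(all_ijk) - ctr)^2)) * 3
  brute <- sort(((all_ijk[, 3] - 1) * 64 + (all_ijk[, 2] - 1) * 8 +
                   all_ijk[, 1])[d <= 9 + 1e-9])
  expect_equal(idx, brute)
  expect_lt(length(idx), 123)
  expect_error(sphere_indices(c(1, 1, 1), 5, g, array(FALSE, g$dim)),
               "outside the mask")
})

test_that("sphere offsets are symmetric under axis permutation and sign flips", {
  g <- volume_geometry(c(15, 15, 15), 3)
  mask <- array(TRUE, g$dim)
  ctr <- c(8, 8, 8)
  idx <- sphere_indices(ctr, 7.5, g, mask)
  ijk <- arrayInd(idx, g$dim)
  off <- sweep(ijk, 2, ctr)
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_equal(key(off), key(-off))
  expect_equal(key(off), key(off[, c(2, 3, 1)]))
})

test_that("pattern extraction is counted, ordered, and lossless", {
  cfg <- tiny_sim_config(seed = 21)
  f <- fit_subject(cfg, 1)
  masks <- sim_roi_masks(cfg)
  ps <- extract_patterns(f$search, masks$FFA, "cue")
  # 8 runs x 4 faces
  expect_equal(nrow(ps$X), 32)
  expect_equal(ps$run, rep(1:8, each = 4))
  expect_equal(ps$condition, rep(1:4, 8))
  expect_equal(ncol(ps$X), attr(masks$FFA, "n_voxels"))
  # lossless: reassembling into the volume reproduces the masked betas
  vol <- array(NA_real_, cfg$geometry$dim)
  vol[ps$voxels] <- ps$X[5, ]
  expect_identical(vol[ps$voxels],
                   unname(f$search[[2]]$beta["cue_face1", which(masks$FFA)]))
  # single-voxel mask
  one <- array(FALSE, cfg$geometry$dim)
  one[which(masks$FFA)[1]] <- TRUE
  p1 <- extract_patterns(f$search, roi_mask(one, cfg$geometry, "one"), "cue")
  expect_equal(ncol(p1$X), 1)
  expect_equal(drop(p1$X), ps$X[, 1])
  # one-back periods give 4 runs x 4 conditions
  po <- extract_patterns(f$oneback, masks$PPA, "delay_scene")
  expect_equal(nrow(po$X), 16)
})

test_that("voxel order within the mask does not change decoding accuracy", {
  cfg <- tiny_sim_config(seed = 22)
  f <- fit_subject(cfg, 1)
  masks <- sim_roi_masks(cfg)
  pr <- decoding_problem(f$search, f$oneback, masks$FFA, "cue_face",
                         cfg$association)
  perm <- sample(ncol(pr$Xtr))
  pr2 <- pr
  pr2$Xtr <- pr$Xtr[, perm]
  pr2$Xte <- pr$Xte[, perm]
  expect_equal(decode_accuracy(pr), decode_accuracy(pr2))
})

test_that("connected components match a brute-force flood fill", {
  set.seed(9)
  vol <- array(runif(6 * 6 * 6) > 0.6, c(6, 6, 6))
  lab <- connected_components(vol, 26)
  # brute force: repeated neighborhood expansion
  idx <- which(vol)
  ijk <- arrayInd(idx, dim(vol))
  adj <- matrix(FALSE, length(idx), length(idx))
  for (a in seq_along(idx)) for (b in seq_along(idx))
    adj[a, b] <- all(abs(ijk[a, ] - ijk[b, ]) <= 1)
  groups <- seq_along(idx)
  repeat {
    new <- groups
    for (a in seq_along(idx)) new[a] <- min(groups[adj[a, ]])
    if (identical(new, groups)) break
    groups <- new
  }
  # same partition (labels may differ)
  expect_equal(length(unique(groups)), attr(lab, "n_components"))
  expect_equal(unname(split(idx, groups)[order(sapply(split(idx, groups), min))]),
               unname(split(idx, lab[idx])[order(sapply(split(idx, lab[idx]), min))]))
})

test_that("functional ROI definition picks the largest cluster and falls back", {
  g <- volume_geometry(c(12, 12, 6), 3)
  tmap <- array(0, g$dim)
  # two disjoint clusters: one of 40 voxels, one of 15
  big <- as.matrix(expand.grid(2:6, 2:5, 2:3))
  small <- as.matrix(expand.grid(9:11, 9:11, 4:5))[1:15, ]
  tmap[big] <- 6
  tmap[small] <- 6
  search <- array(TRUE, g$dim)
  roi <- define_functional_roi(tmap, "statistic", 5, search,
                               geometry = g, label = "FFA")
  expect_equal(attr(roi, "n_voxels"), 40)
  expect_true(all(roi[big]))
  # threshold above the global max triggers the lenient fallback
  roi2 <- define_functional_roi(tmap, "statistic", 100, search,
                                lenient = 5, geometry = g)
  expect_equal(attr(roi2, "n_voxels"), 40)
  expect_error(define_functional_roi(tmap, "statistic", 100, search,
                                     lenient = 50, geometry = g),
               "no suprathreshold")
})

test_that("a simulated localizer recovers the face-selective blob", {
  cfg <- tiny_sim_config(seed = 23, localizer_boost = 3)
  sub <- simulate_subject(cfg, 1, localizer = TRUE)
  fits <- lapply(sub$localizer, function(r) fit_glm(r, r$design))
  # single-run contrast for a parametric t with ample residual df
  cm <- contrast(fits[[1]], c(loc_faces = 1, loc_houses = -0.2,
                              loc_corridors = -0.2, loc_cars = -0.2,
                              loc_instruments = -0.2, loc_scrambled = -0.2))
  roi <- define_functional_roi(cm, "p_uncorrected", threshold = 0.001,
                               search_region = array(TRUE, cfg$geometry$dim),
                               label = "FFA")
  truth <- sim_roi_masks(cfg)$FFA
  ctr_est <- colMeans(arrayInd(which(roi), cfg$geometry$dim))
  ctr_true <- colMeans(arrayInd(which(truth), cfg$geometry$dim))
  expect_lt(sqrt(sum((ctr_est - ctr_true)^2)), 1)
})
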