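# Normalization, pairwise SVM training, cross-classification.

test_that("normalization centers and scales with train statistics only", {
  ps <- toy_patterns(seed = 2)
  nrm <- normalize_patterns(ps, ps)
  expect_lt(max(abs(colMeans(nrm$train$X))), 1e-10)
  expect_equal(unname(apply(nrm$train$X, 2, sd)), rep(1, ncol(ps$X)))
  # constant voxel maps to 0 without a division error
  ps2 <- ps
  ps2$X[, 3] <- 5
  nrm2 <- normalize_patterns(ps2, ps2)
  expect_equal(unname(nrm2$train$X[, 3]), rep(0, nrow(ps$X)))
  # independent oracle re-implementation of the transform on fresh test data
  te <- toy_patterns(seed = 3)
  nrm3 <- normalize_patterns(ps, te)
  oracle <- scale(te$X, center = colMeans(ps$X), scale = apply(ps$X, 2, sd))
  expect_equal(nrm3$test$X, oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("normalization never uses test samples (no-leakage guard)", {
  tr <- toy_patterns(seed = 4)
  te1 <- toy_patterns(seed = 5)
  te2 <- te1
  te2$X <- te1$X + 100  # radically different test data
  a <- normalize_patterns(tr, te1)
  b <- normalize_patterns(tr, te2)
  # the transform must be identical regardless of the test set ...
  expect_equal(attr(a$test$X, "center"), attr(b$test$X, "center"))
  expect_equal(a$train$X, b$train$X)
  # ... and a leaky implementation (stats from train+test) would differ
  leaky_center <- colMeans(rbind(tr$X, te2$X))
  expect_gt(max(abs(leaky_center - attr(b$test$X, "center"))), 1)
})

test_that("pairwise bank has C(k,2) members trained per pair", {
  ps <- toy_patterns(n_cond = 4, seed = 6)
  bank <- train_pairwise(ps)
  expect_length(bank$models, 6)
  expect_equal(t(sapply(bank$models, `[[`, "pair")),
               t(combn(1:4, 2)), ignore_attr = TRUE)
  ps2 <- toy_patterns(n_cond = 2, seed = 6)
  expect_length(train_pairwise(ps2)$models, 1)
  bad <- pattern_set(matrix(rnorm(10), 5), c(1, 1, 2, 2, 3),
                     c(1, 2, 1, 2, 1), "cue")
  expect_error(train_pairwise(bad), "fewer than 2")
})

test_that("the separable toy problem reproduces the maximum-margin separator", {
  # 4 points in 2 voxels: class means (+1, 0) vs (-1, 0), no noise;
  # the max-margin boundary is the voxel-1 axis with w = (1, 0) after
  # accounting for the z-scoring (voxel 2 is constant -> dropped to 0)
  X <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  ps <- pattern_set(X, c(1, 1, 2, 2), c(1, 2, 1, 2), "cue")
  bank <- train_pairwise(ps, normalize = FALSE)
  m <- bank$models[[1]]
  # brute-force margin oracle on the 4 points: w* = (1, 0), b* = 0
  expect_equal(m$w[1], 1, tolerance = 1e-3)
  expect_equal(m$w[2], 0, tolerance = 1e-6)
  expect_equal(m$rho, 0, tolerance = 1e-6)
  res <- cross_classify("cue_face", bank, ps)
  expect_equal(res$accuracy, 1)
})

test_that("own SMO solution matches LIBSVM (e1071) on random problems", {
  skip_if_not_installed("e1071")
  set.seed(10)
  for (r in 1:10) {
    X <- matrix(rnorm(16 * 12), 16, 12)
    y <- sample(rep(c(1L, -1L), each = 8))
    fit <- crossdecode:::.svc_train_cpp(X, y, 1, 1e-5)
    ref <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                      cost = 1, scale = FALSE)
    sgn <- if (y[1] == 1) 1 else -1  # libsvm codes the first-seen label +1
    expect_lt(max(abs(fit$w - sgn * drop(t(ref$coefs) %*% ref$SV))), 5e-3)
    expect_lt(abs(fit$rho - sgn * ref$rho), 5e-3)
  }
})

test_that("cross-classification scores schemes and maps scene labels", {
  expect_error(cross_scheme("nope"), "cue_face")
  # self-test on separable data is perfect
  ps <- toy_patterns(sep = 3, noise = 0.1, seed = 7)
  bank <- train_pairwise(ps)
  res <- cross_classify("cue_face", bank, ps)
  expect_equal(res$accuracy, 1)
  expect_equal(res$accuracy, mean(res$pair_accuracy))
  # shuffled labels converge to chance
  set.seed(8)
  accs <- replicate(50, {
    te <- ps
    te$condition <- sample(te$condition)
    cross_classify("cue_face", bank, te)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.06)
  # scene scheme requires a label map and respects the association
  assoc <- association_map(c(2, 1, 4, 3))
  te_scene <- ps
  te_scene$condition <- as.integer(assoc[ps$condition])  # scenes of each face
  te_scene$period <- "delay_scene"
  expect_error(cross_classify("delay_scene", bank, te_scene), "label_map")
  res2 <- cross_classify("delay_scene", bank, te_scene, label_map = assoc)
  expect_equal(res2$accuracy, 1)
})

test_that("relabeling conditions by a permutation leaves accuracy unchanged", {
  tr <- toy_patterns(seed = 11, noise = 1.5)
  te <- toy_patterns(seed = 12, noise = 1.5)
  base <- cross_classify("cue_face", train_pairwise(tr), te)$accuracy
  perm <- c(3, 1, 4, 2)
  tr2 <- tr; te2 <- te
  tr2$condition <- perm[tr$condition]
  te2$condition <- perm[te$condition]
  permuted <- cross_classify("cue_face", train_pairwise(tr2), te2)$accuracy
  expect_equal(base, permuted)
})

test_that("R bank path and C++ fast path give identical accuracies", {
  cfg <- tiny_sim_config(seed = 24)
  f <- fit_subject(cfg, 1)
  masks <- sim_roi_masks(cfg)
  for (scheme in c("cue_face", "delay_scene")) {
    pr <- decoding_problem(f$search, f$oneback, masks$PPA, scheme,
                           cfg$association)
    sc <- cross_scheme(scheme)
    train <- extract_patterns(f$search, masks$PPA, sc$train_period)
    test <- extract_patterns(f$oneback, masks$PPA, sc$test_period)
    bank <- train_pairwise(train)
    r_path <- cross_classify(scheme, bank, test, cfg$association)$accuracy
    expect_equal(decode_accuracy(pr), r_path, tolerance = 1e-10)
  }
})

test_that("the constructed double dissociation is decoded as designed", {
  cfg <- tiny_sim_config(amplitude = 2, seed = 25)
  f <- fit_subject(cfg, 1)
  masks <- sim_roi_masks(cfg)
  acc <- function(roi, scheme)
    decode_accuracy(decoding_problem(f$search, f$oneback, masks[[roi]],
                                     scheme, cfg$association))
  expect_gt(acc("FFA", "cue_face"), 0.9)
  expect_gt(acc("PPA", "delay_scene"), 0.9)
  expect_lt(abs(acc("PPA", "delay_face") - 0.5), 0.25)
  expect_lt(abs(acc("CTRL", "cue_face") - 0.5), 0.25)
})

test_that("zero-information accuracy sits at chance over many simulations", {
  # property: with amplitude 0, mean accuracy over seeded toy simulations
  # lies in [0.47, 0.53]
  set.seed(13)
  accs <- replicate(100, {
    tr <- pattern_set(matrix(rnorm(16 * 10), 16, 10), rep(1:4, 4),
                      rep(1:4, each = 4), "cue")
    te <- pattern_set(matrix(rnorm(16 * 10), 16, 10), rep(1:4, 4),
                      rep(1:2, each = 8), "sample_face")
    cross_classify("cue_face", train_pairwise(tr), te)$accuracy
  })
  expect_gt(mean(accs), 0.47)
  expect_lt(mean(accs), 0.53)
})
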