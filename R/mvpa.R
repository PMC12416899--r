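# Cross-task pairwise SVM decoding.

#' The four cross-classification schemes
#'
#' Classifiers are always trained on search-task patterns and tested on
#' 1-back patterns: `cue_face` (train on search-cue betas, test on 1-back
#' face samples), `cue_scene` (search cue -> 1-back scene samples),
#' `delay_face` (search delay -> 1-back face delays) and `delay_scene`
#' (search delay -> 1-back scene delays). For the scene schemes each test
#' sample's scene category is mapped to the face id it is associated with,
#' since the training classes are keyed by the cued face.
#'
#' @format `CROSS_SCHEMES` is a character vector of the four scheme names.
#' @export
CROSS_SCHEMES <- c("cue_face", "cue_scene", "delay_face", "delay_scene")

#' Scheme descriptor
#'
#' @param name one of `CROSS_SCHEMES`.
#' @return list with `name`, `train_period`, `test_period`, `modality`.
#' @export
cross_scheme <- function(name) {
  if (!name %in% CROSS_SCHEMES)
    stopf("unknown scheme '%s'; valid schemes: %s", name,
          paste(CROSS_SCHEMES, collapse = ", "))
  switch(name,
    cue_face   = list(name = name, train_period = "cue",
                      test_period = "sample_face", modality = "face"),
    cue_scene  = list(name = name, train_period = "cue",
                      test_period = "sample_scene", modality = "scene"),
    delay_face = list(name = name, train_period = "delay",
                      test_period = "delay_face", modality = "face"),
    delay_scene = list(name = name, train_period = "delay",
                       test_period = "delay_scene", modality = "scene"))
}

#' Normalize train and test patterns with training statistics
#'
#' Per-voxel z-scoring: each voxel is centered and scaled using the mean and
#' standard deviation estimated from the TRAINING samples only, and the same
#' transform is applied to the test set (no test-set leakage). Zero-variance
#' voxels map to 0. This removes univariate (mean activation) differences
#' between conditions before classification.
#'
#' @param train,test [pattern_set()]s sharing a voxel count.
#' @return list with transformed `train` and `test` pattern sets; the
#'   transform is recorded in attributes `center` and `scale` of each `X`.
#' @export
normalize_patterns <- function(train, test) {
  if (ncol(train$X) != ncol(test$X))
    stopf("train and test have different voxel counts (%d vs %d)",
          ncol(train$X), ncol(test$X))
  mu <- colMeans(train$X)
  sdev <- apply(train$X, 2, sd)
  zap <- function(M) {
    Z <- sweep(M, 2, mu)
    Z <- sweep(Z, 2, ifelse(sdev > 0, sdev, 1), "/")
    Z[, sdev == 0] <- 0
    attr(Z, "center") <- mu
    attr(Z, "scale") <- sdev
    Z
  }
  train$X <- zap(train$X)
  test$X <- zap(test$X)
  list(train = train, test = test)
}

#' Train the six pairwise linear SVM classifiers
#'
#' One soft-margin linear SVM (C-SVC, default cost 1) per unordered pair of
#' the four conditions, each trained only on that pair's samples. Patterns
#' are z-scored with training statistics first (unless `normalize = FALSE`);
#' the transform is stored in the bank and re-applied to test data by
#' [cross_classify()].
#'
#' @param train a [pattern_set()] with >= 2 samples per condition.
#' @param cost SVM misclassification cost parameter C (default 1).
#' @param normalize apply per-voxel z-scoring (default `TRUE`).
#' @param tol SMO convergence tolerance (default 1e-3, the LIBSVM convention).
#' @return an object of class `pairwise_bank`: list of 6 classifiers (fields
#'   `pair`, `w`, `rho`), plus the normalization statistics and condition
#'   set.
#' @export
train_pairwise <- function(train, cost = 1, normalize = TRUE, tol = 1e-3) {
  if (cost <= 0) stopf("cost must be > 0")
  conds <- sort(unique(train$condition))
  tab <- table(train$condition)
  if (any(tab < 2))
    stopf("conditions with fewer than 2 training samples: %s",
          paste(names(tab)[tab < 2], collapse = ", "))
  X <- train$X
  if (normalize) {
    mu <- colMeans(X)
    sdev <- apply(X, 2, sd)
    X <- sweep(sweep(X, 2, mu), 2, ifelse(sdev > 0, sdev, 1), "/")
    X[, sdev == 0] <- 0
  } else {
    mu <- rep(0, ncol(X)); sdev <- rep(1, ncol(X))
  }
  pairs <- combn(conds, 2)
  models <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    k <- train$condition %in% c(a, b)
    y <- ifelse(train$condition[k] == a, 1L, -1L)
    fit <- .svc_train_cpp(X[k, , drop = FALSE], y, cost, tol)
    models[[p]] <- list(pair = c(a, b), w = fit$w, rho = fit$rho)
  }
  structure(list(models = models, conditions = conds, cost = cost,
                 center = mu, scale = sdev, normalized = normalize,
                 period = train$period, roi = train$roi),
            class = "pairwise_bank")
}

#' @export
print.pairwise_bank <- function(x, ...) {
  cat(sprintf("pairwise_bank: %d linear SVMs (C=%g) over conditions {%s}\n",
              length(x$models), x$cost, paste(x$conditions, collapse = ",")))
  invisible(x)
}

#' @noRd
map_test_labels <- function(test, modality, label_map) {
  if (modality == "face") return(test$condition)
  if (is.null(label_map))
    stopf("scene schemes require a label_map (face-scene association)")
  inv <- attr(label_map, "face_for_scene")
  y <- inv[test$condition]
  if (anyNA(y)) stopf("unmapped scene category in test labels")
  as.integer(y)
}

#' Cross-task classification accuracy
#'
#' Applies a trained pairwise bank to test patterns from the other task.
#' Test patterns are transformed with the bank's stored training statistics.
#' For face schemes the test labels are face ids; for scene schemes each
#' scene sample is relabeled with the face id associated with its category
#' (via `label_map`) before scoring, because the classifiers were trained on
#' face-keyed search-task classes. Accuracy is the mean of the six pairwise
#' accuracies; boundary ties (decision value exactly 0) go to the smaller
#' condition id.
#'
#' @param scheme scheme name or [cross_scheme()] object.
#' @param bank a [train_pairwise()] bank.
#' @param test a [pattern_set()] (raw; the bank's transform is applied).
#' @param label_map a [association_map()] (required for scene schemes).
#' @return an object of class `accuracy_result`: list with `scheme`, `roi`,
#'   `accuracy` (mean of pairs), `pair_accuracy` (6 values, names "a|b"),
#'   `n_test`.
#' @export
cross_classify <- function(scheme, bank, test, label_map = NULL) {
  if (is.character(scheme)) scheme <- cross_scheme(scheme)
  if (nrow(test$X) == 0) stopf("empty test set")
  if (ncol(test$X) != length(bank$center))
    stopf("test voxel count does not match the bank")
  y <- map_test_labels(test, scheme$modality, label_map)
  Z <- sweep(sweep(test$X, 2, bank$center), 2,
             ifelse(bank$scale > 0, bank$scale, 1), "/")
  Z[, bank$scale == 0] <- 0
  pair_acc <- numeric(length(bank$models))
  pair_names <- character(length(bank$models))
  for (p in seq_along(bank$models)) {
    m <- bank$models[[p]]
    a <- m$pair[1]; b <- m$pair[2]
    k <- y %in% c(a, b)
    pair_names[p] <- paste0(a, "|", b)
    if (!any(k)) { pair_acc[p] <- NA_real_; next }
    f <- drop(Z[k, , drop = FALSE] %*% m$w) - m$rho
    pred <- ifelse(f >= 0, a, b)
    pair_acc[p] <- mean(pred == y[k])
  }
  structure(list(scheme = scheme$name, roi = bank$roi,
                 accuracy = mean(pair_acc, na.rm = TRUE),
                 pair_accuracy = setNames(pair_acc, pair_names),
                 n_test = length(y)),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("accuracy_result: %s in %s: %.3f (pairs: %s)\n",
              x$scheme, x$roi, x$accuracy,
              paste(sprintf("%.2f", x$pair_accuracy), collapse = " ")))
  invisible(x)
}

#' Assemble a per-subject decoding problem
#'
#' Convenience bundling of the normalize/train/test inputs for one subject,
#' ROI and scheme: extracts train (search) and test (1-back) patterns, maps
#' scene test labels to associated face ids, and z-scores both sets with
#' training statistics. This is the unit consumed by [decode_accuracy()],
#' [permutation_null()] and the searchlight engine.
#'
#' @param search_fits,oneback_fits lists of per-run [fit_glm()] results.
#' @param roi_mask ROI mask.
#' @param scheme scheme name or [cross_scheme()].
#' @param label_map a [association_map()].
#' @return list with normalized `Xtr`, `ytr`, `run`, `Xte`, `yte`.
#' @export
decoding_problem <- function(search_fits, oneback_fits, roi_mask, scheme,
                             label_map = NULL) {
  if (is.character(scheme)) scheme <- cross_scheme(scheme)
  train <- extract_patterns(search_fits, roi_mask, scheme$train_period)
  test <- extract_patterns(oneback_fits, roi_mask, scheme$test_period)
  yte <- map_test_labels(test, scheme$modality, label_map)
  nrm <- normalize_patterns(train, test)
  list(Xtr = nrm$train$X, ytr = train$condition, run = train$run,
       Xte = nrm$test$X, yte = yte, scheme = scheme$name,
       roi = train$roi)
}

#' Observed cross-classification accuracy of a decoding problem
#'
#' @param problem a [decoding_problem()].
#' @param cost SVM cost parameter.
#' @param tol SMO tolerance.
#' @return mean accuracy over the six pairwise classifiers.
#' @export
decode_accuracy <- function(problem, cost = 1, tol = 1e-3) {
  acc <- .pairwise_accuracy_cpp(problem$Xtr, as.integer(problem$ytr),
                                problem$Xte, as.integer(problem$yte),
                                4L, cost, tol)
  mean(acc, na.rm = TRUE)
}
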