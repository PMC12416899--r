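# HRF, design matrices, OLS estimation, contrasts.

test_that("canonical HRF peaks near 5 s and has a finite tail", {
  h <- canonical_hrf(1.5)
  # dense double-gamma oracle (delays 6/16, dispersions 1/1, ratio 6)
  # evaluated at 1e-4 s resolution places the peak at 4.9985 s
  expect_lt(abs(h$time[which.max(h$values)] - 4.9985), h$dt)
  expect_equal(max(h$values), 1)
  expect_true(all(abs(h$values[h$time >= 31]) < 1e-3))
  # refinement stability: doubling the oversampling moves the peak by at
  # most one fine-grid step
  h2 <- canonical_hrf(1.5, oversampling = 32)
  expect_lt(abs(h2$time[which.max(h2$values)] - h$time[which.max(h$values)]),
            h$dt + 1e-9)
})

test_that("design matrices have the study regressor counts", {
  ev <- make_search_design(1, 16, 0.75, seed = 2)
  m <- matrix(0, 192, 6)
  X <- build_design_matrix(ev, 192, 1.5, motion = m, scheme = "search")
  # 10 task columns without error trials; 11 with them
  expect_equal(attr(X, "n_task"), 10)
  ev$error <- ev$condition == "search_display" & ev$trial == 3
  X11 <- build_design_matrix(ev, 192, 1.5, motion = m, scheme = "search")
  expect_equal(attr(X11, "n_task"), 11)
  expect_true("display_error" %in% colnames(X11))
  expect_equal(attr(X11, "n_nuisance"), 6)
  expect_equal(ncol(X11), 11 + 6 + 1)

  ob <- make_oneback_design(1, seed = 2)
  nob <- events_n_scans(ob, 1.5)
  Xo <- build_design_matrix(ob, nob, 1.5, motion = matrix(0, nob, 6),
                            scheme = "oneback")
  expect_equal(attr(Xo, "n_task"), 17)

  # error display carries over into the split-delay scheme too
  Xs <- build_design_matrix(ev, 192, 1.5, motion = m,
                            scheme = "search_delay_split")
  expect_equal(attr(Xs, "n_task"), 4 + 8 + 3)
  expect_true(all(c("delay_face1_h1", "delay_face1_h2") %in% colnames(Xs)))

  loc <- make_localizer_design(1, seed = 2)
  nl <- events_n_scans(loc, 1.5)
  Xl <- build_design_matrix(loc, nl, 1.5, motion = matrix(0, nl, 6),
                            scheme = "localizer")
  expect_equal(attr(Xl, "n_task"), 6)
})

test_that("design construction guards its inputs", {
  ev <- make_search_design(1, 16, 0.75, seed = 2)
  expect_error(build_design_matrix(ev, 50, 1.5, motion = matrix(0, 50, 6),
                                   scheme = "search"), "overrun")
  expect_warning(build_design_matrix(ev, 192, 1.5, scheme = "search"),
                 "motion")
})

test_that("delaying events by k TRs shifts regressors by k rows", {
  ev <- make_search_design(1, 16, 0.75, seed = 6)
  k <- 4
  ev2 <- ev
  ev2$onset <- ev2$onset + k * 1.5
  attr(ev2, "run_duration") <- attr(ev, "run_duration") + k * 1.5
  m1 <- matrix(0, 200, 6)
  X1 <- build_design_matrix(ev, 200, 1.5, motion = m1, scheme = "search")
  X2 <- build_design_matrix(ev2, 200, 1.5, motion = m1, scheme = "search")
  nt <- attr(X1, "n_task")
  expect_equal(unclass(X2)[(k + 1):200, 1:nt], unclass(X1)[1:(200 - k), 1:nt],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("OLS betas equal the normal-equation oracle and recover truth", {
  cfg <- tiny_sim_config(noise_sd = 0)
  sub <- simulate_subject(cfg, 1)
  r <- sub$search[[1]]
  fit <- fit_glm(r, r$design)
  # noiseless forward model inverts exactly
  expect_lt(max(abs(fit$beta - r$true_beta)) /
              max(abs(r$true_beta)), 1e-6)
  # independent normal-equation oracle on noisy data
  cfgn <- tiny_sim_config(seed = 33)
  rn <- simulate_subject(cfgn, 1)$search[[1]]
  fitn <- fit_glm(rn, rn$design)
  X <- unclass(rn$design)
  oracle <- solve(t(X) %*% X) %*% t(X) %*% rn$bold
  expect_lt(max(abs(fitn$beta - oracle)), 1e-8)
  # residuals orthogonal to the design
  resid <- rn$bold - X %*% fitn$beta
  expect_lt(max(abs(t(X) %*% resid)) / max(abs(rn$bold)), 1e-6)
  expect_equal(fitn$df, nrow(X) - ncol(X))
})

test_that("GLM estimation is linear in the data", {
  cfg <- tiny_sim_config(seed = 44)
  r1 <- simulate_subject(cfg, 1)$search[[1]]
  r2 <- simulate_subject(tiny_sim_config(seed = 45), 1)$search[[1]]
  X <- r1$design
  fa <- fit_glm(2 * r1$bold + 3 * r2$bold, X)
  f1 <- fit_glm(r1$bold, X)
  f2 <- fit_glm(r2$bold, X)
  expect_equal(fa$beta, 2 * f1$beta + 3 * f2$beta, tolerance = 1e-9)
})

test_that("constant bold yields zero task betas and the constant value", {
  ev <- make_search_design(1, 16, 0.75, seed = 2)
  X <- suppressWarnings(build_design_matrix(ev, 192, 1.5, scheme = "search"))
  Y <- matrix(7, 192, 3)
  fit <- fit_glm(Y, X)
  expect_equal(max(abs(fit$beta[1:attr(X, "n_task"), ])), 0, tolerance = 1e-9)
  expect_equal(unname(fit$beta["constant", ]), rep(7, 3), tolerance = 1e-9)
})

test_that("rank-deficient designs fail with the offending column named", {
  ev <- make_search_design(1, 16, 0.75, seed = 2)
  X <- suppressWarnings(build_design_matrix(ev, 192, 1.5, scheme = "search"))
  Xd <- cbind(unclass(X), dup = unclass(X)[, 1])
  expect_error(fit_glm(matrix(0, 192, 2), Xd), "rank deficient")
})

test_that("contrasts are linear and recover a constructed validity effect", {
  cfg <- tiny_sim_config(validity_effect = list(rois = "PPA", delta = 2),
                         seed = 55)
  sub <- simulate_subject(cfg, 1)
  fits <- lapply(sub$search, function(r) fit_glm(r, r$design))
  cw <- c(display_invalid = 1, display_valid = -1)
  cm <- contrast(fits, cw)
  masks <- sim_roi_masks(cfg)
  # ROI-mean contrast approximates the injected amplitude difference
  expect_lt(abs(mean(cm$values[masks$PPA]) - 2), 0.4)
  expect_lt(abs(mean(cm$values[masks$CTRL])), 0.4)
  # zero weights give a zero map; flipping weights flips the sign
  cz <- contrast(fits, c(display_invalid = 0))
  expect_equal(max(abs(cz$values)), 0)
  cf <- contrast(fits, -cw)
  expect_equal(cf$values, -cm$values, tolerance = 1e-12)
})

test_that("AR(1) prewhitening still recovers noiseless betas", {
  cfg <- tiny_sim_config(noise_sd = 0)
  r <- simulate_subject(cfg, 1)$search[[1]]
  fit <- fit_glm(r, r$design, ar1 = 0.3)
  expect_lt(max(abs(fit$beta - r$true_beta)) / max(abs(r$true_beta)), 1e-6)
})
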