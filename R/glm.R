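# Voxelwise GLM estimation and contrasts.

#' Fit a voxelwise GLM to one run by ordinary least squares
#'
#' Estimates per-voxel regression coefficients for every design column by
#' OLS (no prewhitening; an optional AR(1) prewhitening step is available
#' for data with serially correlated noise). Errors out on rank-deficient
#' designs, naming the collinear columns.
#'
#' @param bold scans x voxels numeric matrix (a `bold_run$bold`), or a
#'   `bold_run` object from [simulate_bold()].
#' @param design a [build_design_matrix()] result with the same number of
#'   rows.
#' @param ar1 optional AR(1) coefficient; when non-zero both sides of the
#'   model are prewhitened with it before OLS.
#' @return an object of class `beta_map`: list with `beta` (regressors x
#'   voxels, rownames = design columns), `sigma2` (residual variance per
#'   voxel), `df` (scans - rank), `design` and, when the input was a
#'   `bold_run`, its `geometry`.
#' @export
fit_glm <- function(bold, design, ar1 = 0) {
  geometry <- NULL
  if (inherits(bold, "bold_run")) {
    geometry <- bold$geometry
    bold <- bold$bold
  }
  Y <- as.matrix(bold)
  X <- unclass(design)
  if (nrow(Y) != nrow(X))
    stopf("bold has %d scans but design has %d rows", nrow(Y), nrow(X))
  if (ar1 != 0) {
    W <- function(M) rbind(M[1, , drop = FALSE] * sqrt(1 - ar1^2),
                           M[-1, , drop = FALSE] - ar1 * M[-nrow(M), , drop = FALSE])
    Y <- W(Y); X <- W(X)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear columns: %s",
          paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrx, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - qrx$rank
  sigma2 <- colSums(resid^2) / max(df, 1)
  structure(list(beta = beta, sigma2 = sigma2, df = df,
                 design = design, geometry = geometry),
            class = "beta_map")
}

#' Voxelwise linear contrast of task betas
#'
#' Computes a weighted sum of task-regressor betas per voxel and the
#' corresponding t statistic. For the scene-validity effect of the search
#' display, use weights +1 on `display_invalid` and -1 on `display_valid`.
#'
#' @param beta_map a [fit_glm()] result, or a list of them (runs); with
#'   several runs the contrast values are averaged and the t statistic is
#'   computed from the per-run contrast estimates.
#' @param weights named numeric vector of weights over design columns
#'   (unnamed columns get 0), or an unnamed vector conformable with the task
#'   regressors.
#' @return an object of class `contrast_map`: list with `values` (voxel
#'   vector or array), `t`, `df`, `weights`, `weight_sum`, `geometry`.
#' @export
contrast <- function(beta_map, weights) {
  runs <- if (inherits(beta_map, "beta_map")) list(beta_map) else beta_map
  b1 <- runs[[1]]
  n_task <- attr(b1$design, "n_task")
  full_w <- function(bm) {
    cols <- rownames(bm$beta)
    w <- numeric(length(cols))
    if (!is.null(names(weights))) {
      unknown <- setdiff(names(weights), cols)
      if (length(unknown))
        stopf("unknown contrast columns: %s", paste(unknown, collapse = ", "))
      w[match(names(weights), cols)] <- weights
    } else {
      if (length(weights) != n_task)
        stopf("contrast has %d weights but the design has %d task regressors",
              length(weights), n_task)
      w[seq_len(n_task)] <- weights
    }
    w
  }
  per_run <- lapply(runs, function(bm) drop(crossprod(bm$beta, full_w(bm))))
  vals <- Reduce(`+`, per_run) / length(per_run)
  if (length(per_run) > 1) {
    M <- do.call(rbind, per_run)
    n <- nrow(M)
    se <- apply(M, 2, sd) / sqrt(n)
    tstat <- ifelse(se > 0, vals / se, 0)
    df <- n - 1
  } else {
    # single run: parametric t from the OLS covariance
    bm <- runs[[1]]
    w <- full_w(bm)
    X <- unclass(bm$design)
    var_c <- drop(t(w) %*% solve(crossprod(X)) %*% w) * bm$sigma2
    tstat <- ifelse(var_c > 0, vals / sqrt(var_c), 0)
    df <- bm$df
  }
  geometry <- b1$geometry
  shape <- function(v) if (!is.null(geometry)) array(v, geometry$dim) else v
  structure(list(values = shape(vals), t = shape(tstat), df = df,
                 weights = weights, weight_sum = sum(weights),
                 geometry = geometry),
            class = "contrast_map")
}
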