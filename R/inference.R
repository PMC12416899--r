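# Permutation-based group inference, Bonferroni control, t statistics and
# the power / sample-size computation.

#' Group-level permutation null distribution of decoding accuracy
#'
#' For each iteration, every subject's TRAINING condition labels are
#' shuffled independently within runs (respecting the chunk structure), the
#' full normalize -> pairwise-train -> cross-test chain is re-run, and the
#' resulting accuracies are averaged across subjects into one group value.
#' Subject streams are paired by iteration index from a common derived seed,
#' so the null is reproducible given (`problems`, `n_perm`, `seed`).
#'
#' @param problems list of per-subject [decoding_problem()]s.
#' @param n_perm number of iterations (study analysis: 10,000).
#' @param seed integer seed.
#' @param cost SVM cost parameter.
#' @param tol SMO tolerance.
#' @param alpha significance level used only to warn when `n_perm` is too
#'   small for the minimum attainable p-value.
#' @return an object of class `null_distribution`: list with `values` (the
#'   `n_perm` group-mean accuracies), `n_perm`, `seed`, `n_subjects`.
#' @export
permutation_null <- function(problems, n_perm, seed = 1, cost = 1,
                             tol = 1e-3, alpha = 0.05) {
  if (length(problems) < 1) stopf("at least one subject required")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (1 / (n_perm + 1) > alpha)
    warnf("n_perm = %d cannot attain p < %.3f (minimum p = %.4f)",
          n_perm, alpha, 1 / (n_perm + 1))
  acc <- matrix(0, n_perm, length(problems))
  for (s in seq_along(problems)) {
    pr <- problems[[s]]
    set.seed(derive_seed(seed, "perm", s))
    acc[, s] <- .perm_null_subject_cpp(pr$Xtr, as.integer(pr$ytr),
                                       as.integer(pr$run),
                                       pr$Xte, as.integer(pr$yte),
                                       4L, cost, tol, as.integer(n_perm))
  }
  structure(list(values = rowMeans(acc), n_perm = n_perm, seed = seed,
                 n_subjects = length(problems),
                 scheme = problems[[1]]$scheme, roi = problems[[1]]$roi),
            class = "null_distribution")
}

#' Permutation p-value
#'
#' `p = (#\{null >= observed\} + 1) / (N + 1)`, one-sided: high accuracies
#' are significant.
#'
#' @param observed observed group-mean accuracy.
#' @param null a `null_distribution` or numeric vector of null values.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, null) {
  v <- if (inherits(null, "null_distribution")) null$values else null
  if (!length(v)) stopf("empty null distribution")
  (sum(v >= observed) + 1) / (length(v) + 1)
}

#' Bonferroni correction
#'
#' @param p_values numeric p-values.
#' @param family_size number of tests in the family (>= number of p-values).
#' @return adjusted p-values, `min(1, m * p)`.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (family_size < 1) stopf("family_size must be >= 1")
  if (family_size < length(p_values))
    stopf("family_size smaller than the number of tests")
  pmin(1, p_values * family_size)
}

#' One-sample t-test of accuracies against chance
#'
#' @param accuracies per-subject values (>= 2).
#' @param chance chance level (default 0.5 for averaged binary decoding).
#' @param tails 1 (default, high values significant) or 2.
#' @return an object of class `group_stat`: list with `mean`, `t`, `df`,
#'   `p`, `cohens_dz`, `tails`, `chance`.
#' @export
group_ttest_vs_chance <- function(accuracies, chance = 0.5, tails = 1) {
  n <- length(accuracies)
  if (n < 2) stopf("need >= 2 values")
  d <- accuracies - chance
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    warnf("zero variance across subjects; t is infinite")
    tval <- ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0))
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    if (tails == 2) p <- ifelse(m == 0, 1, 0)
  } else {
    tval <- m / (s / sqrt(n))
    p <- if (tails == 1) pt(tval, n - 1, lower.tail = FALSE)
         else 2 * pt(abs(tval), n - 1, lower.tail = FALSE)
  }
  structure(list(mean = mean(accuracies), t = tval, df = n - 1, p = p,
                 cohens_dz = if (s > 0) m / s else NA_real_,
                 tails = tails, chance = chance),
            class = "group_stat")
}

#' Paired t-test with Cohen's dz
#'
#' Two-tailed paired t-test on `x - y` with the standardized paired effect
#' size dz = mean(diff) / sd(diff).
#'
#' @param x,y paired numeric vectors of equal length (>= 2).
#' @return a `group_stat` with fields `mean` (mean difference), `t`, `df`,
#'   `p` (two-tailed), `cohens_dz`.
#' @export
paired_t_cohens_d <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 2) stopf("need >= 2 pairs")
  d <- x - y
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    warnf("zero-variance differences; dz undefined")
    tval <- ifelse(m == 0, 0, sign(m) * Inf)
    p <- ifelse(m == 0, 1, 0)
    dz <- NA_real_
  } else {
    tval <- m / (s / sqrt(n))
    p <- 2 * pt(abs(tval), n - 1, lower.tail = FALSE)
    dz <- m / s
  }
  structure(list(mean = m, t = tval, df = n - 1, p = p, cohens_dz = dz,
                 tails = 2, chance = 0),
            class = "group_stat")
}

#' @export
print.group_stat <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (%d-tailed), dz = %.3f\n",
              x$df, x$t, x$p, x$tails, x$cohens_dz))
  invisible(x)
}

#' Power of the one-sample (paired-difference) t-test
#'
#' Exact power from the noncentral t distribution with noncentrality
#' `dz * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param n sample size.
#' @param dz standardized effect size (Cohen's dz).
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return power in (0, 1).
#' @export
ttest_power <- function(n, dz, alpha = 0.05, tails = 2) {
  ncp <- dz * sqrt(n)
  df <- n - 1
  tcrit <- qt(1 - alpha / tails, df)
  pw <- pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
  if (tails == 2) pw <- pw + pt(-tcrit, df, ncp = ncp)
  pw
}

#' Minimum sample size for a target power
#'
#' Smallest integer n >= 2 whose one-sample t-test power (via
#' [ttest_power()]) reaches the desired level. With the study's behavioral
#' validity effect (dz = 0.678, alpha = 0.05 two-tailed, power 0.9) this
#' returns 25.
#'
#' @param dz standardized effect size (> 0).
#' @param alpha significance level in (0, 1).
#' @param power desired power in (0, 1).
#' @param tails 1 or 2 (default 2).
#' @param n_max search ceiling.
#' @return integer minimum sample size.
#' @examples
#' power_sample_size(0.678, alpha = 0.05, power = 0.9, tails = 2)  # 25
#' @export
power_sample_size <- function(dz, alpha = 0.05, power = 0.9, tails = 2,
                              n_max = 10000L) {
  if (dz <= 0) stopf("dz must be > 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stopf("power must be in (0, 1)")
  for (n in 2:n_max) {
    if (ttest_power(n, dz, alpha, tails) >= power) return(as.integer(n))
  }
  stopf("no n <= %d reaches the requested power", n_max)
}
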