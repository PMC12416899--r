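# Small shared fixtures built in code.

tiny_sim_config <- function(..., seed = 101) {
  args <- list(
    n_subjects = 2,
    dim = c(8, 8, 6),
    roi_specs = list(
      FFA  = list(center = c(3, 3, 3), radius_mm = 4),
      PPA  = list(center = c(6, 6, 4), radius_mm = 4),
      CTRL = list(center = c(3, 6, 3), radius_mm = 4)),
    information = list(FFA = "cue_face", PPA = "delay_scene"),
    seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots  # plain replacement, no nested-list merging
  do.call(sim_config, args)
}

# simulate one subject and fit both task GLMs
fit_subject <- function(cfg, s = 1, ...) {
  sub <- simulate_subject(cfg, s, ...)
  list(search = lapply(sub$search, function(r) fit_glm(r, r$design)),
       oneback = lapply(sub$oneback, function(r) fit_glm(r, r$design)),
       sub = sub)
}

# pattern sets with known class structure for classifier tests
toy_patterns <- function(n_per = 4, p = 6, sep = 3, noise = 0.2,
                         n_cond = 4, period = "cue", seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_cond * p, sd = sep), n_cond, p)
  X <- do.call(rbind, lapply(1:n_cond, function(c)
    matrix(rep(centers[c, ], n_per), n_per, p, byrow = TRUE) +
      matrix(rnorm(n_per * p, sd = noise), n_per, p)))
  pattern_set(X, rep(1:n_cond, each = n_per), rep(seq_len(n_per), n_cond),
              period = period)
}
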