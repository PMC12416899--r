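# Canonical haemodynamic response function.

#' Canonical double-gamma HRF kernel
#'
#' Samples the canonical haemodynamic response function — the difference of
#' two gamma densities in the SPM convention (response peak around 5 s, an
#' undershoot around 15 s) — on an oversampled grid of `tr / oversampling`
#' seconds. The kernel is normalized so its peak value is 1; regressor
#' amplitudes therefore carry the units of the condition betas.
#'
#' @param tr repetition time in seconds.
#' @param oversampling integer subdivisions of the TR used for convolution
#'   (default 16).
#' @param peak_delay,undershoot_delay gamma shape parameters (seconds) of the
#'   response and undershoot components; defaults 6 and 16.
#' @param peak_disp,undershoot_disp dispersions (scale, seconds); defaults 1.
#' @param ratio peak-to-undershoot amplitude ratio; default 6.
#' @param length_s kernel support in seconds; default 32.
#' @return an object of class `hrf_kernel`: list with `values`, `dt`
#'   (sampling step, s), `time` (sample times, s) and the parameter record.
#' @examples
#' h <- canonical_hrf(1.5)
#' h$time[which.max(h$values)]  # ~5 s
#' @export
canonical_hrf <- function(tr, oversampling = 16L,
                          peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1,
                          ratio = 6, length_s = 32) {
  if (tr <= 0) stopf("tr must be > 0")
  if (oversampling < 1) stopf("oversampling must be >= 1")
  dt <- tr / oversampling
  t <- seq(0, length_s, by = dt)
  v <- dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    dgamma(t, shape = undershoot_delay / undershoot_disp,
           scale = undershoot_disp) / ratio
  v <- v / max(v)
  structure(
    list(values = v, dt = dt, time = t,
         params = list(peak_delay = peak_delay,
                       undershoot_delay = undershoot_delay,
                       peak_disp = peak_disp,
                       undershoot_disp = undershoot_disp,
                       ratio = ratio, length_s = length_s,
                       tr = tr, oversampling = as.integer(oversampling))),
    class = "hrf_kernel")
}
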