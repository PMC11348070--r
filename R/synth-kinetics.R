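#' Build a kinetic-trace tibble
#'
#' A surfactant-displacement trace: fluorescence peak wavelength versus time,
#' with the surfactant-addition time carried as an attribute.
#'
#' @param times seconds, strictly increasing.
#' @param wavelengths nm, same length as `times`.
#' @param t_add surfactant addition time (s), within the time range.
#' @return a `kinetic_trace` tibble with columns `time_s`, `wavelength_nm`.
#' @export
kinetic_trace <- function(times, wavelengths, t_add) {
  stopifnot(length(times) == length(wavelengths))
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  if (t_add < times[1] || t_add > times[length(times)]) {
    abort("`t_add` must lie within the time range of the trace.")
  }
  out <- tibble(time_s = as.double(times), wavelength_nm = as.double(wavelengths))
  attr(out, "t_add_s") <- as.double(t_add)
  class(out) <- c("kinetic_trace", class(out))
  out
}

#' Surfactant addition time of a trace
#' @param trace a [kinetic_trace()].
#' @return time in seconds.
#' @export
t_add <- function(trace) attr(trace, "t_add_s")

#' Simulate a surfactant-displacement kinetic trace
#'
#' Before surfactant addition the peak sits at `lambda0_nm`; afterwards it
#' relaxes to `lambdaInf_nm` by first-order exponential decay with time
#' constant `tau_s`, plus Gaussian measurement noise. A censored trace (no
#' measurable displacement within the observation window; very strong
#' binding) stays flat at `lambda0_nm` plus noise.
#'
#' @param tau_s time constant in seconds (> 0), ignored when `censored`.
#' @param lambda0_nm initial peak wavelength (default 1129 nm, the tracked
#'   (9,4)-chirality peak).
#' @param lambdaInf_nm plateau wavelength after complete displacement
#'   (default 1115 nm).
#' @param dt_s sampling interval (default 20 s).
#' @param total_s total observation span (default 600 s).
#' @param t_add_s surfactant addition time (default 100 s).
#' @param noise_sd_nm wavelength noise SD.
#' @param censored if `TRUE`, simulate a flat (no-shift) trace.
#' @param seed integer seed.
#' @return a [kinetic_trace()].
#' @export
simulate_kinetic_trace <- function(tau_s, lambda0_nm = 1129, lambdaInf_nm = 1115,
                                   dt_s = 20, total_s = 600, t_add_s = 100,
                                   noise_sd_nm = 0, censored = FALSE, seed = 1L) {
  if (dt_s <= 0) abort("`dt_s` must be positive.")
  if (total_s <= t_add_s) abort("`total_s` must exceed `t_add_s`.")
  if (!censored && (!is.numeric(tau_s) || tau_s <= 0)) {
    abort("`tau_s` must be a positive number unless `censored = TRUE`.")
  }
  times <- seq(0, total_s, by = dt_s)
  lam <- if (censored) {
    rep(lambda0_nm, length(times))
  } else {
    ifelse(times < t_add_s, lambda0_nm,
           lambdaInf_nm + (lambda0_nm - lambdaInf_nm) *
             exp(-(times - t_add_s) / tau_s))
  }
  if (noise_sd_nm > 0) {
    lam <- withr::with_seed(seed, lam + rnorm(length(times), 0, noise_sd_nm))
  }
  kinetic_trace(times, lam, t_add_s)
}
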