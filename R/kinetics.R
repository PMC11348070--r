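#' Peak wavelength of a fluorescence spectrum
#'
#' Finds the maximum-intensity wavelength inside a window and refines it by
#' three-point parabolic interpolation through the maximum and its
#' neighbours. Falls back to the grid wavelength when the maximum lies on
#' the window edge or the parabola degenerates (flat top).
#'
#' @param spectrum data frame with columns `wavelength_nm` and `intensity`.
#' @param window length-2 numeric, wavelength window (lo, hi) in nm.
#' @return peak wavelength in nm.
#' @export
extract_peak_wavelength <- function(spectrum, window = c(1100, 1160)) {
  spectrum <- as_tibble(spectrum)
  stopifnot(all(c("wavelength_nm", "intensity") %in% names(spectrum)))
  inside <- spectrum |>
    filter(.data$wavelength_nm >= window[1], .data$wavelength_nm <= window[2]) |>
    arrange(.data$wavelength_nm)
  if (nrow(inside) < 3) abort("Window must contain at least 3 spectral points.")
  i <- which.max(inside$intensity)
  if (i == 1 || i == nrow(inside)) {
    return(inside$wavelength_nm[i])
  }
  x <- inside$wavelength_nm[(i - 1):(i + 1)]
  y <- inside$intensity[(i - 1):(i + 1)]
  # vertex of the parabola through three (possibly non-uniform) points
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  if (!is.finite(a) || a >= 0) {
    return(x[2])
  }
  -b / (2 * a)
}

#' Fit the surfactant-displacement time constant
#'
#' Least-squares fit of the first-order model
#' `lambda(t) = lambdaInf + (lambda0 - lambdaInf) * exp(-(t - t_add)/tau)`
#' on the points at `t >= t_add`, with all three parameters free.
#' Initialisation: `lambda0` from the mean of the pre-addition points,
#' `lambdaInf` from the last point, `tau` from the log-linear slope of the
#' shifted trace. If the fitted total shift `|lambda0 - lambdaInf|` is below
#' `shift_min_nm` the trace is reported as censored (INF: no measurable
#' displacement, very strong binding).
#'
#' @param trace a [kinetic_trace()].
#' @param shift_min_nm minimum fitted shift (nm) to call a finite time
#'   constant; default 1 nm, the instrument-noise scale.
#' @return a `tau_fit` object; see [tidy.tau_fit()].
#' @export
fit_time_constant <- function(trace, shift_min_nm = 1.0) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (any(diff(trace$time_s) <= 0)) abort("Trace times must be strictly increasing.")
  ta <- t_add(trace)
  pre <- trace$wavelength_nm[trace$time_s < ta]
  post <- trace |> filter(.data$time_s >= ta)
  if (nrow(post) < 5) abort("Need at least 5 points after surfactant addition.")

  l0_init <- if (length(pre)) mean(pre) else post$wavelength_nm[1]
  linf_init <- post$wavelength_nm[nrow(post)]
  shift_obs <- l0_init - linf_init
  tau_init <- {
    z <- (post$wavelength_nm - linf_init) / ifelse(shift_obs == 0, 1, shift_obs)
    ok <- z > 1e-3
    if (sum(ok) >= 2 && abs(shift_obs) > 1e-8) {
      sl <- stats::lm.fit(
        cbind(1, post$time_s[ok] - ta),
        log(z[ok])
      )$coefficients[2]
      if (is.finite(sl) && sl < 0) -1 / sl else diff(range(post$time_s)) / 3
    } else {
      diff(range(post$time_s)) / 3
    }
  }

  df <- tibble(t = post$time_s - ta, y = post$wavelength_nm)
  window <- max(df$t)
  # clamp the initial tau into the resolvable range: outside it the
  # exponential's gradient is numerically singular at the start values
  tau_init <- min(max(tau_init, window / 100), 3 * window)
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ linf + (l0 - linf) * exp(-t / tau),
        data = df, start = start,
        lower = c(l0 = -Inf, linf = -Inf, tau = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
  }
  fit <- try_fit(list(l0 = l0_init, linf = linf_init, tau = tau_init))
  if (inherits(fit, "error")) {
    fit <- try_fit(list(l0 = df$y[1], linf = mean(tail(df$y, 3)),
                        tau = window / 3))
  }

  if (inherits(fit, "error")) {
    # A flat trace gives the exponential nothing to fit; that is censoring,
    # not a failure, when the observed shift is below threshold. Average
    # the tail so a single noisy endpoint cannot fake a shift.
    shift_robust <- l0_init - mean(tail(post$wavelength_nm, 3))
    if (abs(shift_robust) < shift_min_nm) {
      return(new_tau_fit(NA_real_, l0_init, l0_init,
                         rmse = sd(post$wavelength_nm),
                         n = nrow(post), censored = TRUE, trace = trace))
    }
    abort(sprintf("Time-constant fit failed to converge: %s", conditionMessage(fit)))
  }

  cf <- coef(fit)
  resid <- df$y - stats::predict(fit)
  rmse <- sqrt(mean(resid^2))
  # total fitted shift realised within the observation window: an
  # unresolvably slow component (tau >> window) can carry a large nominal
  # amplitude while displacing the peak by almost nothing over the
  # measured span, so the raw |l0 - linf| would under-censor
  shift_fit <- abs(cf[["l0"]] - cf[["linf"]]) *
    (1 - exp(-max(df$t) / cf[["tau"]]))
  censored <- shift_fit < shift_min_nm
  new_tau_fit(
    tau = if (censored) NA_real_ else cf[["tau"]],
    lambda0 = cf[["l0"]], lambdaInf = cf[["linf"]],
    rmse = rmse, n = nrow(post), censored = censored, trace = trace
  )
}

new_tau_fit <- function(tau, lambda0, lambdaInf, rmse, n, censored, trace = NULL) {
  structure(
    list(
      tau_s = tau, lambda0_nm = lambda0, lambdaInf_nm = lambdaInf,
      rmse_nm = rmse, n_points = n, censored = censored, trace = trace
    ),
    class = "tau_fit"
  )
}

#' @export
print.tau_fit <- function(x, ...) {
  if (x$censored) {
    cat(sprintf(
      "<tau_fit> censored (INF): fitted shift below threshold (n = %d)\n",
      x$n_points
    ))
  } else {
    cat(sprintf(
      "<tau_fit> tau = %.2f s, lambda0 = %.2f nm, lambdaInf = %.2f nm, rmse = %.3f nm (n = %d)\n",
      x$tau_s, x$lambda0_nm, x$lambdaInf_nm, x$rmse_nm, x$n_points
    ))
  }
  invisible(x)
}

#' @rdname fit_time_constant
#' @param x a `tau_fit`.
#' @param ... unused.
#' @method tidy tau_fit
#' @export
tidy.tau_fit <- function(x, ...) {
  tibble(
    tau_s = x$tau_s, censored = x$censored, lambda0_nm = x$lambda0_nm,
    lambdaInf_nm = x$lambdaInf_nm, rmse_nm = x$rmse_nm, n_points = x$n_points
  )
}

#' Fit time constants for a batch of traces
#'
#' @param traces named list of [kinetic_trace()] objects (names become
#'   `sequence_id`).
#' @param shift_min_nm censoring threshold, see [fit_time_constant()].
#' @param threshold_s affinity labelling threshold, see [label_affinity()].
#' @return tibble (sequence_id, tau_s, censored, lambda0_nm, lambdaInf_nm,
#'   rmse_nm, label).
#' @export
fit_time_constants <- function(traces, shift_min_nm = 1.0, threshold_s = 90) {
  ids <- names(traces) %||% as.character(seq_along(traces))
  purrr::map2(traces, ids, function(tr, id) {
    fit <- fit_time_constant(tr, shift_min_nm = shift_min_nm)
    tidy(fit) |>
      mutate(
        sequence_id = id,
        label = label_affinity(fit, threshold_s = threshold_s)
      )
  }) |>
    bind_rows() |>
    select("sequence_id", dplyr::everything())
}

#' Label a sequence high/low affinity from its time constant
#'
#' High affinity iff the trace is censored (INF) or `tau >= threshold_s`.
#' The study threshold is 90 s, chosen at a discontinuous gap in the
#' measured time-constant distribution.
#'
#' @param result a `tau_fit`, or a numeric tau in seconds.
#' @param threshold_s threshold in seconds (default 90).
#' @param censored logical, used when `result` is numeric.
#' @return "high" or "low" (character, vectorised over numeric input).
#' @export
label_affinity <- function(result, threshold_s = 90, censored = FALSE) {
  if (inherits(result, "tau_fit")) {
    tau <- result$tau_s
    censored <- result$censored
  } else {
    tau <- result
    censored <- rep_len(censored, length(tau))
  }
  ifelse(censored | (!is.na(tau) & tau >= threshold_s), "high", "low")
}

#' Nuclease cut ratio from gel band intensities
#'
#' `CR = I_c / (I_a + I_c)`, the cleaved fraction of ssDNA, from the
#' intensities of the intact band (`I_a`) and the short-cleaved band (`I_c`).
#'
#' @param I_a intact-band intensity (>= 0).
#' @param I_c cleaved-band intensity (>= 0).
#' @return cut ratio in `[0, 1]`; vectorised.
#' @export
cut_ratio <- function(I_a, I_c) {
  if (any(I_a < 0 | I_c < 0)) abort("Band intensities must be non-negative.")
  if (any(I_a + I_c == 0)) abort("Cut ratio undefined when both bands are zero.")
  I_c / (I_a + I_c)
}

#' Additive dissociation-enthalpy estimate of a sequence
#'
#' Sums user-supplied per-base dissociation enthalpies over the sequence.
#' The per-base values are a required input (they come from calorimetric
#' literature and are not bundled).
#'
#' @param seqs character vector of 30-nt sequences.
#' @param table named numeric vector with entries for A, C, G, T.
#' @return numeric vector of summed enthalpies, same units as `table`.
#' @export
enthalpy_sum <- function(seqs, table) {
  check_sequences(seqs)
  if (!all(DNA_BASES %in% names(table))) {
    abort("`table` must provide enthalpies for all of A, C, G, T.")
  }
  mat <- seq_matrix(seqs)
  rowSums(matrix(as.numeric(table[mat]), nrow = nrow(mat)))
}

#' Pearson correlation between time constants and enthalpy estimates
#'
#' Censored (INF) time constants must be excluded upstream; correlation is
#' computed on the linear tau scale.
#'
#' @param taus numeric vector of finite time constants (s).
#' @param enthalpies numeric vector, same length.
#' @return Pearson correlation coefficient.
#' @export
correlate_tau_enthalpy <- function(taus, enthalpies) {
  if (length(taus) != length(enthalpies) || length(taus) < 3) {
    abort("Need equal-length vectors with at least 3 values.")
  }
  if (!all(is.finite(taus)) || !all(is.finite(enthalpies))) {
    abort("All values must be finite; drop censored time constants first.")
  }
  if (sd(taus) == 0 || sd(enthalpies) == 0) {
    abort("Correlation undefined: zero variance in input.")
  }
  cor(taus, enthalpies)
}
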