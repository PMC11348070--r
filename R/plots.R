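#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col labs
#'   autoplot theme_minimal geom_abline
NULL

#' Plot a round-over-round enrichment table
#'
#' One line per k-mer: frequency in the top-N profile versus round.
#'
#' @param object an `enrichment_table` from [enrichment_table()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, ...) {
  ggplot(object, aes(x = .data$round, y = .data$frequency,
                     colour = .data$kmer)) +
    geom_line() +
    geom_point() +
    labs(x = "Selection round", y = "Frequency in top-N profile",
         colour = sprintf("%d-mer", object$k[1])) +
    theme_minimal()
}

#' Plot a fitted displacement trace
#'
#' Measured peak wavelengths with the fitted first-order decay overlaid
#' (censored fits show the flat level).
#'
#' @param object a `tau_fit` from [fit_time_constant()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tau_fit
#' @export
autoplot.tau_fit <- function(object, ...) {
  trace <- object$trace
  if (is.null(trace)) abort("This tau_fit carries no trace data.")
  ta <- t_add(trace)
  grid <- tibble(time_s = seq(min(trace$time_s), max(trace$time_s),
                              length.out = 200))
  grid$fit <- ifelse(
    grid$time_s < ta | object$censored,
    object$lambda0_nm,
    object$lambdaInf_nm + (object$lambda0_nm - object$lambdaInf_nm) *
      exp(-(grid$time_s - ta) / ifelse(object$censored, Inf, object$tau_s))
  )
  ggplot(trace, aes(x = .data$time_s, y = .data$wavelength_nm)) +
    geom_point(size = 0.8) +
    geom_line(data = grid, aes(y = .data$fit), colour = "red") +
    labs(
      x = "Time (s)", y = "Peak wavelength (nm)",
      title = if (object$censored) "Censored (INF): no measurable shift"
              else sprintf("tau = %.1f s", object$tau_s)
    ) +
    theme_minimal()
}

#' Plot per-position hydrogen-bond means
#'
#' @param object an `hbond_stats` from [hbond_stats()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hbond_stats
#' @export
autoplot.hbond_stats <- function(object, ...) {
  ggplot(object$per_position, aes(x = .data$nt_index, y = .data$mean_hbonds)) +
    geom_col() +
    labs(x = "Nucleotide position", y = "Mean H-bonds (analysis window)") +
    theme_minimal()
}

#' Plot an MSD curve
#'
#' @param object an `msd_curve` from [msd()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$lag, y = .data$msd_nm2)) +
    geom_line() +
    labs(x = "Lag (frames)", y = expression(MSD ~ (nm^2))) +
    theme_minimal()
}

#' Plot per-repeat ROC curves of an evaluation report
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$rocs)) abort("This eval_report carries no ROC curves.")
  ggplot(object$rocs, aes(x = .data$fpr, y = .data$tpr,
                          group = .data$repeat_id)) +
    geom_line(alpha = 0.5) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    labs(x = "False positive rate", y = "True positive rate") +
    theme_minimal()
}
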