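#' Simulate a measured affinity table (synthetic stand-in)
#'
#' Emulates the study design of the surfactant-displacement screen: a
#' panel of `n` sequences with measured time constants, of which `n_high`
#' are high-affinity at the 90-s threshold (including `n_censored` INF
#' sequences showing no measurable shift) and the rest low-affinity. The
#' high group is drawn from the top scorers under the supplied ground-truth
#' affinity model and the low group from the lower scorers, so time
#' constants are monotonically linked to the model's score and a learner
#' pre-trained under the same model can recover the labels. This is a
#' synthetic table: the study's own measurements are not publicly
#' deposited.
#'
#' @param model an [affinity_model()] (ground truth).
#' @param n panel size (default 72).
#' @param n_high high-affinity sequences (default 20).
#' @param n_censored of the high group, how many are censored/INF.
#' @param threshold_s labelling threshold (default 90 s).
#' @param n_pool random candidate pool to draw the panel from.
#' @param seed integer seed.
#' @return tibble (sequence, tau_s, censored, label); `tau_s` is `NA` for
#'   censored sequences.
#' @export
simulate_affinity_table <- function(model, n = 72L, n_high = 20L,
                                    n_censored = 3L, threshold_s = 90,
                                    n_pool = 4000L, seed = 1L) {
  stopifnot(n_high < n, n_censored <= n_high)
  pool <- generate_initial_library(n_pool, seed = derive_seed(seed, 1))$sequence
  sc <- score_sequence(model, pool)
  ord <- order(sc, decreasing = TRUE)
  withr::with_seed(derive_seed(seed, 2), {
    hi_idx <- sample(ord[seq_len(ceiling(0.1 * n_pool))], n_high)
    lo_pool <- ord[seq(ceiling(0.3 * n_pool), n_pool)]
    lo_idx <- sample(lo_pool, n - n_high)
    hi_tau <- threshold_s * exp(runif(n_high, 0.05, 1.5))
    lo_tau <- threshold_s * exp(-runif(n - n_high, 0.05, 1.5))
    censored <- c(
      seq_len(n_high) %in% sample(n_high, n_censored),
      rep(FALSE, n - n_high)
    )
    out <- tibble(
      sequence = pool[c(hi_idx, lo_idx)],
      tau_s = c(hi_tau, lo_tau),
      censored = censored
    ) |>
      mutate(
        tau_s = ifelse(.data$censored, NA_real_, .data$tau_s),
        label = as.integer(
          label_affinity(.data$tau_s, threshold_s, .data$censored) == "high"
        )
      )
    out[sample(n), ]
  })
}
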