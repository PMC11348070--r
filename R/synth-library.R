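#' Build a library-round tibble
#'
#' A selection-round library is a tibble with columns `sequence` (30-nt
#' strings) and `count` (non-negative integers), carrying the round index and
#' seed as attributes.
#'
#' @param sequences character vector of 30-nt sequences (unique).
#' @param counts non-negative integer counts, same length.
#' @param round_index round number (0 = initial random library).
#' @param seed seed the round was generated with (or `NA`).
#' @return a `library_round` tibble.
#' @export
library_round <- function(sequences, counts, round_index = 0L, seed = NA_integer_) {
  check_sequences(sequences)
  stopifnot(length(sequences) == length(counts), all(counts >= 0))
  if (sum(counts) <= 0) abort("Total library count must be positive.")
  out <- tibble(sequence = sequences, count = as.double(counts))
  attr(out, "round_index") <- as.integer(round_index)
  attr(out, "seed") <- seed
  class(out) <- c("library_round", class(out))
  out
}

#' @export
print.library_round <- function(x, ...) {
  cat(sprintf(
    "<library_round %d> %d unique sequences, total count %.0f\n",
    round_index(x), nrow(x), sum(x$count)
  ))
  NextMethod()
}

#' Round index of a library round
#' @param lib a `library_round`.
#' @return integer round index.
#' @export
round_index <- function(lib) {
  attr(lib, "round_index") %||% NA_integer_
}

random_sequences <- function(n, len = INSERT_LEN) {
  mat <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  apply(mat, 1, paste, collapse = "")
}

#' Generate the initial random library (round 0)
#'
#' Sequences are i.i.d. uniform over \{A,C,G,T\}^30; duplicated draws are
#' aggregated. Counts follow the requested distribution per unique sequence.
#'
#' @param n_unique number of unique sequences to draw (>= 1).
#' @param counts_dist "uniform" (all counts 1) or "geometric" (counts ~
#'   1 + Geom(0.5), a mild abundance skew).
#' @param seed integer seed; identical seeds give bit-identical libraries.
#' @return a [library_round()] with `round_index = 0`.
#' @export
generate_initial_library <- function(n_unique, counts_dist = c("uniform", "geometric"),
                                     seed = 1L) {
  if (n_unique < 1) abort("`n_unique` must be >= 1.")
  counts_dist <- match.arg(counts_dist)
  withr::with_seed(seed, {
    seqs <- character(0)
    while (length(seqs) < n_unique) {
      seqs <- unique(c(seqs, random_sequences(n_unique - length(seqs) + 8L)))
    }
    seqs <- seqs[seq_len(n_unique)]
    counts <- switch(counts_dist,
      uniform = rep(1, n_unique),
      geometric = 1 + stats::rgeom(n_unique, 0.5)
    )
    library_round(seqs, counts, round_index = 0L, seed = seed)
  })
}

#' Simulate one selection round
#'
#' Selection is modelled as Boltzmann-weighted multinomial resampling:
#' `n_draw` molecules are drawn with replacement with probability
#' proportional to `count * exp(score / temperature)`, then each surviving
#' unique sequence's count is multiplied by a lognormal factor with
#' coefficient of variation `pcr_cv` (PCR amplification noise) and rounded
#' (minimum 1).
#'
#' @param prev previous [library_round()].
#' @param model an [affinity_model()]; its `temperature` sets stringency.
#' @param n_draw number of molecules sampled onto the nanotube surface.
#' @param pcr_cv coefficient of variation of the multiplicative PCR noise
#'   (0 = exact multinomial counts).
#' @param seed integer seed.
#' @return a [library_round()] with `round_index` incremented.
#' @export
simulate_selection_round <- function(prev, model, n_draw = 50000L,
                                     pcr_cv = 0, seed = 1L) {
  stopifnot(inherits(prev, "library_round"), nrow(prev) > 0, n_draw >= 1,
            pcr_cv >= 0)
  scores <- score_sequence(model, prev$sequence)
  logw <- log(prev$count) + scores / model$temperature
  logw <- logw - max(logw) # overflow guard; weights defined up to a constant
  w <- exp(logw)
  if (!any(w > 0) || !all(is.finite(w))) {
    abort("Selection weights are all zero or non-finite; cannot resample.")
  }
  withr::with_seed(seed, {
    draw <- sample.int(nrow(prev), n_draw, replace = TRUE, prob = w)
    tab <- tabulate(draw, nbins = nrow(prev))
    keep <- tab > 0
    counts <- tab[keep]
    if (pcr_cv > 0) {
      sdlog <- sqrt(log(1 + pcr_cv^2))
      fac <- rlnorm(sum(keep), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      counts <- pmax(1, round(counts * fac))
    }
    library_round(prev$sequence[keep], counts,
                  round_index = round_index(prev) + 1L, seed = seed)
  })
}

#' Simulate a full multi-round selection
#'
#' Convenience wrapper: starts from a fresh random library and applies
#' [simulate_selection_round()] repeatedly, returning every round.
#'
#' @param model an [affinity_model()].
#' @param n_rounds number of selection rounds (the study ran 6).
#' @param n_unique size of the initial library.
#' @param n_draw molecules drawn per round.
#' @param pcr_cv PCR noise CV.
#' @param seed integer seed; per-round seeds are derived from it.
#' @return list of `library_round`s, rounds 0..n_rounds.
#' @export
simulate_selection <- function(model, n_rounds = 6L, n_unique = 50000L,
                               n_draw = 50000L, pcr_cv = 0, seed = 1L) {
  rounds <- vector("list", n_rounds + 1L)
  rounds[[1]] <- generate_initial_library(n_unique, seed = derive_seed(seed, 0))
  for (r in seq_len(n_rounds)) {
    rounds[[r + 1]] <- simulate_selection_round(
      rounds[[r]], model,
      n_draw = n_draw, pcr_cv = pcr_cv, seed = derive_seed(seed, r)
    )
  }
  rounds
}
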