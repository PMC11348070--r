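#' Synthetic ground-truth affinity model
#'
#' A linear additive scoring function standing in for the unknown physical
#' affinity of a 30-nt ssDNA sequence for the nanotube surface. The score is
#' a sum of per-base weights, overlapping-dimer weights, and position-anchored
#' trimer motif weights. The motif term makes affinity depend on base *order*,
#' not just composition, mirroring the experimental observation that scrambled
#' sequences of identical composition lose affinity. `temperature` controls
#' how soft the Boltzmann selection acting on these scores is.
#'
#' @param base_weights named numeric vector over A, C, G, T (score per
#'   occurrence). Missing bases default to 0.
#' @param dimer_weights named numeric vector over 2-mers (e.g. "AC").
#' @param motif_weights tibble/data.frame with columns `motif` (3-mer),
#'   `position` (anchor, 1-based start in 1..28) and `weight`; or `NULL`.
#' @param temperature positive real; selection softness.
#' @return an object of class `affinity_model`.
#' @examples
#' m <- affinity_model(base_weights = c(A = 0.1, C = 0.1, G = -0.1, T = -0.1))
#' score_sequence(m, strrep("AC", 15))
#' @export
affinity_model <- function(base_weights = NULL, dimer_weights = NULL,
                           motif_weights = NULL, temperature = 1) {
  stopifnot(is.numeric(temperature), length(temperature) == 1, temperature > 0)
  bw <- setNames(numeric(4), DNA_BASES)
  if (!is.null(base_weights)) {
    if (is.null(names(base_weights)) || !all(names(base_weights) %in% DNA_BASES)) {
      abort("`base_weights` must be named with bases A, C, G, T.")
    }
    bw[names(base_weights)] <- base_weights
  }
  all_dimers <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  dw <- setNames(numeric(16), sort(all_dimers))
  if (!is.null(dimer_weights)) {
    if (is.null(names(dimer_weights)) || !all(names(dimer_weights) %in% names(dw))) {
      abort("`dimer_weights` must be named with 2-mers over A, C, G, T.")
    }
    dw[names(dimer_weights)] <- dimer_weights
  }
  if (!is.null(motif_weights)) {
    motif_weights <- as_tibble(motif_weights)
    stopifnot(all(c("motif", "position", "weight") %in% names(motif_weights)))
    if (any(nchar(motif_weights$motif) != 3)) abort("Motifs must be 3-mers.")
    if (any(motif_weights$position < 1 | motif_weights$position > INSERT_LEN - 2)) {
      abort("Motif anchor positions must lie in 1..28.")
    }
  } else {
    motif_weights <- tibble(
      motif = character(), position = integer(), weight = numeric()
    )
  }
  if (!all(is.finite(c(bw, dw, motif_weights$weight)))) {
    abort("All weights must be finite.")
  }
  structure(
    list(
      base_weights = bw, dimer_weights = dw,
      motif_weights = motif_weights, temperature = temperature
    ),
    class = "affinity_model"
  )
}

#' @export
print.affinity_model <- function(x, ...) {
  cat("<affinity_model>\n")
  cat("  base weights: ",
      paste(sprintf("%s=%.3g", names(x$base_weights), x$base_weights),
            collapse = " "), "\n")
  nz <- x$dimer_weights[x$dimer_weights != 0]
  if (length(nz)) {
    cat("  dimer weights:", paste(sprintf("%s=%.3g", names(nz), nz),
                                  collapse = " "), "\n")
  }
  if (nrow(x$motif_weights)) {
    cat("  motifs:       ",
        paste(sprintf("%s@%d(%.3g)", x$motif_weights$motif,
                      x$motif_weights$position, x$motif_weights$weight),
              collapse = " "), "\n")
  }
  cat("  temperature:  ", x$temperature, "\n")
  invisible(x)
}

#' Score sequences under an affinity model
#'
#' score = sum of base weights + sum of overlapping dimer weights + sum of
#' exact position-anchored motif hits.
#'
#' @param model an [affinity_model()].
#' @param seqs character vector of 30-nt sequences.
#' @return numeric vector of scores.
#' @export
score_sequence <- function(model, seqs) {
  stopifnot(inherits(model, "affinity_model"))
  check_sequences(seqs)
  mat <- seq_matrix(seqs)
  base_part <- rowSums(matrix(model$base_weights[mat], nrow = nrow(mat)))
  dimers <- matrix(
    paste0(mat[, -ncol(mat), drop = FALSE], mat[, -1, drop = FALSE]),
    nrow = nrow(mat)
  )
  dimer_part <- rowSums(matrix(model$dimer_weights[dimers], nrow = nrow(mat)))
  motif_part <- numeric(length(seqs))
  if (nrow(model$motif_weights)) {
    for (i in seq_len(nrow(model$motif_weights))) {
      mw <- model$motif_weights[i, ]
      hit <- substr(seqs, mw$position, mw$position + 2L) == mw$motif
      motif_part <- motif_part + hit * mw$weight
    }
  }
  base_part + dimer_part + motif_part
}
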