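all_kmers <- function(k) {
  sort(apply(
    expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE),
    1, function(r) paste(rev(r), collapse = "")
  ))
}

#' k-mer feature encoding
#'
#' Overlapping k-mer counts per sequence, columns in fixed lexicographic
#' k-mer order (4^k columns). Each 30-mer contributes 31 - k windows;
#' `normalize = TRUE` divides rows by the window count so rows sum to 1.
#'
#' @param seqs character vector of 30-nt sequences.
#' @param k k-mer size, 1..5 (the study found 2-mers best for RF/MLP).
#' @param normalize return frequencies instead of counts.
#' @return numeric matrix, n x 4^k, with k-mer column names.
#' @export
encode_kmer <- function(seqs, k = 2L, normalize = FALSE) {
  if (k < 1 || k > 5) abort("`k` must be in 1..5.")
  check_sequences(seqs)
  m <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k, step = 1
  )
  m <- m[, order(colnames(m)), drop = FALSE]
  m <- matrix(as.numeric(m), nrow = length(seqs),
              dimnames = list(NULL, colnames(m)))
  if (normalize) m <- m / (INSERT_LEN - k + 1)
  m
}

#' One-hot sequence encoding
#'
#' Each of the 30 positions becomes a binary length-4 vector in column
#' order A, C, G, T; exactly one entry per position is 1.
#'
#' @param seqs character vector of 30-nt sequences.
#' @return numeric array, dim (n, 30, 4); dimnames carry base labels.
#' @export
encode_onehot <- function(seqs) {
  check_sequences(seqs)
  mat <- seq_matrix(seqs)
  n <- length(seqs)
  out <- array(0, dim = c(n, INSERT_LEN, 4),
               dimnames = list(NULL, NULL, DNA_BASES))
  base_idx <- matrix(match(mat, DNA_BASES), nrow = n)
  for (b in 1:4) {
    out[, , b] <- (base_idx == b) * 1
  }
  out
}

#' Decode a one-hot array back to sequences
#'
#' @param x array from [encode_onehot()].
#' @return character vector of sequences.
#' @export
decode_onehot <- function(x) {
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 4)
  apply(x, 1, function(s) paste(DNA_BASES[apply(s, 1, which.max)], collapse = ""))
}

#' Composition-preserving sequence shuffle
#'
#' Randomly permutes the bases within each sequence, preserving its 1-mer
#' composition exactly. Used by the shuffling ablation: a model that only
#' uses composition is unaffected, a model using base order degrades.
#'
#' @param seqs character vector of sequences.
#' @param seed integer seed.
#' @return character vector of shuffled sequences.
#' @export
shuffle_sequences <- function(seqs, seed = 1L) {
  withr::with_seed(seed, {
    vapply(seqs, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}
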