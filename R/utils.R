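#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise
#'   desc bind_rows across
#' @importFrom purrr map map_dbl map_chr map2 imap map_dfr
#' @importFrom stats rnorm runif rlnorm setNames sd cor coef
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")
INSERT_LEN <- 30L

#' Check that sequences are valid fixed-length DNA strings
#'
#' @param seqs character vector of sequences.
#' @param len required length (default 30, the random-insert length).
#' @return invisibly, `seqs`; aborts on violation.
#' @keywords internal
check_sequences <- function(seqs, len = INSERT_LEN) {
  if (!is.character(seqs) || length(seqs) == 0) {
    abort("`seqs` must be a non-empty character vector.")
  }
  bad_len <- nchar(seqs) != len
  if (any(bad_len)) {
    abort(sprintf(
      "All sequences must be exactly %d nt; %d sequence(s) violate this.",
      len, sum(bad_len)
    ))
  }
  if (any(grepl(sprintf("[^%s]", paste(DNA_BASES, collapse = "")), seqs))) {
    abort("Sequences must contain only A, C, G, T.")
  }
  invisible(seqs)
}

# Split sequences into an n x len character matrix of single bases.
seq_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

# Derive a child seed from a base seed and a stream index, staying < 2^31.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 1009 + 97 * as.double(stream)) %% 2147483629
}

#' Exact size of the random-sequence library space
#'
#' Computes `alphabet ^ length` with exact integer arithmetic (a small
#' base-10000 big-integer multiply), since 4^30 exceeds the range where
#' doubles carry every decimal digit. For the study design (30-nt inserts
#' over A/C/G/T) this is 4^30 = 1152921504606846976, approximately 1.1e18.
#'
#' @param length insert length in nucleotides (default 30).
#' @param alphabet alphabet size (default 4).
#' @return a list with `exact` (decimal string) and `approx` (double).
#' @examples
#' library_space()$approx # ~1.15e18
#' @export
library_space <- function(length = 30L, alphabet = 4L) {
  stopifnot(length >= 1, alphabet >= 2)
  base <- 10000L
  digits <- c(1L) # little-endian base-1e4 limbs
  for (i in seq_len(length)) {
    carry <- 0L
    for (j in seq_along(digits)) {
      v <- digits[j] * alphabet + carry
      digits[j] <- v %% base
      carry <- v %/% base
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% base)
      carry <- carry %/% base
    }
  }
  limbs <- rev(digits)
  exact <- paste0(
    limbs[1],
    paste(sprintf("%04d", limbs[-1]), collapse = "")
  )
  list(exact = exact, approx = as.numeric(exact))
}
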