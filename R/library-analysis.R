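FWD_PRIMER <- "AGCGTCGAATACCACTAC"
REV_PRIMER <- "GACCACGAGCTCCATTAG"

#' Read a sequencing library from FASTA/FASTQ
#'
#' Parses reads with Biostrings (gzip-transparent); qualities are ignored.
#' Identical sequences are aggregated into counts when `aggregate = TRUE`.
#' A sidecar count table (TSV with columns `sequence`, `count`) may be
#' supplied instead of encoding counts by record duplication.
#'
#' @param path FASTA or FASTQ file.
#' @param format "auto" (from extension), "fasta" or "fastq".
#' @param aggregate aggregate identical sequences into counts.
#' @param counts_tsv optional path to a sidecar TSV (sequence, count); when
#'   given, counts come from it (sequences absent from the file are dropped).
#' @return tibble (sequence, count).
#' @export
read_library <- function(path, format = c("auto", "fasta", "fastq"),
                         aggregate = TRUE, counts_tsv = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  if (format == "fastq") {
    n_lines <- length(readLines(path, warn = FALSE))
    if (n_lines == 0) abort(sprintf("Empty file: %s", path))
    if (n_lines %% 4 != 0) {
      abort(sprintf(
        "Malformed FASTQ %s: %d lines is not a multiple of 4 (truncated record near line %d).",
        path, n_lines, n_lines
      ))
    }
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      abort(sprintf("Failed to parse %s as %s: %s", path, format,
                    conditionMessage(e)))
    }
  )
  if (length(set) == 0) abort(sprintf("Empty file: %s", path))
  seqs <- as.character(set)
  out <- if (aggregate) {
    tibble(sequence = seqs) |>
      dplyr::count(.data$sequence, name = "count") |>
      arrange(desc(.data$count), .data$sequence)
  } else {
    tibble(sequence = seqs, count = 1)
  }
  if (!is.null(counts_tsv)) {
    side <- readr::read_tsv(counts_tsv, col_types = readr::cols(
      sequence = readr::col_character(), count = readr::col_double()
    ))
    out <- out |>
      select("sequence") |>
      dplyr::inner_join(side, by = "sequence")
  }
  out
}

#' Write a library as FASTA (optionally full-length reads)
#'
#' @param lib tibble (sequence, count).
#' @param path output FASTA path.
#' @param full_reads if `TRUE`, write the 66-nt construct
#'   (forward primer + insert + reverse region) instead of the bare insert.
#' @param counts "duplicate" (one record per molecule) or "sidecar" (one
#'   record per unique sequence plus `<path>.counts.tsv`).
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, full_reads = FALSE,
                          counts = c("sidecar", "duplicate")) {
  counts <- match.arg(counts)
  seqs <- lib$sequence
  if (full_reads) seqs <- paste0(FWD_PRIMER, seqs, REV_PRIMER)
  if (counts == "duplicate") {
    seqs <- rep(seqs, times = lib$count)
    names(seqs) <- sprintf("read_%06d", seq_along(seqs))
  } else {
    names(seqs) <- sprintf("seq_%06d", seq_along(seqs))
    readr::write_tsv(
      tibble(sequence = lib$sequence, count = lib$count),
      paste0(path, ".counts.tsv")
    )
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Leftmost ungapped match of `primer` in `read` with <= max_mismatch
# Hamming mismatches; returns start position or NA.
hamming_find <- function(read, primer, max_mismatch, from = 1L) {
  n <- nchar(read)
  k <- nchar(primer)
  if (n - from + 1 < k) return(NA_integer_)
  rr <- charToRaw(read)
  pr <- charToRaw(primer)
  for (p in from:(n - k + 1)) {
    if (sum(rr[p:(p + k - 1)] != pr) <= max_mismatch) return(p)
  }
  NA_integer_
}

#' Extract the random 30-nt insert from library reads
#'
#' Locates the forward primer then the reverse anchor (each allowing up to
#' `max_mismatch` Hamming mismatches) and returns the span between them.
#' Reads are searched as given first, then reverse-complemented (paired-end
#' reads may arrive in either orientation). Rejection reasons: `not_found`
#' (primers not located), `bad_length` (span is not exactly 30 nt),
#' `ambiguous_base` (insert contains N).
#'
#' @param reads character vector over A, C, G, T, N.
#' @param fwd forward primer (default the study construct's 18-mer).
#' @param rev reverse anchor (default the study construct's 18-mer).
#' @param max_mismatch maximum Hamming mismatches per primer (default 1).
#' @return tibble (read, insert, status, reason): `status` "ok" or
#'   "rejected"; `insert` NA when rejected.
#' @export
extract_insert <- function(reads, fwd = FWD_PRIMER, rev = REV_PRIMER,
                           max_mismatch = 1L) {
  if (any(grepl("[^ACGTN]", reads))) {
    abort("Reads must contain only A, C, G, T, N.")
  }
  one <- function(read) {
    for (r in c(read, revcomp(read))) {
      pf <- hamming_find(r, fwd, max_mismatch)
      if (is.na(pf)) next
      insert_start <- pf + nchar(fwd)
      pr <- hamming_find(r, rev, max_mismatch, from = insert_start)
      if (is.na(pr)) next
      span <- pr - insert_start
      if (span != INSERT_LEN) {
        return(list(insert = NA_character_, status = "rejected",
                    reason = "bad_length"))
      }
      ins <- substr(r, insert_start, pr - 1L)
      if (grepl("N", ins, fixed = TRUE)) {
        return(list(insert = NA_character_, status = "rejected",
                    reason = "ambiguous_base"))
      }
      return(list(insert = ins, status = "ok", reason = NA_character_))
    }
    list(insert = NA_character_, status = "rejected", reason = "not_found")
  }
  res <- purrr::map(reads, one)
  tibble(
    read = reads,
    insert = map_chr(res, "insert"),
    status = map_chr(res, "status"),
    reason = map_chr(res, "reason")
  )
}

#' Rank unique sequences by count
#'
#' Descending by count; ties broken by ascending lexicographic order so the
#' top-N boundary is deterministic.
#'
#' @param records tibble (sequence, count); duplicate sequences are summed.
#' @return tibble (sequence, count), ranked.
#' @export
rank_unique <- function(records) {
  if (nrow(records) == 0) abort("`records` must be non-empty.")
  records |>
    as_tibble() |>
    group_by(.data$sequence) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(desc(.data$count), .data$sequence)
}

#' Take the top N ranked sequences
#'
#' @param ranked output of [rank_unique()].
#' @param n number of sequences (default 20000, the study's profile depth).
#' @return the first `min(n, nrow)` rows.
#' @export
top_n_sequences <- function(ranked, n = 20000L) {
  if (n < 1) abort("`n` must be >= 1.")
  head(ranked, n)
}

#' k-mer frequency profile of a sequence set
#'
#' Overlapping k-mer windows, normalised over all windows. Weighting
#' "by_unique" counts each unique sequence once (matching profiles over
#' "the top 20,000 sequences"); "by_count" weights windows by sequence
#' abundance.
#'
#' @param records tibble (sequence\[, count\]) or character vector.
#' @param k k-mer size, 1..5.
#' @param weighting "by_unique" or "by_count".
#' @return tibble (kmer, frequency) covering all 4^k k-mers (zeros kept),
#'   frequencies summing to 1.
#' @export
kmer_profile <- function(records, k = 1L, weighting = c("by_unique", "by_count")) {
  weighting <- match.arg(weighting)
  if (k < 1 || k > 5) abort("`k` must be in 1..5.")
  if (is.character(records)) records <- tibble(sequence = records, count = 1)
  if (any(nchar(records$sequence) < k)) abort("All sequences must be >= k long.")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(records$sequence), width = k, step = 1
  )
  w <- if (weighting == "by_count" && "count" %in% names(records)) {
    records$count
  } else {
    rep(1, nrow(records))
  }
  tot <- as.numeric(w %*% counts)
  tibble(kmer = colnames(counts), frequency = tot / sum(tot))
}

#' Round-over-round k-mer enrichment table
#'
#' For each library round, ranks unique sequences, keeps the top `n_top`,
#' and computes the k-mer profile. Rows within a round sum to 1.
#'
#' @param rounds list of [library_round()]s (or tibbles with a
#'   `round_index` attribute).
#' @param k k-mer size.
#' @param n_top profile depth (default 20000).
#' @param weighting passed to [kmer_profile()].
#' @return tibble (round, k, kmer, frequency) of class `enrichment_table`.
#' @export
enrichment_table <- function(rounds, k = 1L, n_top = 20000L,
                             weighting = c("by_unique", "by_count")) {
  weighting <- match.arg(weighting)
  if (length(rounds) == 0) abort("Need at least one round.")
  out <- purrr::imap(rounds, function(lib, idx) {
    r <- round_index(lib)
    if (is.na(r)) r <- idx - 1L
    top <- top_n_sequences(rank_unique(lib), n_top)
    kmer_profile(top, k = k, weighting = weighting) |>
      mutate(round = r, k = k, .before = 1)
  }) |>
    bind_rows()
  class(out) <- c("enrichment_table", class(out))
  out
}
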