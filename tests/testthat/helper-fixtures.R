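# Shared fixtures, built in code at test time.

# An A/C-favouring model: the qualitative selection pressure seen in the
# study (A and C enrich, G and T deplete over rounds).
ac_model <- function(temperature = 1) {
  affinity_model(
    base_weights = c(A = 0.1, C = 0.1, G = -0.1, T = -0.1),
    temperature = temperature
  )
}

# Deterministic 30-mers from a recycled template.
fixed_seq <- function(template) {
  paste(rep(strsplit(template, "")[[1]],
            length.out = 30), collapse = "")
}

# A dataset whose labels follow a purely compositional, linearly separable
# rule: positive iff the sequence has more than 15 A+C bases. Sequences
# sitting exactly on the boundary are dropped so the classes are (almost)
# balanced by the symmetry of the binomial count.
composition_dataset <- function(n = 400, seed = 1) {
  seqs <- withr::with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      mat <- matrix(sample(c("A", "C", "G", "T"), n * 30, replace = TRUE), n)
      cand <- apply(mat, 1, paste, collapse = "")
      ac <- vapply(strsplit(cand, ""),
                   function(s) sum(s %in% c("A", "C")), integer(1))
      out <- c(out, cand[ac != 15])
    }
    out[seq_len(n)]
  })
  ac <- vapply(strsplit(seqs, ""),
               function(s) sum(s %in% c("A", "C")), integer(1))
  tibble::tibble(sequence = seqs, label = as.integer(ac > 15))
}

# A dataset whose labels depend on base *order*: positives carry two fixed
# position-anchored 3-mers, negatives carry the same trinucleotides at
# random other anchors (so class composition is closely matched and only
# position/order separates the classes).
motif_dataset <- function(n = 400, seed = 1) {
  motifs <- list(c("ACG", 5L), c("TTC", 20L))
  withr::with_seed(seed, {
    half <- n %/% 2
    mk <- function(planted) {
      mat <- matrix(sample(c("A", "C", "G", "T"), 30, replace = TRUE), 1)
      s <- strsplit(apply(mat, 1, paste, collapse = ""), "")[[1]]
      for (m in motifs) {
        anchor <- if (planted) as.integer(m[2]) else {
          sample(setdiff(1:28, (as.integer(m[2]) - 2):(as.integer(m[2]) + 2)), 1)
        }
        s[anchor:(anchor + 2)] <- strsplit(m[1], "")[[1]]
      }
      paste(s, collapse = "")
    }
    tibble::tibble(
      sequence = c(
        vapply(seq_len(half), function(i) mk(TRUE), character(1)),
        vapply(seq_len(n - half), function(i) mk(FALSE), character(1))
      ),
      label = rep(c(1L, 0L), c(half, n - half))
    )
  })
}

# Small, fast neural spec overrides used throughout the tests.
small_cnn_spec <- function(...) {
  model_spec("cnn", filters = 12L, n_conv = 5L, fc = 16L,
             max_epochs = 25L, patience = 5L, ...)
}

# All permutations of a character vector (brute-force enumeration oracle).
combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}
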