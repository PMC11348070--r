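#' Build a binding-versus-random dataset from a library round
#'
#' Positives are the top `n_pos` ranked unique sequences of the round;
#' negatives are uniform random 30-mers rejection-sampled so that none
#' matches a positive (the check is against the positive set, not the
#' whole library).
#'
#' @param round_lib a [library_round()] with at least `n_pos` unique
#'   sequences.
#' @param n_pos,n_neg class sizes (study design: 10000 each).
#' @param seed integer seed; the dataset is bit-reproducible.
#' @return tibble (id, sequence, label) with label 1 = binding, 0 = random.
#' @export
make_binding_dataset <- function(round_lib, n_pos = 10000L, n_neg = 10000L,
                                 seed = 1L) {
  ranked <- rank_unique(round_lib)
  if (nrow(ranked) < n_pos) {
    abort(sprintf("Library has %d unique sequences; need %d positives.",
                  nrow(ranked), n_pos))
  }
  pos <- top_n_sequences(ranked, n_pos)$sequence
  pos_set <- new.env(hash = TRUE, parent = emptyenv())
  for (s in pos) assign(s, TRUE, envir = pos_set)
  neg <- withr::with_seed(seed, {
    out <- character(0)
    while (length(out) < n_neg) {
      cand <- random_sequences(n_neg - length(out) + 8L)
      cand <- cand[!vapply(cand, exists, logical(1), envir = pos_set)]
      out <- unique(c(out, cand))
    }
    out[seq_len(n_neg)]
  })
  tibble(
    id = sprintf("s%05d", seq_len(n_pos + n_neg)),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), c(n_pos, n_neg))
  )
}

stratified_split <- function(labels, fracs, seed) {
  withr::with_seed(seed, {
    assign_one <- function(idx) {
      n <- length(idx)
      sizes <- floor(fracs * n)
      sizes[1] <- n - sum(sizes[-1])
      sample(rep(seq_along(fracs), sizes))
    }
    out <- integer(length(labels))
    for (cl in unique(labels)) {
      sel <- which(labels == cl)
      out[sel] <- assign_one(sel)
    }
    out
  })
}

#' Train and evaluate a binding classifier with repeated random splits
#'
#' Per repeat: a fresh stratified 60/20/20 train/validation/test split,
#' model fit on the training set (neural families early-stop on validation
#' AUC), metrics on the held-out test set. Reports all five metrics per
#' repeat plus their mean and SD.
#'
#' @param data tibble (sequence, label) from [make_binding_dataset()].
#' @param spec a [model_spec()].
#' @param split length-3 fractions for train/validation/test.
#' @param repeats number of repeats (study design: 10).
#' @param seed integer seed.
#' @return an `eval_report`; `$models` holds the fitted model of each
#'   repeat, `$rocs` the per-repeat ROC curves.
#' @export
train_eval_binding <- function(data, spec, split = c(0.6, 0.2, 0.2),
                               repeats = 10L, seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-8, length(split) == 3)
  if (length(unique(data$label)) < 2) abort("Both classes must be present.")
  if (abs(mean(data$label) - 0.5) > 0.1) {
    warn("Classes are imbalanced; metrics at threshold 0.5 may mislead.")
  }
  X <- encode_for(spec, data$sequence)
  y <- data$label

  rows <- list()
  rocs <- list()
  models <- list()
  for (r in seq_len(repeats)) {
    split_seed <- derive_seed(seed, r)
    grp <- stratified_split(y, split, split_seed)
    attempt <- 0
    while (any(vapply(1:3, function(g) length(unique(y[grp == g])), 1L) < 2)) {
      # degenerate single-class partition: resample with the next seed
      attempt <- attempt + 1
      warn(sprintf("Repeat %d: degenerate split, resampling (attempt %d).",
                   r, attempt))
      split_seed <- derive_seed(split_seed, 1000 + attempt)
      grp <- stratified_split(y, split, split_seed)
    }
    tr <- grp == 1; va <- grp == 2; te <- grp == 3
    model <- fit_model(spec, subset_X(X, which(tr)), y[tr],
                       subset_X(X, which(va)), y[va],
                       seed = as.integer(derive_seed(seed, 100 + r)))
    prob <- if (spec$family == "rf") {
      as.numeric(stats::predict(
        model$fit, data = as.data.frame(subset_X(X, which(te)))
      )$predictions[, "1"])
    } else {
      nn_predict(spec$family, model$fit$params, subset_X(X, which(te)),
                 model$fit$config)
    }
    m <- compute_metrics(y[te], prob)
    rows[[r]] <- m |> mutate(repeat_id = r, .before = 1)
    rocs[[r]] <- attr(m, "roc") |> mutate(repeat_id = r, .before = 1)
    models[[r]] <- model
  }
  new_eval_report(bind_rows(rows), rocs = bind_rows(rocs),
                  extra = list(models = models, spec = spec))
}

first_conv_names <- function(n_freeze) {
  if (n_freeze == 0) character(0) else {
    as.vector(rbind(paste0("convW", seq_len(n_freeze)),
                    paste0("convb", seq_len(n_freeze))))
  }
}

stratified_folds <- function(labels, folds, seed) {
  withr::with_seed(seed, {
    out <- integer(length(labels))
    for (cl in unique(labels)) {
      sel <- which(labels == cl)
      if (length(sel) < folds) {
        abort("Stratification error: a fold would contain a single class.")
      }
      out[sel] <- sample(rep_len(seq_len(folds), length(sel)))
    }
    out
  })
}

#' Transfer-learn an affinity classifier from a binding CNN
#'
#' Takes a CNN pre-trained on the abundant binding-versus-random task and
#' fine-tunes it on the scarce high/low-affinity labels: the first
#' `n_freeze` convolutional layers are frozen (their parameters are
#' asserted bit-identical before and after fine-tuning) and the remaining
#' layers are updated. Evaluation is repeated stratified k-fold
#' cross-validation; per repeat, out-of-fold probabilities are pooled over
#' all sequences and summarised as one ROC/metric set.
#'
#' @param base_cnn a `binding_model` with family "cnn" from
#'   [train_eval_binding()] / `fit_model`.
#' @param affinity_data tibble (sequence, label) with label 1 = high
#'   affinity (tau >= 90 s or censored), 0 = low.
#' @param n_freeze number of frozen conv layers (default 3; set to
#'   `n_conv` to freeze all convolutions so only the head updates).
#' @param folds cross-validation folds (default 4).
#' @param repeats repeats with re-randomised folds (default 10).
#' @param seed integer seed.
#' @param fine_tune overrides for fine-tuning optimisation (list; e.g.
#'   `list(max_epochs = 60)`).
#' @return an `eval_report`; `$oof` holds pooled out-of-fold probabilities
#'   (repeat_id, sequence, label, prob), `$frozen_checked` is `TRUE`.
#' @export
transfer_affinity <- function(base_cnn, affinity_data, n_freeze = 3L,
                              folds = 4L, repeats = 10L, seed = 1L,
                              fine_tune = list()) {
  stopifnot(inherits(base_cnn, "binding_model"))
  if (base_cnn$spec$family != "cnn") {
    abort("Transfer learning requires a CNN base model.")
  }
  cfg <- utils::modifyList(base_cnn$fit$config, fine_tune)
  if (n_freeze < 0 || n_freeze > cfg$n_conv) {
    abort(sprintf("`n_freeze` must be in 0..%d.", cfg$n_conv))
  }
  frozen <- first_conv_names(n_freeze)
  y <- as.integer(affinity_data$label)
  X <- encode_onehot(affinity_data$sequence)

  rows <- list()
  rocs <- list()
  oof <- list()
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds, derive_seed(seed, r))
    prob <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      te <- fold_id == f
      params <- base_cnn$fit$params
      fit <- fit_nn("cnn", subset_X(X, which(!te)), y[!te],
                    config = cfg, frozen = frozen, params = params,
                    seed = as.integer(derive_seed(seed, 100 * r + f)))
      for (nm in frozen) {
        stopifnot(identical(fit$params[[nm]], params[[nm]]))
      }
      prob[te] <- nn_predict("cnn", fit$params, subset_X(X, which(te)), cfg)
    }
    m <- compute_metrics(y, prob)
    rows[[r]] <- m |> mutate(repeat_id = r, .before = 1)
    rocs[[r]] <- attr(m, "roc") |> mutate(repeat_id = r, .before = 1)
    oof[[r]] <- tibble(repeat_id = r, sequence = affinity_data$sequence,
                       label = y, prob = prob)
  }
  new_eval_report(
    bind_rows(rows), rocs = bind_rows(rocs),
    extra = list(oof = bind_rows(oof), frozen_checked = TRUE,
                 n_freeze = n_freeze)
  )
}

#' Rank candidate sequences by predicted affinity
#'
#' Scores candidates and returns the `n_top` highest- and `n_bottom`
#' lowest-probability sequences (the study design validated 5 + 5 from
#' 100,000 random candidates). Ties break by ascending lexicographic
#' order of the sequence.
#'
#' @param model a fitted `binding_model` (or list with a `predict_prob`able
#'   structure).
#' @param candidate_seqs character vector of 30-nt sequences.
#' @param n_top,n_bottom list sizes (default 5 each).
#' @return list with tibbles `top` and `bottom` (sequence, prob).
#' @export
predict_rank <- function(model, candidate_seqs, n_top = 5L, n_bottom = 5L) {
  prob <- predict_prob(model, candidate_seqs)
  scored <- tibble(sequence = candidate_seqs, prob = prob)
  top <- scored |> arrange(desc(.data$prob), .data$sequence) |> head(n_top)
  bottom <- scored |> arrange(.data$prob, .data$sequence) |> head(n_bottom)
  list(top = top, bottom = bottom)
}

#' Sequence-shuffling ablation of a fitted model
#'
#' Evaluates the model on the original test sequences and on
#' composition-preserving per-sequence permutations of them. A model that
#' relies only on base composition is unaffected; a model using base order
#' degrades. The paired comparison across shuffle replicates is a
#' sign-flip permutation test on the per-replicate AUC differences.
#'
#' @param model a fitted `binding_model`.
#' @param test_set tibble (sequence, label).
#' @param n_shuffles number of independent shuffle replicates.
#' @param seed integer seed.
#' @return list with `original` (metrics tibble), `shuffled` (per-replicate
#'   metrics), `auc_drop` (mean original - shuffled AUC), and `p_value`.
#' @export
shuffled_evaluation <- function(model, test_set, n_shuffles = 1L, seed = 1L) {
  y <- as.integer(test_set$label)
  orig <- compute_metrics(y, predict_prob(model, test_set$sequence))
  shuf <- purrr::map_dfr(seq_len(n_shuffles), function(s) {
    sh <- shuffle_sequences(test_set$sequence, seed = derive_seed(seed, s))
    compute_metrics(y, predict_prob(model, sh)) |>
      mutate(shuffle_id = s, .before = 1)
  })
  d <- orig$auc - shuf$auc
  p_value <- sign_flip_test(d)
  list(original = orig, shuffled = shuf,
       auc_drop = mean(d), p_value = p_value)
}

# One-sided sign-flip permutation test that mean(d) > 0; exact for
# n <= 12 differences, else 10,000 sampled flips.
sign_flip_test <- function(d, n_sample = 10000L) {
  n <- length(d)
  obs <- mean(d)
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- signs %*% d / n
    mean(null >= obs)
  } else {
    withr::with_seed(1L, {
      null <- replicate(n_sample, mean(d * sample(c(-1, 1), n, replace = TRUE)))
      (sum(null >= obs) + 1) / (n_sample + 1)
    })
  }
}
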