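test_that("metrics follow the rank-statistic AUC and 0.5-threshold rules", {
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)

  # enumerate the 4 label pairs: 3 concordant of 4
  m2 <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(m2$auc, 0.75)

  m3 <- compute_metrics(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(m3$auc, 0)

  expect_error(compute_metrics(c(1, 1), c(0.3, 0.6)), "both classes")
})

test_that("rank-statistic AUC equals trapezoidal ROC area exactly", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- if (rep %% 2) runif(n) else sample(seq(0, 1, 0.1), n, replace = TRUE)
    roc <- cntselex:::roc_points(labels, scores)
    expect_equal(cntselex:::auc_rank(labels, scores),
                 cntselex:::trapezoid_auc(roc), tolerance = 1e-12)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  }
})

test_that("binding datasets pair top-ranked positives with clean negatives", {
  rounds <- simulate_selection(ac_model(), n_rounds = 2, n_unique = 500,
                               n_draw = 800, seed = 2)
  ds <- make_binding_dataset(rounds[[3]], n_pos = 100, n_neg = 100, seed = 4)
  expect_equal(nrow(ds), 200)
  expect_equal(mean(ds$label), 0.5)
  expect_length(intersect(ds$sequence[ds$label == 1],
                          ds$sequence[ds$label == 0]), 0)
  ds2 <- make_binding_dataset(rounds[[3]], n_pos = 100, n_neg = 100, seed = 4)
  expect_identical(ds, ds2)

  tiny <- make_binding_dataset(rounds[[3]], n_pos = 10, n_neg = 10, seed = 1)
  expect_equal(nrow(tiny), 20)
  expect_error(make_binding_dataset(rounds[[3]], n_pos = 1e6), "unique")
})

test_that("RF on 2-mers separates a compositional rule and is deterministic", {
  ds <- composition_dataset(400, seed = 11)
  spec <- model_spec("rf", num_trees = 200)
  rep1 <- train_eval_binding(ds, spec, repeats = 3, seed = 5)
  expect_gte(min(tidy(rep1)$auc), 0.95)
  rep2 <- train_eval_binding(ds, spec, repeats = 3, seed = 5)
  expect_equal(tidy(rep1), tidy(rep2))
  g <- glance(rep1)
  expect_true(all(c("auc_mean", "auc_sd", "f1_mean") %in% names(g)))
})

test_that("permuted labels give chance-level AUC", {
  ds <- composition_dataset(400, seed = 21)
  ds$label <- withr::with_seed(3, sample(ds$label))
  rep <- train_eval_binding(ds, model_spec("rf", num_trees = 200),
                            repeats = 10, seed = 7)
  expect_lt(abs(mean(tidy(rep)$auc) - 0.5), 0.05)
})

test_that("each neural family learns a separable rule on small data", {
  ds <- composition_dataset(260, seed = 41)
  specs <- list(
    mlp = model_spec("mlp", hidden = c(16, 8), max_epochs = 40, patience = 8),
    cnn = model_spec("cnn", filters = 8, n_conv = 2, fc = 8,
                     max_epochs = 40, patience = 8),
    gru = model_spec("gru", hidden = 12, max_epochs = 40, patience = 8),
    transformer = model_spec("transformer", dim = 12, heads = 2, blocks = 1,
                             ff = 16, max_epochs = 40, patience = 8)
  )
  for (nm in names(specs)) {
    rep <- train_eval_binding(ds, specs[[nm]], repeats = 1, seed = 17)
    expect_gt(tidy(rep)$auc, 0.8, label = sprintf("%s AUC", nm))
  }
})

test_that("transfer learning freezes the first conv layers bitwise", {
  ds <- composition_dataset(300, seed = 51)
  base_rep <- train_eval_binding(
    ds, model_spec("cnn", filters = 8, n_conv = 5, fc = 8,
                   max_epochs = 20, patience = 5),
    repeats = 1, seed = 9
  )
  base <- base_rep$models[[1]]

  aff <- simulate_affinity_table(ac_model(), n = 48, n_high = 16,
                                 n_censored = 2, seed = 3)
  tr <- transfer_affinity(base, aff |> dplyr::select(sequence, label),
                          n_freeze = 3, folds = 4, repeats = 2, seed = 13,
                          fine_tune = list(max_epochs = 10))
  expect_true(tr$frozen_checked)
  expect_equal(nrow(tr$oof), 2 * 48)
  expect_true(all(!is.na(tr$oof$prob)))
  expect_equal(nrow(tidy(tr)), 2)

  # n_freeze = n_conv: only the head updates
  tr_all <- transfer_affinity(base, aff |> dplyr::select(sequence, label),
                              n_freeze = 5, folds = 4, repeats = 1, seed = 13,
                              fine_tune = list(max_epochs = 5))
  expect_true(tr_all$frozen_checked)
  expect_error(
    transfer_affinity(base, aff, n_freeze = 9),
    "0..5"
  )
  rf <- train_eval_binding(ds, model_spec("rf", num_trees = 50),
                           repeats = 1, seed = 1)
  expect_error(transfer_affinity(rf$models[[1]], aff), "CNN")
})

test_that("prediction ranking returns disjoint extremes with lexicographic ties", {
  ds <- composition_dataset(300, seed = 61)
  rep <- train_eval_binding(ds, model_spec("rf", num_trees = 100),
                            repeats = 1, seed = 2)
  model <- rep$models[[1]]
  cand <- generate_initial_library(200, seed = 77)$sequence
  rk <- predict_rank(model, cand, n_top = 5, n_bottom = 5)
  expect_equal(nrow(rk$top), 5)
  expect_equal(nrow(rk$bottom), 5)
  expect_length(intersect(rk$top$sequence, rk$bottom$sequence), 0)
  expect_true(min(rk$top$prob) >= max(rk$bottom$prob))

  # all-equal scores: heads/tails are the lexicographic extremes
  const_model <- structure(
    list(spec = model_spec("rf"), fit = NULL, seed = 1L),
    class = c("constant_model", "binding_model")
  )
  with_mocked_bindings(
    predict_prob = function(model, seqs) rep(0.5, length(seqs)),
    {
      rk2 <- predict_rank(const_model, cand)
      expect_equal(rk2$top$sequence, sort(cand)[1:5])
      expect_equal(rk2$bottom$sequence, sort(cand)[1:5])
    }
  )
})

test_that("shuffling hurts order-driven but not composition-driven models", {
  comp <- composition_dataset(300, seed = 71)
  rep_c <- train_eval_binding(comp, model_spec("rf", num_trees = 200),
                              repeats = 1, seed = 3)
  test_c <- composition_dataset(150, seed = 72)
  sh_c <- shuffled_evaluation(rep_c$models[[1]], test_c, n_shuffles = 5,
                              seed = 11)
  expect_lt(abs(sh_c$auc_drop), 0.02)
  expect_equal(nrow(sh_c$shuffled), 5)

  mot <- motif_dataset(300, seed = 73)
  rep_m <- train_eval_binding(
    mot, model_spec("cnn", filters = 12, n_conv = 3, fc = 12,
                    max_epochs = 40, patience = 8),
    repeats = 1, seed = 5
  )
  test_m <- motif_dataset(150, seed = 74)
  sh_m <- shuffled_evaluation(rep_m$models[[1]], test_m, n_shuffles = 5,
                              seed = 12)
  expect_gt(sh_m$auc_drop, 0.05)
  expect_lt(sh_m$p_value, 0.05)
})
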