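#' Specify a binding-classifier model
#'
#' Five families are supported: random forest (`rf`) and multi-layer
#' perceptron (`mlp`) on k-mer features (2-mers by default, the
#' best-performing k for these families), and convolutional (`cnn`),
#' recurrent (`gru`) and attention (`transformer`) networks on 30x4
#' one-hot input (positions along the sequence, bases as channels).
#'
#' Defaults: RF = 500 trees; MLP = hidden (128, 64); CNN = 5 same-padded
#' conv layers (64 filters, kernel 5, ReLU) -> global max pool -> dense 64
#' -> sigmoid; GRU = 1 layer, hidden 64, last-state readout; transformer =
#' 2 encoder blocks, 4 heads, model dim 64, feed-forward 128, learned
#' positional encoding, mean-pool readout. Neural families train with
#' cross-entropy, Adam (lr 1e-3), batch 64, early stopping on validation
#' AUC (patience 10, max 200 epochs). All overridable via `...`.
#'
#' @param family one of "rf", "mlp", "cnn", "gru", "transformer".
#' @param k k-mer size for k-mer-encoded families (default 2).
#' @param ... family-specific overrides (e.g. `filters`, `n_conv`, `hidden`,
#'   `num_trees`, `lr`, `batch`, `max_epochs`, `patience`, `dim`, `heads`,
#'   `blocks`, `ff`, `kernel`, `fc`).
#' @return a `model_spec` object.
#' @export
model_spec <- function(family = c("rf", "mlp", "cnn", "gru", "transformer"),
                       k = 2L, ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    rf = list(num_trees = 500L),
    mlp = list(hidden = c(128L, 64L)),
    cnn = list(n_conv = 5L, filters = 64L, kernel = 5L, fc = 64L,
               seq_len = INSERT_LEN),
    gru = list(hidden = 64L),
    transformer = list(blocks = 2L, heads = 4L, dim = 64L, ff = 128L,
                       seq_len = INSERT_LEN)
  )
  train_defaults <- list(lr = 1e-3, batch = 64L, max_epochs = 200L,
                         patience = 10L)
  overrides <- list(...)
  config <- utils::modifyList(c(defaults, train_defaults), overrides)
  structure(
    list(family = family, k = as.integer(k), config = config),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> family = %s", x$family))
  if (x$family %in% c("rf", "mlp")) cat(sprintf(" (k-mer k = %d)", x$k))
  cat("\n")
  invisible(x)
}

uses_kmer <- function(spec) spec$family %in% c("rf", "mlp")

encode_for <- function(spec, seqs) {
  if (uses_kmer(spec)) {
    encode_kmer(seqs, k = spec$k, normalize = TRUE)
  } else {
    encode_onehot(seqs)
  }
}

# Fit one model on already-encoded features. Returns a `binding_model`.
fit_model <- function(spec, X, y, Xval = NULL, yval = NULL, seed = 1L,
                      init_params = NULL, frozen = character()) {
  if (spec$family == "rf") {
    df <- as.data.frame(X)
    df$.label <- factor(y, levels = c(0, 1))
    fit <- ranger::ranger(
      dependent.variable.name = ".label", data = df,
      num.trees = spec$config$num_trees, probability = TRUE,
      importance = spec$config$importance %||% "none",
      seed = seed, num.threads = 1
    )
    model <- list(fit = fit)
  } else {
    cfg <- spec$config
    if (spec$family == "mlp") cfg$input_dim <- ncol(X)
    fit <- fit_nn(spec$family, X, y, Xval, yval, config = cfg,
                  frozen = frozen, params = init_params, seed = seed)
    model <- list(fit = fit)
  }
  structure(
    c(model, list(spec = spec, seed = seed)),
    class = "binding_model"
  )
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("<binding_model> family = %s, seed = %d\n", x$spec$family, x$seed))
  invisible(x)
}

#' Predict binding probabilities for sequences
#'
#' @param model a fitted `binding_model`.
#' @param seqs character vector of 30-nt sequences.
#' @return numeric vector of probabilities of the positive (binding) class.
#' @export
predict_prob <- function(model, seqs) {
  stopifnot(inherits(model, "binding_model"))
  X <- encode_for(model$spec, seqs)
  if (model$spec$family == "rf") {
    as.numeric(stats::predict(model$fit, data = as.data.frame(X))$predictions[, "1"])
  } else {
    cfg <- model$fit$config
    nn_predict(model$spec$family, model$fit$params, X, cfg)
  }
}
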