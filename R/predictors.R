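# Uniform predictor contract: POLR, the recorded random-forest and
# neural-network configurations, and two trivial baselines are
# interchangeable in every experiment. Every fitted predictor exposes
# predict_proba() returning an n x 8 probability matrix.

PREDICTOR_KINDS <- c("polr", "random_forest", "neural_net",
                     "majority_class", "uniform_random")

# Hyperparameters the study recorded for the delegated model families.
default_hyperparameters <- function(kind) {
  switch(kind,
    random_forest = list(mtry = 1L, ntree = 500L, criterion = "gini",
                         min_split = 2L, min_node = 1L),
    neural_net = list(hidden = c(1600L, 800L, 200L, 100L),
                      activation = "relu", output = "softmax",
                      batch_size = 64L, epochs = 24L,
                      loss = "categorical_crossentropy", optimizer = "rmsprop",
                      one_hot_inputs = TRUE, standardize_age = TRUE),
    polr = list(gcs_numeric = FALSE),
    list()
  )
}

#' Specify a predictor
#'
#' @param kind one of `"polr"`, `"random_forest"`, `"neural_net"`,
#'   `"majority_class"`, `"uniform_random"`. The random-forest
#'   (mtry 1, 500 trees, Gini impurity, default node sizes 2/1) and
#'   neural-network (hidden layers 1600-800-200-100 with ReLU, 8-way
#'   softmax, batch 64, 24 epochs, categorical cross-entropy, RMSprop,
#'   one-hot inputs with standardized age) hyperparameters are recorded
#'   as configuration; fitting them requires an installed backend.
#' @param hyperparameters overrides of the recorded defaults.
#' @param seed integer seed for any stochastic fitting or prediction.
#' @return A `gose_predictor_spec`.
#' @export
predictor_spec <- function(kind, hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind, PREDICTOR_KINDS)
  hp <- modifyList(default_hyperparameters(kind), hyperparameters)
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "gose_predictor_spec")
}

#' Fit a predictor to a design matrix and GOSE labels
#'
#' @param spec a [predictor_spec()].
#' @param design a `gose_design` from [encode_design()].
#' @param labels observed GOSE values (1-8).
#' @return A `gose_fitted_predictor` exposing [predict_proba()] and
#'   [predict_set()].
#' @export
fit_predictor <- function(spec, design, labels) {
  stopifnot(inherits(spec, "gose_predictor_spec"))
  labels <- as.integer(labels)
  stopifnot(all(labels >= 1L & labels <= 8L))
  fit <- switch(spec$kind,
    polr = polr_fit(design, labels),
    majority_class = {
      counts <- tabulate(labels, nbins = 8L)
      # modal class; ties toward the lower (worse) category
      list(mode = which.max(counts))
    },
    uniform_random = list(),
    random_forest = stop("random_forest backend requires the 'randomForest' ",
                         "package, which is not installed; the hyperparameter ",
                         "configuration is recorded in the spec only"),
    neural_net = stop("neural_net backend requires the 'keras' package, ",
                      "which is not installed; the hyperparameter ",
                      "configuration is recorded in the spec only")
  )
  structure(list(spec = spec, kind = spec$kind, fit = fit,
                 encoding = if (inherits(design, "gose_design")) design$encoding,
                 n_train = length(labels)),
            class = "gose_fitted_predictor")
}

#' Predicted category probabilities from a fitted predictor
#'
#' @param model a `gose_fitted_predictor`.
#' @param design a `gose_design` encoded like the training design.
#' @return `n x 8` probability matrix.
#' @export
predict_proba <- function(model, design) {
  stopifnot(inherits(model, "gose_fitted_predictor"))
  n <- nrow(as_design_matrix(design))
  switch(model$kind,
    polr = polr_predict(model$fit, design),
    majority_class = {
      out <- matrix(0, n, 8L, dimnames = list(NULL, paste0("p", 1:8)))
      out[, model$fit$mode] <- 1
      out
    },
    uniform_random = matrix(1 / 8, n, 8L, dimnames = list(NULL, paste0("p", 1:8))),
    stop("unsupported kind: ", model$kind)
  )
}

#' Bundle observed labels, point predictions and probability vectors
#'
#' Point predictions are the per-row argmax of the probabilities with ties
#' broken toward the lower (worse) GOSE category -- the package-wide
#' declared rule -- except for the `uniform_random` baseline, whose
#' prediction is a category sampled uniformly (so its accuracy converges
#' to 1/8 rather than being fixed by the tie rule).
#'
#' @param model a `gose_fitted_predictor`.
#' @param design a `gose_design` for the patients to predict.
#' @param observed their observed GOSE values.
#' @return A [prediction_set()].
#' @export
predict_set <- function(model, design, observed) {
  observed <- as.integer(observed)
  probs <- predict_proba(model, design)
  if (nrow(probs) != length(observed)) stop("length mismatch")
  predicted <- if (model$kind == "uniform_random") {
    with_seed(substream_seed(model$spec$seed, "uniform-predict"),
              sample.int(8L, nrow(probs), replace = TRUE))
  } else {
    argmax_low(probs)
  }
  prediction_set(observed, predicted, probs,
                 model_tag = model$kind)
}

#' Construct a prediction set
#'
#' @param observed,predicted integer GOSE vectors.
#' @param probabilities `n x 8` matrix; rows must be non-negative and sum
#'   to 1 within `1e-9`.
#' @param model_tag label carried into reports.
#' @return A `gose_prediction_set`.
#' @export
prediction_set <- function(observed, predicted, probabilities,
                           model_tag = "model") {
  observed <- as.integer(observed)
  predicted <- as.integer(predicted)
  probabilities <- as.matrix(probabilities)
  stopifnot(length(observed) == length(predicted),
            nrow(probabilities) == length(observed),
            ncol(probabilities) == 8L)
  if (length(observed)) {
    stopifnot(all(observed %in% GOSE_LEVELS), all(predicted %in% GOSE_LEVELS))
    if (any(probabilities < -1e-12) ||
        any(abs(rowSums(probabilities) - 1) > 1e-9)) {
      stop("probability vectors must be non-negative and sum to 1 (1e-9)")
    }
  }
  colnames(probabilities) <- paste0("p", 1:8)
  structure(list(observed = observed, predicted = predicted,
                 probabilities = probabilities, model_tag = model_tag),
            class = "gose_prediction_set")
}

#' @export
print.gose_prediction_set <- function(x, ...) {
  cat(sprintf("<gose_prediction_set> %s: n=%d, accuracy=%.3f\n", x$model_tag,
              length(x$observed),
              if (length(x$observed)) mean(x$observed == x$predicted) else NA))
  invisible(x)
}

#' Write / read predictions as CSV
#'
#' Flat schema `patient_id, observed, predicted, p1..p8`.
#'
#' @param ps a [prediction_set()].
#' @param path CSV path.
#' @param patient_id optional id column (defaults to the probability
#'   matrix rownames or a running index).
#' @return `path` invisibly; `read_prediction_set` returns the set.
#' @export
write_prediction_set <- function(ps, path, patient_id = NULL) {
  stopifnot(inherits(ps, "gose_prediction_set"))
  ids <- patient_id %||% rownames(ps$probabilities) %||%
    sprintf("P%06d", seq_along(ps$observed))
  df <- data.frame(patient_id = ids, observed = ps$observed,
                   predicted = ps$predicted, ps$probabilities)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prediction_set
#' @param model_tag label for the restored set.
#' @export
read_prediction_set <- function(path, model_tag = basename(path)) {
  df <- read.csv(path)
  probs <- as.matrix(df[, paste0("p", 1:8)])
  rownames(probs) <- df$patient_id
  prediction_set(df$observed, df$predicted, probs, model_tag = model_tag)
}
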