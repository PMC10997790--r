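# Study-protocol stages: GOSE-stratified train/test split, stratified
# k-fold cross-validation, and the sample-size / accuracy learning curve.

#' GOSE-stratified train/test split
#'
#' Randomized assignment constrained to keep the GOSE distribution
#' balanced between partitions: per observed GOSE level,
#' `floor(test_fraction * class size)` patients go to the test set
#' (round-half-down, so a singleton class stays in training), the rest to
#' training. Deterministic given `seed`.
#'
#' @param cohort a complete-case [cohort()].
#' @param test_fraction fraction in (0, 1); the study used 0.2.
#' @param seed integer seed.
#' @return A `gose_split`: disjoint `train_ids` / `test_ids` covering the
#'   cohort.
#' @export
stratified_split <- function(cohort, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(cohort, "gose_cohort"),
            test_fraction > 0, test_fraction < 1)
  y <- cohort$gose
  if (anyNA(y)) stop("cohort must be complete-case")
  test_ids <- with_seed(seed, {
    unlist(lapply(sort(unique(y)), function(lvl) {
      ids <- cohort$patient_id[y == lvl]
      k <- floor(test_fraction * length(ids))
      if (k == 0L) character(0) else sample(ids, k)
    }), use.names = FALSE)
  })
  structure(list(train_ids = setdiff(cohort$patient_id, test_ids),
                 test_ids = test_ids, test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "gose_split")
}

#' Apply a split plan to a cohort
#'
#' @param cohort the cohort the plan was built from.
#' @param split a `gose_split`.
#' @return List with `train` and `test` cohorts.
#' @export
split_cohort <- function(cohort, split) {
  stopifnot(inherits(cohort, "gose_cohort"), inherits(split, "gose_split"))
  take <- function(ids, tag) {
    out <- structure(as.data.frame(cohort)[cohort$patient_id %in% ids, , drop = FALSE],
                     class = c("gose_cohort", "data.frame"),
                     name = paste0(attr(cohort, "name"), "-", tag),
                     profile = attr(cohort, "profile"))
    rownames(out) <- NULL
    out
  }
  list(train = take(split$train_ids, "train"), test = take(split$test_ids, "test"))
}

#' Stratified k-fold cross-validation of a predictor
#'
#' Builds GOSE-stratified folds (per class, shuffled members are dealt
#' round-robin with a rotating offset, so per-class and overall fold sizes
#' are within one patient of equal), fits the predictor on each k-1
#' training portion and evaluates the held-out fold with [full_report()].
#'
#' @param cohort a complete-case [cohort()].
#' @param spec a [predictor_spec()].
#' @param k number of folds (the study used 10).
#' @param seed integer seed for the fold assignment.
#' @return A `gose_cv`: `fold_reports` (list of `gose_report`),
#'   `pooled_report` over the concatenated held-out predictions, and the
#'   `fold` assignment (named by patient_id).
#' @export
cross_validate <- function(cohort, spec, k = 10L, seed = 1L) {
  stopifnot(inherits(cohort, "gose_cohort"), k >= 2L, nrow(cohort) >= k)
  y <- cohort$gose
  if (anyNA(y)) stop("cohort must be complete-case")
  fold <- with_seed(seed, {
    assignment <- integer(nrow(cohort))
    offset <- 0L
    for (lvl in sort(unique(y))) {
      i <- sample(which(y == lvl))
      assignment[i] <- ((offset + seq_along(i) - 1L) %% k) + 1L
      offset <- (offset + length(i)) %% k
    }
    assignment
  })
  names(fold) <- cohort$patient_id
  standardize_age <- identical(spec$kind, "neural_net")
  gcs_numeric <- isTRUE(spec$hyperparameters$gcs_numeric)
  fold_sets <- vector("list", k)
  for (f in seq_len(k)) {
    train <- as.data.frame(cohort)[fold != f, , drop = FALSE]
    test <- as.data.frame(cohort)[fold == f, , drop = FALSE]
    train_c <- cohort(train, name = sprintf("fold%d-train", f))
    test_c <- cohort(test, name = sprintf("fold%d-test", f))
    design_train <- encode_design(train_c, standardize_age = standardize_age,
                                  gcs_numeric = gcs_numeric)
    model <- fit_predictor(spec, design_train, train_c$gose)
    design_test <- encode_design(test_c, encoding = design_train$encoding)
    fold_sets[[f]] <- predict_set(model, design_test, test_c$gose)
  }
  pooled <- prediction_set(
    observed = unlist(lapply(fold_sets, `[[`, "observed")),
    predicted = unlist(lapply(fold_sets, `[[`, "predicted")),
    probabilities = do.call(rbind, lapply(fold_sets, `[[`, "probabilities")),
    model_tag = paste0(spec$kind, "-cv", k)
  )
  structure(list(fold_reports = lapply(fold_sets, full_report),
                 pooled_report = full_report(pooled),
                 fold = fold, k = as.integer(k), spec = spec),
            class = "gose_cv")
}

#' @export
print.gose_cv <- function(x, ...) {
  cat(sprintf("<gose_cv> %d-fold, %s\npooled:\n", x$k, x$spec$kind))
  print(x$pooled_report)
  invisible(x)
}

#' Sample-size / accuracy learning curve
#'
#' For each training size `n`, simulates `replicates` fresh training
#' cohorts from the generator, fits a POLR model to each, and measures
#' accuracy on one fixed large simulated test cohort (so evaluation noise
#' is isolated from training-size variance). Replicates whose fit fails
#' are skipped and counted.
#'
#' @param config a [generator_config()]; training draws use substreams of
#'   its seed.
#' @param sizes increasing vector of training sizes.
#' @param replicates training cohorts per size.
#' @param test_n size of the fixed test cohort.
#' @param seed root seed (defaults to the config's).
#' @return A `gose_sscurve` data.frame with columns `n_train`,
#'   `mean_accuracy`, `sd_accuracy`, `replicates`; attribute
#'   `accuracies` holds the per-replicate values.
#' @export
sample_size_curve <- function(config, sizes, replicates = 10L,
                              test_n = 10000L, seed = config$seed) {
  stopifnot(inherits(config, "gose_genconfig"), length(sizes) >= 1L,
            replicates >= 1L, !is.unsorted(sizes, strictly = TRUE))
  test_config <- config
  test_config$n <- as.integer(test_n)
  test_config$seed <- substream_seed(seed, "sscurve-test")
  test_cohort <- simulate_cohort(test_config)
  test_design <- encode_design(test_cohort)
  acc <- matrix(NA_real_, length(sizes), replicates,
                dimnames = list(sizes, NULL))
  for (si in seq_along(sizes)) {
    for (r in seq_len(replicates)) {
      train_config <- config
      train_config$n <- as.integer(sizes[si])
      train_config$seed <- substream_seed(seed, sprintf("sscurve-%d-%d", sizes[si], r))
      train <- simulate_cohort(train_config)
      fit <- tryCatch(
        polr_fit(encode_design(train), train$gose,
                 control = polr_control(drop_collinear = TRUE)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      pred <- argmax_low(polr_predict(fit, test_design))
      acc[si, r] <- mean(pred == test_cohort$gose)
    }
  }
  out <- data.frame(
    n_train = as.integer(sizes),
    mean_accuracy = rowMeans(acc, na.rm = TRUE),
    sd_accuracy = apply(acc, 1, sd, na.rm = TRUE),
    replicates = rowSums(!is.na(acc))
  )
  attr(out, "accuracies") <- acc
  attr(out, "test_n") <- as.integer(test_n)
  class(out) <- c("gose_sscurve", "data.frame")
  out
}
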