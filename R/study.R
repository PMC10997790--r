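# End-to-end study runner and figure generation: cohort acquisition
# (file or generator profile), stratified split, model fitting, test-set
# evaluation, figures, and a machine-readable manifest. Figures are
# artifacts, not assertions -- tests check the numeric tables beneath them.

#' Run the full study pipeline from one configuration
#'
#' Configuration fields (R list, or a JSON/YAML file path):
#' \describe{
#'   \item{cohort}{either `list(profile=, n=)` for a synthetic cohort or
#'     `list(path=)` for a cohort CSV.}
#'   \item{predictors}{character vector of predictor kinds or list of
#'     [predictor_spec()]-style lists.}
#'   \item{split}{`list(test_fraction=)`, default 0.2.}
#'   \item{ensemble}{optional `list(members=, target_per_class=)`; adds a
#'     balanced-undersampling POLR ensemble.}
#'   \item{seed}{root seed; every stage derives a named substream.}
#' }
#' Writes the cohort snapshot, per-model predictions CSV, metrics JSON, a
#' combined summary TSV, the figure files, and `manifest.json` recording
#' seeds, versions and every file produced.
#'
#' @param config list or path to a JSON/YAML config file.
#' @param outdir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_study <- function(config, outdir) {
  config <- load_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  files <- character(0)
  log <- function(...) message("[goseprog] ", sprintf(...))

  co <- if (!is.null(config$cohort$path)) {
    log("reading cohort from %s", config$cohort$path)
    read_cohort(config$cohort$path)
  } else {
    log("simulating %s cohort, n=%d", config$cohort$profile, config$cohort$n)
    simulate_cohort(profile_config(config$cohort$profile, config$cohort$n,
                                   seed = substream_seed(seed, "cohort")))
  }
  co <- complete_cases(co)
  log("complete cases: %d (removed %d)", nrow(co), attr(co, "n_removed"))
  f <- file.path(outdir, "cohort.csv"); write_cohort(co, f); files <- c(files, f)

  split <- stratified_split(co, config$split$test_fraction,
                            seed = substream_seed(seed, "split"))
  parts <- split_cohort(co, split)
  log("split: %d train / %d test", nrow(parts$train), nrow(parts$test))

  summary_rows <- list()
  run_model <- function(tag, probs, predicted, observed) {
    ps <- prediction_set(observed, predicted, probs, model_tag = tag)
    f1 <- file.path(outdir, paste0("predictions_", tag, ".csv"))
    write_prediction_set(ps, f1, patient_id = parts$test$patient_id)
    report <- full_report(ps)
    f2 <- file.path(outdir, paste0("metrics_", tag, ".json"))
    jsonlite::write_json(report_to_list(report), f2, auto_unbox = TRUE, digits = NA)
    figs <- render_figures(ps, outdir, prefix = tag)
    files <<- c(files, f1, f2, figs)
    summary_rows[[tag]] <<- report_row(report)
    log("%s: accuracy=%.3f tcpd=%.3f", tag, report$accuracy, report$tcpd)
  }

  for (spec in config$predictors) {
    standardize_age <- identical(spec$kind, "neural_net")
    design_train <- encode_design(parts$train, standardize_age = standardize_age,
                                  gcs_numeric = isTRUE(spec$hyperparameters$gcs_numeric))
    model <- fit_predictor(spec, design_train, parts$train$gose)
    design_test <- encode_design(parts$test, encoding = design_train$encoding)
    ps <- predict_set(model, design_test, parts$test$gose)
    run_model(spec$kind, ps$probabilities, ps$predicted, ps$observed)
  }

  if (!is.null(config$ensemble)) {
    ens <- fit_ensemble(parts$train, m = config$ensemble$members,
                        target_per_class = config$ensemble$target_per_class %||% "auto",
                        seed = substream_seed(seed, "ensemble"))
    design_test <- encode_design(parts$test)
    probs <- ensemble_predict(ens, design_test)
    run_model("polr_ensemble", probs, argmax_low(probs), parts$test$gose)
  }

  tsv <- file.path(outdir, "table_summary.tsv")
  write.table(do.call(rbind, summary_rows), tsv, sep = "\t",
              row.names = FALSE, quote = FALSE)
  files <- c(files, tsv)

  manifest <- list(
    package = "goseprog",
    version = as.character(utils::packageVersion("goseprog")),
    r_version = R.version.string,
    seed = seed,
    substreams = list(cohort = substream_seed(seed, "cohort"),
                      split = substream_seed(seed, "split"),
                      ensemble = substream_seed(seed, "ensemble")),
    files = basename(files)
  )
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

report_to_list <- function(report) {
  out <- unclass(report)
  out$confusion <- unname(apply(report$confusion, 1, as.list))
  out$error_distribution <- as.list(report$error_distribution)
  out
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML config requires the 'yaml' package; use JSON instead")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$cohort) ||
      (is.null(config$cohort$path) &&
       (is.null(config$cohort$profile) || is.null(config$cohort$n)))) {
    stop("config validation: 'cohort' needs either $path or $profile + $n")
  }
  if ((is.null(config$predictors) || length(config$predictors) == 0L) &&
      is.null(config$ensemble)) {
    stop("config validation: no predictor specified")
  }
  preds <- config$predictors %||% list()
  if (is.character(preds)) preds <- as.list(preds)
  config$predictors <- lapply(preds, function(p) {
    if (is.character(p)) predictor_spec(p, seed = config$seed %||% 1L)
    else predictor_spec(p$kind, p$hyperparameters %||% list(),
                        seed = p$seed %||% config$seed %||% 1L)
  })
  config$split <- modifyList(list(test_fraction = 0.2), config$split %||% list())
  config$seed <- as.integer(config$seed %||% 1L)
  if (!is.null(config$ensemble)) {
    config$ensemble$members <- as.integer(config$ensemble$members %||% 200L)
  }
  config
}

#' Render the study's figure set for one prediction set
#'
#' Writes four figure types: confusion heat map (rows observed, columns
#' predicted), paired predicted/observed category-proportion bars, the
#' error-distribution histogram over -7..+7, and per-category calibration
#' plots with a band of two binomial standard errors (categories that
#' received no probability mass are skipped).
#'
#' @param prediction_set a [prediction_set()].
#' @param outdir output directory.
#' @param prefix file-name prefix (defaults to the model tag).
#' @param format `"png"` or `"svg"`.
#' @return Character vector of the files written.
#' @export
render_figures <- function(prediction_set, outdir, prefix = NULL,
                           format = "png") {
  ps <- prediction_set
  stopifnot(inherits(ps, "gose_prediction_set"), length(ps$observed) > 0)
  prefix <- prefix %||% ps$model_tag
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dev <- match.arg(format, c("png", "svg"))
  out <- character(0)
  save_plot <- function(plot, name, width = 6, height = 5) {
    f <- file.path(outdir, paste0(prefix, "_", name, ".", dev))
    ggplot2::ggsave(f, plot, width = width, height = height, dpi = 120)
    out <<- c(out, f)
  }

  cm <- as.data.frame(as.table(confusion_matrix(ps$predicted, ps$observed)))
  names(cm) <- c("observed", "predicted", "count")
  save_plot(
    ggplot2::ggplot(cm, ggplot2::aes(x = predicted, y = observed, fill = count)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = count), size = 3) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
      ggplot2::labs(title = paste0(ps$model_tag, ": observed GOSE over predicted GOSE")),
    "confusion")

  cpd <- category_proportion_discrepancy(ps$predicted, ps$observed)
  props <- data.frame(gose = factor(rep(GOSE_LEVELS, 2)),
                      proportion = c(cpd$pcp, cpd$ocp),
                      which = rep(c("predicted", "observed"), each = 8))
  save_plot(
    ggplot2::ggplot(props, ggplot2::aes(x = gose, y = proportion, fill = which)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(title = paste0(ps$model_tag, ": category proportions")),
    "category_proportions")

  ed <- error_distribution(ps$predicted, ps$observed)
  edf <- data.frame(error = factor(names(ed), levels = as.character(-7:7)),
                    count = as.integer(ed))
  save_plot(
    ggplot2::ggplot(edf, ggplot2::aes(x = error, y = count)) +
      ggplot2::geom_col(fill = "grey40") +
      ggplot2::labs(title = paste0(ps$model_tag, ": observed minus predicted GOSE")),
    "error_distribution")

  with_mass <- which(colSums(ps$probabilities) > 0)
  cal <- do.call(rbind, lapply(with_mass, function(j) {
    cc <- suppressWarnings(calibration_curve(ps$probabilities, ps$observed, j,
                                             n_bins = min(10L, max(2L, length(ps$observed) %/% 10L))))
    cbind(gose = j, as.data.frame(cc))
  }))
  save_plot(
    ggplot2::ggplot(cal, ggplot2::aes(x = mean_predicted, y = observed_freq)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, observed_freq - 2 * se),
                                        ymax = pmin(1, observed_freq + 2 * se)),
                           fill = "grey80") +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_abline(linetype = "dashed") +
      ggplot2::facet_wrap(~gose, scales = "free") +
      ggplot2::labs(title = paste0(ps$model_tag, ": calibration"),
                    x = "mean predicted probability", y = "observed frequency"),
    "calibration", width = 8, height = 6)

  out
}
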