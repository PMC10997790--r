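# Balanced-undersampling ensemble: many POLR models, each trained on a
# per-class balanced subsample of the cohort, aggregated by the per-category
# median of the predicted probabilities (then renormalized). Mitigates the
# bias toward the majority GOSE categories at a slight accuracy cost.

#' Draw one balanced undersample of a cohort
#'
#' Samples without replacement `min(target_per_class, class size)` patients
#' from every observed GOSE level; with `target_per_class = "auto"` the
#' target is the smallest observed class size, so every class contributes
#' equally.
#'
#' @param cohort a complete-case [cohort()].
#' @param target_per_class positive count or `"auto"`.
#' @param seed integer seed; the draw is reproducible from it.
#' @return The subsampled cohort (original record order preserved).
#' @export
balanced_undersample <- function(cohort, target_per_class = "auto", seed = 1L) {
  stopifnot(inherits(cohort, "gose_cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort")
  y <- cohort$gose
  if (anyNA(y)) stop("cohort must be complete-case (missing GOSE)")
  counts <- table(y)
  target <- if (identical(target_per_class, "auto")) min(counts)
            else as.integer(target_per_class)
  stopifnot(target >= 1L)
  keep <- with_seed(seed, {
    unlist(lapply(sort(unique(y)), function(lvl) {
      i <- which(y == lvl)
      if (length(i) <= target) i else sample(i, target)
    }), use.names = FALSE)
  })
  out <- structure(as.data.frame(cohort)[sort(keep), , drop = FALSE],
                   class = c("gose_cohort", "data.frame"),
                   name = paste0(attr(cohort, "name"), "-balanced"),
                   profile = attr(cohort, "profile"))
  rownames(out) <- NULL
  out
}

#' Fit a balanced-undersampling POLR ensemble
#'
#' Fits `m` proportional-odds models, each on an independent balanced
#' subsample (substream-seeded, so any member is reproducible in
#' isolation). Members whose optimizer does not converge are refitted on a
#' fresh subsample up to `retry_max` times, with retry counts logged in
#' the result. Subsamples can lose covariate levels, so member fits drop
#' collinear columns (`polr_control(drop_collinear = TRUE)`); a member
#' that never observed a GOSE level predicts probability 0 for it, which
#' is how the rarest level (GOSE 2) can remain unpredicted even by the
#' ensemble.
#'
#' @param cohort a complete-case [cohort()].
#' @param m number of members (the study used 10,000; desk-scale default
#'   200).
#' @param target_per_class per-class subsample size or `"auto"` (smallest
#'   class).
#' @param seed root seed.
#' @param retry_max refit attempts per member before giving up.
#' @param on_exhaust `"error"` (default) or `"keep"` the last
#'   non-converged fit, flagged.
#' @return A `gose_ensemble`: `members` (list of `gose_polr`),
#'   `subsample_plan` (list of patient-id vectors), `aggregation`
#'   (`"median"`), `retries`, `encoding`, `seed`.
#' @export
fit_ensemble <- function(cohort, m = 200L, target_per_class = "auto",
                         seed = 1L, retry_max = 10L,
                         on_exhaust = c("error", "keep")) {
  on_exhaust <- match.arg(on_exhaust)
  stopifnot(inherits(cohort, "gose_cohort"), m >= 1L)
  encoding <- encode_design(cohort)$encoding
  members <- vector("list", m)
  plan <- vector("list", m)
  retries <- integer(m)
  for (i in seq_len(m)) {
    fit <- NULL
    for (attempt in 0:retry_max) {
      sub_seed <- substream_seed(seed, sprintf("member-%d-try-%d", i, attempt))
      sub <- balanced_undersample(cohort, target_per_class, seed = sub_seed)
      fit_try <- tryCatch(
        polr_fit(encode_design(sub), sub$gose,
                 control = polr_control(drop_collinear = TRUE)),
        error = function(e) NULL
      )
      if (!is.null(fit_try) && fit_try$converged) {
        fit <- fit_try
        retries[i] <- attempt
        plan[[i]] <- sub$patient_id
        break
      }
      if (attempt == retry_max) {
        if (on_exhaust == "error" || is.null(fit_try)) {
          stop(sprintf(paste0("ensemble member %d failed to converge after %d ",
                              "retries (last grad norm: %s)"),
                       i, retry_max,
                       if (is.null(fit_try)) "fit error"
                       else format(fit_try$grad_norm)))
        }
        fit <- fit_try
        retries[i] <- attempt
        plan[[i]] <- sub$patient_id
      }
    }
    members[[i]] <- fit
  }
  structure(list(members = members, m = m, subsample_plan = plan,
                 aggregation = "median", retries = retries,
                 encoding = encoding, seed = as.integer(seed)),
            class = "gose_ensemble")
}

#' @export
print.gose_ensemble <- function(x, ...) {
  cat(sprintf("<gose_ensemble> m=%d members, median aggregation, %d retries total\n",
              x$m, sum(x$retries)))
  cat(sprintf("training ids covered by >=1 member: %d\n",
              length(unique(unlist(x$subsample_plan)))))
  invisible(x)
}

#' Ensemble predictions by median probability aggregation
#'
#' For every patient and GOSE category, takes the median across members of
#' the predicted probability, then renormalizes the 8 medians to sum to 1
#' (medians of proper vectors are not themselves proper). The median --
#' rather than the mean -- follows from the skewness of the members'
#' predicted probabilities.
#'
#' @param model a `gose_ensemble`.
#' @param design a `gose_design` encoded like the training cohort.
#' @return `n x 8` probability matrix.
#' @export
ensemble_predict <- function(model, design) {
  stopifnot(inherits(model, "gose_ensemble"))
  if (model$m == 0L || !length(model$members)) stop("empty ensemble")
  per_member <- lapply(model$members, polr_predict, design = design)
  arr <- array(unlist(per_member), dim = c(dim(per_member[[1]]), model$m))
  med <- apply(arr, c(1, 2), median)
  out <- med / rowSums(med)
  dimnames(out) <- dimnames(per_member[[1]])
  out
}
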