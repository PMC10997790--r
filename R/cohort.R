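# Patient cohorts: a validated data.frame of IMPACT admission variables plus
# the observed 8-level GOSE outcome, with reading/writing in a fixed CSV
# schema and dummy encoding into a design matrix.

COHORT_COLUMNS <- c("patient_id", "age", "gcs_motor", "pupils", "marshall", "gose")
MODEL_FIELDS <- c("age", "gcs_motor", "pupils", "marshall", "gose")

#' Construct a patient cohort
#'
#' A cohort is an ordered set of adult TBI patient records carrying the
#' IMPACT admission variables (age in years, GCS-motor score 1-6, pupillary
#' reaction, Marshall CT class) and the observed GOSE outcome (1 = death to
#' 8 = upper good recovery), assessed months after injury. Fields other
#' than `patient_id` may be missing (`NA`); [complete_cases()] restricts to
#' fully observed records before modelling.
#'
#' @param data data.frame with columns `patient_id`, `age`, `gcs_motor`,
#'   `pupils` (one of `"both"`, `"one"`, `"none"` reacting), `marshall`
#'   (one of `"diffuse_I"` .. `"diffuse_IV"`, `"evacuated_mass"`,
#'   `"non_evacuated_mass"`), and `gose` (integer 1-8).
#' @param name cohort label.
#' @param profile optional generator profile tag
#'   (`"uppsala"`, `"leuven"`, `"protect"`, `"custom"`).
#' @return An object of class `gose_cohort` (a validated data.frame).
#' @export
cohort <- function(data, name = "cohort", profile = NULL) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(COHORT_COLUMNS, names(data))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[, COHORT_COLUMNS]
  data$patient_id <- as.character(data$patient_id)
  data$age <- as.numeric(data$age)
  data$gcs_motor <- as.integer(data$gcs_motor)
  data$pupils <- as.character(data$pupils)
  data$marshall <- as.character(data$marshall)
  data$gose <- as.integer(data$gose)
  validate_cohort_fields(data)
  if (anyDuplicated(data$patient_id)) {
    stop("validation error: duplicated patient_id: ",
         paste(unique(data$patient_id[duplicated(data$patient_id)]), collapse = ", "))
  }
  rownames(data) <- NULL
  structure(data, class = c("gose_cohort", "data.frame"),
            name = name, profile = profile)
}

validate_cohort_fields <- function(data) {
  bad_row <- function(ok, field, rule) {
    bad <- which(!ok)
    if (length(bad)) {
      stop("validation error: ", field, " ", rule, " violated at row(s) ",
           paste(head(bad, 5L), collapse = ", "))
    }
  }
  bad_row(!is.na(data$patient_id) & nzchar(data$patient_id), "patient_id", "nonempty")
  bad_row(is.na(data$age) | data$age >= 18, "age", ">= 18 (adults only)")
  bad_row(is.na(data$gcs_motor) | data$gcs_motor %in% GCSM_LEVELS, "gcs_motor", "in 1..6")
  bad_row(is.na(data$pupils) | data$pupils %in% PUPIL_LEVELS, "pupils",
          paste0("in {", paste(PUPIL_LEVELS, collapse = ","), "}"))
  bad_row(is.na(data$marshall) | data$marshall %in% MARSHALL_LEVELS, "marshall",
          "in the 6-level Marshall classification")
  bad_row(is.na(data$gose) | (data$gose >= 1L & data$gose <= 8L), "gose", "in 1..8")
  invisible(TRUE)
}

#' @export
print.gose_cohort <- function(x, ...) {
  cat(sprintf("<gose_cohort> '%s'%s: %d patients\n", attr(x, "name"),
              if (!is.null(attr(x, "profile"))) paste0(" [", attr(x, "profile"), "]") else "",
              nrow(x)))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read a cohort from CSV
#'
#' The canonical schema is `patient_id,age,gcs_motor,pupils,marshall,gose`
#' (header row, comma-separated, UTF-8); columns may appear in any order,
#' and missing values are an empty string or `NA`. A `schema` mapping
#' renames registry export headers onto the canonical ones.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical column
#'   name -> column name in the file.
#' @param name cohort label (defaults to the file name).
#' @return A [cohort()].
#' @export
read_cohort <- function(path, schema = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = c("", "NA"))
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src)) {
      stop("schema error: file lacks column(s): ", paste(missing_src, collapse = ", "))
    }
    for (canonical in names(schema)) {
      names(raw)[names(raw) == schema[[canonical]]] <- canonical
    }
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  # Flag unparseable numerics by row rather than silently coercing to NA.
  for (field in c("age", "gcs_motor", "gose")) {
    v <- raw[[field]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop("validation error: unparseable ", field, " at row(s) ",
           paste(head(bad, 5L), collapse = ", "))
    }
    raw[[field]] <- num
  }
  cohort(raw, name = name %||% basename(path))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: fixed column order, empty string for missing
#' values, no row names.
#'
#' @param cohort a [cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "gose_cohort"))
  write.csv(as.data.frame(cohort)[, COHORT_COLUMNS], path,
            row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict a cohort to complete cases
#'
#' Keeps only records with all five model fields observed (age, GCS-motor,
#' pupils, Marshall class, GOSE), preserving order. The number of removed
#' records is attached as attribute `n_removed`; no imputation is ever
#' performed.
#'
#' @param cohort a [cohort()].
#' @return The filtered cohort with attribute `n_removed`.
#' @export
complete_cases <- function(cohort) {
  stopifnot(inherits(cohort, "gose_cohort"))
  keep <- complete.cases(as.data.frame(cohort)[, MODEL_FIELDS])
  out <- structure(as.data.frame(cohort)[keep, , drop = FALSE],
                   class = c("gose_cohort", "data.frame"),
                   name = attr(cohort, "name"), profile = attr(cohort, "profile"))
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Encode a cohort into a model design matrix
#'
#' Categorical covariates enter as unordered 0/1 dummies against declared
#' reference levels (GCS-motor 1, both pupils reacting, Marshall diffuse I);
#' age is continuous, optionally standardized. When an `encoding` from a
#' training partition is supplied, its reference levels and age statistics
#' are reused so test data are encoded without leakage.
#'
#' @param cohort a complete-case [cohort()].
#' @param standardize_age standardize age to mean 0 / unit variance
#'   (training-partition statistics). Used by the neural-network input
#'   path; the POLR and random-forest paths use raw age.
#' @param gcs_numeric treat the GCS-motor score as a single numeric column
#'   instead of 5 dummies.
#' @param encoding an `encoding_spec` from a previous call, for encoding
#'   held-out data consistently.
#' @return A `gose_design`: list with the numeric `matrix` (rows aligned to
#'   records) and the `encoding` spec (serializable with
#'   [write_encoding()]).
#' @export
encode_design <- function(cohort, standardize_age = FALSE, gcs_numeric = FALSE,
                          encoding = NULL) {
  stopifnot(inherits(cohort, "gose_cohort"))
  df <- as.data.frame(cohort)
  if (anyNA(df[, c("age", "gcs_motor", "pupils", "marshall")])) {
    stop("encode_design requires a complete-case cohort (see complete_cases())")
  }
  if (is.null(encoding)) {
    encoding <- list(
      references = list(gcs_motor = 1L, pupils = "both", marshall = "diffuse_I"),
      gcs_numeric = isTRUE(gcs_numeric),
      standardize_age = isTRUE(standardize_age),
      age_center = if (standardize_age) mean(df$age) else 0,
      age_scale = if (standardize_age) sd(df$age) else 1
    )
    if (standardize_age && (is.na(encoding$age_scale) || encoding$age_scale == 0)) {
      stop("cannot standardize age: zero variance in training partition")
    }
  } else {
    check_encoding_spec(encoding)
  }
  check_levels <- function(values, allowed, field) {
    bad <- setdiff(unique(values), allowed)
    if (length(bad)) {
      stop("encoding error: unseen ", field, " level(s): ", paste(bad, collapse = ", "))
    }
  }
  check_levels(df$gcs_motor, GCSM_LEVELS, "gcs_motor")
  check_levels(df$pupils, PUPIL_LEVELS, "pupils")
  check_levels(df$marshall, MARSHALL_LEVELS, "marshall")

  age <- (df$age - encoding$age_center) / encoding$age_scale
  cols <- list(age = age)
  if (encoding$gcs_numeric) {
    cols$gcs_motor <- as.numeric(df$gcs_motor)
  } else {
    for (lvl in setdiff(GCSM_LEVELS, encoding$references$gcs_motor)) {
      cols[[paste0("gcs_motor_", lvl)]] <- as.numeric(df$gcs_motor == lvl)
    }
  }
  for (lvl in setdiff(PUPIL_LEVELS, encoding$references$pupils)) {
    cols[[paste0("pupils_", lvl)]] <- as.numeric(df$pupils == lvl)
  }
  for (lvl in setdiff(MARSHALL_LEVELS, encoding$references$marshall)) {
    cols[[paste0("marshall_", lvl)]] <- as.numeric(df$marshall == lvl)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  rownames(X) <- df$patient_id
  structure(list(matrix = X, encoding = encoding), class = "gose_design")
}

check_encoding_spec <- function(encoding) {
  stopifnot(is.list(encoding),
            all(c("references", "gcs_numeric", "standardize_age",
                  "age_center", "age_scale") %in% names(encoding)))
  invisible(TRUE)
}

#' @export
print.gose_design <- function(x, ...) {
  cat(sprintf("<gose_design> %d x %d [%s]\n", nrow(x$matrix), ncol(x$matrix),
              paste(colnames(x$matrix), collapse = ", ")))
  invisible(x)
}

#' Serialize / restore an encoding spec as JSON
#'
#' The encoding spec travels alongside any fitted model so held-out data
#' can be encoded identically.
#'
#' @param encoding encoding spec from [encode_design()].
#' @param path JSON file path.
#' @return `path` invisibly; `read_encoding` returns the spec.
#' @export
write_encoding <- function(encoding, path) {
  check_encoding_spec(encoding)
  jsonlite::write_json(encoding, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_encoding
#' @export
read_encoding <- function(path) {
  encoding <- jsonlite::read_json(path, simplifyVector = TRUE)
  encoding$references <- as.list(encoding$references)
  check_encoding_spec(encoding)
  encoding
}
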