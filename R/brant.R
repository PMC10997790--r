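# Brant (1990) test of the parallel-regression assumption: fit the J-1
# binary logistic regressions P(Y > level_j | x) separately, then test
# whether their slope vectors are equal with a Wald statistic whose
# covariance uses the shared-observation cross-split blocks of the original
# construction (no bootstrap).

#' Brant test of the proportional-odds (parallel regression) assumption
#'
#' For each cumulative split between adjacent observed outcome levels, a
#' binary logistic regression `I(y > level_j) ~ x` is fitted. Under the
#' proportional-odds model all split-specific slope vectors are equal; the
#' omnibus Wald statistic tests that equality with
#' `df = (J - 2) * p` for `J` observed levels and `p` design columns, and
#' per-variable statistics test each column across splits with
#' `df = J - 2`. When rare outcome levels make adjacent cumulative splits
#' nearly identical, the contrast covariance is numerically singular; the
#' quadratic form is then evaluated on its retained eigen-directions, the
#' degrees of freedom are reduced accordingly (`omnibus_df` vs
#' `nominal_df`), and a warning is raised.
#'
#' @param design a `gose_design` or numeric matrix (no intercept column).
#' @param labels observed GOSE values aligned to the design rows.
#' @return A `gose_brant` object: `omnibus_stat`, `omnibus_df`,
#'   `omnibus_p`, and a `per_variable` data.frame.
#' @references Brant, R. (1990). Assessing proportionality in the
#'   proportional odds model for ordinal logistic regression.
#'   Biometrics 46, 1171-1178.
#' @export
brant_test <- function(design, labels) {
  X <- as_design_matrix(design)
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(X))
  observed <- sort(unique(y))
  J <- length(observed)
  if (J < 3L) stop("Brant test needs >= 3 observed outcome levels")
  p <- ncol(X)
  n <- nrow(X)
  X1 <- cbind(`(Intercept)` = 1, X)
  cols <- colnames(X) %||% paste0("x", seq_len(p))

  K <- J - 1L                       # number of cumulative splits
  betas <- matrix(NA_real_, p, K)   # slopes only, one column per split
  pis <- matrix(NA_real_, n, K)     # fitted P(y > level_j)
  for (j in seq_len(K)) {
    z <- as.numeric(y > observed[j])
    fitj <- suppressWarnings(
      glm.fit(X1, z, family = binomial(), control = list(maxit = 100))
    )
    betas[, j] <- fitj$coefficients[-1]
    pis[, j] <- fitj$fitted.values
  }

  # Joint covariance of the stacked slope estimates. For splits j <= l,
  # cov block = (X'W_jj X)^-1 X'W_jl X (X'W_ll X)^-1 with
  # W_jl = diag(pi_l - pi_j pi_l), then intercept row/col dropped.
  xtwx <- function(w) crossprod(X1 * w, X1)
  inv_jj <- lapply(seq_len(K), function(j) solve(xtwx(pis[, j] * (1 - pis[, j]))))
  V <- matrix(0, K * p, K * p)
  idx <- function(j) ((j - 1L) * p + 1L):(j * p)
  for (j in seq_len(K)) {
    for (l in j:K) {
      w_jl <- pis[, l] - pis[, j] * pis[, l]
      block <- (inv_jj[[j]] %*% xtwx(w_jl) %*% inv_jj[[l]])[-1, -1, drop = FALSE]
      V[idx(j), idx(l)] <- block
      if (l > j) V[idx(l), idx(j)] <- t(block)
    }
  }
  b <- as.vector(betas)

  # Contrasts beta_1 - beta_j, j = 2..K
  D <- matrix(0, (K - 1L) * p, K * p)
  for (j in 2:K) {
    rows <- ((j - 2L) * p + 1L):((j - 1L) * p)
    D[rows, idx(1L)] <- diag(p)
    D[rows, idx(j)] <- -diag(p)
  }
  # Wald quadratic form through an eigendecomposition: with rare outcome
  # levels, adjacent cumulative splits are nearly identical and D V D' is
  # near-singular, so a plain solve() is numerically meaningless there.
  # Directions with eigenvalues below tol * max are dropped and the
  # degrees of freedom reduced to the retained rank (reported).
  wald <- function(Dm) {
    db <- drop(Dm %*% b)
    S <- Dm %*% V %*% t(Dm)
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    keep <- e$values > max(e$values) * 1e-10
    proj <- drop(crossprod(e$vectors[, keep, drop = FALSE], db))
    list(stat = sum(proj^2 / e$values[keep]), rank = sum(keep))
  }
  omnibus <- wald(D)
  omnibus_stat <- omnibus$stat
  omnibus_df <- omnibus$rank
  nominal_df <- (J - 2L) * p
  if (omnibus_df < nominal_df) {
    warning(sprintf(paste0("Brant omnibus covariance is rank deficient ",
                           "(%d of %d contrasts retained); rare outcome ",
                           "levels make adjacent cumulative splits nearly ",
                           "identical"), omnibus_df, nominal_df))
  }

  per_k <- lapply(seq_len(p), function(k) {
    Dk <- matrix(0, K - 1L, K * p)
    for (j in 2:K) {
      Dk[j - 1L, (1L - 1L) * p + k] <- 1
      Dk[j - 1L, (j - 1L) * p + k] <- -1
    }
    wald(Dk)
  })
  per_variable <- data.frame(
    column = cols,
    stat = vapply(per_k, `[[`, numeric(1), "stat"),
    df = vapply(per_k, `[[`, integer(1), "rank"),
    stringsAsFactors = FALSE
  )
  per_variable$p_value <- pchisq(per_variable$stat, per_variable$df,
                                 lower.tail = FALSE)

  structure(list(
    omnibus_stat = omnibus_stat,
    omnibus_df = omnibus_df,
    nominal_df = nominal_df,
    omnibus_p = pchisq(omnibus_stat, omnibus_df, lower.tail = FALSE),
    per_variable = per_variable,
    levels = observed
  ), class = "gose_brant")
}

#' @export
print.gose_brant <- function(x, ...) {
  cat(sprintf("Brant test of parallel regression: X2 = %.3f, df = %d, p = %.4g\n",
              x$omnibus_stat, x$omnibus_df, x$omnibus_p))
  print(transform(x$per_variable, stat = round(stat, 3),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  invisible(x)
}
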