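# Fixtures and independent oracles shared across the suite.

# Small hand-built cohort; `gose` etc. may be overridden or set to NA.
tiny_cohort <- function(n = 6, gose = c(1, 3, 5, 8, 3, 8)) {
  cohort(data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    age = seq(20, by = 7, length.out = n),
    gcs_motor = rep(c(6, 3, 1), length.out = n),
    pupils = rep(c("both", "one", "none"), length.out = n),
    marshall = rep(c("diffuse_I", "diffuse_II", "evacuated_mass"), length.out = n),
    gose = rep(gose, length.out = n),
    stringsAsFactors = FALSE
  ), name = "tiny")
}

# Brute-force negative log-likelihood: per-observation category-probability
# summation, written independently of the vectorized implementation.
oracle_negloglik <- function(beta, zeta, X, y) {
  z <- c(-Inf, zeta, Inf)
  -sum(vapply(seq_along(y), function(i) {
    eta <- sum(X[i, ] * beta)
    log(plogis(z[y[i] + 1] - eta) - plogis(z[y[i]] - eta))
  }, numeric(1)))
}

# Exhaustive pair-counting AUROC with 0.5 credit for ties.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# Simulate ordinal data from an explicit cumulative-logit law; beta_per_split
# as a (J-1) x p matrix allows non-proportional alternatives.
sim_cumlogit <- function(n, beta_per_split, zeta) {
  p <- ncol(beta_per_split)
  X <- cbind(runif(n, -1, 1), matrix(rbinom(n * (p - 1), 1, 0.5), n))[, seq_len(p), drop = FALSE]
  cum <- sapply(seq_along(zeta), function(j) {
    plogis(zeta[j] - drop(X %*% beta_per_split[j, ]))
  })
  u <- runif(n)
  y <- rowSums(u > cum) + 1L
  list(X = X, y = as.integer(y))
}

# Intercept-only fitted model with prescribed 8-category probabilities,
# used to exercise prediction/aggregation paths without fitting.
manual_polr <- function(probs8) {
  stopifnot(length(probs8) == 8, abs(sum(probs8) - 1) < 1e-12)
  structure(list(beta = setNames(numeric(0), character(0)),
                 zeta = qlogis(cumsum(probs8)[1:7]),
                 observed_levels = 1:8, n_obs = 0L, loglik = NA_real_,
                 converged = TRUE, grad_norm = 0, dropped = character(0),
                 encoding = NULL, note = NULL),
            class = "gose_polr")
}

empty_design <- function(n) matrix(numeric(0), nrow = n, ncol = 0)
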