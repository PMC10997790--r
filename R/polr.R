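# Proportional-odds logistic regression, written out from the likelihood:
#   P(Y <= j | x) = logistic(zeta_j - x.beta),  zeta_1 < ... < zeta_{J-1}.
# One shared slope vector across all cumulative splits (the parallel
# regression assumption), ordered cutpoints enforced by a log-increment
# reparameterization, maximum likelihood by BFGS with analytic gradient
# plus a Newton polish. No regularization anywhere.

as_design_matrix <- function(design) {
  if (inherits(design, "gose_design")) design$matrix
  else if (is.matrix(design)) design
  else stop("design must be a gose_design or a numeric matrix")
}

#' Negative log-likelihood of the proportional-odds model
#'
#' `-sum log[ logistic(zeta_y - x.beta) - logistic(zeta_{y-1} - x.beta) ]`
#' with `zeta_0 = -Inf` and `zeta_J = +Inf`, where `J = length(zeta) + 1`
#' outcome levels are coded `1..J` in `labels`.
#'
#' @param beta slope vector (one per design column).
#' @param zeta strictly increasing cutpoints, length `J - 1`.
#' @param design a `gose_design` or numeric matrix.
#' @param labels integer outcomes in `1..J`.
#' @return The negative log-likelihood (sum over observations).
#' @export
polr_negloglik <- function(beta, zeta, design, labels) {
  X <- as_design_matrix(design)
  J <- length(zeta) + 1L
  stopifnot(length(beta) == ncol(X), length(labels) == nrow(X),
            all(labels >= 1L & labels <= J))
  if (length(zeta) > 1L && any(diff(zeta) <= 0)) {
    stop("domain error: zeta must be strictly increasing")
  }
  polr_nll_core(beta, zeta, X, as.integer(labels))$value
}

# Value + gradient (and optionally the exact Hessian) of the negative
# log-likelihood in the natural (beta, zeta) parameterization. Writing
# -ll_i = m(u_i, v_i) with u = zeta_y - eta (upper cutpoint, +Inf for the
# top level) and v = zeta_{y-1} - eta, the second-order chain rule gives
# per-observation weights from m_uu, m_vv and m_uv; only adjacent
# cutpoints ever share an observation.
polr_nll_core <- function(beta, zeta, X, y, hessian = FALSE) {
  K <- length(zeta)
  eta <- drop(X %*% beta)
  zlo <- c(-Inf, zeta)[y] - eta
  zhi <- c(zeta, Inf)[y] - eta
  Fhi <- plogis(zhi); Flo <- plogis(zlo)
  p <- pmax(Fhi - Flo, 1e-300)
  fhi <- dlogis(zhi); flo <- dlogis(zlo)   # dlogis(+-Inf) is 0
  w <- (fhi - flo) / p
  g_zeta <- numeric(K)
  for (j in seq_len(K)) {
    g_zeta[j] <- -sum(fhi[y == j] / p[y == j]) + sum(flo[y == j + 1L] / p[y == j + 1L])
  }
  out <- list(value = -sum(log(p)),
              grad_beta = drop(crossprod(X, w)),
              grad_zeta = g_zeta)
  if (hessian) {
    fphi <- fhi * (1 - 2 * Fhi)            # d/dx dlogis(x)
    fplo <- flo * (1 - 2 * Flo)
    m_uu <- (fhi / p)^2 - fphi / p
    m_vv <- (flo / p)^2 + fplo / p
    m_uv <- -fhi * flo / p^2
    H_bb <- crossprod(X * (m_uu + 2 * m_uv + m_vv), X)
    H_bz <- matrix(0, ncol(X), K)
    H_zz <- matrix(0, K, K)
    for (j in seq_len(K)) {
      up <- y == j          # zeta_j is this obs's upper cutpoint
      lo <- y == j + 1L     # ... lower cutpoint
      if (any(up)) {
        H_bz[, j] <- H_bz[, j] - colSums(X[up, , drop = FALSE] *
                                           (m_uu[up] + m_uv[up]))
        H_zz[j, j] <- H_zz[j, j] + sum(m_uu[up])
      }
      if (any(lo)) {
        H_bz[, j] <- H_bz[, j] - colSums(X[lo, , drop = FALSE] *
                                           (m_vv[lo] + m_uv[lo]))
        H_zz[j, j] <- H_zz[j, j] + sum(m_vv[lo])
      }
      if (j < K) {
        shared <- y == j + 1L   # upper = zeta_{j+1}, lower = zeta_j
        H_zz[j, j + 1L] <- H_zz[j + 1L, j] <- sum(m_uv[shared])
      }
    }
    out$hessian <- rbind(cbind(H_bb, H_bz), cbind(t(H_bz), H_zz))
  }
  out
}

# Map between natural zeta and the unconstrained (zeta_1, log-increments)
# parameterization used by the optimizer.
zeta_to_theta <- function(zeta) {
  if (length(zeta) == 1L) zeta else c(zeta[1], log(diff(zeta)))
}
theta_to_zeta <- function(theta) {
  if (length(theta) == 1L) theta else cumsum(c(theta[1], exp(theta[-1])))
}

#' Optimizer settings for [polr_fit()]
#'
#' @param grad_tol convergence tolerance on the max-abs gradient of the
#'   per-observation (mean) negative log-likelihood.
#' @param maxit BFGS iteration cap.
#' @param newton_maxit cap on Newton polish steps after BFGS.
#' @param drop_collinear drop zero-variance / linearly dependent design
#'   columns (their coefficients are reported as 0 and listed in
#'   `$dropped`) instead of erroring. Used by the undersampling ensemble,
#'   whose small balanced subsamples can lose covariate levels.
#' @return A list of settings.
#' @export
polr_control <- function(grad_tol = 1e-8, maxit = 500L, newton_maxit = 25L,
                         drop_collinear = FALSE) {
  list(grad_tol = grad_tol, maxit = as.integer(maxit),
       newton_maxit = as.integer(newton_maxit),
       drop_collinear = isTRUE(drop_collinear))
}

#' Fit a proportional-odds logistic regression by maximum likelihood
#'
#' Maximizes the proportional-odds likelihood over the slopes and a
#' reparameterized strictly increasing cutpoint vector
#' `(zeta_1, log(zeta_2 - zeta_1), ...)`. Start values are zero slopes and
#' cutpoints at the logits of the empirical cumulative proportions (the
#' exact intercept-only solution). Cutpoints are placed between adjacent
#' *observed* outcome levels only; prediction maps back to the full 1-8
#' GOSE scale with zero mass on unobserved levels.
#'
#' @param design a `gose_design` from [encode_design()] (or a plain
#'   numeric matrix).
#' @param labels observed GOSE values (1-8), aligned with the design rows.
#' @param control a [polr_control()].
#' @return A `gose_polr` object: named `beta`, increasing `zeta` (named by
#'   the cumulative splits between observed levels), `observed_levels`,
#'   `loglik`, `n_obs`, `converged` (max-abs mean-scale gradient below
#'   `grad_tol`), `grad_norm`, `dropped` columns, and the design
#'   `encoding` when available.
#' @export
polr_fit <- function(design, labels, control = polr_control()) {
  X <- as_design_matrix(design)
  encoding <- if (inherits(design, "gose_design")) design$encoding else NULL
  y_raw <- as.integer(labels)
  stopifnot(length(y_raw) == nrow(X), all(y_raw >= 1L & y_raw <= 8L))
  observed <- sort(unique(y_raw))
  if (length(observed) < 2L) stop("polr_fit needs >= 2 distinct outcome levels")
  y <- match(y_raw, observed)
  J <- length(observed)
  n <- nrow(X)

  full_cols <- colnames(X) %||%
    (if (ncol(X) > 0L) paste0("x", seq_len(ncol(X))) else character(0))
  if (ncol(X) > 0L) colnames(X) <- full_cols
  dropped <- character(0)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- full_cols[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    if (!control$drop_collinear) {
      stop("rank-deficient design; collinear column(s): ",
           paste(dropped, collapse = ", "),
           " (set polr_control(drop_collinear = TRUE) to drop them)")
    }
    X <- X[, setdiff(full_cols, dropped), drop = FALSE]
  }
  p <- ncol(X)

  cum <- cumsum(tabulate(y, nbins = J) / n)[seq_len(J - 1L)]
  zeta0 <- qlogis(pmin(pmax(cum, 1e-6), 1 - 1e-6))
  zeta0 <- zeta0 + cumsum(c(0, pmax(0, 1e-4 - diff(zeta0))))  # enforce increase
  theta0 <- c(numeric(p), zeta_to_theta(zeta0))

  nll_mean <- function(par) {
    zeta <- theta_to_zeta(par[(p + 1L):length(par)])
    polr_nll_core(par[seq_len(p)], zeta, X, y)$value / n
  }
  grad_mean <- function(par) {
    th <- par[(p + 1L):length(par)]
    core <- polr_nll_core(par[seq_len(p)], theta_to_zeta(th), X, y)
    gz <- core$grad_zeta
    # chain rule through the log-increment reparameterization
    gt <- rev(cumsum(rev(gz)))
    if (length(th) > 1L) gt[-1] <- gt[-1] * exp(th[-1])
    c(core$grad_beta, gt) / n
  }
  hess_mean <- function(par) {
    th <- par[(p + 1L):length(par)]
    K <- length(th)
    core <- polr_nll_core(par[seq_len(p)], theta_to_zeta(th), X, y, hessian = TRUE)
    Jz <- matrix(0, K, K)
    Jz[, 1] <- 1
    if (K > 1L) for (m in 2:K) Jz[m:K, m] <- exp(th[m])
    Jc <- rbind(cbind(diag(1, p), matrix(0, p, K)),
                cbind(matrix(0, K, p), Jz))
    H <- t(Jc) %*% core$hessian %*% Jc
    if (K > 1L) {  # curvature of zeta_k in theta_m (second-order chain term)
      for (m in 2:K) {
        H[p + m, p + m] <- H[p + m, p + m] + exp(th[m]) * sum(core$grad_zeta[m:K])
      }
    }
    H / n
  }

  # BFGS warm start, then exact-Hessian Newton with Levenberg damping.
  opt <- optim(theta0, nll_mean, grad_mean, method = "BFGS",
               control = list(maxit = control$maxit, reltol = 1e-10))
  par <- opt$par
  g <- grad_mean(par)
  iters <- 0L
  mu <- 0
  while (max(abs(g)) > control$grad_tol && iters < control$newton_maxit) {
    H <- hess_mean(par)
    step <- tryCatch(solve(H + diag(mu, length(par)), g),
                     error = function(e) NULL)
    if (is.null(step)) { mu <- max(mu * 10, 1e-8); iters <- iters + 1L; next }
    f0 <- nll_mean(par)
    lambda <- 1
    while (lambda >= 1e-10) {
      cand <- par - lambda * step
      fc <- nll_mean(cand)
      if (is.finite(fc) && fc <= f0 + 1e-14) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-10) { mu <- max(mu * 10, 1e-8); iters <- iters + 1L; next }
    par <- par - lambda * step
    g <- grad_mean(par)
    mu <- mu / 4
    iters <- iters + 1L
  }

  beta_hat <- par[seq_len(p)]
  zeta_hat <- theta_to_zeta(par[(p + 1L):length(par)])
  grad_norm <- max(abs(g))
  converged <- grad_norm <= control$grad_tol
  note <- NULL
  if (!converged && max(abs(beta_hat)) > 15) {
    note <- "possible complete separation: diverging slope estimates"
  }

  beta_full <- setNames(numeric(length(full_cols)), full_cols)
  beta_full[colnames(X)] <- beta_hat
  structure(list(
    beta = beta_full,
    zeta = setNames(zeta_hat, paste0("<=", observed[seq_len(J - 1L)])),
    observed_levels = observed,
    n_obs = n,
    loglik = -polr_nll_core(beta_hat, zeta_hat, X, y)$value,
    converged = converged,
    grad_norm = grad_norm,
    newton_steps = iters,
    dropped = dropped,
    encoding = encoding,
    note = note
  ), class = "gose_polr")
}

# Central finite-difference Jacobian of a gradient function (the Hessian).
fd_jacobian <- function(gfun, par, h = 1e-6) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    e <- numeric(k); e[i] <- h * max(1, abs(par[i]))
    H[, i] <- (gfun(par + e) - gfun(par - e)) / (2 * e[i])
  }
  (H + t(H)) / 2
}

#' @export
print.gose_polr <- function(x, ...) {
  cat(sprintf("<gose_polr> n=%d levels={%s} loglik=%.3f %s\n", x$n_obs,
              paste(x$observed_levels, collapse = ","), x$loglik,
              if (x$converged) "converged" else
                sprintf("NOT converged (|grad|=%.2e)", x$grad_norm)))
  cat("beta:\n"); print(round(x$beta, 4))
  cat("zeta:\n"); print(round(x$zeta, 4))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Predicted GOSE category probabilities from a fitted model
#'
#' Per patient, `p_j = logistic(zeta_j - x.beta) - logistic(zeta_{j-1} -
#' x.beta)` over the observed levels, mapped onto the full 8-category GOSE
#' scale with zero mass on levels unobserved at training time.
#'
#' @param fit a `gose_polr` from [polr_fit()].
#' @param design a `gose_design` or matrix encoded with the same spec as
#'   the training design.
#' @return An `n x 8` matrix of probabilities (columns `p1..p8`), each row
#'   summing to 1.
#' @export
polr_predict <- function(fit, design) {
  stopifnot(inherits(fit, "gose_polr"))
  X <- as_design_matrix(design)
  if (!is.null(fit$encoding) && inherits(design, "gose_design")) {
    if (!identical(fit$encoding[c("references", "gcs_numeric", "standardize_age")],
                   design$encoding[c("references", "gcs_numeric", "standardize_age")])) {
      stop("encoding mismatch: design was not encoded with the fit's encoding spec")
    }
  }
  if (!setequal(colnames(X), names(fit$beta))) {
    stop("encoding mismatch: design columns do not match the fitted coefficients")
  }
  if (ncol(X) > 0L) X <- X[, names(fit$beta), drop = FALSE]
  eta <- drop(X %*% fit$beta)
  cum <- plogis(outer(-eta, unname(fit$zeta), `+`))
  cum <- cbind(0, cum, 1)
  p_obs <- cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
  out <- matrix(0, nrow(X), 8L, dimnames = list(rownames(X), paste0("p", 1:8)))
  out[, fit$observed_levels] <- p_obs
  out
}
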