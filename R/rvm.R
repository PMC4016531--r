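#' Logistic sigmoid
#'
#' @param y numeric vector
#' @return `1 / (1 + exp(-y))`
#' @export
sigmoid <- function(y) 1 / (1 + exp(-y))

# MAP weights of the penalised logistic model for fixed hyperparameters:
# maximise sum_i log sigma(t_i * phi_i' w) - 0.5 * w' A w by IRLS (Newton).
# Returns the mode, the posterior covariance (Laplace) and the Bernoulli
# log-likelihood at the mode.
rvm_irls <- function(Phi, t01, alpha_h, w0, max_newton = 50, tol = 1e-8) {
  A <- diag(alpha_h, length(alpha_h))
  w <- w0
  obj <- function(w) {
    y <- as.numeric(Phi %*% w)
    p <- sigmoid(y)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(t01 * log(p) + (1 - t01) * log(1 - p)) - 0.5 * sum(alpha_h * w^2)
  }
  cur <- obj(w)
  for (it in seq_len(max_newton)) {
    y <- as.numeric(Phi %*% w)
    p <- sigmoid(y)
    g <- as.numeric(t(Phi) %*% (t01 - p)) - alpha_h * w
    beta <- pmax(p * (1 - p), 1e-12)
    H <- t(Phi * beta) %*% Phi + A
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, nrow(H)), g)
    })
    # backtracking line search keeps the Newton step monotone
    lam <- 1
    repeat {
      w_new <- w + lam * step
      new <- obj(w_new)
      if (new >= cur - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    conv <- abs(new - cur) < tol
    w <- w_new
    cur <- new
    if (conv) break
  }
  y <- as.numeric(Phi %*% w)
  p <- sigmoid(y)
  beta <- pmax(p * (1 - p), 1e-12)
  H <- t(Phi * beta) %*% Phi + A
  Sigma <- tryCatch(solve(H), error = function(e) {
    solve(H + diag(1e-8, nrow(H)))
  })
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  loglik <- sum(t01 * log(pc) + (1 - t01) * log(1 - pc))
  list(w = w, Sigma = Sigma, loglik = loglik)
}

# Laplace evidence of the model restricted to the active bases:
# log p(t|mu) - 0.5 mu'A mu + 0.5 log|Sigma| + 0.5 log|A|,
# with the weight posterior mode found by IRLS (warm-started at w0)
rvm_evidence <- function(Phi, t01, alpha_act, w0) {
  fit <- rvm_irls(Phi, t01, alpha_act, w0)
  ld_S <- as.numeric(determinant(fit$Sigma, logarithm = TRUE)$modulus)
  L <- fit$loglik - 0.5 * sum(alpha_act * fit$w^2) +
    0.5 * ld_S + 0.5 * sum(log(alpha_act))
  list(L = L, mu = fit$w, Sigma = fit$Sigma)
}

# Sparsity (S, s) and quality (Q, q) factors of every candidate basis under
# the Laplace linearisation at the current active-set fit. For out-of-model
# bases s = S and q = Q; for in-model bases the factors are adjusted to the
# model with that basis removed. theta = q^2 - s > 0 means the evidence is
# maximised at the finite precision s^2 / theta; theta <= 0 means the
# evidence wants the basis out of the model.
rvm_factors <- function(Phi_full, active, t01, alpha_act, cur) {
  Phi <- Phi_full[, active, drop = FALSE]
  y <- as.numeric(Phi %*% cur$mu)
  p <- sigmoid(y)
  beta <- pmax(p * (1 - p), 1e-12)
  W <- Phi * beta                              # B Phi_active
  U <- t(Phi_full) %*% W                       # Phi_full' B Phi_active
  SU <- tcrossprod(cur$Sigma, U)               # Sigma (U')  [active x m]
  S_all <- colSums(beta * Phi_full^2) - colSums(t(U) * SU)
  bt <- beta * y + (t01 - p)                   # B t_hat
  g_full <- as.numeric(t(Phi_full) %*% bt)
  g_act <- g_full[active]
  Q_all <- g_full - as.numeric(U %*% (cur$Sigma %*% g_act))
  s_f <- S_all
  q_f <- Q_all
  a_of <- rep(Inf, ncol(Phi_full))
  a_of[active] <- alpha_act
  inm <- is.finite(a_of)
  den <- pmax(a_of[inm] - S_all[inm], 1e-12)
  s_f[inm] <- a_of[inm] * S_all[inm] / den
  q_f[inm] <- a_of[inm] * Q_all[inm] / den
  list(s = s_f, q = q_f, theta = q_f^2 - s_f)
}

#' Fit a sparse-Bayesian (relevance vector) classifier
#'
#' Kernel classifier with an independent zero-mean Gaussian prior on each
#' weight, precision hyperparameters `gamma_i`, and a logistic likelihood
#' `sigma(y(x))`. Fitting is sequential sparse-Bayesian learning with a
#' Laplace approximation: starting from a single active basis (the bias
#' column when present), each iteration considers adding the most promising
#' inactive basis, deleting the least supported active basis, or jointly
#' re-estimating the precisions of the active set, scores every candidate
#' by its exact Laplace marginal log-likelihood (the weight posterior mode
#' refitted by iteratively reweighted least squares), and accepts the best
#' action only if the evidence improves — so the marginal log-likelihood is
#' non-decreasing across iterations by construction. Candidate precisions
#' come from the sparsity/quality factors s and q: the evidence for a basis
#' is maximised at precision `s^2 / (q^2 - s)` when `q^2 > s` and at
#' infinity (basis excluded) otherwise. Precisions crossing the prune
#' threshold delete their basis. The basis matrix is used as given and need
#' not be positive semidefinite. Initialisation is deterministic (no random
#' restarts).
#'
#' @param design numeric matrix of basis responses, one row per example
#'   (typically kernel columns plus a constant bias column)
#' @param labels vector of -1/+1 class labels
#' @param max_iter maximum accepted update iterations
#' @param tol convergence threshold on the change in the (Laplace) marginal
#'   log-likelihood
#' @param prune_threshold precision above which a basis function is removed
#' @return object of class `rvm_model`: `weights` (dense, pruned entries
#'   exactly 0), `gamma` (hyperparameters, `Inf` for pruned bases),
#'   `relevance` (retained column indices), `converged` flag,
#'   `marginal_loglik` trace (one entry per accepted iteration), `n_basis`
#' @export
fit_rvm <- function(design, labels, max_iter = 500, tol = 1e-6,
                    prune_threshold = 1e12) {
  Phi_full <- as.matrix(design)
  n <- nrow(Phi_full)
  m <- ncol(Phi_full)
  labels <- as.numeric(labels)
  stopifnot(length(labels) == n, max_iter >= 1, tol > 0)
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (length(unique(labels)) < 2L) {
    stop("training requires both classes to be present")
  }
  t01 <- (labels + 1) / 2

  # initial active basis: the first constant nonzero (bias) column, else
  # the column best aligned with the centred targets
  col_sd <- apply(Phi_full, 2, stats::sd)
  const_nz <- which(col_sd == 0 & Phi_full[1, ] != 0)
  init <- if (length(const_nz) > 0) const_nz[1] else {
    which.max(abs(as.numeric(t(Phi_full) %*% (t01 - 0.5))) /
                pmax(sqrt(colSums(Phi_full^2)), 1e-12))
  }
  active <- init
  alpha_h <- rep(Inf, m)
  alpha_h[init] <- 1            # gamma start for the seeded basis
  cur <- rvm_evidence(Phi_full[, active, drop = FALSE], t01,
                      alpha_h[active], 0)
  trace <- cur$L
  converged <- FALSE

  try_candidate <- function(act, alph, w0) {
    rvm_evidence(Phi_full[, act, drop = FALSE], t01, alph, w0)
  }

  for (iter in seq_len(max_iter)) {
    fac <- rvm_factors(Phi_full, active, t01, alpha_h[active], cur)
    cands <- list()

    # joint re-estimation of the active precisions (with pruning)
    prop <- ifelse(fac$theta[active] > 0,
                   pmin(pmax(fac$s[active]^2 / fac$theta[active], 1e-12),
                        1e300),
                   100 * prune_threshold)
    keep <- prop < prune_threshold
    if (any(keep)) {
      cands$reestimate <- list(active = active[keep], alpha = prop[keep],
                               w0 = cur$mu[keep])
    }
    # best addition among inactive bases with positive theta
    inactive <- setdiff(seq_len(m), active)
    addable <- inactive[fac$theta[inactive] > 0]
    if (length(addable) > 0) {
      gain <- 0.5 * ((fac$q[addable]^2 - fac$s[addable]) /
                       pmax(fac$s[addable], 1e-12) +
                       log(pmax(fac$s[addable], 1e-300)) -
                       log(fac$q[addable]^2))
      j <- addable[which.max(gain)]
      a_new <- min(max(fac$s[j]^2 / fac$theta[j], 1e-12), 1e300)
      cands$add <- list(active = c(active, j),
                        alpha = c(alpha_h[active], a_new),
                        w0 = c(cur$mu, 0))
    }
    # deletion of the least supported active basis
    if (length(active) > 1) {
      j <- which.min(fac$theta[active])
      cands$delete <- list(active = active[-j], alpha = alpha_h[active][-j],
                           w0 = cur$mu[-j])
    }
    if (length(cands) == 0) {
      converged <- TRUE
      break
    }
    fits <- lapply(cands, function(cd) {
      try_candidate(cd$active, cd$alpha, cd$w0)
    })
    best <- which.max(vapply(fits, function(f) f$L, 0))
    if (fits[[best]]$L < cur$L + tol) {
      converged <- TRUE
      break
    }
    chosen <- cands[[best]]
    alpha_h[] <- Inf
    alpha_h[chosen$active] <- chosen$alpha
    active <- sort(chosen$active)
    o <- order(chosen$active)
    cur <- fits[[best]]
    cur$mu <- cur$mu[o]
    cur$Sigma <- cur$Sigma[o, o, drop = FALSE]
    trace <- c(trace, cur$L)
  }

  weights <- numeric(m)
  weights[active] <- cur$mu
  # drop numerically dead relevance vectors
  dead <- abs(weights[active]) < 1e-9
  if (any(dead)) {
    weights[active[dead]] <- 0
    active <- active[!dead]
  }
  structure(list(weights = weights, gamma = alpha_h,
                 relevance = active, converged = converged,
                 marginal_loglik = trace, n_basis = m),
            class = "rvm_model")
}

#' @export
print.rvm_model <- function(x, ...) {
  cat(sprintf(
    "Relevance vector machine: %d/%d bases retained, %sconverged (%d iters)\n",
    length(x$relevance), x$n_basis, if (x$converged) "" else "NOT ",
    length(x$marginal_loglik)))
  invisible(x)
}

#' Predict with a relevance vector classifier
#'
#' @param model an `rvm_model`
#' @param basis_row numeric vector (or matrix, rows = examples) of basis
#'   responses indexed consistently with the model's design matrix
#' @return list with `probability` (`sigma(y)`) and `label` (+1 iff
#'   probability > 0.5, else -1)
#' @export
predict_rvm <- function(model, basis_row) {
  if (!is.matrix(basis_row)) basis_row <- matrix(basis_row, nrow = 1)
  if (ncol(basis_row) != model$n_basis) {
    stop("basis row length does not match the model's basis count")
  }
  y <- as.numeric(basis_row %*% model$weights)
  p <- sigmoid(y)
  list(probability = p, label = ifelse(p > 0.5, 1, -1), y = y)
}
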