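# Quadratic inference functions for the identity-link Gaussian marginal
# model with the exchangeable basis: M_1 = I, M_2 = J - I (zero diagonal,
# ones off-diagonal). The inverse working correlation is expanded as
# R^{-1} = a_1 M_1 + a_2 M_2, turning GEE into 2m unbiased estimating
# equations combined by 2-step GMM. The objective is invariant to the
# dispersion scale in the Gaussian/identity case, so scores are built from
# raw residuals.

qif_parts <- function(y, X, fam) {
  fam <- as.integer(factor(fam, levels = unique(fam)))
  N <- max(fam)
  p <- ncol(X)
  S <- rowsum(X, fam)                               # cluster sums of X
  B1 <- crossprod(X)                                # sum X_i' X_i
  B2 <- crossprod(S) - B1                           # sum X_i' (J - I) X_i
  list(fam = fam, N = N, p = p, S = S, W = rbind(B1, B2), B1 = B1)
}

qif_score_matrix <- function(e, X, parts) {
  A <- rowsum(X * e, parts$fam)                     # X_i' e_i, one row per cluster
  Tm <- parts$S * as.vector(rowsum(e, parts$fam)) - A # X_i' (J - I) e_i
  cbind(A, Tm)                                      # N x 2p, g_i in rows
}

#' Extended (stacked) QIF scores
#'
#' Evaluates the per-cluster extended score vectors
#' `g_i(beta) = [X_i' (y_i - X_i beta); X_i' M_2 (y_i - X_i beta)]` for the
#' exchangeable basis (`M_1 = I`, `M_2` zero diagonal / ones off-diagonal;
#' for a singleton cluster the `M_2` block is identically zero), together
#' with their average.
#'
#' @param beta Coefficient vector at which to evaluate the scores.
#' @param data,formula,id As in [fit_qif()].
#' @return List with `g_bar` (length `2p` average score) and `G`
#'   (`N x 2p` matrix of per-cluster scores in rows).
#' @export
qif_scores <- function(beta, data, formula, id) {
  fam <- dplyr::pull(data, {{ id }})
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  parts <- qif_parts(y, X, fam)
  G <- qif_score_matrix(y - as.vector(X %*% beta), X, parts)
  list(g_bar = colMeans(G), G = G)
}

# Inverse of the empirical weighting matrix. C_N is exactly rank-deficient
# in common designs — all-singleton clusters zero the M_2 block, and equal
# cluster sizes make the intercept rows of the two blocks collinear
# ((n-1) * identity-block score) — so the spectral pseudoinverse is used:
# redundant moment directions carry no information and are dropped rather
# than inflated.
sym_pinv <- function(C, tol = 1e-11) {
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, .Machine$double.eps)
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

qif_fit_core <- function(y, X, fam, tol = 1e-8, max_iter = 100L) {
  parts <- qif_parts(y, X, fam)
  N <- parts$N
  p <- parts$p
  beta <- qr.coef(qr(X), y)
  if (anyNA(beta)) abort("design matrix is rank deficient",
                         class = "famgxm_rank_error")
  W <- parts$W                                       # 2p x p, -N * Jbar
  q_old <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- y - as.vector(X %*% beta)
    G <- qif_score_matrix(e, X, parts)
    gbar <- colMeans(G)
    Ci <- sym_pinv(crossprod(G) / N)
    q <- N * as.numeric(crossprod(gbar, Ci %*% gbar))
    JCJ <- crossprod(W, Ci %*% W)                    # W' C^- W
    step <- N * solve(JCJ, crossprod(W, Ci %*% gbar))
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol && abs(q - q_old) < tol * (1 + abs(q))) {
      converged <- TRUE
      break
    }
    q_old <- q
    if (iter >= max_iter) break
  }
  e <- y - as.vector(X %*% beta)
  G <- qif_score_matrix(e, X, parts)
  gbar <- colMeans(G)
  Ci <- sym_pinv(crossprod(G) / N)
  q_stat <- max(N * as.numeric(crossprod(gbar, Ci %*% gbar)), 0)
  cov_plain <- N * solve(crossprod(W, Ci %*% W))

  list(beta = setNames(as.vector(beta), colnames(X)),
       cov_plain = cov_plain, q_stat = q_stat,
       n_iter = iter, converged = converged,
       N = N, n = length(y), p = p,
       y = y, X = X, fam = parts$fam, residuals = e,
       parts = parts)
}

# Leverage-corrected weighting matrix: cluster residuals pre-multiplied by
# (I - H_i)^{-1}, where H_i is the QIF hat matrix from the GMM
# linearization beta_hat = (W'C^-W)^{-1} W'C^- sum_i B_i' y_i with
# B_i = [X_i, M_2 X_i]:  H_i = X_i (W'C^-W)^{-1} W'C^- B_i'.
qif_bc_core <- function(fit) {
  G0 <- qif_score_matrix(fit$residuals, fit$X, fit$parts)
  Ci <- sym_pinv(crossprod(G0) / fit$N)
  W <- fit$parts$W
  K <- solve(crossprod(W, Ci %*% W), crossprod(W, Ci))  # p x 2p
  idx <- split(seq_len(fit$n), fit$fam)
  e_adj <- fit$residuals
  p <- fit$p
  for (ii in idx) {
    Xi <- fit$X[ii, , drop = FALSE]
    ni <- length(ii)
    # B_i = [X_i, M2 X_i] with M2 = J - I
    M2Xi <- matrix(colSums(Xi), ni, p, byrow = TRUE) - Xi
    Hi <- Xi %*% K %*% t(cbind(Xi, M2Xi))
    IH <- diag(ni) - Hi
    e_adj[ii] <- tryCatch(solve(IH, fit$residuals[ii]),
                          error = function(e) abort(
                            "cluster leverage makes (I - H_i) singular",
                            class = "famgxm_leverage_error"))
  }
  G <- qif_score_matrix(e_adj, fit$X, fit$parts)
  Ci_bc <- sym_pinv(crossprod(G) / fit$N)
  fit$N * solve(crossprod(W, Ci_bc %*% W))
}

#' Fit a marginal linear model by quadratic inference functions
#'
#' Minimizes the quadratic inference function
#' `Q_N(beta) = N * g_bar(beta)' C_N^{-1} g_bar(beta)` over the
#' exchangeable basis expansion of the inverse working correlation, with
#' `C_N = N^{-1} sum_i g_i g_i'` (2-step GMM: the weighting matrix is
#' frozen at the current beta for each Newton step, then refreshed). For
#' the linear model the score Jacobian is constant, so each step is exact.
#' The plain covariance is the GMM asymptotic form
#' `N^{-1} (J' C_N^{-1} J)^{-1}`; [qif_bc_cov()] applies a
#' Mancl-DeRouen-type leverage correction to `C_N`.
#'
#' `C_N` is inverted through its spectral pseudoinverse because it is
#' exactly rank-deficient in common designs: all-singleton clusters zero
#' the `M_2` block, and equal cluster sizes make the intercept rows of the
#' two blocks collinear. Redundant moment directions carry no information
#' and are dropped.
#'
#' @inheritParams fit_gee
#' @return Object of class `famgxm_qif` with `beta`, `cov_plain`, `cov_bc`,
#'   `q_stat`, `n_iter`, `converged`. Supports [tidy()] and [glance()].
#' @export
fit_qif <- function(data, formula, id, tol = 1e-8, max_iter = 100L) {
  fam <- dplyr::pull(data, {{ id }})
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  fit <- qif_fit_core(y, X, fam, tol, max_iter)
  fit$cov_bc <- qif_bc_core(fit)
  fit$formula <- formula
  class(fit) <- "famgxm_qif"
  fit
}

#' Bias-corrected QIF covariance
#'
#' Recomputes the GMM weighting matrix with cluster residuals
#' pre-multiplied by `(I - H_i)^{-1}` (leverage under the independence
#' working covariance) and returns
#' `N^{-1} (J' C_bc^{-1} J)^{-1}`. Equals the plain covariance in the
#' zero-leverage limit.
#'
#' @param fit A `famgxm_qif`.
#' @return A symmetric p x p covariance matrix.
#' @export
qif_bc_cov <- function(fit) {
  stopifnot(inherits(fit, "famgxm_qif"))
  fit$cov_bc
}

#' @export
print.famgxm_qif <- function(x, ...) {
  cat(sprintf("<famgxm_qif: exchangeable basis, %d clusters, %d obs>\n",
              x$N, x$n))
  cat(sprintf("  Q_N = %.4f, %s in %d iterations\n", x$q_stat,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(x$beta)
  invisible(x)
}
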