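# Core GEE machinery for the identity-link Gaussian marginal model.
#
# With A_i = phi * I and an exchangeable working correlation, V_i^{-1} has
# the closed form (1 / (phi (1 - alpha))) * (I - c_i J) with
# c_i = alpha / (1 + (n_i - 1) alpha), which lets every cluster sum be
# accumulated with rowsum() instead of per-cluster loops.

gee_fit_core <- function(y, X, fam, structure = c("exchangeable", "independence"),
                         tol = 1e-8, max_iter = 100L) {
  structure <- match.arg(structure)
  fam <- as.integer(factor(fam, levels = unique(fam)))
  n_i <- tabulate(fam)
  N <- length(n_i)
  n <- length(y)
  p <- ncol(X)
  if (n - p <= 0) abort("fewer observations than coefficients",
                        class = "famgxm_rank_error")
  npairs <- sum(n_i * (n_i - 1)) / 2

  beta <- qr.coef(qr(X), y)
  if (anyNA(beta)) abort("design matrix is rank deficient",
                         class = "famgxm_rank_error")
  alpha <- 0
  phi <- 1
  alpha_clipped <- FALSE
  XtX <- crossprod(X)

  moment_updates <- function(e) {
    phi <- sum(e^2) / (n - p)
    alpha <- 0
    if (structure == "exchangeable" && npairs > 0) {
      Se <- rowsum(e, fam)
      Se2 <- rowsum(e^2, fam)
      cross <- sum(Se^2 - Se2) / 2
      alpha <- cross / phi / max(npairs - p, 1)
      hi <- 1 - 1e-6
      lo <- -1 / (max(n_i) - 1 + 1e-12) + 1e-6
      if (alpha > hi || alpha < lo) {
        alpha_clipped <<- TRUE
        alpha <- min(max(alpha, lo), hi)
      }
    }
    list(phi = phi, alpha = alpha)
  }

  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- y - as.vector(X %*% beta)
    mom <- moment_updates(e)
    phi <- mom$phi
    alpha <- mom$alpha
    cvec <- alpha / (1 + (n_i - 1) * alpha)
    S <- rowsum(X, fam)                       # cluster column sums of X
    Sy <- rowsum(y, fam)
    B_raw <- XtX - crossprod(S * cvec, S)     # sum X' (I - cJ) X
    rhs <- crossprod(X, y) - crossprod(S * cvec, Sy)
    beta_new <- solve(B_raw, rhs)
    delta <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (alpha_clipped) {
    warn("exchangeable alpha estimate clipped into the positive-definite range")
  }

  # final residual-based quantities at the converged beta
  e <- y - as.vector(X %*% beta)
  mom <- moment_updates(e)
  phi <- mom$phi
  alpha <- if (structure == "exchangeable") mom$alpha else 0
  cvec <- alpha / (1 + (n_i - 1) * alpha)
  S <- rowsum(X, fam)
  scale <- 1 / (phi * (1 - alpha))
  B <- scale * (XtX - crossprod(S * cvec, S)) # sum X' V^{-1} X
  bread <- solve(B)
  cov_model <- bread

  # robust sandwich: meat = sum X' V^{-1} e e' V^{-1} X
  ve <- scale * (e - cvec[fam] * rowsum(e, fam)[fam])
  U <- rowsum(X * ve, fam)                    # N x p of X_i' V_i^{-1} e_i
  cov_robust <- bread %*% crossprod(U) %*% bread

  fit <- list(beta = setNames(beta, colnames(X)),
              cov_model = cov_model, cov_robust = cov_robust,
              alpha = alpha, phi = phi, n_iter = iter,
              converged = converged, structure = structure,
              N = N, n = n, p = p,
              y = y, X = X, fam = fam, residuals = e,
              bread = bread, cvec = cvec, scale = scale)
  fit$cov_bc <- gee_md_core(fit)
  fit
}

# Mancl-DeRouen bias-corrected sandwich: residual cross-products inflated
# by (I - H_i)^{-1}, H_i = X_i B^{-1} X_i' V_i^{-1}.
gee_md_core <- function(fit) {
  idx <- split(seq_len(fit$n), fit$fam)
  U <- matrix(0, fit$N, fit$p)
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    Xi <- fit$X[ii, , drop = FALSE]
    ni <- length(ii)
    Viinv <- fit$scale *
      (diag(ni) - matrix(fit$cvec[i], ni, ni))
    Hi <- Xi %*% fit$bread %*% t(Xi) %*% Viinv
    IH <- diag(ni) - Hi
    ei <- tryCatch(solve(IH, fit$residuals[ii]),
                   error = function(e) abort(
                     "cluster leverage makes (I - H_i) singular",
                     class = "famgxm_leverage_error"))
    U[i, ] <- as.vector(t(Xi) %*% Viinv %*% ei)
  }
  fit$bread %*% crossprod(U) %*% fit$bread
}

#' Fit a marginal linear model by generalized estimating equations
#'
#' Gaussian working variances with identity link; the working correlation
#' is exchangeable (one common within-cluster correlation `alpha`) or
#' independence. Coefficients solve the estimating equations
#' `sum_i X_i' V_i^{-1} (y_i - X_i beta) = 0` with
#' `V_i = phi (R_i(alpha))`, iterating weighted least squares with moment
#' updates of `phi` (Pearson residual sum of squares over `n - p`) and
#' `alpha` (degrees-of-freedom-adjusted mean of within-cluster residual
#' cross-products). Three covariance estimates are returned: model-based
#' `(sum X'V^{-1}X)^{-1}`, the robust sandwich, and the Mancl-DeRouen
#' bias-corrected sandwich in which each cluster's residual is
#' pre-multiplied by `(I - H_i)^{-1}` with cluster leverage
#' `H_i = X_i B^{-1} X_i' V_i^{-1}`.
#'
#' @param data Data frame with one row per observation.
#' @param formula Model formula (identity link).
#' @param id Cluster identifier column (unquoted).
#' @param structure `"exchangeable"` (default) or `"independence"`.
#' @param tol,max_iter Convergence tolerance on `max |delta beta|` and
#'   iteration cap.
#' @return Object of class `famgxm_gee` with elements `beta`, `cov_model`,
#'   `cov_robust`, `cov_bc`, `alpha`, `phi`, `n_iter`, `converged`.
#'   Supports [tidy()] and [glance()].
#' @examples
#' d <- data.frame(y = rnorm(20), x = rnorm(20), f = rep(1:5, each = 4))
#' fit <- fit_gee(d, y ~ x, id = f)
#' tidy(fit, cov = "bc")
#' @export
fit_gee <- function(data, formula, id,
                    structure = c("exchangeable", "independence"),
                    tol = 1e-8, max_iter = 100L) {
  structure <- match.arg(structure)
  fam <- dplyr::pull(data, {{ id }})
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  fit <- gee_fit_core(y, X, fam, structure, tol, max_iter)
  fit$formula <- formula
  class(fit) <- "famgxm_gee"
  fit
}

#' Sandwich covariance estimates from a GEE fit
#'
#' `robust_cov()` returns the uncorrected robust (Liang-Zeger) sandwich;
#' `mancl_derouen_cov()` returns the small-sample bias-corrected sandwich.
#' Both are stored on the fit; these accessors recompute nothing.
#'
#' @param fit A `famgxm_gee`.
#' @return A symmetric p x p covariance matrix.
#' @export
robust_cov <- function(fit) {
  stopifnot(inherits(fit, "famgxm_gee"))
  fit$cov_robust
}

#' @rdname robust_cov
#' @export
mancl_derouen_cov <- function(fit) {
  stopifnot(inherits(fit, "famgxm_gee"))
  fit$cov_bc
}

#' @export
print.famgxm_gee <- function(x, ...) {
  cat(sprintf("<famgxm_gee: %s working correlation, %d clusters, %d obs>\n",
              x$structure, x$N, x$n))
  cat(sprintf("  alpha = %.4f, phi = %.4f, %s in %d iterations\n",
              x$alpha, x$phi,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(x$beta)
  invisible(x)
}
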