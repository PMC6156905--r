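# Kinship linear mixed model: y = X beta + g + eps with
# g ~ N(0, sigma_g^2 * 2 Phi) and eps ~ N(0, sigma_e^2 I). One spectral
# decomposition 2 Phi = U Lambda U' rotates the problem to independent
# observations with variances sigma_e^2 (1 + delta lambda_j),
# delta = sigma_g^2 / sigma_e^2; beta and sigma_e^2 profile out, leaving a
# bounded 1-D search over log(delta).

lme_profile <- function(log_delta, yt, Xt, lambda, reml) {
  delta <- exp(log_delta)
  n <- length(yt)
  p <- ncol(Xt)
  w <- 1 / (1 + delta * lambda)
  sw <- sqrt(w)
  Xw <- Xt * sw
  XtWX <- crossprod(Xw)
  beta <- solve(XtWX, crossprod(Xt, w * yt))
  r <- yt - as.vector(Xt %*% beta)
  rss <- sum(w * r^2)
  logdet_sigma <- -sum(log(w))
  if (reml) {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdet_sigma +
                    determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + logdet_sigma + n)
  }
  list(ll = as.numeric(ll), beta = as.vector(beta), s2 = s2,
       XtWX = XtWX, delta = delta)
}

lme_fit_core <- function(y, X, eig, method = c("REML", "ML"),
                         lower = 1e-8, upper = 1e4, tol = 1e-10) {
  method <- match.arg(method)
  reml <- method == "REML"
  p <- ncol(X)
  if (qr(X)$rank < p) abort("design matrix is rank deficient",
                            class = "famgxm_rank_error")
  U <- eig$vectors
  lambda <- eig$values
  yt <- as.vector(crossprod(U, y))
  Xt <- crossprod(U, X)
  opt <- optimize(function(ld) lme_profile(ld, yt, Xt, lambda, reml)$ll,
                  interval = c(log(lower), log(upper)),
                  maximum = TRUE, tol = tol)
  # the variance-ratio optimum may sit on the sigma_g^2 = 0 boundary
  at_lower <- lme_profile(log(lower), yt, Xt, lambda, reml)
  best <- lme_profile(opt$maximum, yt, Xt, lambda, reml)
  if (at_lower$ll > best$ll) best <- at_lower
  delta <- if (best$delta <= lower * (1 + 1e-6)) 0 else best$delta
  cov_beta <- best$s2 * solve(best$XtWX)
  list(beta = setNames(best$beta, colnames(X)),
       cov_beta = cov_beta,
       sigma2_g = delta * best$s2, sigma2_e = best$s2,
       delta = delta, loglik = best$ll, method = method,
       converged = TRUE, n = length(y), p = p)
}

#' Fit a linear mixed model with a kinship-structured random effect
#'
#' Fits `y = X beta + g + eps` where the genetic random effect `g` has
#' covariance `sigma_g^2` times the relationship matrix `2 * Phi` from the
#' pedigree, and `eps` is i.i.d. Gaussian noise. The relationship matrix is
#' eigendecomposed once; the (restricted) likelihood is profiled over
#' `beta` and `sigma_e^2` and the variance ratio
#' `delta = sigma_g^2 / sigma_e^2` is optimized by bounded 1-D search on
#' the log scale over `[1e-8, 1e4]`. `beta` is the GLS estimate at the
#' optimum with `cov_beta = sigma_e^2 (X' W X)^{-1}` in the rotated
#' coordinates.
#'
#' @param data Data frame with one row per subject; rows are matched to the
#'   kinship ids through `subject` (any order, but every row must have a
#'   kinship entry).
#' @param formula Fixed-effects formula.
#' @param kinship A `famgxm_kinship`, `famgxm_kinship_eigen`, or pedigree.
#' @param subject Column identifying subjects (unquoted; default
#'   `subject_id`).
#' @param method `"REML"` (default) or `"ML"`.
#' @return Object of class `famgxm_lme` with `beta`, `cov_beta`,
#'   `sigma2_g`, `sigma2_e`, `loglik`, `converged`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_lme_kinship <- function(data, formula, kinship, subject = subject_id,
                            method = c("REML", "ML")) {
  ids <- dplyr::pull(data, {{ subject }})
  if (inherits(kinship, "famgxm_pedigree")) kinship <- kinship_matrix(kinship)
  if (inherits(kinship, "famgxm_kinship")) {
    # subset to the rows present, preserving data order
    pos <- match(ids, kinship$ids)
    if (anyNA(pos)) abort("some subjects are missing from the kinship matrix",
                          class = "famgxm_kinship_error")
    A <- 2 * kinship$phi[pos, pos, drop = FALSE]
    e <- eigen(A, symmetric = TRUE)
    eig <- list(ids = ids, values = pmax(e$values, 0), vectors = e$vectors)
  } else if (inherits(kinship, "famgxm_kinship_eigen")) {
    if (!identical(as.character(ids), as.character(kinship$ids))) {
      abort("data rows must match the precomputed eigendecomposition order",
            class = "famgxm_kinship_error")
    }
    eig <- kinship
  } else {
    abort("kinship must be a famgxm_kinship, famgxm_kinship_eigen, or pedigree")
  }
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  fit <- lme_fit_core(y, X, eig, method)
  fit$formula <- formula
  class(fit) <- "famgxm_lme"
  fit
}

#' Wald test of a single fixed effect
#'
#' `z = beta_j / se_j` with a two-sided p-value from the standard normal
#' reference. Works for any fitted object in this package; for GEE and QIF
#' fits `cov` selects which covariance estimate supplies the standard
#' error.
#'
#' @param fit A `famgxm_lme`, `famgxm_gee` or `famgxm_qif`.
#' @param term Coefficient name or index.
#' @param cov For GEE: `"robust"`, `"bc"` or `"model"`; for QIF: `"plain"`
#'   or `"bc"`. Ignored for LME (model-based).
#' @return One-row tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
wald_fixed_effect <- function(fit, term, cov = NULL) {
  V <- fit_covariance(fit, cov)
  j <- if (is.character(term)) match(term, names(fit$beta)) else as.integer(term)
  if (is.na(j) || j < 1 || j > length(fit$beta)) {
    abort("term not found in the fitted coefficients",
          class = "famgxm_term_error")
  }
  est <- fit$beta[j]
  se <- sqrt(V[j, j])
  z <- est / se
  tibble(term = names(fit$beta)[j], estimate = unname(est),
         std.error = se, statistic = unname(z),
         p.value = 2 * pnorm(-abs(unname(z))))
}

fit_covariance <- function(fit, cov = NULL) {
  if (inherits(fit, "famgxm_lme")) return(fit$cov_beta)
  if (inherits(fit, "famgxm_gee")) {
    cov <- cov %||% "robust"
    return(switch(cov, robust = fit$cov_robust, bc = fit$cov_bc,
                  model = fit$cov_model,
                  abort("cov must be 'robust', 'bc' or 'model'")))
  }
  if (inherits(fit, "famgxm_qif")) {
    cov <- cov %||% "plain"
    return(switch(cov, plain = fit$cov_plain, bc = fit$cov_bc,
                  abort("cov must be 'plain' or 'bc'")))
  }
  abort("unsupported fit object")
}

#' @export
print.famgxm_lme <- function(x, ...) {
  cat(sprintf("<famgxm_lme: kinship mixed model (%s), %d obs>\n",
              x$method, x$n))
  cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f, loglik = %.2f\n",
              x$sigma2_g, x$sigma2_e, x$loglik))
  print(x$beta)
  invisible(x)
}
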