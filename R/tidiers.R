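# broom-style tidiers for the three fit classes.

tidy_from <- function(beta, V) {
  se <- sqrt(diag(V))
  z <- beta / se
  tibble(term = names(beta), estimate = unname(beta), std.error = unname(se),
         statistic = unname(z), p.value = 2 * pnorm(-abs(unname(z))))
}

#' @describeIn fit_gee Coefficient table; `cov` picks the covariance
#'   (`"robust"`, `"bc"` or `"model"`).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.famgxm_gee <- function(x, cov = c("robust", "bc", "model"), ...) {
  cov <- match.arg(cov)
  tidy_from(x$beta, fit_covariance(x, cov))
}

#' @describeIn fit_gee One-row model summary.
#' @export
glance.famgxm_gee <- function(x, ...) {
  tibble(alpha = x$alpha, phi = x$phi, n_clusters = x$N, n_obs = x$n,
         n_iter = x$n_iter, converged = x$converged)
}

#' @describeIn fit_qif Coefficient table; `cov` is `"plain"` or `"bc"`.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.famgxm_qif <- function(x, cov = c("plain", "bc"), ...) {
  cov <- match.arg(cov)
  tidy_from(x$beta, fit_covariance(x, cov))
}

#' @describeIn fit_qif One-row model summary including the minimized
#'   objective `q_stat`.
#' @export
glance.famgxm_qif <- function(x, ...) {
  tibble(q_stat = x$q_stat, n_clusters = x$N, n_obs = x$n,
         n_iter = x$n_iter, converged = x$converged)
}

#' @describeIn fit_lme_kinship Coefficient table (model-based covariance).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.famgxm_lme <- function(x, ...) {
  tidy_from(x$beta, x$cov_beta)
}

#' @describeIn fit_lme_kinship One-row summary with variance components.
#' @export
glance.famgxm_lme <- function(x, ...) {
  tibble(sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
         heritability = x$sigma2_g / (x$sigma2_g + x$sigma2_e),
         logLik = x$loglik, method = x$method, n_obs = x$n,
         converged = x$converged)
}
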