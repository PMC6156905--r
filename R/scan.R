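# Per-site regression assembly and the replicate scan that produces the
# empirical power / Type I error tables.

#' Build the per-site regression problem
#'
#' Assembles outcome and design matrix for one SNP-CpG site under one
#' outcome setting. TG values are log-transformed; SNP dosage and CpG
#' methylation are standardized (mean 0, SD 1) within the replicate. The
#' design columns are intercept, standardized SNP, standardized CpG, their
#' product, age, sex (female = 1), center indicators against the first
#' level and — in the `"prepost"` setting — log pretreatment TG. In the
#' `"change"` setting the outcome is `log(tg_post) - log(tg_pre)` with no
#' baseline covariate.
#'
#' @param data One replicate's subject table (as produced by
#'   [simulate_replicate()]; any data frame with the same columns works).
#' @param site Site id, e.g. `"s1"` (expects `g_<site>` and `m_<site>`
#'   columns).
#' @param setting `"prepost"` or `"change"`.
#' @return List with `y`, `X`, `family` (cluster ids aligned with rows),
#'   `subject`, and `interaction` (the product-term column name).
#' @export
build_design <- function(data, site, setting = c("prepost", "change")) {
  setting <- match.arg(setting)
  gcol <- paste0("g_", site)
  mcol <- paste0("m_", site)
  if (!all(c(gcol, mcol) %in% names(data))) {
    abort(paste0("no genotype/methylation columns for site ", site),
          class = "famgxm_design_error")
  }
  data <- data[stats::complete.cases(
    data[c(gcol, mcol, "tg_pre", "tg_post", "age", "sex", "center")]), ]
  g <- data[[gcol]]
  m <- data[[mcol]]
  if (sd(g) == 0 || sd(m) == 0) {
    abort(paste0("zero variance SNP or CpG at site ", site),
          class = "famgxm_degenerate_site")
  }
  snp <- as.vector(scale(g))
  cpg <- as.vector(scale(m))
  log_pre <- log(data$tg_pre)
  Xdf <- tibble(
    snp = snp, cpg = cpg, snp_cpg = snp * cpg,
    age = data$age, sexF = as.numeric(data$sex == "female")
  )
  cen <- factor(data$center)
  if (nlevels(cen) > 1) {
    cm <- model.matrix(~cen)[, -1, drop = FALSE]
    colnames(cm) <- paste0("center", levels(cen)[-1])
    Xdf <- dplyr::bind_cols(Xdf, as_tibble(cm))
  }
  if (setting == "prepost") {
    y <- log(data$tg_post)
    Xdf$log_pre <- log_pre
  } else {
    y <- log(data$tg_post) - log_pre
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(Xdf))
  list(y = y, X = X, family = data$family_id, subject = data$subject_id,
       interaction = "snp_cpg", setting = setting, site = site)
}

model_grid <- function(estimators, settings) {
  tidyr::expand_grid(estimator = estimators, setting = settings)
}

#' Scan all replicates, sites and models
#'
#' For every replicate x site x outcome setting, fits the kinship LME, GEE
#' (exchangeable) and QIF models as requested and records the Wald test of
#' the SNP-by-CpG product term. The five estimator labels map to fits and
#' covariances as: `"lme"` (model-based), `"gee"` (robust sandwich),
#' `"gee-bc"` (Mancl-DeRouen), `"qif"` (plain GMM), `"qif-bc"`
#' (leverage-corrected). BC variants share their parent fit's coefficients
#' and differ only in the standard error. Non-convergent fits are recorded
#' with `converged = FALSE` and an `NA` p-value.
#'
#' @param cohort A `famgxm_cohort` from [simulate_cohort()].
#' @param estimators Subset of `c("lme", "gee", "gee-bc", "qif", "qif-bc")`.
#' @param settings Subset of `c("prepost", "change")`.
#' @return Tibble of class `famgxm_scan`: one row per replicate x site x
#'   estimator x setting with `estimate`, `std.error`, `statistic`,
#'   `p.value`, `converged`, plus site metadata (`causal`, `h2`).
#' @export
run_scan <- function(cohort,
                     estimators = c("lme", "gee", "gee-bc", "qif", "qif-bc"),
                     settings = c("prepost", "change")) {
  stopifnot(inherits(cohort, "famgxm_cohort"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  settings <- match.arg(settings, several.ok = TRUE)
  need_lme <- "lme" %in% estimators
  need_gee <- any(c("gee", "gee-bc") %in% estimators)
  need_qif <- any(c("qif", "qif-bc") %in% estimators)
  eig <- if (need_lme) kinship_eigen(cohort$kinship) else NULL
  sites <- cohort$config$sites
  reps <- split(cohort$replicates,
                cohort$replicates$replicate)
  out <- vector("list", length(reps) * nrow(sites) * length(settings))
  k <- 0L
  skipped <- 0L
  for (rd in reps) {
    r <- rd$replicate[1]
    for (s in seq_len(nrow(sites))) {
      for (setting in settings) {
        k <- k + 1L
        d <- tryCatch(build_design(rd, sites$site_id[s], setting),
                      famgxm_degenerate_site = function(e) NULL)
        if (is.null(d)) { skipped <- skipped + 1L; next }
        rows <- list()
        j <- match(d$interaction, colnames(d$X))
        if (need_lme) {
          fit <- lme_fit_core(d$y, d$X, eig)
          rows$lme <- wald_row("lme", fit$beta[j],
                               sqrt(fit$cov_beta[j, j]), fit$converged)
        }
        if (need_gee) {
          fit <- gee_fit_core(d$y, d$X, d$family)
          rows$gee <- wald_row("gee", fit$beta[j],
                               sqrt(fit$cov_robust[j, j]), fit$converged)
          rows$`gee-bc` <- wald_row("gee-bc", fit$beta[j],
                                    sqrt(fit$cov_bc[j, j]), fit$converged)
        }
        if (need_qif) {
          fit <- qif_fit_core(d$y, d$X, d$family)
          fit$cov_bc <- qif_bc_core(fit)
          rows$qif <- wald_row("qif", fit$beta[j],
                               sqrt(fit$cov_plain[j, j]), fit$converged)
          rows$`qif-bc` <- wald_row("qif-bc", fit$beta[j],
                                    sqrt(fit$cov_bc[j, j]), fit$converged)
        }
        rows <- dplyr::bind_rows(rows[intersect(
          c("lme", "gee", "gee-bc", "qif", "qif-bc"), names(rows))])
        rows <- rows[rows$estimator %in% estimators, ]
        out[[k]] <- dplyr::bind_cols(
          tibble(replicate = r, site = sites$site_id[s],
                 causal = sites$causal[s], h2 = sites$h2[s],
                 setting = setting),
          rows)
      }
    }
  }
  if (skipped > 0) {
    warn(sprintf("%d replicate-site designs skipped (zero-variance SNP or CpG)",
                 skipped))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("famgxm_scan", class(res))
  res
}

wald_row <- function(estimator, est, se, converged) {
  z <- est / se
  tibble(estimator = estimator, estimate = unname(est), std.error = se,
         statistic = unname(z),
         p.value = if (converged) 2 * pnorm(-abs(unname(z))) else NA_real_,
         converged = converged)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests corrected for (e.g. 461281 genome-wide
#'   CpG sites).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 461281) # ~1.08e-7
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}

#' Summarize empirical power and Type I error
#'
#' Power at a causal site is the fraction of replicates whose interaction
#' p-value falls below the threshold; the Type I error is pooled over all
#' noncausal sites and replicates (count significant / (sites x
#' replicates)). Non-convergent fits are excluded from both numerator and
#' denominator; `n` records the denominator actually used.
#'
#' @param results A `famgxm_scan` from [run_scan()].
#' @param thresholds Significance thresholds; default nominal 0.05 and the
#'   genome-wide Bonferroni threshold 0.05/461281.
#' @return Tibble of class `famgxm_power`: one row per estimator x setting
#'   x threshold x site (plus one pooled `type1` row per estimator x
#'   setting x threshold), with columns `metric` (`"power"`/`"type1"`),
#'   `site`, `h2`, `rate`, `n`.
#' @export
summarize_power <- function(results,
                            thresholds = c(0.05,
                                           bonferroni_threshold(0.05, 461281))) {
  ok <- dplyr::filter(results, .data$converged, !is.na(.data$p.value))
  per_thr <- purrr::map(thresholds, function(thr) {
    pw <- ok |>
      dplyr::filter(.data$causal) |>
      dplyr::group_by(.data$estimator, .data$setting, .data$site, .data$h2) |>
      dplyr::summarise(rate = mean(.data$p.value < thr),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(metric = "power", threshold = thr)
    t1 <- ok |>
      dplyr::filter(!.data$causal) |>
      dplyr::group_by(.data$estimator, .data$setting) |>
      dplyr::summarise(rate = mean(.data$p.value < thr),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(metric = "type1", site = NA_character_, h2 = NA_real_,
                    threshold = thr)
    dplyr::bind_rows(pw, t1)
  })
  res <- dplyr::bind_rows(per_thr) |>
    dplyr::select("estimator", "setting", "threshold", "metric",
                  "site", "h2", "rate", "n")
  if (any(res$n == 0)) warn("some rates have an empty denominator")
  class(res) <- c("famgxm_power", class(res))
  res
}

#' Wide power table
#'
#' Pivots a [summarize_power()] result into the conventional layout: one
#' row per estimator x setting x threshold, per-site power columns ordered
#' by decreasing heritability, and the pooled Type I error last.
#'
#' @param power A `famgxm_power`.
#' @return A wide tibble.
#' @export
power_wide <- function(power) {
  pw <- power |>
    dplyr::filter(.data$metric == "power") |>
    dplyr::arrange(dplyr::desc(.data$h2)) |>
    dplyr::mutate(col = sprintf("%s (h2=%.3g)", .data$site, .data$h2)) |>
    dplyr::select("estimator", "setting", "threshold", "col", "rate") |>
    tidyr::pivot_wider(names_from = "col", values_from = "rate")
  t1 <- power |>
    dplyr::filter(.data$metric == "type1") |>
    dplyr::select("estimator", "setting", "threshold", type1 = "rate")
  dplyr::left_join(pw, t1, by = c("estimator", "setting", "threshold"))
}
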