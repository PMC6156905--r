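#' Simulation scenario configuration
#'
#' Bundles every knob of the family-clustered pharmacoepigenetic simulation:
#' cohort shape, per-site minor-allele frequencies and heritabilities, the
#' methylation distribution, variance components of log-triglycerides, the
#' baseline-anchoring coefficient, covariate effects, replicate count and
#' master seed.
#'
#' Causal sites carry an expected heritability `h2`: the fraction of the
#' null-model outcome variance (family + residual + covariates) contributed
#' by the site's suppression term `b * G * (1 - M)`, where `G` is allele
#' dosage and `M` the methylation proportion. Noncausal sites carry no
#' effect but their CpGs share a fraction `cpg_shared_var_frac` of latent
#' variance with a paired causal CpG.
#'
#' @param n_families Number of families (>= 2).
#' @param family_size_mean Expected members per nuclear family (2 founders
#'   plus a zero-truncated Poisson number of offspring).
#' @param n_total If not `NA`, offspring counts are nudged so the cohort has
#'   exactly this many individuals.
#' @param sites Tibble with columns `site_id`, `causal` (logical), `h2`
#'   (`NA` for noncausal sites), `maf`, and `pair` (for a noncausal site,
#'   the `site_id` of the causal CpG it shares variability with; `NA`
#'   otherwise).
#' @param sigma_family Family (polygenic) SD on the log-TG scale; the
#'   genetic random effect has covariance `sigma_family^2 * 2 * Phi`.
#' @param sigma_resid Residual SD on the log-TG scale.
#' @param baseline_anchor Coefficient anchoring the pretreatment mean to the
#'   non-treatment part of the posttreatment linear predictor.
#' @param treatment_shift Mean log-TG reduction from pre to post (pre mean
#'   is `mu_post + treatment_shift`).
#' @param mu_post Posttreatment mean log-TG.
#' @param beta_age,beta_sex,beta_center Covariate effects on log-TG; ages in
#'   years (centred at 50 in the generative model), sex coded female = 1,
#'   `beta_center` one effect per study center with the first as reference.
#' @param methylation Methylation distribution: `list(dist = "uniform")` or
#'   `list(dist = "beta", shape1 =, shape2 =)`.
#' @param cpg_shared_var_frac Fraction of a noncausal CpG's latent variance
#'   shared with its paired causal CpG, in `[0, 1)`.
#' @param n_replicates Number of simulation replicates.
#' @param seed Master seed; per-replicate child seeds are derived from it.
#' @return A list of class `famgxm_scenario`.
#' @seealso [default_gaw20_scenario()] for the preset emulating the study
#'   conditions this package was built around.
#' @export
scenario_config <- function(n_families = 164,
                            family_size_mean = 680 / 164,
                            n_total = NA_integer_,
                            sites = default_sites(),
                            sigma_family = 0.3,
                            sigma_resid = 0.4,
                            baseline_anchor = 0.6,
                            treatment_shift = 0.25,
                            mu_post = log(120),
                            beta_age = 0.004,
                            beta_sex = -0.08,
                            beta_center = c(0, 0.05, -0.05),
                            methylation = list(dist = "uniform"),
                            cpg_shared_var_frac = 0.5,
                            n_replicates = 200,
                            seed = 1L) {
  sites <- as_tibble(sites)
  stopifnot(all(c("site_id", "causal", "h2", "maf") %in% names(sites)))
  if (!"pair" %in% names(sites)) sites$pair <- NA_character_
  if (n_families < 2) {
    abort("n_families must be >= 2", class = "famgxm_config_error")
  }
  if (any(sites$maf <= 0 | sites$maf > 0.5)) {
    abort("maf must lie in (0, 0.5]", class = "famgxm_config_error")
  }
  h2 <- sites$h2[sites$causal]
  if (any(is.na(h2)) || any(h2 < 0 | h2 >= 1)) {
    abort("causal sites need h2 in [0, 1)", class = "famgxm_config_error")
  }
  if (any(!is.na(sites$h2[!sites$causal]))) {
    abort("noncausal sites must not carry h2", class = "famgxm_config_error")
  }
  if (cpg_shared_var_frac < 0 || cpg_shared_var_frac >= 1) {
    abort("cpg_shared_var_frac must lie in [0, 1)", class = "famgxm_config_error")
  }
  if (!methylation$dist %in% c("uniform", "beta")) {
    abort("methylation dist must be 'uniform' or 'beta'", class = "famgxm_config_error")
  }
  # noncausal sites default to cyclic pairing with the causal sites
  causal_ids <- sites$site_id[sites$causal]
  nc <- which(!sites$causal & is.na(sites$pair))
  if (length(nc) > 0 && length(causal_ids) > 0) {
    sites$pair[nc] <- causal_ids[((seq_along(nc) - 1L) %% length(causal_ids)) + 1L]
  }
  structure(list(
    n_families = as.integer(n_families),
    family_size_mean = family_size_mean,
    n_total = n_total,
    sites = sites,
    sigma_family = sigma_family,
    sigma_resid = sigma_resid,
    baseline_anchor = baseline_anchor,
    treatment_shift = treatment_shift,
    mu_post = mu_post,
    beta_age = beta_age,
    beta_sex = beta_sex,
    beta_center = beta_center,
    methylation = methylation,
    cpg_shared_var_frac = cpg_shared_var_frac,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "famgxm_scenario")
}

default_sites <- function(h2 = c(0.125, 0.10, 0.075, 0.05, 0.025), maf = 0.3) {
  tibble(
    site_id = paste0("s", 1:10),
    causal = rep(c(TRUE, FALSE), each = 5),
    h2 = c(h2, rep(NA_real_, 5)),
    maf = maf,
    pair = c(rep(NA_character_, 5), paste0("s", 1:5))
  )
}

#' Default study scenario
#'
#' The preset simulation: 164 nuclear families totalling exactly 680
#' individuals, 10 SNP-CpG pairs of which 5 are causal with expected
#' heritabilities 0.125, 0.10, 0.075, 0.05 and 0.025 (fully expressed at
#' methylation 0, fully suppressed at methylation 1), 5 noncausal pairs
#' whose CpGs share half their latent variance with the causal CpGs,
#' pretreatment log-TG anchored to the posttreatment mean, covariates age,
#' sex and study center, and 200 replicates.
#'
#' @param seed Master seed.
#' @param n_replicates Replicate count (default 200).
#' @param null_effects If `TRUE`, every causal heritability is set to zero
#'   (a global-null scenario for Type I error calibration); site labels and
#'   everything else are unchanged.
#' @return A [scenario_config()].
#' @export
default_gaw20_scenario <- function(seed = 1L, n_replicates = 200,
                                   null_effects = FALSE) {
  sites <- default_sites()
  if (null_effects) sites$h2[sites$causal] <- 0
  scenario_config(n_families = 164, n_total = 680L, sites = sites,
                  n_replicates = n_replicates, seed = seed)
}

#' @export
print.famgxm_scenario <- function(x, ...) {
  cat(sprintf(paste0(
    "<famgxm_scenario: %d families (target n = %s), %d sites (%d causal),\n",
    "  sigma_family = %.3g, sigma_resid = %.3g, anchor = %.3g, %d replicates, seed %d>\n"),
    x$n_families, ifelse(is.na(x$n_total), "free", x$n_total),
    nrow(x$sites), sum(x$sites$causal),
    x$sigma_family, x$sigma_resid, x$baseline_anchor,
    x$n_replicates, x$seed))
  invisible(x)
}

# First/second moments of (1 - M) and the variance of M under the
# configured methylation distribution.
meth_moments <- function(methylation) {
  if (methylation$dist == "uniform") {
    list(mean = 0.5, var = 1 / 12, one_minus_m1 = 0.5, one_minus_m2 = 1 / 3)
  } else {
    a <- methylation$shape1
    b <- methylation$shape2
    mu <- a / (a + b)
    v <- a * b / ((a + b)^2 * (a + b + 1))
    list(mean = mu, var = v, one_minus_m1 = 1 - mu,
         one_minus_m2 = (1 - mu)^2 + v)
  }
}

#' Calibrate a causal effect size to an expected heritability
#'
#' Returns the coefficient `b` of the suppression term `b * G * (1 - M)`
#' such that its variance equals `h2 * var_total`, with dosage
#' `G ~ Binomial(2, maf)` independent of methylation `M`:
#' `b = sqrt(h2 * var_total / (E[G^2] E[(1-M)^2] - E[G]^2 E[1-M]^2))`.
#' Under Uniform(0,1) methylation `E[(1-M)^2] = 1/3` and `E[1-M] = 1/2`.
#'
#' @param h2 Expected heritability in `[0, 1)`; `h2 = 0` gives `b = 0`.
#' @param var_total Reference outcome variance (the null-model marginal
#'   variance of posttreatment log-TG).
#' @param maf Minor-allele frequency in `(0, 0.5]`.
#' @param methylation Methylation distribution spec as in
#'   [scenario_config()].
#' @return The nonnegative effect size `b`.
#' @export
calibrate_effect <- function(h2, var_total, maf,
                             methylation = list(dist = "uniform")) {
  if (is.na(h2) || h2 < 0 || h2 >= 1) {
    abort("h2 must lie in [0, 1)", class = "famgxm_calibration_error")
  }
  if (var_total <= 0) {
    abort("var_total must be positive", class = "famgxm_calibration_error")
  }
  if (maf <= 0 || maf > 0.5) {
    abort("maf must lie in (0, 0.5]", class = "famgxm_config_error")
  }
  mm <- meth_moments(methylation)
  eg <- 2 * maf
  eg2 <- 2 * maf * (1 - maf) + (2 * maf)^2
  denom <- eg2 * mm$one_minus_m2 - eg^2 * mm$one_minus_m1^2
  if (denom <= 0) {
    abort("suppression term has no attainable variance under this configuration",
          class = "famgxm_calibration_error")
  }
  sqrt(h2 * var_total / denom)
}
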