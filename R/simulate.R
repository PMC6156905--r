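#' Simulate a nuclear-family pedigree for a scenario
#'
#' Families have two founders and a zero-truncated Poisson number of
#' offspring with mean `family_size_mean - 2`; when the scenario fixes
#' `n_total`, offspring counts are nudged (keeping at least one child per
#' family) until the cohort size matches exactly. Uses the current RNG
#' state.
#'
#' @param cfg A [scenario_config()].
#' @return A [pedigree()].
#' @export
simulate_pedigree <- function(cfg) {
  k_mean <- cfg$family_size_mean - 2
  if (k_mean <= 0) abort("family_size_mean must exceed 2", class = "famgxm_config_error")
  # lambda of the zero-truncated Poisson with the requested mean
  lam <- stats::uniroot(function(l) l / (1 - exp(-l)) - k_mean,
                        c(1e-8, 50))$root
  nf <- cfg$n_families
  k <- stats::qpois(runif(nf, stats::dpois(0, lam), 1), lam) # >= 1 by construction
  if (!is.na(cfg$n_total)) {
    target <- cfg$n_total - 2L * nf
    if (target < nf) abort("n_total too small for one offspring per family",
                           class = "famgxm_config_error")
    while (sum(k) != target) {
      if (sum(k) < target) {
        i <- sample.int(nf, 1)
        k[i] <- k[i] + 1L
      } else {
        cand <- which(k > 1L)
        i <- cand[sample.int(length(cand), 1)]
        k[i] <- k[i] - 1L
      }
    }
  }
  fam_ids <- sprintf("F%03d", seq_len(nf))
  rows <- purrr::map2(fam_ids, k, function(fid, kk) {
    ids <- paste0(fid, "_", seq_len(kk + 2L))
    tibble(
      family_id = fid,
      individual_id = ids,
      father_id = c(NA, NA, rep(ids[1], kk)),
      mother_id = c(NA, NA, rep(ids[2], kk)),
      sex = c("male", "female",
              sample(c("male", "female"), kk, replace = TRUE))
    )
  })
  pedigree(dplyr::bind_rows(rows))
}

#' Drop genotypes through a pedigree
#'
#' Founders draw allele dosages from Binomial(2, maf); each offspring
#' receives one allele from each parent, transmitted with probability
#' dosage/2, so genotypes are Mendelian-consistent by construction. Uses
#' the current RNG state.
#'
#' @param ped A [pedigree()].
#' @param maf Minor-allele frequency per site, recycled to `n_sites`.
#' @param n_sites Number of independent sites to simulate.
#' @return Integer matrix (individuals x sites) of dosages in 0:2, rows in
#'   pedigree order with `individual_id` rownames.
#' @export
simulate_genotypes <- function(ped, maf, n_sites = length(maf)) {
  ped <- as_pedigree(ped)
  maf <- rep_len(maf, n_sites)
  if (any(maf <= 0 | maf > 0.5)) {
    abort("maf must lie in (0, 0.5]", class = "famgxm_config_error")
  }
  ord <- ped_topological_order(ped)
  ids <- ped$individual_id[ord]
  fa <- match(ped$father_id[ord], ids)
  mo <- match(ped$mother_id[ord], ids)
  n <- length(ids)
  # generation depth allows vectorised gene dropping level by level
  depth <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(fa[i])) depth[i] <- max(depth[fa[i]], depth[mo[i]]) + 1L
  }
  G <- matrix(0L, n, n_sites, dimnames = list(ids, NULL))
  for (s in seq_len(n_sites)) {
    founders <- which(depth == 0L)
    G[founders, s] <- rbinom(length(founders), 2L, maf[s])
    for (d in seq_len(max(depth))) {
      lev <- which(depth == d)
      if (length(lev) == 0) next
      G[lev, s] <- rbinom(length(lev), 1L, G[fa[lev], s] / 2) +
        rbinom(length(lev), 1L, G[mo[lev], s] / 2)
    }
  }
  # return in the original row order of the pedigree
  G[match(ped$individual_id, ids), , drop = FALSE]
}

#' Simulate CpG methylation proportions
#'
#' Causal-site methylation is drawn i.i.d. from the configured distribution
#' on \[0, 1\] (Uniform(0,1) by default). Each noncausal CpG is built from
#' its paired causal CpG: the causal signal is standardized, mixed with
#' independent Gaussian noise as
#' `sqrt(f) * z_causal + sqrt(1 - f) * noise` with
#' `f = cpg_shared_var_frac`, mapped back to the methylation scale, and
#' clamped to \[0, 1\]. Uses the current RNG state.
#'
#' @param n Number of subjects.
#' @param cfg A [scenario_config()] (supplies `sites`, the methylation
#'   distribution and `cpg_shared_var_frac`).
#' @return Numeric matrix (subjects x sites) with columns named by
#'   `site_id`, all entries in \[0, 1\].
#' @export
simulate_methylation <- function(n, cfg) {
  sites <- cfg$sites
  f <- cfg$cpg_shared_var_frac
  mm <- meth_moments(cfg$methylation)
  M <- matrix(NA_real_, n, nrow(sites),
              dimnames = list(NULL, sites$site_id))
  draw <- function(n) {
    if (cfg$methylation$dist == "uniform") runif(n)
    else rbeta(n, cfg$methylation$shape1, cfg$methylation$shape2)
  }
  for (j in which(sites$causal)) M[, j] <- draw(n)
  # any unpaired noncausal site just gets an independent draw
  for (j in which(!sites$causal)) {
    pj <- match(sites$pair[j], sites$site_id)
    if (is.na(pj)) {
      M[, j] <- draw(n)
    } else {
      z <- (M[, pj] - mm$mean) / sqrt(mm$var)
      lat <- sqrt(f) * z + sqrt(1 - f) * rnorm(n)
      M[, j] <- pmin(pmax(mm$mean + lat * sqrt(mm$var), 0), 1)
    }
  }
  M
}

# Fixed (across-replicate) cohort structure: pedigree, kinship, ages, sex,
# centers, the Cholesky factor of 2*Phi for drawing family effects, the
# realized covariate linear predictor and the null-model outcome variance
# used to calibrate causal effects.
build_cohort_structure <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  kin <- kinship_matrix(ped)
  # reorder pedigree rows to the kinship (family-block) ordering once
  ped <- ped[match(kin$ids, ped$individual_id), ]
  n <- nrow(ped)
  founder <- is.na(ped$father_id)
  age <- numeric(n)
  age[founder] <- rnorm(sum(founder), 53, 7)
  age[!founder] <- rnorm(sum(!founder), 27, 6)
  age <- round(pmax(age, 18))
  n_centers <- length(cfg$beta_center)
  fam_levels <- unique(ped$family_id)
  center_of_family <- sample.int(n_centers, length(fam_levels), replace = TRUE)
  center <- center_of_family[match(ped$family_id, fam_levels)]
  eta_cov <- cfg$beta_age * (age - 50) +
    cfg$beta_sex * (ped$sex == "female") +
    cfg$beta_center[center]
  var_null <- cfg$sigma_family^2 + cfg$sigma_resid^2 + var(eta_cov)
  A <- relationship_matrix(kin)
  L <- t(chol(A + diag(1e-10, n)))
  b <- vapply(seq_len(nrow(cfg$sites)), function(j) {
    if (!cfg$sites$causal[j] || cfg$sites$h2[j] == 0) return(0)
    calibrate_effect(cfg$sites$h2[j], var_null, cfg$sites$maf[j],
                     cfg$methylation)
  }, numeric(1))
  names(b) <- cfg$sites$site_id
  list(pedigree = ped, kinship = kin, age = age, center = center,
       eta_cov = eta_cov, var_null = var_null, L = L, b = b)
}

#' Simulate one cohort replicate
#'
#' Draws genotypes, methylation, the family genetic effect and residual
#' noise, and assembles pre/posttreatment triglycerides on the natural
#' scale. On the log scale the posttreatment outcome is
#' `mu + sum_k b_k G_k (1 - M_k) + covariates + g + eps` with
#' `g ~ N(0, sigma_family^2 * 2 * Phi)`; the pretreatment value is anchored
#' to the non-treatment part of the posttreatment mean
#' (`mu + shift + anchor * (covariates + g) + noise`), so it carries family
#' and covariate signal but none of the causal interaction. Uses the
#' current RNG state.
#'
#' @param cfg A [scenario_config()].
#' @param structure Internal cohort structure; built from `cfg` when `NULL`
#'   (callers looping over replicates should build it once via
#'   [simulate_cohort()]).
#' @return A tibble with one row per subject: ids, covariates, `tg_pre`,
#'   `tg_post`, and per-site dosage (`g_<site>`) and methylation
#'   (`m_<site>`) columns.
#' @export
simulate_replicate <- function(cfg, structure = NULL) {
  st <- structure %||% build_cohort_structure(cfg)
  ped <- st$pedigree
  n <- nrow(ped)
  sites <- cfg$sites
  G <- simulate_genotypes(ped, sites$maf, nrow(sites))
  M <- simulate_methylation(n, cfg)
  g <- cfg$sigma_family * as.vector(st$L %*% rnorm(n))
  eps <- rnorm(n, 0, cfg$sigma_resid)
  causal_term <- as.vector((G * (1 - M)) %*% st$b)
  post_log <- cfg$mu_post + st$eta_cov + causal_term + g + eps
  sigma_nu2 <- st$var_null -
    cfg$baseline_anchor^2 * (var(st$eta_cov) + cfg$sigma_family^2)
  nu <- rnorm(n, 0, sqrt(max(sigma_nu2, 0.01)))
  pre_log <- cfg$mu_post + cfg$treatment_shift +
    cfg$baseline_anchor * (st$eta_cov + g) + nu
  out <- tibble(
    subject_id = ped$individual_id,
    family_id = ped$family_id,
    sex = ped$sex,
    age = st$age,
    center = factor(paste0("c", st$center),
                    levels = paste0("c", seq_along(cfg$beta_center))),
    tg_pre = exp(pre_log),
    tg_post = exp(post_log)
  )
  colnames(G) <- paste0("g_", sites$site_id)
  colnames(M) <- paste0("m_", sites$site_id)
  dplyr::bind_cols(out, as_tibble(G), as_tibble(M))
}

#' Simulate a full replicate set
#'
#' Seeds the RNG from the scenario's master seed, builds the fixed cohort
#' structure (pedigree, kinship, covariates, calibrated effects), then
#' derives one child seed per replicate so any replicate can be reproduced
#' independently.
#'
#' @param cfg A [scenario_config()].
#' @return An object of class `famgxm_cohort`: list with `config`,
#'   `pedigree`, `kinship`, calibrated effects `b`, the null-model outcome
#'   variance `var_null`, and `replicates` (a tibble stacking all
#'   replicates with a leading `replicate` column).
#' @export
simulate_cohort <- function(cfg) {
  set.seed(cfg$seed)
  st <- build_cohort_structure(cfg)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_replicates)
  reps <- purrr::map(seq_len(cfg$n_replicates), function(r) {
    set.seed(rep_seeds[r])
    dplyr::bind_cols(tibble(replicate = r), simulate_replicate(cfg, st))
  })
  structure(list(
    config = cfg,
    pedigree = st$pedigree,
    kinship = st$kinship,
    b = st$b,
    var_null = st$var_null,
    replicate_seeds = rep_seeds,
    replicates = dplyr::bind_rows(reps)
  ), class = "famgxm_cohort")
}

#' @export
print.famgxm_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "<famgxm_cohort: %d subjects in %d families, %d replicates,\n",
    "  %d sites (%d causal), null outcome variance %.4f>\n"),
    nrow(x$pedigree), length(unique(x$pedigree$family_id)),
    x$config$n_replicates, nrow(x$config$sites),
    sum(x$config$sites$causal), x$var_null))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Serializes the replicate table as tidy CSV, the pedigree as PED, and the
#' scenario as YAML into `dir`.
#'
#' @param cohort A `famgxm_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "famgxm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$replicates, file.path(dir, "replicates.csv"))
  write_ped(cohort$pedigree, file.path(dir, "pedigree.ped"))
  cfg <- cohort$config
  cfg$sites <- as.data.frame(cfg$sites)
  yaml::write_yaml(unclass(cfg), file.path(dir, "scenario.yaml"))
  invisible(dir)
}
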