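test_that("gene dropping is Mendelian-consistent and hits the allele frequency", {
  ped <- make_ped("F1", c("A", "B", "C", "D"),
                  c(NA, NA, "A", "A"), c(NA, NA, "B", "B"),
                  c("male", "female", "male", "female"))
  # forcing: homozygous parents determine the offspring
  set.seed(1)
  for (i in 1:20) {
    G <- simulate_genotypes(ped, 0.5, 1)
    if (G["A", 1] == 0 && G["B", 1] == 0) expect_true(all(G[c("C", "D"), 1] == 0))
    if (G["A", 1] == 2 && G["B", 1] == 2) expect_true(all(G[c("C", "D"), 1] == 2))
    # offspring dosage never exceeds what the parents can transmit
    expect_true(all(G[c("C", "D"), 1] <= ceiling(G["A", 1] / 2) + ceiling(G["B", 1] / 2)))
    expect_true(all(G[c("C", "D"), 1] >= floor(G["A", 1] / 2) + floor(G["B", 1] / 2)))
  }

  # founders-only cohort: mean dosage -> 2 * maf
  founders <- pedigree(data.frame(
    family_id = paste0("F", 1:10000), individual_id = paste0("I", 1:10000),
    father_id = NA, mother_id = NA, sex = "male"))
  set.seed(2)
  G <- simulate_genotypes(founders, 0.3, 1)
  se <- sqrt(2 * 0.3 * 0.7 / 10000)
  expect_lt(abs(mean(G) - 0.6), 3 * se)

  expect_error(simulate_genotypes(ped, 0.7), class = "famgxm_config_error")
})

test_that("Mendelian consistency holds across random pedigrees", {
  set.seed(33)
  for (rep in 1:10) {
    ped <- random_outbred_ped(12)
    G <- simulate_genotypes(ped, runif(1, 0.05, 0.5), 1)
    fa <- match(ped$father_id, ped$individual_id)
    mo <- match(ped$mother_id, ped$individual_id)
    kids <- which(!is.na(fa))
    for (k in kids) {
      lo <- floor(G[fa[k], 1] / 2) + floor(G[mo[k], 1] / 2)
      hi <- ceiling(G[fa[k], 1] / 2) + ceiling(G[mo[k], 1] / 2)
      expect_true(G[k, 1] >= lo && G[k, 1] <= hi)
    }
  }
})

test_that("noncausal CpGs share the configured variance fraction", {
  n <- 10000
  cfg0 <- scenario_config(cpg_shared_var_frac = 0)
  set.seed(3)
  M <- simulate_methylation(n, cfg0)
  expect_true(all(M >= 0 & M <= 1))
  expect_lt(abs(cor(M[, "s6"], M[, "s1"])), 3 / sqrt(n) + 0.01)

  cfg5 <- scenario_config(cpg_shared_var_frac = 0.5)
  set.seed(4)
  M <- simulate_methylation(n, cfg5)
  expect_true(all(M >= 0 & M <= 1))
  # quadrature oracle for the clamped-mixture correlation (near sqrt(0.5))
  target <- expected_noncausal_cor(0.5)
  expect_equal(target, sqrt(0.5), tolerance = 0.05)
  expect_lt(abs(cor(M[, "s6"], M[, "s1"]) - target), 3 / sqrt(n) + 0.01)

  expect_error(scenario_config(cpg_shared_var_frac = 1),
               class = "famgxm_config_error")
})

test_that("effect calibration delivers the requested variance fraction", {
  expect_equal(calibrate_effect(0, 1, 0.3), 0)
  expect_error(calibrate_effect(1.2, 1, 0.3), class = "famgxm_calibration_error")
  expect_error(calibrate_effect(0.1, -1, 0.3), class = "famgxm_calibration_error")

  b <- calibrate_effect(0.125, 1, 0.3)
  set.seed(6)
  n <- 2e5
  G <- rbinom(n, 2, 0.3)
  M <- runif(n)
  expect_lt(abs(var(b * G * (1 - M)) - 0.125), 0.005)

  # beta-distributed methylation uses its own moments
  meth <- list(dist = "beta", shape1 = 0.5, shape2 = 0.5)
  b2 <- calibrate_effect(0.1, 2, 0.4, meth)
  set.seed(7)
  G <- rbinom(n, 2, 0.4)
  M <- rbeta(n, 0.5, 0.5)
  expect_lt(abs(var(b2 * G * (1 - M)) / 2 - 0.1), 0.005)
})

test_that("null replicates have the advertised outcome variance and normality", {
  cfg <- scenario_config(n_families = 164, n_total = 680L,
                         sites = default_sites(h2 = rep(0, 5)),
                         sigma_family = 0, seed = 8)
  co <- simulate_cohort(scenario_config(
    n_families = 164, n_total = 680L,
    sites = default_sites(h2 = rep(0, 5)),
    sigma_family = 0, n_replicates = 2, seed = 8))
  y <- log(co$replicates$tg_post[co$replicates$replicate == 1])
  expect_equal(var(y), co$var_null, tolerance = 0.15)
  expect_gt(stats::shapiro.test(y)$p.value, 1e-4)
})

test_that("family effects induce the analytic sibling intraclass correlation", {
  cfg <- scenario_config(n_families = 800, sites = default_sites(h2 = rep(0, 5)),
                         beta_age = 0, beta_sex = 0, beta_center = c(0, 0, 0),
                         n_replicates = 3, seed = 9)
  co <- simulate_cohort(cfg)
  icc_target <- 0.5 * cfg$sigma_family^2 / (cfg$sigma_family^2 + cfg$sigma_resid^2)
  reps <- co$replicates
  kids <- reps[!is.na(match(reps$subject_id, co$pedigree$individual_id)) &
                 !is.na(co$pedigree$father_id[match(reps$subject_id,
                                                    co$pedigree$individual_id)]), ]
  pairs <- kids |>
    dplyr::group_by(.data$replicate, .data$family_id) |>
    dplyr::summarise(y1 = log(tg_post[1]), y2 = log(tg_post[2]),
                     nk = dplyr::n(), .groups = "drop") |>
    dplyr::filter(nk >= 2)
  r_sib <- cor(pairs$y1, pairs$y2)
  expect_lt(abs(r_sib - icc_target), 3 / sqrt(nrow(pairs)))
  # spouses are unrelated: founder pairs should be uncorrelated
  founders <- reps[is.na(co$pedigree$father_id[match(reps$subject_id,
                                                     co$pedigree$individual_id)]), ]
  sp <- founders |>
    dplyr::group_by(.data$replicate, .data$family_id) |>
    dplyr::summarise(y1 = log(tg_post[1]), y2 = log(tg_post[2]),
                     .groups = "drop")
  expect_lt(abs(cor(sp$y1, sp$y2)), 3 / sqrt(nrow(sp)))
})

test_that("realized heritability matches the configured values", {
  cfg <- default_gaw20_scenario(seed = 10, n_replicates = 25)
  co <- simulate_cohort(cfg)
  for (s in c("s1", "s5")) {
    h2 <- cfg$sites$h2[cfg$sites$site_id == s]
    fr <- co$replicates |>
      dplyr::group_by(.data$replicate) |>
      dplyr::summarise(v = var(co$b[s] * .data[[paste0("g_", s)]] *
                                 (1 - .data[[paste0("m_", s)]])),
                       .groups = "drop")
    expect_lt(abs(mean(fr$v) / co$var_null - h2), 0.15 * h2 + 0.002)
  }
})

test_that("cohorts are deterministic given the seed and shaped as configured", {
  cfg <- default_gaw20_scenario(seed = 123, n_replicates = 2)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$replicates, co2$replicates)
  expect_identical(co1$b, co2$b)

  expect_equal(nrow(co1$pedigree), 680)
  expect_equal(length(unique(co1$pedigree$family_id)), 164)
  expect_equal(nrow(cfg$sites), 10)
  expect_equal(sum(cfg$sites$causal), 5)
  expect_equal(cfg$sites$h2[cfg$sites$causal],
               c(0.125, 0.10, 0.075, 0.05, 0.025))
  expect_equal(cfg$n_replicates, 2)
  expect_true(all(co1$replicates$tg_pre > 0 & co1$replicates$tg_post > 0))
  m <- as.matrix(co1$replicates[paste0("m_", cfg$sites$site_id)])
  expect_true(all(m >= 0 & m <= 1))
})

test_that("cohorts serialize to plain-text files and PED round-trips", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(default_gaw20_scenario(seed = 2, n_replicates = 1))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "replicates.csv")))
  back <- read_ped(file.path(dir, "pedigree.ped"))
  expect_equal(as.data.frame(back)[c("individual_id", "father_id")],
               as.data.frame(co$pedigree)[c("individual_id", "father_id")])
  cfg2 <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
  expect_equal(cfg2$n_families, 164)
})
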