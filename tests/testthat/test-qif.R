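test_that("extended scores behave as the basis structure dictates", {
  d <- toy_clusters()
  ols <- coef(lm(y ~ x, d))
  sc <- qif_scores(ols, d, y ~ x, id = fam)
  p <- 2
  # M1 block at the OLS solution is the OLS normal equation: zero
  expect_lt(max(abs(sc$g_bar[1:p])), 1e-10)
  # singleton cluster contributes nothing to the M2 block
  expect_true(all(abs(sc$G[3, (p + 1):(2 * p)]) < 1e-12))

  # hand arithmetic on one cluster of size 2, p = 1 (no intercept)
  dd <- data.frame(y = c(1, 2), x = c(0.5, -1), fam = c(1, 1))
  b <- 0.3
  e <- dd$y - b * dd$x
  sc2 <- qif_scores(b, dd, y ~ x - 1, id = fam)
  expect_equal(unname(sc2$G[1, ]),
               c(sum(dd$x * e), dd$x[1] * e[2] + dd$x[2] * e[1]),
               tolerance = 1e-12)
})

test_that("all-singleton QIF reduces to OLS", {
  set.seed(2)
  d <- data.frame(y = rnorm(40), x = rnorm(40), fam = 1:40)
  fit <- fit_qif(d, y ~ x, id = fam)
  expect_equal(unname(fit$beta), unname(coef(lm(y ~ x, d))), tolerance = 1e-8)
  expect_gte(fit$q_stat, 0)
})

test_that("QIF minimizes its objective: brute-force check on a toy instance", {
  # 4 clusters, single slope: 2 moment conditions for 1 parameter
  set.seed(3)
  fam <- rep(1:4, times = c(2, 3, 2, 3))
  x <- rnorm(10)
  y <- 0.5 * x + rep(rnorm(4, 0, 0.5), times = c(2, 3, 2, 3)) + rnorm(10, 0, 0.4)
  d <- data.frame(y = y, x = x, fam = fam)
  fit <- fit_qif(d, y ~ x - 1, id = fam)
  expect_true(fit$converged)
  X <- model.matrix(~x - 1, d)

  # freeze the converged weighting matrix and minimize Q from elsewhere
  sc <- qif_scores(fit$beta, d, y ~ x - 1, id = fam)
  Cfix <- crossprod(sc$G) / fit$N
  bf <- optimize(function(b) naive_qif_Q(b, d$y, X, d$fam, Cfixed = Cfix),
                 interval = fit$beta + c(-1, 1), tol = 1e-10)
  expect_equal(unname(bf$minimum), unname(fit$beta), tolerance = 1e-6)
  expect_equal(naive_qif_Q(fit$beta, d$y, X, d$fam), fit$q_stat,
               tolerance = 1e-8)
  expect_gte(fit$q_stat, 0)

  # larger toy with intercept: Nelder-Mead on the frozen objective
  set.seed(8)
  sizes <- c(2, 3, 2, 3, 4, 2, 3, 4)
  fam2 <- rep(seq_along(sizes), times = sizes)
  x2 <- rnorm(sum(sizes))
  y2 <- 1 + 0.5 * x2 + rep(rnorm(8, 0, 0.5), times = sizes) +
    rnorm(sum(sizes), 0, 0.4)
  d2 <- data.frame(y = y2, x = x2, fam = fam2)
  fit2 <- fit_qif(d2, y ~ x, id = fam)
  expect_true(fit2$converged)
  X2 <- model.matrix(~x, d2)
  sc2 <- qif_scores(fit2$beta, d2, y ~ x, id = fam)
  Cfix2 <- crossprod(sc2$G) / fit2$N
  bf2 <- optim(fit2$beta + c(0.3, -0.2),
               function(b) naive_qif_Q(b, d2$y, X2, d2$fam, Cfixed = Cfix2),
               method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 10000))
  expect_equal(unname(bf2$par), unname(fit2$beta), tolerance = 1e-6)
})

test_that("QIF agrees with exchangeable GEE on correctly specified data", {
  d <- exch_data(500, 4, beta = c(1, 0.5), icc = 0.4, seed = 4)
  fq <- fit_qif(d, y ~ x, id = fam)
  fg <- fit_gee(d, y ~ x, id = fam)
  expect_lt(max(abs(fq$beta - fg$beta) / pmax(abs(fg$beta), 1)), 1e-3)
})

test_that("QIF stays consistent under working-structure misspecification", {
  # AR-like decay within families of size 4; exchangeable basis still fits
  gen_ar <- function(N, seed) {
    set.seed(seed)
    rho <- 0.7
    Sig <- rho^abs(outer(1:4, 1:4, "-"))
    L <- chol(Sig)
    x <- rnorm(4 * N)
    eps <- as.vector(t(L) %*% matrix(rnorm(4 * N), 4))
    data.frame(y = 1 + 0.5 * x + eps, x = x, fam = rep(1:N, each = 4))
  }
  est <- vapply(1:20, function(r) fit_qif(gen_ar(300, 600 + r),
                                          y ~ x, id = fam)$beta["x"],
                numeric(1))
  expect_lt(abs(mean(est) - 0.5), 3 * sd(est) / sqrt(20))
})

test_that("bias-corrected QIF covariance matches a direct evaluation", {
  set.seed(5)
  fam <- rep(1:5, times = c(2, 3, 2, 3, 2))
  n <- length(fam)
  x <- rnorm(n)
  d <- data.frame(y = 1 + 0.5 * x + rnorm(n, 0, 0.5), x = x, fam = fam)
  fit <- fit_qif(d, y ~ x, id = fam)
  X <- model.matrix(~x, d)

  # direct formula: per-cluster hat from the GMM linearization,
  # H_i = X_i (W'C^-1 W)^{-1} W'C^-1 B_i' with B_i = [X_i, M2 X_i],
  # residuals adjusted by (I - H_i)^{-1}, C rebuilt, information inverted
  idx <- split(seq_len(n), fam)
  e <- d$y - X %*% fit$beta
  p <- 2
  G0 <- matrix(0, 5, 2 * p)
  W <- matrix(0, 2 * p, p)
  Blist <- vector("list", 5)
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    ni <- length(ii)
    Xi <- X[ii, , drop = FALSE]
    M2 <- matrix(1, ni, ni) - diag(ni)
    Blist[[i]] <- cbind(Xi, M2 %*% Xi)
    G0[i, ] <- t(Blist[[i]]) %*% e[ii]
    W <- W + rbind(t(Xi) %*% Xi, t(Xi) %*% M2 %*% Xi)
  }
  Cinv <- solve(crossprod(G0) / 5)
  K <- solve(t(W) %*% Cinv %*% W) %*% t(W) %*% Cinv
  G <- matrix(0, 5, 2 * p)
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    Xi <- X[ii, , drop = FALSE]
    Hi <- Xi %*% K %*% t(Blist[[i]])
    eadj <- solve(diag(length(ii)) - Hi, e[ii])
    G[i, ] <- t(Blist[[i]]) %*% eadj
  }
  Cbc <- crossprod(G) / 5
  direct <- 5 * solve(t(W) %*% solve(Cbc) %*% W)
  expect_equal(unname(qif_bc_cov(fit)), unname(direct), tolerance = 1e-8)

  # bias correction never shrinks the Wald statistic on this instance
  expect_true(all(diag(fit$cov_bc) >= diag(fit$cov_plain) - 1e-12))

  # zero-leverage limit: many clusters, tiny p -> correction negligible
  d2 <- exch_data(400, 2, seed = 6)
  f2 <- fit_qif(d2, y ~ x, id = fam)
  expect_equal(unname(f2$cov_bc), unname(f2$cov_plain), tolerance = 0.05)
})

test_that("QIF is permutation invariant and scale equivariant", {
  d <- exch_data(30, 3, seed = 7)
  fit <- fit_qif(d, y ~ x, id = fam)
  perm <- unlist(split(seq_len(nrow(d)), d$fam)[sample(30)])
  fitp <- fit_qif(d[perm, ], y ~ x, id = fam)
  expect_equal(fitp$beta, fit$beta, tolerance = 1e-8)
  expect_equal(fitp$q_stat, fit$q_stat, tolerance = 1e-8)

  d2 <- d; d2$y <- 2 * d$y
  fit2 <- fit_qif(d2, y ~ x, id = fam)
  expect_equal(fit2$beta, 2 * fit$beta, tolerance = 1e-6)
  expect_equal(fit2$cov_plain, 4 * fit$cov_plain, tolerance = 1e-6)
})

test_that("the minimized objective is chi-square-like under correct specification", {
  # unequal cluster sizes keep all 2p moment directions informative
  gen <- function(seed) {
    set.seed(seed)
    sizes <- sample(2:4, 120, replace = TRUE)
    fam <- rep(seq_along(sizes), times = sizes)
    x <- rnorm(sum(sizes))
    u <- rep(rnorm(120, 0, sqrt(0.3)), times = sizes)
    data.frame(y = 1 + 0.5 * x + u + rnorm(sum(sizes), 0, sqrt(0.7)),
               x = x, fam = fam)
  }
  q <- vapply(1:50, function(r) fit_qif(gen(900 + r), y ~ x, id = fam)$q_stat,
              numeric(1))
  expect_true(all(q >= 0))
  df <- 2 # (m - 1) * p overidentifying conditions
  med <- stats::qchisq(0.5, df)
  expect_gt(median(q), med / 3)
  expect_lt(median(q), 3 * med)
})
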