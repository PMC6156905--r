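# Independent oracles used across the test files. Everything here is coded
# from first principles (dense matrices, explicit loops, enumeration) so it
# shares no code path with the package internals it checks.

# ---- pedigrees ------------------------------------------------------------

make_ped <- function(fid, iid, fa, mo, sex) {
  pedigree(data.frame(family_id = fid, individual_id = iid,
                      father_id = fa, mother_id = mo, sex = sex))
}

# grandparents GF,GM -> parent P (with spouse S) -> children C1, C2
three_gen_ped <- function() {
  make_ped("F1",
           c("GF", "GM", "P", "S", "C1", "C2"),
           c(NA, NA, "GF", NA, "P", "P"),
           c(NA, NA, "GM", NA, "S", "S"),
           c("male", "female", "male", "female", "female", "male"))
}

# Random outbred pedigree: growth by adding children to existing couples;
# spouses always marry in as new founders, so there are no inbreeding loops.
random_outbred_ped <- function(n_max = 12) {
  iid <- c("M1", "F1")
  fa <- c(NA, NA)
  mo <- c(NA, NA)
  sex <- c("male", "female")
  couples <- list(c("M1", "F1"))
  k <- 2L
  while (k < n_max) {
    cp <- couples[[sample.int(length(couples), 1)]]
    k <- k + 1L
    child <- paste0("I", k)
    child_sex <- sample(c("male", "female"), 1)
    iid <- c(iid, child); fa <- c(fa, cp[1]); mo <- c(mo, cp[2])
    sex <- c(sex, child_sex)
    if (k < n_max && runif(1) < 0.4) {
      # marry the child to a new founder
      k <- k + 1L
      spouse <- paste0("I", k)
      iid <- c(iid, spouse); fa <- c(fa, NA); mo <- c(mo, NA)
      sex <- c(sex, ifelse(child_sex == "male", "female", "male"))
      couples <- c(couples, list(
        if (child_sex == "male") c(child, spouse) else c(spouse, child)))
    }
  }
  make_ped("F1", iid, fa, mo, sex)
}

# Path-counting kinship for outbred pedigrees: phi(i, j) sums
# (1/2)^(l1 + l2 + 1) over pairs of ancestry paths from i and from j that
# meet at a common ancestor and share no other node; phi(i, i) = 1/2.
path_counting_kinship <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  # all upward paths (node sequences, starting at i) to every ancestor
  paths_up <- function(i) {
    out <- list(i)
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) out <- c(out, lapply(paths_up(p), function(pp) c(i, pp)))
    }
    out
  }
  phi <- diag(0.5, n)
  for (i in seq_len(n)) {
    pi_ <- paths_up(i)
    for (j in seq_len(n)) {
      if (j <= i) next
      pj_ <- paths_up(j)
      tot <- 0
      for (a in pi_) for (b in pj_) {
        A <- a[length(a)]
        if (A != b[length(b)]) next
        shared <- intersect(a, b)
        if (length(shared) == 1 && shared == A) {
          tot <- tot + 0.5^(length(a) - 1 + length(b) - 1 + 1)
        }
      }
      phi[i, j] <- phi[j, i] <- tot
    }
  }
  dimnames(phi) <- list(ped$individual_id, ped$individual_id)
  phi
}

# ---- clustered toy data ---------------------------------------------------

toy_clusters <- function(seed = 42) {
  set.seed(seed)
  sizes <- c(2, 3, 1, 2, 3, 2)
  fam <- rep(letters[seq_along(sizes)], times = sizes)
  x <- rnorm(sum(sizes))
  u <- rep(rnorm(length(sizes), 0, 0.4), times = sizes)
  y <- 1 + 0.5 * x + u + rnorm(sum(sizes), 0, 0.4)
  data.frame(y = y, x = x, fam = fam)
}

# exchangeable Gaussian clusters with a known intraclass correlation
exch_data <- function(N, size, beta = c(1, 0.5), icc = 0.3, sigma = 1,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fam <- rep(seq_len(N), each = size)
  x <- rnorm(N * size)
  u <- rep(rnorm(N, 0, sigma * sqrt(icc)), each = size)
  e <- rnorm(N * size, 0, sigma * sqrt(1 - icc))
  data.frame(y = beta[1] + beta[2] * x + u + e, x = x, fam = fam)
}

# ---- naive GEE (dense matrices, explicit loops) ---------------------------

naive_gee <- function(y, X, fam, max_iter = 100, tol = 1e-10) {
  fam <- as.integer(factor(fam, levels = unique(fam)))
  idx <- split(seq_along(y), fam)
  p <- ncol(X); n <- length(y)
  npairs <- sum(vapply(idx, function(ii) choose(length(ii), 2), 1))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  alpha <- 0; phi <- 1
  for (it in 1:max_iter) {
    e <- y - X %*% beta
    phi <- sum(e^2) / (n - p)
    cross <- 0
    for (ii in idx) {
      ei <- e[ii]
      if (length(ei) > 1) {
        for (j in seq_along(ei)) for (k in seq_along(ei)) {
          if (j < k) cross <- cross + ei[j] * ei[k]
        }
      }
    }
    alpha <- if (npairs > 0) cross / phi / max(npairs - p, 1) else 0
    A <- matrix(0, p, p); rhs <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      R <- matrix(alpha, ni, ni); diag(R) <- 1
      Vinv <- solve(phi * R)
      Xi <- X[ii, , drop = FALSE]
      A <- A + t(Xi) %*% Vinv %*% Xi
      rhs <- rhs + t(Xi) %*% Vinv %*% y[ii]
    }
    beta_new <- solve(A, rhs)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  e <- y - X %*% beta
  bread <- solve(A)
  meat <- matrix(0, p, p)
  meat_bc <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    R <- matrix(alpha, ni, ni); diag(R) <- 1
    Vinv <- solve(phi * R)
    Xi <- X[ii, , drop = FALSE]
    u <- t(Xi) %*% Vinv %*% e[ii]
    meat <- meat + u %*% t(u)
    Hi <- Xi %*% bread %*% t(Xi) %*% Vinv
    ebc <- solve(diag(ni) - Hi, e[ii])
    ubc <- t(Xi) %*% Vinv %*% ebc
    meat_bc <- meat_bc + ubc %*% t(ubc)
  }
  list(beta = as.vector(beta), alpha = alpha, phi = phi,
       cov_robust = bread %*% meat %*% bread,
       cov_bc = bread %*% meat_bc %*% bread)
}

# norm of the GEE estimating equation at beta, alpha and phi fixed
gee_ee_norm <- function(beta, y, X, fam, alpha, phi) {
  idx <- split(seq_along(y), as.integer(factor(fam, levels = unique(fam))))
  s <- numeric(ncol(X))
  for (ii in idx) {
    ni <- length(ii)
    R <- matrix(alpha, ni, ni); diag(R) <- 1
    Xi <- X[ii, , drop = FALSE]
    s <- s + t(Xi) %*% solve(phi * R) %*% (y[ii] - Xi %*% beta)
  }
  sqrt(sum(s^2))
}

# ---- naive QIF objective --------------------------------------------------

naive_qif_Q <- function(beta, y, X, fam, Cfixed = NULL) {
  fam <- as.integer(factor(fam, levels = unique(fam)))
  idx <- split(seq_along(y), fam)
  p <- ncol(X); N <- length(idx)
  G <- matrix(0, N, 2 * p)
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    ni <- length(ii)
    Xi <- X[ii, , drop = FALSE]
    ei <- y[ii] - Xi %*% beta
    M2 <- matrix(1, ni, ni) - diag(ni)
    G[i, ] <- c(t(Xi) %*% ei, t(Xi) %*% M2 %*% ei)
  }
  gbar <- colMeans(G)
  C <- if (is.null(Cfixed)) crossprod(G) / N else Cfixed
  N * as.numeric(t(gbar) %*% MASS::ginv(C) %*% gbar)
}

# sib-pair cohort data aligned to its kinship matrix (two parents, two
# offspring per family; draws use the current RNG state)
sib_cohort <- function(n_fam, s2g, s2e, beta = c(1, 0.5)) {
  ped <- pedigree(dplyr::bind_rows(lapply(seq_len(n_fam), function(i) {
    f <- sprintf("F%03d", i)
    data.frame(family_id = f,
               individual_id = paste0(f, "_", 1:4),
               father_id = c(NA, NA, paste0(f, "_1"), paste0(f, "_1")),
               mother_id = c(NA, NA, paste0(f, "_2"), paste0(f, "_2")),
               sex = c("male", "female", "female", "male"))
  })))
  kin <- kinship_matrix(ped)
  A <- relationship_matrix(kin)
  n <- nrow(A)
  g <- as.vector(t(chol(A + diag(1e-10, n))) %*% rnorm(n)) * sqrt(s2g)
  x <- rnorm(n)
  y <- beta[1] + beta[2] * x + g + rnorm(n, 0, sqrt(s2e))
  list(data = tibble::tibble(subject_id = kin$ids, x = x, y = y),
       kin = kin, A = A)
}

# ---- dense mixed-model likelihood -----------------------------------------

dense_reml_loglik <- function(y, X, A, s2g, s2e, reml = TRUE) {
  n <- length(y); p <- ncol(X)
  Sig <- s2g * A + s2e * diag(n)
  Si <- solve(Sig)
  XtSiX <- t(X) %*% Si %*% X
  beta <- solve(XtSiX, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Si %*% r)
  ld_sig <- as.numeric(determinant(Sig, logarithm = TRUE)$modulus)
  if (reml) {
    ld_x <- as.numeric(determinant(XtSiX, logarithm = TRUE)$modulus)
    -0.5 * (ld_sig + ld_x + quad + (n - p) * log(2 * pi))
  } else {
    -0.5 * (ld_sig + quad + n * log(2 * pi))
  }
}

# ---- methylation mixing oracle --------------------------------------------

# Expected correlation between a causal Uniform(0,1) CpG and its clamped
# noncausal partner, by numerical integration (no simulation involved).
expected_noncausal_cor <- function(f) {
  sdm <- sqrt(1 / 12)
  clamp_moment <- function(mu, s, k) {
    stats::integrate(function(x) pmin(pmax(x, 0), 1)^k * stats::dnorm(x, mu, s),
                     mu - 8 * s, mu + 8 * s)$value
  }
  s <- sqrt(1 - f) * sdm
  em <- function(k) {
    stats::integrate(Vectorize(function(mc) {
      clamp_moment(0.5 + sqrt(f) * (mc - 0.5), s, k)
    }), 0, 1)$value
  }
  exy <- stats::integrate(Vectorize(function(mc) {
    mc * clamp_moment(0.5 + sqrt(f) * (mc - 0.5), s, 1)
  }), 0, 1)$value
  m1 <- em(1); m2 <- em(2)
  (exy - 0.5 * m1) / sqrt((1 / 12) * (m2 - m1^2))
}
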