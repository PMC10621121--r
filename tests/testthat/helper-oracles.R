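# Independent brute-force oracles used across the suite. Each transcribes
# the defining formula of a statistic directly, with none of the package's
# vectorization or caching, so agreement is a genuine dual-route check.

# Weir & Cockerham (1984) two-population variance components from two
# vectors of diploid genotype dosages (0/1/2, NA allowed).
oracle_wc_fst <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2); r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

oracle_pbs <- function(f_ab, f_ac, f_bc) {
  tt <- function(f) -log(1 - min(max(f, 0), 1 - 1e-6))
  (tt(f_ab) + tt(f_ac) - tt(f_bc)) / 2
}

# Exhaustive pairwise tract-length nSL: loops over every haplotype pair and
# every site, no early exit, no vectorization.
oracle_nsl <- function(haps, focal, derived_allele = 1L, max_extend = 100L) {
  der <- haps[, focal] == derived_allele
  class_mean <- function(rows) {
    h <- haps[rows, , drop = FALSE]
    k <- nrow(h); m <- ncol(h)
    tot <- 0; np <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      len <- 1
      s <- focal + 1
      while (s <= min(m, focal + max_extend) && h[i, s] == h[j, s]) {
        len <- len + 1; s <- s + 1
      }
      s <- focal - 1
      while (s >= max(1, focal - max_extend) && h[i, s] == h[j, s]) {
        len <- len + 1; s <- s - 1
      }
      tot <- tot + len; np <- np + 1
    }
    tot / np
  }
  sl_a <- class_mean(which(!der))
  sl_d <- class_mean(which(der))
  list(raw = log(sl_a / sl_d), sl_a = sl_a, sl_d = sl_d)
}

# Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(p[o][js] * m / js, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Upper-tail hypergeometric by direct pmf summation with choose().
oracle_hyper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Pooled two-sample proportion z and one-sided p.
oracle_prop_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

oracle_ivw <- function(bx, by, sy) {
  w <- sy^-2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  list(estimate = est, se = se, p = 2 * pnorm(-abs(est / se)))
}

# Weighted least squares of by on (1, bx) by normal equations.
oracle_wls <- function(bx, by, w) {
  X <- cbind(1, bx)
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% by)
  res <- by - X %*% beta
  sigma2 <- sum(w * res^2) / (length(by) - 2)
  cov <- sigma2 * solve(XtW %*% X)
  list(intercept = beta[1], slope = beta[2],
       se_intercept = sqrt(cov[1, 1]), se_slope = sqrt(cov[2, 2]))
}

# Two-population Bayes factor through an independent route: eigen-rotate
# omega, evaluate each grid likelihood as a product of univariate normal
# densities, and average.
oracle_bf_2pop <- function(y, env, omega, beta_bound = 0.3,
                           grid_points = 201L) {
  eg <- eigen(omega, symmetric = TRUE)
  rot <- function(v) drop(t(eg$vectors) %*% v)
  sdv <- sqrt(eg$values)
  dens <- function(b) prod(dnorm(rot(y), mean = b * rot(env), sd = sdv))
  grid <- seq(-beta_bound, beta_bound, length.out = grid_points)
  mean(vapply(grid, dens, numeric(1))) / dens(0)
}

# Naive Ward.D2 agglomeration via the Lance-Williams update on squared
# distances; returns cluster membership after cutting at `h`.
oracle_ward_cut <- function(d, h) {
  d <- as.matrix(d)
  n <- nrow(d)
  ids <- rownames(d)
  clusters <- as.list(seq_len(n))
  names(clusters) <- NULL
  sizes <- rep(1, n)
  d2 <- d^2
  active <- rep(TRUE, n)
  membership <- seq_len(n)
  heights <- c()
  repeat {
    act <- which(active)
    if (length(act) < 2) break
    best <- c(NA, NA); bestv <- Inf
    for (i in act) for (j in act) if (i < j && d2[i, j] < bestv) {
      bestv <- d2[i, j]; best <- c(i, j)
    }
    hgt <- sqrt(bestv)
    if (hgt > h) break
    i <- best[1]; j <- best[2]
    for (k in act) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((sizes[i] + sizes[k]) * d2[i, k] + (sizes[j] + sizes[k]) * d2[j, k] -
           sizes[k] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    membership[membership == membership[j]] <- membership[i]
  }
  out <- as.integer(factor(membership, levels = unique(membership)))
  names(out) <- ids
  out
}

# Random small diploid fixture for Fst oracle comparisons.
random_geno_gm <- function(m = 10, n_per_pop = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_pop
  haps <- matrix(rbinom(2 * n * m, 1, runif(m, 0.1, 0.9)[rep(1:m, each = 2 * n)]),
                 nrow = 2 * n, ncol = m)
  gm <- genotype_matrix(paste0("v", 1:m), rep("1", m), seq_len(m) * 100,
                        rep("A", m), rep("G", m), haps,
                        paste0("s", 1:n), phased = TRUE)
  panel <- population_panel(setNames(rep(c("P1", "P2"), each = n_per_pop),
                                     paste0("s", 1:n)))
  list(gm = gm, panel = panel)
}

make_gwas <- function(rsid, p, beta = -0.01, se = 0.005,
                      a1 = "G", a2 = "A") {
  data.frame(rsid = rsid,
             effect_allele = rep_len(a1, length(rsid)),
             other_allele = rep_len(a2, length(rsid)),
             beta = rep_len(beta, length(rsid)),
             se = rep_len(se, length(rsid)),
             p = p, stringsAsFactors = FALSE)
}
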