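## Independent oracles (brute force / enumeration / closed form) and small
## fixture builders shared across the suite. Oracles deliberately avoid
## the package's own code paths.

## mean pairwise Hamming distance per site
oracle_pi <- function(m) {
  A <- m$alleles
  n <- nrow(A)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    tot <- tot + sum(A[i, ] != A[j, ])
  }
  tot / choose(n, 2) / ncol(A)
}

## textbook Tajima's D coded from scratch (pairwise pi, Watterson S)
oracle_tajima_d <- function(m) {
  A <- m$alleles
  n <- nrow(A)
  p <- colMeans(A)
  seg <- p > 0 & p < 1
  S <- sum(seg)
  k_hat <- oracle_pi(m) * ncol(A)       # mean pairwise differences
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## brute-force theta_H = sum 2 S_i i^2 / (n (n-1)); unnormalized
## Fay & Wu H = theta_pi - theta_H
oracle_faywu_h_unnorm <- function(m) {
  A <- m$alleles
  n <- nrow(A)
  cnt <- colSums(A)
  cnt <- cnt[cnt > 0 & cnt < n]
  theta_h <- sum(2 * cnt^2) / (n * (n - 1))
  oracle_pi(m) * ncol(A) - theta_h
}

## EHH by direct pair enumeration over carrier pairs
oracle_ehh_at <- function(m, core_idx, allele, x_idx) {
  carriers <- which(m$alleles[, core_idx] == allele)
  lo <- min(core_idx, x_idx); hi <- max(core_idx, x_idx)
  idx <- lo:hi
  tot <- 0; same <- 0
  for (i in seq_along(carriers)[-length(carriers)]) {
    for (j in seq(i + 1, length(carriers))) {
      tot <- tot + 1
      if (all(m$alleles[carriers[i], idx] == m$alleles[carriers[j], idx])) {
        same <- same + 1
      }
    }
  }
  same / tot
}

## nSL tract lengths by direct scanning, one pair at a time
oracle_sl_pair <- function(a, b, focal) {
  if (a[focal] != b[focal]) return(0)
  S <- length(a)
  len <- 1
  k <- focal - 1
  while (k >= 1 && a[k] == b[k]) { len <- len + 1; k <- k - 1 }
  k <- focal + 1
  while (k <= S && a[k] == b[k]) { len <- len + 1; k <- k + 1 }
  len
}

oracle_nsl_raw <- function(m, focal) {
  A <- m$alleles
  anc <- which(A[, focal] == 0)
  der <- which(A[, focal] == 1)
  mean_sl <- function(grp) {
    if (length(grp) < 2) return(NA_real_)
    v <- c()
    for (i in seq_along(grp)[-length(grp)]) for (j in seq(i + 1, length(grp))) {
      v <- c(v, oracle_sl_pair(A[grp[i], ], A[grp[j], ], focal))
    }
    mean(v)
  }
  log(mean_sl(anc) / mean_sl(der))
}

## D'/r2 from the 2x2 haplotype contingency table
oracle_ld <- function(a, b) {
  n <- length(a)
  p11 <- sum(a == 1 & b == 1) / n
  pA <- mean(a); pB <- mean(b)
  D <- p11 - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(d_prime = if (dmax == 0) 0 else abs(D) / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

## random polarized haplotype matrix (segregating columns only)
random_matrix <- function(n, S, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0L, n, S)
  for (s in seq_len(S)) {
    k <- sample(seq_len(n - 1), 1)
    A[sample(n, k), s] <- 1L
  }
  haplotype_matrix(A, positions = seq_len(S) * 10)
}

## matrix whose haplotype classes have prescribed frequencies
class_matrix <- function(class_sizes, n_sites = 8, seed = 1) {
  set.seed(seed)
  protos <- matrix(0L, length(class_sizes), n_sites)
  for (k in seq_along(class_sizes)) {
    protos[k, ] <- as.integer(intToBits(k))[1:n_sites]
  }
  A <- protos[rep(seq_along(class_sizes), class_sizes), , drop = FALSE]
  haplotype_matrix(A, positions = seq_len(n_sites) * 5)
}

## memoised shared IAV null (small-world: n = 60 panel, core at 0.5)
.shared_nulls <- new.env(parent = emptyenv())
shared_iav_null <- function(n = 60, core_freq = 0.5, n_reps = 1000,
                            theta = 8, seed = 42) {
  key <- sprintf("%d_%g_%d_%g_%d", n, core_freq, n_reps, theta, seed)
  if (is.null(.shared_nulls[[key]])) {
    .shared_nulls[[key]] <- null_distribution(
      "F_c", n = n, core_freq = core_freq, n_reps = n_reps, theta = theta,
      seed = seed)
  }
  .shared_nulls[[key]]
}

## small sweep-fixture world used by power/specificity checks
small_fixture_cfg <- function(seed, diversity = 0, neutral = FALSE) {
  sweep_fixture_config(n_total = 60, n_derived = 30, split = c(14, 16),
                       diversity = diversity, shared_old = 3,
                       n_background = 20, n_flank = 8, theta = 8,
                       neutral = neutral, seed = seed)
}
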