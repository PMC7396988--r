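test_that("hudson_fst matches the 1 - Hw/Hb algebraic form on random draws", {
  set.seed(101)
  for (k in 1:1000) {
    n1 <- sample(4:300, 1); n2 <- sample(4:300, 1)
    c1 <- sample(1:(n1 - 1), 1); c2 <- sample(1:(n2 - 1), 1)
    p1 <- c1 / n1; p2 <- c2 / n2
    got <- hudson_fst(site_freq(c1, n1), site_freq(c2, n2), clamp = FALSE)$fst
    hw <- p1 * (1 - p1) * n1 / (n1 - 1) + p2 * (1 - p2) * n2 / (n2 - 1)
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    expect_lt(abs(got - (1 - hw / hb)), 1e-12)
  }
})

test_that("hudson_fst handles clamping, undefined and bad input", {
  expect_equal(hudson_fst(site_freq(50, 100), site_freq(50, 100))$fst, 0)
  expect_true(hudson_fst(site_freq(50, 100), site_freq(50, 100))$clamped)
  f <- hudson_fst(site_freq(0, 10), site_freq(0, 12))
  expect_true(f$undefined)
  expect_error(site_freq(1, 1), "sample size")
})

test_that("fst_scan matches the sitewise estimator and honours exclusions", {
  set.seed(5)
  pan <- make_two_pop_panel(0.2, 40, 50, n_snps = 60)
  scan <- fst_scan(pan$pop1, pan$pop2)
  for (k in c(1, 17, 60)) {
    n1 <- n_hap(pan$pop1); n2 <- n_hap(pan$pop2)
    ref <- hudson_fst(site_freq(sum(pan$pop1$alleles[, k]), n1),
                      site_freq(sum(pan$pop2$alleles[, k]), n2))
    expect_equal(scan$fst[k], ref$fst)
  }
  ## a fixed difference gives FST = 1
  A1 <- pan$pop1; A2 <- pan$pop2
  A1$alleles[, 3] <- 1L; A2$alleles[, 3] <- 0L
  expect_equal(fst_scan(A1, A2)$fst[3], 1)
  ## excluded-region semantics
  ex <- data.frame(chrom = "sim", start = pan$pop1$positions[10],
                   end = pan$pop1$positions[20])
  scan_ex <- fst_scan(pan$pop1, pan$pop2, exclusions = ex)
  expect_false(any(scan_ex$pos >= ex$start & scan_ex$pos <= ex$end))
  expect_error(fst_rank(scan_ex, scan$site_id[12]), "not found")
  ## misaligned panels fail
  expect_error(fst_scan(pan$pop1, pan$pop2[, 1:50]), "aligned")
})

test_that("block_fst tiles windows, ranks, and flags empty windows", {
  scan <- data.frame(site_id = paste0("s", 1:6), chrom = "1",
                     pos = c(100, 200, 300, 2100, 2200, 4300),
                     fst = c(0.1, 0.1, 0.1, 0.5, 0.7, 0.1),
                     undefined = FALSE)
  b <- block_fst(scan, 1000)
  expect_equal(b$mean_fst[1], 0.1)
  expect_true(is.na(b$mean_fst[2]))        # no sites in 1100-2099
  expect_equal(b$rank[3], 1)               # elevated block ranks first
  flat <- block_fst(scan[1:3, ], 150)
  expect_true(all(na.omit(flat$mean_fst) == 0.1))
})

test_that("nucleotide diversity equals the all-pairs Hamming oracle", {
  two <- haplotype_matrix(rbind(rep(0L, 100), c(1L, rep(0L, 99))),
                          positions = 1:100)
  expect_equal(nucleotide_diversity(two)$pi, 0.01)
  same <- haplotype_matrix(matrix(0L, 5, 30), positions = 1:30)
  expect_equal(nucleotide_diversity(same)$pi, 0)
  for (seed in 1:5) {
    m <- random_matrix(8, 50, seed)
    expect_equal(nucleotide_diversity(m)$pi, oracle_pi(m), tolerance = 1e-12)
  }
  expect_error(nucleotide_diversity(two, start = 5000), "no sites")
})

test_that("compare_pi_ztest is antisymmetric with correct normal tails", {
  a <- nucleotide_diversity(random_matrix(10, 40, 1))
  expect_equal(compare_pi_ztest(a, a)$z, 0)
  expect_equal(compare_pi_ztest(a, a)$p_value, 1)
  b <- a; b$pi <- a$pi + 3 * sqrt(a$var_pi); b$var_pi <- 0
  expect_equal(compare_pi_ztest(b, a)$p_value, 2 * pnorm(-3),
               tolerance = 1e-10)
  z1 <- compare_pi_ztest(a, b); z2 <- compare_pi_ztest(b, a)
  expect_equal(z1$z, -z2$z)
  expect_equal(z1$p_value, z2$p_value)
})

test_that("tajimas_d matches the independently coded textbook oracle", {
  for (seed in 1:6) {
    m <- random_matrix(5 + seed, 10 + 2 * seed, seed)
    got <- tajimas_d(m, p_method = "none")
    expect_equal(got$statistic, oracle_tajima_d(m), tolerance = 1e-10)
  }
  ## all singletons at large n gives negative D
  A <- matrix(0L, 40, 10); for (s in 1:10) A[s, s] <- 1L
  m <- haplotype_matrix(A, positions = 1:10 * 3)
  expect_lt(tajimas_d(m, p_method = "none")$statistic, 0)
  ## S = 0 yields the undefined marker
  m0 <- haplotype_matrix(matrix(0L, 6, 4), positions = 1:4)
  expect_true(is.na(tajimas_d(m0, p_method = "none")$statistic))
})

test_that("fay_wu_h matches the brute-force theta_H oracle", {
  for (seed in 1:6) {
    m <- random_matrix(7 + seed, 12 + seed, seed + 50)
    got <- fay_wu_h_norm(m, p_method = "none")
    expect_equal(got$H_unnorm, oracle_faywu_h_unnorm(m), tolerance = 1e-10)
  }
  ## all-singleton spectrum: no high-frequency derived excess, H >= 0
  A <- matrix(0L, 20, 8); for (s in 1:8) A[s, s] <- 1L
  expect_gte(fay_wu_h_norm(haplotype_matrix(A, 1:8), p_method = "none")$H_unnorm, 0)
  ## near-fixed derived alleles: strongly negative H
  B <- matrix(1L, 20, 8); for (s in 1:8) B[s, s] <- 0L
  expect_lt(fay_wu_h_norm(haplotype_matrix(B, 1:8), p_method = "none")$statistic, -1)
})

test_that("h12 matches hand examples, closed forms and relabeling invariance", {
  m <- class_matrix(c(4, 3, 2, 1))
  expect_equal(h12(m), 0.54)
  expect_equal(h12(class_matrix(5)), 1)
  n <- 9
  distinct <- haplotype_matrix(diag(n) * 1L, positions = 1:n)
  expect_equal(h12(distinct), (2 / n)^2 + (n - 2) / n^2)
  ## invariance under haplotype relabeling (row permutation)
  perm <- m[sample(n_hap(m)), ]
  expect_equal(h12(perm), h12(m))
  expect_true(h12(m) > 0 && h12(m) <= 1)
})

test_that("h12_scan reduces to h12 on a full-width window and sees sweeps", {
  m <- random_matrix(20, 30, 9)
  sc <- h12_scan(m, window_snps = 30)
  expect_equal(nrow(sc$track), 1)
  expect_equal(sc$track$h12, h12(m))
  expect_error(h12_scan(m, 10, step = 0), "step")
  ## 80% sweep haplotype drives windowed H12 >= 0.64
  A <- rbind(matrix(0L, 16, 30), matrix(rbinom(4 * 30, 1, 0.5), 4, 30))
  sw <- haplotype_matrix(A, positions = 1:30 * 7)
  expect_gte(max(h12_scan(sw, 15, 5)$track$h12), 0.64)
})

test_that("ehh equals pair enumeration, is 1 at the core, non-increasing", {
  set.seed(33)
  m <- random_matrix(16, 25, 77)
  core <- m$site_ids[13]
  for (allele in 0:1) {
    e <- ehh(m, core, core_allele = allele, maf_min = 0)
    core_row <- e[e$distance_sites == 0, ]
    expect_equal(core_row$ehh, 1)
    ## non-increasing on both sides
    left <- e[e$pos <= core_row$pos, ]
    right <- e[e$pos >= core_row$pos, ]
    expect_true(all(diff(left$ehh) >= -1e-12))
    expect_true(all(diff(right$ehh) <= 1e-12))
    ## brute-force oracle at a handful of sites
    for (x in c(3, 9, 20)) {
      expect_equal(e$ehh[e$pos == m$positions[x]],
                   oracle_ehh_at(m, 13, allele, x))
    }
  }
  ## identical carriers keep EHH at 1 everywhere
  A <- rbind(matrix(0L, 4, 10), matrix(rep(c(1L, rep(0L, 9)), 4),
                                       4, 10, byrow = TRUE))
  ident <- haplotype_matrix(A, positions = 1:10 * 2)
  e <- ehh(ident, ident$site_ids[1], core_allele = 1, maf_min = 0)
  expect_true(all(e$ehh == 1))
  expect_error(ehh(ident, ident$site_ids[2], core_allele = 1), "< 2")
})

test_that("nsl matches the exhaustive pair-scan oracle and cap semantics", {
  set.seed(12)
  m <- random_matrix(6, 30, 5)
  res <- nsl(m, maf_min = 0)
  for (s in c(4, 15, 26)) {
    o <- oracle_nsl_raw(m, s)
    if (is.finite(o)) expect_equal(res$nsl_raw[s], o, tolerance = 1e-10)
  }
  ## cap larger than the matrix changes nothing
  res_cap <- nsl(m, maf_min = 0, max_window = 100)
  expect_equal(res$nsl_raw, res_cap$nsl_raw)
  ## standardized scores have ~zero mean within bins on a neutral panel
  big <- simulate_coalescent(coalescent_config(n = 30, theta = 20, seed = 4))
  std <- nsl(big)$nsl
  expect_lt(abs(mean(std, na.rm = TRUE)), 0.3)
})

test_that("pbs matches plug-in values, symmetry and monotonicity", {
  expect_equal(pbs(0, 0, 0)$pbs_a, 0)
  expect_equal(pbs(0.1, 0.1, 0)$pbs_a, -log(0.9), tolerance = 1e-12)
  sym <- pbs(0.2, 0.15, 0.15)
  expect_equal(sym$pbs_a, sym$pbs_b)
  expect_true(is.infinite(pbs(1, 0.1, 0.1, clamp = FALSE)$pbs_a))
  ## monotone in fst_ab and fst_ao
  g <- seq(0.05, 0.6, by = 0.05)
  expect_true(all(diff(pbs(g, 0.2, 0.2)$pbs_a) > 0))
  expect_true(all(diff(pbs(0.2, g, 0.2)$pbs_a) > 0))
})

test_that("d_prime_r2 matches the contingency-table oracle", {
  ## perfectly coupled and exactly independent constructions
  a <- c(1, 1, 1, 0, 0, 0, 0, 0)
  cpl <- haplotype_matrix(cbind(a, a), positions = c(10, 20))
  expect_equal(d_prime_r2(cpl, "s10", "s20")$d_prime, 1)
  expect_equal(d_prime_r2(cpl, "s10", "s20")$r2, 1)
  ind <- haplotype_matrix(cbind(c(1, 1, 0, 0), c(1, 0, 1, 0)),
                          positions = c(1, 2))
  expect_equal(d_prime_r2(ind, 1, 2)$d_prime, 0)
  expect_equal(d_prime_r2(ind, 1, 2)$r2, 0)
  set.seed(3)
  for (k in 1:50) {
    x <- rbinom(40, 1, 0.5); y <- rbinom(40, 1, 0.4)
    if (all(x == x[1]) || all(y == y[1])) next
    m <- haplotype_matrix(cbind(x, y), positions = c(5, 9))
    got <- d_prime_r2(m, 5, 9)
    ref <- oracle_ld(x, y)
    expect_equal(got$d_prime, ref$d_prime, tolerance = 1e-12)
    expect_equal(got$r2, ref$r2, tolerance = 1e-12)
  }
  mono <- haplotype_matrix(cbind(c(1, 1, 1, 1), c(1, 0, 1, 0)),
                           positions = c(1, 2))
  expect_error(d_prime_r2(mono, 1, 2), "monomorphic")
})

test_that("find_ld_block chains adjacent D' and respects breaks", {
  a <- rep(c(0L, 1L), each = 5)
  coupled <- haplotype_matrix(matrix(rep(a, 10), ncol = 10),
                              positions = 1:10 * 100)
  blk <- find_ld_block(coupled, coupled$site_ids[4])
  expect_equal(blk$n_sites, 10)
  ## break the coupling between sites 5 and 6
  set.seed(8)
  broken <- coupled
  broken$alleles[, 6:10] <- matrix(rep(sample(a), 5), ncol = 5)
  blk2 <- find_ld_block(broken, broken$site_ids[3])
  expect_equal(blk2$start_index, 1)
  expect_equal(blk2$end_index, 5)
  expect_error(find_ld_block(coupled, coupled$site_ids[1], maf_min = 0.6),
               "MAF")
})

test_that("select_core_region expands while r2 exceeds the threshold", {
  set.seed(21)
  a <- rep(c(0L, 1L), each = 6)
  m <- haplotype_matrix(cbind(a, a, a, sample(a), a),
                        positions = 1:5 * 10)
  reg <- select_core_region(m, m$site_ids[2], r2_min = 0.75)
  expect_equal(reg$start_index, 1)
  expect_equal(reg$end_index, 3)
  full <- haplotype_matrix(matrix(rep(a, 4), ncol = 4), positions = 1:4)
  expect_equal(select_core_region(full, 2)$n_sites, 4)
})

test_that("bh_fdr reproduces the step-up hand example and edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  ## monotone non-decreasing in sorted-p order, bounded by 1
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= 1))
})
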