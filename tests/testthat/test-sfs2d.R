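test_that("build_phi2d tallies hand examples and conserves site counts", {
  ## 4 haplotypes, D = {h1, h2}; site 2 derived only in h1; site 3 derived
  ## in h1 and one non-D haplotype
  A <- cbind(c(1L, 1L, 0L, 0L),    # core
             c(1L, 0L, 0L, 0L),
             c(1L, 0L, 1L, 0L))
  m <- haplotype_matrix(A, positions = c(10, 20, 30))
  phi <- build_phi2d(m, "s10")
  expect_equal(phi$n_D, 2)
  expect_equal(phi$phi["1", "0"], 1L)
  expect_equal(phi$phi["1", "1"], 1L)
  expect_equal(sum(phi$phi), 2)
  ## conservation on a random panel: sum Phi = segregating sites - core
  set.seed(60)
  big <- random_matrix(20, 40, 61)
  core <- which(colSums(big$alleles) >= 2)[1]
  phi2 <- build_phi2d(big, big$site_ids[core])
  cnt <- colSums(big$alleles)
  expect_equal(sum(phi2$phi), sum(cnt > 0 & cnt < 20) - 1)
  expect_error(build_phi2d(m, "s20"), ">= 2")
})

test_that("iav_stats: star-genealogy limit, shared-split i*_max, ranges", {
  ## perfect hard-sweep limit: all D-exclusive variants are singletons
  fx <- make_sweep_fixture(sweep_fixture_config(diversity = 0.4, seed = 3))
  phi <- build_phi2d(fx$matrix, fx$core_site, start = fx$core_start,
                     end = fx$core_end)
  s <- iav_stats(phi)
  expect_equal(s$i_max, 1L)
  expect_lte(s$i_star_max, s$n_D)
  expect_gte(s$gamma_star_10, 0); expect_lte(s$gamma_star_10, 1)
  ## the 75/80 shared split surfaces as i*_max = 75 (tag sites are the
  ## highest-carrier shared variants in the fixture)
  expect_equal(s$i_star_max, 75L)
  ## degenerate flag when no exclusive site exists
  A <- cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  phi0 <- build_phi2d(haplotype_matrix(A, c(1, 5)), "s1")
  expect_true(iav_stats(phi0)$degenerate)
})

test_that("IAV statistics respond monotonically over a sweep-strength ladder", {
  ladder <- c(0, 0.25, 0.5, 1, 2, 4)
  vals <- t(vapply(ladder, function(d) {
    fx <- make_sweep_fixture(sweep_fixture_config(diversity = d, seed = 99))
    s <- iav_stats(build_phi2d(fx$matrix, fx$core_site,
                               start = fx$core_start, end = fx$core_end))
    c(s$F_c, s$G_c0, s$L_c0)
  }, numeric(3)))
  ## stronger sweep (smaller diversity) never increases the statistics
  for (col in 1:3) expect_true(all(diff(vals[, col]) >= -1e-9))
})

test_that("null_distribution is seed-deterministic and enforces rep floor", {
  n1 <- suppressWarnings(null_distribution(
    "F_c", n = 20, core_freq = 0.5, n_reps = 50, theta = 6, seed = 7,
    allow_small = TRUE))
  n2 <- suppressWarnings(null_distribution(
    "F_c", n = 20, core_freq = 0.5, n_reps = 50, theta = 6, seed = 7,
    allow_small = TRUE))
  expect_identical(n1$values, n2$values)
  expect_warning(null_distribution("F_c", n = 20, core_freq = 0.5,
                                   n_reps = 50, theta = 6, seed = 7,
                                   allow_small = TRUE), "1000")
})

test_that("sweep_test applies the >= 2 significant rule", {
  s <- structure(list(F_c = 0.01, G_c0 = 0.01, L_c0 = 0.001, n_D = 10,
                      degenerate = FALSE), class = "iav_summary")
  fake_null <- list(F_c = seq(0.2, 0.9, length.out = 200),
                    G_c0 = seq(5, 50, length.out = 200),
                    L_c0 = seq(0.05, 0.5, length.out = 200))
  t1 <- sweep_test(s, fake_null)
  expect_equal(t1$call, "positive_selection")
  expect_true(all(t1$q_values < 0.05))
  ## all q large: no signal
  s2 <- s; s2$F_c <- 0.5; s2$G_c0 <- 25; s2$L_c0 <- 0.25
  expect_equal(sweep_test(s2, fake_null)$call, "no_signal")
  ## exactly one significant: still no signal (threshold is >= 2)
  s3 <- s; s3$G_c0 <- 25; s3$L_c0 <- 0.25
  t3 <- sweep_test(s3, fake_null)
  expect_equal(t3$n_significant, 1)
  expect_equal(t3$call, "no_signal")
  expect_error(sweep_test(s, list(F_c = 1:10)), "missing null")
})

test_that("classify_subhaplotypes recovers a planted 75/80 split exactly", {
  fx <- make_sweep_fixture(sweep_fixture_config(seed = 11))
  cl <- classify_subhaplotypes(fx$matrix, fx$core_site, fx$tag_sites)
  expect_equal(as.integer(cl$counts["A-G"]), 75L)
  expect_equal(as.integer(cl$counts["C-A"]), 80L)
  expect_equal(as.integer(cl$counts["recombinant"]), 0L)
  expect_equal(cl$n_D, 155)
  ## partition property
  expect_equal(sum(cl$counts[c("C-A", "A-G", "recombinant")]), cl$n_D)
  ## truth labels agree
  d <- fx$truth$class == "derived"
  expect_identical(cl$labels[d], fx$truth$subhap[d])
  ## mixed tag alleles are recombinant
  m <- fx$matrix
  t1 <- site_index(m, fx$tag_sites[1])
  hit <- which(m$alleles[, site_index(m, fx$core_site)] == 1)[1]
  m$alleles[hit, t1] <- 1L - m$alleles[hit, t1]
  cl2 <- classify_subhaplotypes(m, fx$core_site, fx$tag_sites)
  expect_equal(as.integer(cl2$counts["recombinant"]), 1L)
  ## monomorphic tag errors
  mono <- m; mono$alleles[, t1] <- 0L
  expect_error(classify_subhaplotypes(mono, fx$core_site, fx$tag_sites),
               "monomorphic")
})

test_that("remove_recombinants removes exactly the planted mosaic", {
  ## two clean classes with opposite patterns at 20 diagnostic sites
  n_diag <- 20
  A <- rbind(
    cbind(1L, matrix(1L, 10, n_diag)),   # derived class: core + all 1
    cbind(0L, matrix(0L, 10, n_diag)))   # ancestral class: all 0
  clean <- haplotype_matrix(A, positions = seq_len(n_diag + 1) * 10)
  r0 <- remove_recombinants(clean, "s10")
  expect_length(r0$removed, 0)
  ## plant one half-and-half mosaic carrying the derived core allele
  B <- rbind(A, c(1L, rep(1L, 10), rep(0L, 10)))
  mosaic <- haplotype_matrix(B, positions = seq_len(n_diag + 1) * 10)
  r1 <- remove_recombinants(mosaic, "s10")
  expect_identical(r1$removed, 21L)
  expect_equal(n_hap(r1$matrix), 20)
  ## degenerate guard: when every haplotype fails the match threshold,
  ## warn and remove none
  expect_warning(r2 <- remove_recombinants(clean, "s10", match_min = 1.01),
                 "mosaic")
  expect_length(r2$removed, 0)
})

test_that("divergence_time is exact, linear in pi and inverse in mu", {
  expect_equal(divergence_time(2.4e-4, 0.5e-9)$time_years, 240000)
  expect_equal(divergence_time(0)$time_years, 0)
  expect_equal(divergence_time(4.8e-4)$time_years,
               2 * divergence_time(2.4e-4)$time_years)
  expect_equal(divergence_time(2.4e-4, 1e-9)$time_years, 120000)
  expect_error(divergence_time(1e-4, 0), "positive")
})

test_that("tmrca_within: identical group at 0, plug-in and star closed form", {
  same <- haplotype_matrix(matrix(0L, 5, 40), positions = 1:40)
  expect_equal(tmrca_within(same)$time_years, 0)
  ## pairwise method equals pi / (2 mu): construct pi_within = 0.4e-4 over
  ## L = 50000 sites -> 2 pairwise differences between 2 haplotypes
  two <- haplotype_matrix(rbind(rep(0L, 4), c(1L, 1L, 0L, 0L)),
                          positions = c(1, 2, 3, 4))
  got <- tmrca_within(two, mu = 0.5e-9, L = 50000)
  expect_equal(got$time_years, (2 / 50000) / (2 * 0.5e-9))  # 40,000 y
  ## star genealogy: k mutations per lineage, mean-derived-count method
  k <- 3; L <- 1000
  star <- matrix(0L, 4, 12)
  for (h in 1:4) star[h, (h - 1) * k + 1:k] <- 1L
  sm <- haplotype_matrix(star, positions = 1:12)
  est <- tmrca_within(sm, mu = 1e-8, method = "mean-derived-count", L = L)
  expect_equal(est$time_years, k / (1e-8 * L))
  expect_error(tmrca_within(same[1, ]), ">= 2")
})

test_that("sweep_mode implements the decision table", {
  sig <- list(call = "positive_selection")
  ns <- list(call = "no_signal")
  expect_equal(sweep_mode(sig, list(`C-A` = sig, `A-G` = sig))$mode, "soft")
  expect_equal(sweep_mode(sig, list(`C-A` = sig, `A-G` = ns))$mode, "hard")
  expect_equal(sweep_mode(ns, list(`C-A` = sig, `A-G` = ns))$mode,
               "hardening")
  expect_equal(sweep_mode(ns, list(`C-A` = ns, `A-G` = ns))$mode, "none")
  expect_error(sweep_mode(sig, list()), "required")
})
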