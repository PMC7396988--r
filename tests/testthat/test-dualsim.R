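test_that("wf_step absorbs at 0/1 and follows the selection closed form", {
  expect_equal(wf_step(0, 1000), 0)
  expect_equal(wf_step(1, 1000), 1)
  expect_error(wf_step(0.5, 1), ">= 2")
  ## one-step selection expectation p* = p / (p + (1-p)(1+s))
  expect_equal(wf_selection_adjust(0.5, 0.1), 0.5 / (0.5 + 0.5 * 1.1),
               tolerance = 1e-12)
  expect_equal(wf_selection_adjust(0.5, 0.1), 0.47619, tolerance = 1e-5)
  ## neutrality: one-generation mean is a martingale
  set.seed(1)
  x <- wf_step(rep(0.5, 1e5), 1e4)
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(0.5 * 0.5 / 1e4 / 1e5) * 5 + 1e-4)
})

test_that("admixture arithmetic is exact and r -> 1 limit holds", {
  p <- demography_params(t1 = 30, r = 0.4, N_JMN = 500, N_A_CNT = 1000)
  set.seed(9)
  b <- simulate_batch(p, selection_params(0), 0.5, n_reps = 200)
  expect_equal(b$jpt0, 0.4 * b$f_jmn + 0.6 * b$f_acnt, tolerance = 0)
  ## mixture example: r = 0.4, f_JMN = 1, f_A_CNT = 0.2 -> 0.52
  expect_equal(0.4 * 1 + 0.6 * 0.2, 0.52)
  ## huge N, s = 0: frequencies stay put
  ph <- demography_params(t1 = 5, r = 0.4, N_JMN = 1e7, N_A_CNT = 1e7,
                          N_simJPT = 1e7, N_simCHB = 1e7, t2 = 5)
  bh <- simulate_batch(ph, selection_params(0, N_simCHB = 1e7), 0.3, 50)
  expect_true(all(abs(bh$jpt - 0.3) < 0.01))
  expect_true(all(abs(bh$chb - 0.3) < 0.01))
})

test_that("neutral fixation probability equals the initial frequency", {
  set.seed(4)
  N <- 100; f <- 0.3; reps <- 20000
  x <- rep(f, reps)
  for (g in 1:100000) {
    active <- x > 0 & x < 1
    if (!any(active)) break
    x[active] <- wf_step(x[active], N)
  }
  expect_true(all(x %in% c(0, 1)))
  expect_equal(mean(x == 1), f, tolerance = 0.01 / f)  # 0.30 +/- 0.01
})

test_that("selection on the continental lineage depresses its T frequency", {
  p <- demography_params(t1 = 200, r = 0.4, N_JMN = 2000, N_A_CNT = 8000)
  set.seed(12)
  b0 <- simulate_batch(p, selection_params(0), 0.5, n_reps = 2000)
  b1 <- simulate_batch(p, selection_params(100), 0.5, n_reps = 2000)
  tt <- t.test(b1$chb, b0$chb, alternative = "less")
  expect_lt(tt$p.value, 0.001)
  ## the isolated indigenous lineage is untouched by selection
  expect_gt(t.test(b1$f_jmn, b0$f_jmn)$p.value, 0.001)
})

test_that("grid enumeration honours the N_JMN <= N_A_CNT constraint", {
  g <- default_grid()
  expect_equal(nrow(g), 570)
  expect_true(all(g$N_JMN <= g$N_A_CNT))
  ## selection design: 4 coefficients x a 410-combination subset
  sub <- g[seq_len(410), ]
  sel_design <- expand.grid(combo = seq_len(nrow(sub)),
                            scaled = c(1, 10, 50, 100))
  expect_equal(nrow(sel_design), 1640)
})

test_that("simulate_grid is seed-deterministic and subset-reproducible", {
  g <- utils::head(default_grid(), 3)
  r1 <- simulate_grid(g, selection_params(0), n_reps = 10, seed = 5)
  r2 <- simulate_grid(g, selection_params(0), n_reps = 10, seed = 5)
  expect_identical(r1$summary, r2$summary)
  ## per-combination streams depend on parameters, not position: a subset
  ## reproduces the full grid's rows
  r3 <- simulate_grid(g[2:3, ], selection_params(0), n_reps = 10, seed = 5)
  expect_equal(r3$summary$n_success, r1$summary$n_success[2:3])
  expect_equal(r3$summary$mean_fst, r1$summary$mean_fst[2:3])
})

test_that("success rule: thresholds, ordering and fixation edges", {
  crit <- success_criteria()
  mk <- function(jpt, chb) {
    list(jpt = jpt, chb = chb, excl_before = FALSE, excl_after = FALSE)
  }
  ok <- popsweep:::replicate_success(mk(0.64, 0.20), 0.30, crit)
  expect_true(ok)
  expect_false(popsweep:::replicate_success(mk(0.64, 0.20), 0.10, crit))
  expect_false(popsweep:::replicate_success(mk(0.50, 0.20), 0.30, crit))
  expect_false(popsweep:::replicate_success(mk(0.64, 0.70), 0.30, crit))
  ## fixation excludes even with high FST
  expect_false(popsweep:::replicate_success(mk(1.0, 0.20), 0.90, crit))
  expect_false(popsweep:::replicate_success(mk(0.64, 0.0), 0.90, crit))
})

test_that("batch_fst clamps negatives and masks excluded replicates", {
  p <- demography_params(t1 = 10, r = 0.2, N_JMN = 500, N_A_CNT = 1000)
  b <- list(jpt = c(0.5, 0.9, 1), chb = c(0.5, 0.2, 1),
            excl_before = c(FALSE, FALSE, TRUE),
            excl_after = c(FALSE, FALSE, TRUE))
  f <- batch_fst(b, p)
  expect_gte(f[1], 0)
  expect_true(is.na(f[3]))
  expect_equal(f[2],
               max(0, popsweep:::hudson_fst_raw(0.9, p$N_simJPT, 0.2,
                                                p$N_simCHB)))
})

test_that("weighted_fst_hist respects weights and the published p_i", {
  p_i <- c(0.5589, 0.0984, 0.0734, 0.0623, 0.0494, 0.0436, 0.0360,
           0.0342, 0.0438)
  expect_equal(sum(p_i), 1, tolerance = 1e-4)
  reps <- data.frame(f_i = rep(seq(0.1, 0.9, 0.1), each = 20),
                     fst = rep(seq(0.1, 0.9, 0.1), each = 20) / 2)
  ## weight 1 on the f_i = 0.5 stratum: only that stratum's values appear
  w <- rep(0, 9); w[5] <- 1
  set.seed(2)
  one <- weighted_fst_hist(reps, w, total = 500)
  expect_true(all(one == 0.25))
  ## uniform weights draw from every stratum
  uni <- weighted_fst_hist(reps, rep(1 / 9, 9), total = 900)
  expect_setequal(unique(uni), unique(reps$fst))
  expect_error(weighted_fst_hist(reps, w[1:5]), "lengths differ")
  expect_error(weighted_fst_hist(reps, w * 2), "sum to 1")
})

test_that("ks_compare flags identical, disjoint and calibrated samples", {
  x <- runif(500)
  same <- ks_compare(x, x)
  expect_equal(same$D, 0)
  expect_true(same$pass)
  dis <- ks_compare(runif(200), runif(200) + 5)
  expect_equal(dis$D, 1)
  expect_false(dis$pass)
  expect_error(ks_compare(numeric(0), x), "empty")
  ## calibration: U(0,1) vs U(0,1) passes ~95% of the time
  set.seed(77)
  pass <- mean(replicate(200, ks_compare(runif(300), runif(300))$pass))
  expect_gt(pass, 0.85)
})

test_that("trajectory paths line up with reported finals", {
  p <- demography_params(t1 = 20, r = 0.3, N_JMN = 800, N_A_CNT = 1600)
  set.seed(31)
  tr <- simulate_trajectory(p, selection_params(10), 0.6, keep_path = TRUE)
  expect_equal(nrow(tr$path), p$t1 + p$t2 + 1)
  expect_equal(tr$path$jmn_jpt[nrow(tr$path)], tr$jpt)
  expect_equal(tr$path$acnt_chb[nrow(tr$path)], tr$chb)
  expect_equal(tr$path$jmn_jpt[1], 0.6)
})
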