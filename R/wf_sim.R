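## Forward Wright-Fisher simulator of the dual-structure demography:
## an indigenous lineage (JMN) isolated from a continental lineage (A_CNT)
## for t1 generations, admixture with proportion r of JMN, then t2 = 125
## generations of independent drift of the admixed population (simJPT)
## and the continental population (simCHB), optionally with selection
## favouring the C allele on the continental lineage.

#' Demography parameters for the dual-structure model
#'
#' @param t1 generations of isolation between JMN and A_CNT (the study
#'   grid uses 875, 1125, 1375, 1875, 2375, i.e. 17,500-47,500 years at 20
#'   years/generation).
#' @param r admixture proportion of the JMN component, in (0, 1).
#' @param N_JMN,N_A_CNT haploid population sizes before admixture; the
#'   model constrains `N_JMN <= N_A_CNT`.
#' @param t2 generations after admixture (constant 125).
#' @param N_simJPT,N_simCHB haploid sizes after admixture (constants
#'   12,824 and 29,204).
#' @param generation_years years per generation (20; the conservative
#'   short end of 20-30).
#' @return list of class `demography_params`.
#' @export
demography_params <- function(t1, r, N_JMN, N_A_CNT, t2 = 125,
                              N_simJPT = 12824, N_simCHB = 29204,
                              generation_years = 20) {
  stopifnot(t1 >= 1, t2 >= 1, r > 0, r < 1,
            N_JMN >= 2, N_A_CNT >= 2, N_simJPT >= 2, N_simCHB >= 2)
  if (N_JMN > N_A_CNT) stop("model constraint violated: N_JMN must be <= N_A_CNT")
  structure(list(t1 = as.integer(t1), r = r, N_JMN = as.integer(N_JMN),
                 N_A_CNT = as.integer(N_A_CNT), t2 = as.integer(t2),
                 N_simJPT = as.integer(N_simJPT),
                 N_simCHB = as.integer(N_simCHB),
                 generation_years = generation_years),
            class = "demography_params")
}

#' Selection parameters
#'
#' Selection favours the C allele (i.e. acts against the tracked T
#' frequency) on the continental (CHB-side) lineage only, for 126
#' generations: the admixture generation plus the t2 = 125 post-admixture
#' generations. The per-generation coefficient is `s = scaled / (2
#' N_simCHB)`; the printed scaled values are 0 (neutral), 1, 10, 50, 100.
#'
#' @param scaled `2 * N_simCHB * s`.
#' @param N_simCHB size used to de-scale (default 29,204).
#' @return list of class `selection_params` with `scaled`, `s`,
#'   `duration = 126`, `target_lineage = "CHB"`.
#' @export
selection_params <- function(scaled = 0, N_simCHB = 29204) {
  stopifnot(scaled >= 0)
  structure(list(scaled = scaled, s = scaled / (2 * N_simCHB),
                 duration = 126L, target_lineage = "CHB"),
            class = "selection_params")
}

#' One Wright-Fisher generation (haploid, vectorized)
#'
#' Deterministic selection adjustment of the T frequency when the C allele
#' has advantage s, \eqn{p^* = p / (p + (1-p)(1+s))}, followed by binomial
#' resampling `Binomial(N, p*) / N`. Frequencies 0 and 1 are absorbing.
#'
#' @param freq_T current T-allele frequency (vectorized over replicates).
#' @param N haploid population size (>= 2).
#' @param s_on_C selection coefficient favouring C (default 0).
#' @return next-generation frequencies.
#' @export
wf_step <- function(freq_T, N, s_on_C = 0) {
  if (N < 2) stop("population size must be >= 2")
  p <- wf_selection_adjust(freq_T, s_on_C)
  stats::rbinom(length(p), N, p) / N
}

#' @rdname wf_step
#' @export
wf_selection_adjust <- function(freq_T, s_on_C = 0) {
  freq_T / (freq_T + (1 - freq_T) * (1 + s_on_C))
}

#' Simulate one replicate of the dual-structure trajectory
#'
#' Both lineages start at `f_i`; JMN and A_CNT drift independently for t1
#' generations; the admixture event sets the simJPT starting frequency to
#' `r * f_JMN + (1-r) * f_A_CNT` exactly, while simCHB continues from the
#' A_CNT frequency; both drift for t2 more generations. With selection
#' enabled, the C-favouring adjustment applies to the continental lineage
#' in the admixture generation and throughout t2 (126 generations total).
#'
#' @param params a [demography_params()].
#' @param sel a [selection_params()] (default: neutral).
#' @param f_i initial T frequency in the common ancestor.
#' @param keep_path if TRUE, return the per-generation frequency paths.
#' @return list `f_jmn`, `f_acnt` (final pre-admixture), `jpt0` (simJPT
#'   starting frequency), `jpt`, `chb` (final), and optionally `path`
#'   (data.frame generation x lineage frequencies).
#' @export
simulate_trajectory <- function(params, sel = selection_params(0), f_i,
                                keep_path = FALSE) {
  b <- simulate_batch(params, sel, f_i, n_reps = 1, keep_path = keep_path)
  out <- lapply(b[c("f_jmn", "f_acnt", "jpt0", "jpt", "chb")], `[`, 1)
  if (keep_path) out$path <- b$path[[1]]
  out
}

#' Simulate a batch of replicates (vectorized across replicates)
#'
#' @inheritParams simulate_trajectory
#' @param n_reps number of replicates.
#' @return list of numeric vectors `f_jmn`, `f_acnt`, `jpt0`, `jpt`,
#'   `chb`, logical `excl_before` / `excl_after` (fixation-exclusion
#'   flags), and `path` (list of data.frames) when `keep_path`.
#' @export
simulate_batch <- function(params, sel = selection_params(0), f_i,
                           n_reps, keep_path = FALSE) {
  stopifnot(inherits(params, "demography_params"),
            inherits(sel, "selection_params"),
            f_i >= 0, f_i <= 1)
  jmn <- rep(f_i, n_reps)
  acnt <- rep(f_i, n_reps)
  paths <- if (keep_path) list(jmn = matrix(NA_real_, params$t1 + params$t2 + 1, n_reps),
                               acnt = matrix(NA_real_, params$t1 + params$t2 + 1, n_reps))
           else NULL
  record <- function(g) {
    if (keep_path) {
      paths$jmn[g, ] <<- jmn
      paths$acnt[g, ] <<- acnt
    }
  }
  record(1)
  ## isolation phase; the final generation of the continental lineage is
  ## the admixture generation, where selection (if any) already acts
  for (g in seq_len(params$t1)) {
    jmn <- wf_step(jmn, params$N_JMN)
    s_here <- if (g == params$t1) sel$s else 0
    acnt <- wf_step(acnt, params$N_A_CNT, s_here)
    record(g + 1)
  }
  f_jmn <- jmn; f_acnt <- acnt
  jpt0 <- params$r * f_jmn + (1 - params$r) * f_acnt
  jpt <- jpt0; chb <- f_acnt
  jmn <- jpt; acnt <- chb  # path bookkeeping continues with descendants
  for (g in seq_len(params$t2)) {
    jpt <- wf_step(jpt, params$N_simJPT)
    chb <- wf_step(chb, params$N_simCHB, sel$s)
    jmn <- jpt; acnt <- chb
    record(params$t1 + g + 1)
  }
  excl_before <- (f_jmn == 1 & f_acnt == 1) | (f_jmn == 0 & f_acnt == 0)
  excl_after <- (jpt == 1 & chb == 1) | (jpt == 0 & chb == 0)
  out <- list(f_jmn = f_jmn, f_acnt = f_acnt, jpt0 = jpt0, jpt = jpt,
              chb = chb, excl_before = excl_before, excl_after = excl_after)
  if (keep_path) {
    out$path <- lapply(seq_len(n_reps), function(r)
      data.frame(generation = seq_len(nrow(paths$jmn)) - 1,
                 jmn_jpt = paths$jmn[, r], acnt_chb = paths$acnt[, r]))
  }
  out
}

#' Per-replicate Hudson FST from final frequencies
#'
#' Uses the final population frequencies with the haploid population sizes
#' as Hudson-estimator sample sizes (set `sample_n` to e.g. c(208, 206) to
#' emulate drawing a sample instead). Negative values are clamped to 0;
#' replicates flagged by the fixation-exclusion rules get NA.
#'
#' @param batch output of [simulate_batch()].
#' @param params the [demography_params()] used.
#' @param sample_n optional length-2 sample sizes overriding the
#'   population sizes.
#' @return numeric vector of FST values (NA for excluded replicates).
#' @export
batch_fst <- function(batch, params, sample_n = NULL) {
  n1 <- if (is.null(sample_n)) params$N_simJPT else sample_n[1]
  n2 <- if (is.null(sample_n)) params$N_simCHB else sample_n[2]
  f <- hudson_fst_raw(batch$jpt, n1, batch$chb, n2)
  f <- pmax(f, 0)
  f[batch$excl_before | batch$excl_after] <- NA_real_
  f
}

#' The full dual-structure parameter grid
#'
#' Enumerates the study grid: t1 in \{875, 1125, 1375, 1875, 2375\}, r in
#' \{0.4, 0.2, 0.1\}, N_JMN in \{500, 1000, 2000, 4000, 8000, 10000,
#' 12500, 15000\}, N_A_CNT in \{1000, 2000, 4000, 8000, 16000, 25000,
#' 30000\}, subject to N_JMN <= N_A_CNT: 570 combinations.
#'
#' @param t1_set,r_set,N_JMN_set,N_A_CNT_set parameter sets (defaults as
#'   above).
#' @return data.frame with one row per combination (`t1`, `r`, `N_JMN`,
#'   `N_A_CNT`).
#' @export
default_grid <- function(t1_set = c(875, 1125, 1375, 1875, 2375),
                         r_set = c(0.4, 0.2, 0.1),
                         N_JMN_set = c(500, 1000, 2000, 4000, 8000, 10000,
                                       12500, 15000),
                         N_A_CNT_set = c(1000, 2000, 4000, 8000, 16000,
                                         25000, 30000)) {
  g <- expand.grid(t1 = t1_set, r = r_set, N_JMN = N_JMN_set,
                   N_A_CNT = N_A_CNT_set, KEEP.OUT.ATTRS = FALSE)
  g <- g[g$N_JMN <= g$N_A_CNT, ]
  rownames(g) <- NULL
  g
}

## deterministic per-combination child seed from the root seed and the
## combination's parameter values (subgrids reproduce the full grid)
combo_seed <- function(seed, combo, scaled = 0) {
  v <- c(seed, combo$t1, round(combo$r * 1000), combo$N_JMN,
         combo$N_A_CNT, scaled)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483629
  as.integer(h + 1)
}

#' Simulate the grid
#'
#' Runs [simulate_batch()] for every combination and every initial
#' frequency f_i = 0.1 ... 0.9, computes per-replicate FST and success
#' flags, and returns per-combination summaries. Reproducible under a
#' fixed seed; per-combination RNG streams are derived from the parameter
#' values so that subsets of the grid reproduce the full grid's rows.
#'
#' @param grid data.frame from [default_grid()] (or a subset).
#' @param sel a [selection_params()].
#' @param n_reps replicates per (combination, f_i); the study used 10,000
#'   (use fewer for desk-scale runs).
#' @param seed root integer seed.
#' @param f_set initial frequencies (default `seq(0.1, 0.9, 0.1)`).
#' @param criteria a [success_criteria()].
#' @param keep_replicates if TRUE, keep per-replicate vectors (memory!).
#' @return list of class `grid_result`: `summary` data.frame (one row per
#'   combination: params, `n_success`, `n_excluded`, `mean_fst`,
#'   `jmn_success_min`/`median` among successes) and, when requested,
#'   `replicates` (list per combination of data.frames `f_i`, `f_jmn`,
#'   `jpt`, `chb`, `fst`, `success`).
#' @export
simulate_grid <- function(grid, sel = selection_params(0), n_reps = 100,
                          seed = 1, f_set = seq(0.1, 0.9, by = 0.1),
                          criteria = success_criteria(),
                          keep_replicates = FALSE) {
  summaries <- vector("list", nrow(grid))
  reps_out <- if (keep_replicates) vector("list", nrow(grid)) else NULL
  for (k in seq_len(nrow(grid))) {
    combo <- grid[k, ]
    set.seed(combo_seed(seed, combo, sel$scaled))
    params <- demography_params(combo$t1, combo$r, combo$N_JMN,
                                combo$N_A_CNT)
    acc <- vector("list", length(f_set))
    for (fi in seq_along(f_set)) {
      b <- simulate_batch(params, sel, f_set[fi], n_reps)
      fst <- batch_fst(b, params)
      succ <- replicate_success(b, fst, criteria)
      acc[[fi]] <- data.frame(f_i = f_set[fi], f_jmn = b$f_jmn,
                              jpt = b$jpt, chb = b$chb, fst = fst,
                              excluded = b$excl_before | b$excl_after,
                              success = succ)
    }
    df <- do.call(rbind, acc)
    summaries[[k]] <- data.frame(
      combo, n_reps = n_reps,
      n_success = sum(df$success),
      n_excluded = sum(df$excluded),
      mean_fst = mean(df$fst, na.rm = TRUE),
      jmn_success_min = if (any(df$success)) min(df$f_jmn[df$success]) else NA_real_,
      jmn_success_median = if (any(df$success)) stats::median(df$f_jmn[df$success]) else NA_real_)
    if (keep_replicates) reps_out[[k]] <- df
  }
  structure(list(summary = do.call(rbind, summaries),
                 replicates = reps_out, sel = sel, seed = seed,
                 f_set = f_set, criteria = criteria),
            class = "grid_result")
}

#' Success criteria for a simulated replicate
#'
#' A replicate is a success when its FST exceeds `fst_min`, the simulated
#' JPT T frequency exceeds `t_freq_min`, the JPT T frequency exceeds the
#' CHB one, and neither allele is fixed in either final population.
#' Defaults are the observed values (FST 0.2547, T frequency 0.62).
#'
#' @param fst_min,t_freq_min thresholds.
#' @return list of class `success_criteria`.
#' @export
success_criteria <- function(fst_min = 0.2547, t_freq_min = 0.62) {
  stopifnot(fst_min > 0, t_freq_min > 0)
  structure(list(fst_min = fst_min, t_freq_min = t_freq_min),
            class = "success_criteria")
}

replicate_success <- function(batch, fst, criteria) {
  !is.na(fst) & fst > criteria$fst_min &
    batch$jpt > criteria$t_freq_min &
    batch$jpt > batch$chb &
    batch$jpt > 0 & batch$jpt < 1 & batch$chb > 0 & batch$chb < 1
}

#' Count success cases across combinations
#'
#' @param result a `grid_result` from [simulate_grid()].
#' @return list `per_combination` (data.frame params + `n_success`),
#'   `n_cases` (total successful replicates), `n_combinations`
#'   (combinations with >= 1 success).
#' @export
count_success_cases <- function(result) {
  s <- result$summary
  list(per_combination = s[, c(names(s)[1:4], "n_success")],
       n_cases = sum(s$n_success),
       n_combinations = sum(s$n_success > 0))
}

#' Weighted FST sample from a replicate batch
#'
#' Weights each initial-frequency stratum by the supplied probability and
#' realizes the weighted distribution by proportional resampling to a
#' fixed total (classical two-sample KS has no weighted form). The default
#' weights are the empirical derived-allele-frequency proportions
#' p_i = (0.5589, 0.0984, 0.0734, 0.0623, 0.0494, 0.0436, 0.0360, 0.0342,
#' 0.0438) for f_i = 0.1 ... 0.9.
#'
#' @param replicates data.frame with columns `f_i` and `fst` (one row per
#'   replicate; NA fst = excluded).
#' @param p_weights weights over the f_i strata (must sum to 1 within
#'   1e-9).
#' @param total size of the resampled distribution (default 90,000).
#' @param f_set the stratum levels (default `seq(0.1, 0.9, 0.1)`).
#' @return numeric vector of weighted FST draws.
#' @export
weighted_fst_hist <- function(replicates,
                              p_weights = c(0.5589, 0.0984, 0.0734, 0.0623,
                                            0.0494, 0.0436, 0.0360, 0.0342,
                                            0.0438),
                              total = 90000,
                              f_set = seq(0.1, 0.9, by = 0.1)) {
  if (length(p_weights) != length(f_set)) {
    stop("weights and f_i strata lengths differ")
  }
  if (abs(sum(p_weights) - 1) > 1e-9) stop("weights must sum to 1")
  out <- vector("list", length(f_set))
  for (k in seq_along(f_set)) {
    v <- replicates$fst[!is.na(replicates$fst) &
                          abs(replicates$f_i - f_set[k]) < 1e-9]
    n_k <- round(total * p_weights[k])
    if (n_k > 0 && length(v) > 0) {
      out[[k]] <- sample(v, n_k, replace = TRUE)
    }
  }
  unlist(out)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param sim simulated (weighted) FST sample.
#' @param empirical empirical FST sample.
#' @param alpha pass threshold on the p-value (default 0.05).
#' @return list `D`, `p_value`, `pass` (p >= alpha).
#' @export
ks_compare <- function(sim, empirical, alpha = 0.05) {
  if (!length(sim) || !length(empirical)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(sim, empirical))
  list(D = as.numeric(kt$statistic), p_value = kt$p.value,
       pass = kt$p.value >= alpha)
}
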