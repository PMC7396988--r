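## Pipeline driver and plumbing: region parsing, run configuration,
## stage-ordered execution with TSV reports and a seeded manifest.

#' Parse a region string
#'
#' Accepts `chrom:start-end` with optional thousands separators, e.g.
#' `"8:143,752,235-143,774,193"`; coordinates are 1-based inclusive.
#'
#' @param region region string.
#' @return list `chrom`, `start`, `end`.
#' @export
parse_region <- function(region) {
  s <- gsub(",", "", region)
  m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4) stop("cannot parse region string: ", region)
  out <- list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
  if (out$start > out$end) stop("region start exceeds end: ", region)
  out
}

#' Run configuration
#'
#' Thresholds default to the study's printed values: MAF 0.05 (EHH/LD),
#' MAF 0.01 (nSL), D' 0.98, r-squared 0.75, q < 0.05, FST 0.2547,
#' T-frequency 0.62.
#'
#' @param seed integer seed recorded in every output.
#' @param out_dir output directory for stage TSVs and the manifest.
#' @param maf_ld,maf_nsl,dprime_min,r2_min,q_threshold,fst_min,t_freq_min
#'   thresholds.
#' @param null_reps replicates for the IAV null distribution.
#' @param sim_reps replicates per (combination, f_i) in the simulation
#'   stage.
#' @param n_grid number of grid combinations run in the simulation stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("popsweep_run_"),
                       maf_ld = 0.05, maf_nsl = 0.01, dprime_min = 0.98,
                       r2_min = 0.75, q_threshold = 0.05,
                       fst_min = 0.2547, t_freq_min = 0.62,
                       null_reps = 1000, sim_reps = 50, n_grid = 6) {
  stopifnot(maf_ld >= 0, maf_ld < 0.5, dprime_min > 0, dprime_min <= 1,
            r2_min > 0, r2_min <= 1, q_threshold > 0, q_threshold < 1)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 maf_ld = maf_ld, maf_nsl = maf_nsl,
                 dprime_min = dprime_min, r2_min = r2_min,
                 q_threshold = q_threshold, fst_min = fst_min,
                 t_freq_min = t_freq_min, null_reps = null_reps,
                 sim_reps = sim_reps, n_grid = n_grid),
            class = "run_config")
}

## polynomial hash (base 31, prime modulus) of the canonical JSON of an
## object; manifest fingerprint only, not cryptographic
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", h)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes the stages in pipeline order -- differentiation scan, LD
#' block, neutrality tests, 2D-SFS sweep test, dual-structure simulation,
#' haplotype census -- on a generated two-population panel plus a sweep
#' fixture, writing one TSV per stage and a JSON manifest carrying the
#' seed and a config hash. Any stage failure halts with a stage-tagged
#' error.
#'
#' @param cfg a [run_config()].
#' @param fixture_cfg a [sweep_fixture_config()] for the analysis stages;
#'   defaults to the full-size (206-haplotype) fixture. Tests use a small
#'   one to stay inside their time budget.
#' @return list `manifest` (list) and `files` (named paths), invisibly;
#'   the manifest is also written to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(cfg = run_config(), fixture_cfg = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  files <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## stage 1: differentiation scan on a two-population panel
  panel <- stage("fst_scan", {
    make_two_pop_panel(0.25, 208, 206, n_snps = 120)
  })
  scan <- stage("fst_scan", fst_scan(panel$pop1, panel$pop2))
  files$fst_scan <- write_tsv(scan, file.path(cfg$out_dir, "fst_scan.tsv"))

  ## stage 2: LD block + core region on a sweep fixture
  if (is.null(fixture_cfg)) fixture_cfg <- sweep_fixture_config(seed = cfg$seed)
  fixture_cfg$seed <- cfg$seed
  fx <- stage("ld_block", make_sweep_fixture(fixture_cfg))
  blk <- stage("ld_block", find_ld_block(
    fx$matrix, fx$core_site, cfg$dprime_min, cfg$maf_ld))
  core_reg <- stage("ld_block", select_core_region(
    fx$matrix, fx$core_site, cfg$r2_min))
  files$ld_block <- write_tsv(
    data.frame(start_bp = c(blk$start_bp, core_reg$start_bp),
               end_bp = c(blk$end_bp, core_reg$end_bp),
               n_sites = c(blk$n_sites, core_reg$n_sites),
               rule = c(sprintf("dprime>%g", cfg$dprime_min),
                        sprintf("r2>%g", cfg$r2_min))),
    file.path(cfg$out_dir, "ld_block.tsv"))

  ## stage 3: neutrality tests on the fixture core region
  core_m <- stage("neutrality", restrict_region(fx$matrix, fx$core_start,
                                                fx$core_end))
  td <- stage("neutrality", tajimas_d(core_m, n_reps = 500))
  fw <- stage("neutrality", fay_wu_h_norm(core_m, n_reps = 500))
  h12v <- stage("neutrality", h12(core_m))
  files$neutrality <- write_tsv(
    data.frame(statistic = c("tajimas_d", "fay_wu_h_norm", "h12"),
               value = c(td$statistic, fw$statistic, h12v),
               p_value = c(td$p_value, fw$p_value, NA)),
    file.path(cfg$out_dir, "neutrality.tsv"))

  ## stage 4: 2D-SFS sweep test
  sfs <- stage("sfs2d", {
    phi <- build_phi2d(fx$matrix, fx$core_site, start = fx$core_start,
                       end = fx$core_end)
    s <- iav_stats(phi)
    nulls <- suppressWarnings(null_distribution(
      "F_c", n = n_hap(fx$matrix),
      core_freq = phi$n_D / n_hap(fx$matrix),
      n_reps = cfg$null_reps, seed = cfg$seed + 1,
      allow_small = cfg$null_reps < 1000))
    list(summary = s, test = sweep_test(s, nulls, cfg$q_threshold))
  })
  files$sfs2d <- write_tsv(
    data.frame(statistic = c("F_c", "G_c0", "L_c0", "G_star_c0",
                             "gamma_star_10", "i_max", "i_star_max"),
               value = c(sfs$summary$F_c, sfs$summary$G_c0,
                         sfs$summary$L_c0, sfs$summary$G_star_c0,
                         sfs$summary$gamma_star_10, sfs$summary$i_max,
                         sfs$summary$i_star_max),
               q_value = c(sfs$test$q_values, rep(NA, 4)),
               call = sfs$test$call),
    file.path(cfg$out_dir, "sfs2d.tsv"))

  ## stage 5: dual-structure simulation (reduced grid)
  sim <- stage("simulation", {
    g <- utils::head(default_grid(), cfg$n_grid)
    simulate_grid(g, selection_params(0), n_reps = cfg$sim_reps,
                  seed = cfg$seed,
                  criteria = success_criteria(cfg$fst_min, cfg$t_freq_min))
  })
  files$simulation <- write_tsv(sim$summary,
                                file.path(cfg$out_dir, "simulation.tsv"))

  ## stage 6: haplotype census across the two panel populations
  census <- stage("census", {
    both <- haplotype_matrix(
      rbind(panel$pop1$alleles, panel$pop2$alleles),
      panel$pop1$positions, panel$pop1$site_ids,
      c(panel$pop1$pop_labels, panel$pop2$pop_labels), "sim")
    haplotype_census(both, panel$core_site)
  })
  files$census <- write_tsv(
    data.frame(n_distinct = census$n_distinct,
               n_shared = census$n_shared,
               t(census$n_specific)),
    file.path(cfg$out_dir, "census.tsv"))

  manifest <- list(package = "popsweep",
                   version = as.character(utils::packageVersion("popsweep")),
                   seed = cfg$seed,
                   config_hash = config_hash(unclass(cfg)[names(unclass(cfg))
                                                          != "out_dir"]),
                   stages = names(files),
                   sweep_call = sfs$test$call)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files$manifest <- file.path(cfg$out_dir, "manifest.json")
  invisible(list(manifest = manifest, files = files))
}
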