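## Seed-deterministic generators: neutral coalescent panels (internal
## ms-equivalent engine), sweep/subhaplotype fixtures, two-population
## FST-tuned panels and a genome-wide surrogate FST distribution.

#' Coalescent configuration
#'
#' @param n number of sampled haplotypes (>= 2).
#' @param theta per-region scaled mutation rate (4 N0 mu L); ignored when
#'   `fixed_s` is given.
#' @param rho per-region scaled recombination rate (4 N0 r L); 0 gives the
#'   fast single-tree path.
#' @param hotspot optional list `(start, end, intensity)` in relative
#'   coordinates [0, 1]: recombination intensity multiplier inside the
#'   interval.
#' @param sizes optional piecewise-constant population-size history:
#'   data.frame with columns `time` (in units of 2 N0 generations, past-
#'   ward, first row must be 0) and `size` (relative to N0).
#' @param fixed_s if non-NULL, place exactly this many mutations
#'   (ms `-s` style) instead of Poisson(theta).
#' @param region_bp physical length used for site positions (default
#'   22000, a ~22 kb block).
#' @param seed optional integer seed.
#' @return list of class `coalescent_config`.
#' @export
coalescent_config <- function(n, theta = 10, rho = 0, hotspot = NULL,
                              sizes = NULL, fixed_s = NULL,
                              region_bp = 22000, seed = NULL) {
  stopifnot(n >= 2, theta >= 0, rho >= 0)
  if (!is.null(sizes)) {
    stopifnot(is.data.frame(sizes), all(c("time", "size") %in% names(sizes)),
              sizes$time[1] == 0, all(diff(sizes$time) > 0),
              all(sizes$size > 0))
  }
  structure(list(n = as.integer(n), theta = theta, rho = rho,
                 hotspot = hotspot, sizes = sizes, fixed_s = fixed_s,
                 region_bp = region_bp, seed = seed),
            class = "coalescent_config")
}

## population-size scaling nu(t) at coalescent time t (units of 2 N0)
.size_at <- function(sizes, t) {
  if (is.null(sizes)) return(1)
  sizes$size[findInterval(t, sizes$time)]
}

## draw the waiting time to the next event when the total rate at relative
## size nu is rate0 / nu(t) for the coalescence part plus a constant part
.next_event_time <- function(t, coal_rate, other_rate, sizes) {
  if (is.null(sizes)) {
    return(stats::rexp(1, coal_rate + other_rate))
  }
  ## integrate the piecewise-constant hazard epoch by epoch
  target <- stats::rexp(1, 1)
  acc <- 0
  cur <- t
  repeat {
    nu <- .size_at(sizes, cur)
    rate <- coal_rate / nu + other_rate
    idx <- findInterval(cur, sizes$time)
    nxt <- if (idx < nrow(sizes)) sizes$time[idx + 1] else Inf
    span <- nxt - cur
    if (rate * span >= target - acc || !is.finite(span)) {
      return(cur - t + (target - acc) / rate)
    }
    acc <- acc + rate * span
    cur <- nxt
  }
}

#' Simulate a neutral coalescent haplotype panel
#'
#' Standard coalescent with recombination under the infinite-sites model,
#' the internal equivalent of an `ms` run. Without recombination a single
#' Kingman genealogy is drawn (piecewise-constant population sizes
#' supported); with `rho > 0` an ancestral recombination graph is simulated
#' with ancestral-segment tracking, and a recombination hotspot is realized
#' through a piecewise-linear physical-to-genetic map. Mutations are placed
#' uniformly (physical coordinates) on branches proportionally to length;
#' ancestral states are known by construction. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [coalescent_config()].
#' @return a [haplotype_matrix()] (0 columns possible when no mutation
#'   falls on the genealogy).
#' @export
simulate_coalescent <- function(cfg) {
  stopifnot(inherits(cfg, "coalescent_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$rho == 0) {
    muts <- .sim_tree_mutations(cfg)
  } else {
    muts <- .sim_arg_mutations(cfg)
  }
  .mutations_to_matrix(muts, cfg)
}

## rho = 0: Kingman tree; returns list(pos = relative positions,
## carriers = list of sample index vectors)
.sim_tree_mutations <- function(cfg) {
  n <- cfg$n
  active <- as.list(seq_len(n))         # descendant sets
  birth <- rep(0, n)
  t <- 0
  branch_sets <- vector("list", 2 * n - 2)
  branch_len <- numeric(2 * n - 2)
  nb <- 0L
  while (length(active) > 1) {
    k <- length(active)
    dt <- .next_event_time(t, k * (k - 1) / 2, 0, cfg$sizes)
    t <- t + dt
    pick <- sample.int(k, 2)
    for (p in pick) {
      nb <- nb + 1L
      branch_sets[[nb]] <- active[[p]]
      branch_len[nb] <- t - birth[p]
    }
    merged <- c(active[[pick[1]]], active[[pick[2]]])
    active <- c(active[-pick], list(merged))
    birth <- c(birth[-pick], t)
  }
  total <- sum(branch_len[seq_len(nb)])
  n_mut <- if (!is.null(cfg$fixed_s)) cfg$fixed_s else
    stats::rpois(1, cfg$theta / 2 * total)
  if (n_mut == 0) return(list(pos = numeric(0), carriers = list()))
  br <- sample.int(nb, n_mut, replace = TRUE,
                   prob = branch_len[seq_len(nb)])
  list(pos = stats::runif(n_mut), carriers = branch_sets[br])
}

## physical -> genetic map with optional hotspot; returns list(g = map fn,
## g_inv = inverse, total = genetic length of [0,1])
.genetic_map <- function(hotspot) {
  if (is.null(hotspot)) {
    return(list(g = identity, g_inv = identity, total = 1))
  }
  a <- hotspot$start; b <- hotspot$end; lam <- hotspot$intensity
  total <- a + lam * (b - a) + (1 - b)
  g <- function(x) ifelse(x < a, x,
                   ifelse(x < b, a + lam * (x - a),
                          a + lam * (b - a) + (x - b)))
  g_inv <- function(y) {
    ga <- a; gb <- a + lam * (b - a)
    ifelse(y < ga, y, ifelse(y < gb, a + (y - ga) / lam, b + (y - gb)))
  }
  list(g = g, g_inv = g_inv, total = total)
}

## rho > 0: Hudson ancestral recombination graph. Each lineage is a list of
## segments (left, right in physical [0,1], set = descendant samples).
.sim_arg_mutations <- function(cfg) {
  n <- cfg$n
  map <- .genetic_map(cfg$hotspot)
  full <- seq_len(n)
  lineages <- lapply(full, function(i)
    list(segs = data.frame(left = 0, right = 1), sets = list(i)))
  t <- 0
  mut_pos <- numeric(0)
  mut_carriers <- list()
  gspan <- function(lin) {
    lo <- min(lin$segs$left); hi <- max(lin$segs$right)
    map$g(hi) - map$g(lo)
  }
  accrue <- function(dt) {
    ## Poisson mutations on every (lineage, segment) during dt
    for (lin in lineages) {
      for (s in seq_len(nrow(lin$segs))) {
        lenp <- lin$segs$right[s] - lin$segs$left[s]
        nm <- stats::rpois(1, cfg$theta / 2 * dt * lenp)
        if (nm > 0) {
          pos <- stats::runif(nm, lin$segs$left[s], lin$segs$right[s])
          mut_pos <<- c(mut_pos, pos)
          mut_carriers <<- c(mut_carriers,
                             rep(lin$sets[s], nm))
        }
      }
    }
  }
  while (length(lineages) > 1) {
    k <- length(lineages)
    spans <- vapply(lineages, gspan, numeric(1))
    coal_rate <- k * (k - 1) / 2
    rec_rate <- cfg$rho / 2 * sum(spans)
    dt <- .next_event_time(t, coal_rate, rec_rate, cfg$sizes)
    ## decide event type with the rates at the event time
    nu <- .size_at(cfg$sizes, t + dt)
    p_coal <- (coal_rate / nu) / (coal_rate / nu + rec_rate)
    accrue(dt)
    t <- t + dt
    if (stats::runif(1) < p_coal) {
      pick <- sample.int(k, 2)
      merged <- .merge_lineages(lineages[[pick[1]]], lineages[[pick[2]]], n)
      lineages <- lineages[-pick]
      if (!is.null(merged)) lineages <- c(lineages, list(merged))
    } else {
      li <- sample.int(k, 1, prob = spans)
      lin <- lineages[[li]]
      lo <- min(lin$segs$left); hi <- max(lin$segs$right)
      cut <- map$g_inv(stats::runif(1, map$g(lo), map$g(hi)))
      lineages[[li]] <- NULL
      lineages <- c(lineages, .split_lineage(lin, cut))
    }
  }
  ## last lineage: remaining segments are ancestral to a strict subset only
  ## if material was lost; any segment with full set already dropped
  list(pos = mut_pos, carriers = mut_carriers)
}

## split one lineage at physical position cut into (left part, right part)
.split_lineage <- function(lin, cut) {
  left_segs <- list(); left_sets <- list()
  right_segs <- list(); right_sets <- list()
  for (s in seq_len(nrow(lin$segs))) {
    l <- lin$segs$left[s]; r <- lin$segs$right[s]
    if (r <= cut) {
      left_segs <- c(left_segs, list(c(l, r))); left_sets <- c(left_sets, lin$sets[s])
    } else if (l >= cut) {
      right_segs <- c(right_segs, list(c(l, r))); right_sets <- c(right_sets, lin$sets[s])
    } else {
      left_segs <- c(left_segs, list(c(l, cut))); left_sets <- c(left_sets, lin$sets[s])
      right_segs <- c(right_segs, list(c(cut, r))); right_sets <- c(right_sets, lin$sets[s])
    }
  }
  mk <- function(segs, sets) {
    if (!length(segs)) return(NULL)
    m <- do.call(rbind, segs)
    list(segs = data.frame(left = m[, 1], right = m[, 2]), sets = sets)
  }
  out <- list(mk(left_segs, left_sets), mk(right_segs, right_sets))
  out[!vapply(out, is.null, logical(1))]
}

## coalesce two lineages: union descendant sets on overlaps, drop segments
## whose set reaches all n samples (locally at their MRCA)
.merge_lineages <- function(a, b, n) {
  bounds <- sort(unique(c(a$segs$left, a$segs$right,
                          b$segs$left, b$segs$right)))
  segs <- list(); sets <- list()
  find_set <- function(lin, lo, hi) {
    for (s in seq_len(nrow(lin$segs))) {
      if (lin$segs$left[s] <= lo && lin$segs$right[s] >= hi) {
        return(lin$sets[[s]])
      }
    }
    NULL
  }
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    sa <- find_set(a, lo, hi); sb <- find_set(b, lo, hi)
    u <- union(sa, sb)
    if (!length(u) || length(u) >= n) next   # non-ancestral or local MRCA
    segs <- c(segs, list(c(lo, hi))); sets <- c(sets, list(u))
  }
  if (!length(segs)) return(NULL)
  m <- do.call(rbind, segs)
  list(segs = data.frame(left = m[, 1], right = m[, 2]), sets = sets)
}

.mutations_to_matrix <- function(muts, cfg) {
  n <- cfg$n
  if (!length(muts$pos)) {
    return(haplotype_matrix(matrix(integer(0), nrow = n, ncol = 0),
                            positions = numeric(0), chrom = "sim"))
  }
  ord <- order(muts$pos)
  pos_bp <- pmax(1, round(muts$pos[ord] * cfg$region_bp))
  ## infinite sites live in continuous space; resolve bp collisions by a
  ## minimal rightward shift so positions stay strictly increasing
  for (k in seq_along(pos_bp)[-1]) {
    if (pos_bp[k] <= pos_bp[k - 1]) pos_bp[k] <- pos_bp[k - 1] + 1
  }
  A <- matrix(0L, nrow = n, ncol = length(ord))
  for (k in seq_along(ord)) {
    A[muts$carriers[[ord[k]]], k] <- 1L
  }
  haplotype_matrix(A, positions = pos_bp, chrom = "sim")
}

#' Sweep fixture configuration
#'
#' Describes the synthetic ~22 kb haplotype block the generators emulate:
#' a biallelic core splitting the sample into derived (C-like) and
#' ancestral (T-like) classes, one or two recent star-like subclades
#' inside the derived class (low intra-allelic variability), two tag sites
#' materializing the subhaplotype split, optional shared old variants
#' (j > 0 sites) and a flanking "hotspot" zone of permuted sites that
#' breaks LD outside the core region.
#'
#' @param n_total total haplotypes (default 206, a CHB-sized panel).
#' @param n_derived size of the derived (D) class (default 155).
#' @param split length-2 subhaplotype split inside D (default c(75, 80);
#'   must sum to `n_derived`).
#' @param diversity numeric scalar >= 0 per subclade (recycled): expected
#'   number of exclusive variants per subclade member; 0 = perfect star
#'   tips with no internal mutations (sweep strength increases as this
#'   decreases).
#' @param shared_old number of old variant sites shared between part of the
#'   D group and outsiders (default 6).
#' @param n_background segregating sites private to the ancestral class
#'   (default 40).
#' @param n_flank permuted flanking sites on each side beyond the core
#'   region (default 15), emulating a recombination hotspot at the core
#'   boundary.
#' @param core_bp region span in bp (default 22000); the core region is the
#'   central 15 kb.
#' @param neutral if TRUE the panel is a plain coalescent draw (no planted
#'   structure); the D group is then defined by the site closest to
#'   `n_derived / n_total` frequency.
#' @param theta coalescent theta used for `neutral` panels.
#' @param seed optional seed.
#' @return list of class `sweep_fixture_config`.
#' @export
sweep_fixture_config <- function(n_total = 206, n_derived = 155,
                                 split = c(75, 80), diversity = 0.5,
                                 shared_old = 6, n_background = 40,
                                 n_flank = 15, core_bp = 22000,
                                 neutral = FALSE, theta = 30, seed = NULL) {
  if (sum(split) != n_derived) stop("split must sum to the derived-class size")
  stopifnot(all(diversity >= 0), n_derived >= 2, n_total > n_derived)
  structure(list(n_total = n_total, n_derived = n_derived, split = split,
                 diversity = rep_len(diversity, length(split)),
                 shared_old = shared_old, n_background = n_background,
                 n_flank = n_flank, core_bp = core_bp, neutral = neutral,
                 theta = theta, seed = seed),
            class = "sweep_fixture_config")
}

#' Build a sweep / subhaplotype fixture
#'
#' Constructs a [haplotype_matrix()] with planted truth labels. The
#' derived class carries the core allele and is split into subclades; each
#' subclade is star-like with `diversity` exclusive mutations per member
#' on average. Tag sites are derived exactly in the first subclade, so
#' [classify_subhaplotypes()] recovers the split exactly. Sites outside
#' the central core region have their allele columns permuted across
#' haplotypes, destroying LD with the core (hotspot surrogate).
#'
#' @param cfg a [sweep_fixture_config()].
#' @return list: `matrix` ([haplotype_matrix()]), `truth` (data.frame
#'   `class`, `subhap` per haplotype), `core_site`, `tag_sites`,
#'   `core_start`, `core_end` (bp bounds of the unpermuted core region).
#' @export
make_sweep_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_fixture_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_total
  if (cfg$neutral) {
    m <- simulate_coalescent(coalescent_config(
      n = n, theta = cfg$theta, region_bp = cfg$core_bp))
    p_target <- cfg$n_derived / n
    cnt <- colSums(m$alleles)
    core <- which.min(abs(cnt - p_target * n))
    truth <- data.frame(
      class = ifelse(m$alleles[, core] == 1, "derived", "ancestral"),
      subhap = NA_character_)
    return(list(matrix = m, truth = truth,
                core_site = m$site_ids[core], tag_sites = NULL,
                core_start = min(m$positions), core_end = max(m$positions)))
  }
  d_idx <- seq_len(cfg$n_derived)
  sub1 <- d_idx[seq_len(cfg$split[1])]
  sub2 <- setdiff(d_idx, sub1)
  out_idx <- setdiff(seq_len(n), d_idx)
  cols <- list(); owners <- list()
  add <- function(carriers) {
    cols[[length(cols) + 1L]] <<- carriers
  }
  add(d_idx)                                   # core site
  core_col <- 1L
  add(c(sub1, sample(out_idx, max(1, round(length(out_idx) * 0.1)))))  # tag 1
  add(c(sub1, sample(out_idx, max(1, round(length(out_idx) * 0.1)))))  # tag 2
  tag_cols <- c(2L, 3L)
  ## subclade-exclusive variants (j = 0): Poisson(diversity) per member,
  ## each a singleton within its subclade (star-like tips)
  for (sc in seq_along(cfg$split)) {
    members <- if (sc == 1) sub1 else sub2
    for (h in members) {
      k <- stats::rpois(1, cfg$diversity[sc])
      for (dummy in seq_len(k)) add(h)
    }
  }
  ## shared old variants (j > 0): they predate the subclade MRCA, so they
  ## are carried by the whole tag-defined subclade plus some outsiders --
  ## monomorphic within each subclade (pi_within = 0 at diversity 0) and
  ## i = |sub1| for every shared site, so i*_max equals the split size
  for (dummy in seq_len(cfg$shared_old)) {
    add(c(sub1,
          sample(out_idx, sample.int(max(1, length(out_idx) %/% 4), 1))))
  }
  ## ancestral-class background diversity (i = 0 sites)
  for (dummy in seq_len(cfg$n_background)) {
    sz <- 1 + stats::rgeom(1, 0.3)
    sz <- min(sz, length(out_idx) - 1)
    add(sample(out_idx, max(1, sz)))
  }
  n_core_sites <- length(cols)
  ## flanking sites: frequencies like the background but permuted later
  for (dummy in seq_len(2 * cfg$n_flank)) {
    sz <- 1 + stats::rgeom(1, 0.15)
    add(sample(n, min(sz, n - 1)))
  }
  A <- matrix(0L, nrow = n, ncol = length(cols))
  for (k in seq_along(cols)) A[cols[[k]], k] <- 1L
  ## layout: core region = central 15 kb of core_bp; flanks outside
  core_lo <- round(cfg$core_bp * 0.16); core_hi <- round(cfg$core_bp * 0.84)
  pos_core <- sort(sample(seq(core_lo, core_hi), n_core_sites))
  n_fl <- length(cols) - n_core_sites
  pos_left <- sort(sample(seq(1, core_lo - 1), n_fl %/% 2))
  pos_right <- sort(sample(seq(core_hi + 1, cfg$core_bp), n_fl - n_fl %/% 2))
  ## permute flank columns across haplotypes (hotspot: LD broken)
  flank_cols <- if (n_fl > 0) seq(n_core_sites + 1, length(cols)) else integer(0)
  for (k in flank_cols) A[, k] <- A[sample.int(n), k]
  ord_cols <- c(seq_len(n_core_sites), flank_cols)
  pos_all <- c(pos_core, pos_left, pos_right)
  ord <- order(pos_all)
  A <- A[, ord_cols[ord], drop = FALSE]
  pos <- pos_all[ord]
  ids <- paste0("s", seq_along(pos))
  core_site <- ids[which(ord == core_col)]
  tag_sites <- ids[match(tag_cols, ord)]
  truth <- data.frame(
    class = ifelse(seq_len(n) %in% d_idx, "derived", "ancestral"),
    subhap = ifelse(seq_len(n) %in% sub1, "A-G",
                    ifelse(seq_len(n) %in% sub2, "C-A", NA)))
  m <- haplotype_matrix(A, positions = pos, site_ids = ids, chrom = "sim")
  list(matrix = m, truth = truth, core_site = core_site,
       tag_sites = tag_sites, core_start = core_lo, core_end = core_hi)
}

## mean Hudson FST of a Balding-Nichols pair at ancestral p = 0.5 under
## divergence parameter F, by deterministic Gauss-Legendre quadrature
## (E[ratio] != ratio of expectations: the estimator is biased downward
## for a single site, so the generator calibrates F against this map)
.bn_mean_fst <- function(F, n_nodes = 64) {
  if (F <= 0) return(0)
  a <- 0.5 * (1 - F) / F
  gl <- .gauss_legendre(n_nodes)
  x <- gl$nodes; w <- gl$weights
  dens <- stats::dbeta(x, a, a) * w
  dens <- dens / sum(dens)
  num <- outer(x, x, function(p1, p2) (p1 - p2)^2)
  den <- outer(x, x, function(p1, p2) p1 * (1 - p2) + p2 * (1 - p1))
  ratio <- ifelse(den > 0, num / den, 0)
  as.numeric(t(dens) %*% ratio %*% dens)
}

.gauss_legendre <- function(n) {
  ## nodes/weights on (0, 1) via the Golub-Welsch eigen method
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b; J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = (rev(e$values) + 1) / 2,
       weights = rev(e$vectors[1, ]^2 * 2) / 2)
}

.bn_calibrate <- function(target) {
  if (target <= 0) return(0)
  f <- stats::uniroot(function(F) .bn_mean_fst(F) - target,
                      lower = 1e-4, upper = 0.98, tol = 1e-5)
  f$root
}

#' Two-population panel with a target FST
#'
#' Balding-Nichols island-model draw: per site an ancestral frequency
#' p ~ Uniform(0.05, 0.95) and population frequencies
#' Beta(p (1-F)/F, (1-p)(1-F)/F), then binomial haplotype sampling. The
#' first site is the "core" site, drawn with ancestral frequency 0.5. The
#' internal divergence parameter F is calibrated (deterministic
#' quadrature) so that the mean realized single-site Hudson FST matches
#' `target_fst` despite the estimator's single-site ratio bias.
#'
#' @param target_fst target differentiation in [0, 0.9].
#' @param n1,n2 haplotype sample sizes.
#' @param n_snps number of sites (default 200).
#' @param seed optional seed.
#' @return list `pop1`, `pop2` ([haplotype_matrix()] objects sharing site
#'   lists), `core_site`.
#' @export
make_two_pop_panel <- function(target_fst, n1, n2, n_snps = 200,
                               seed = NULL) {
  stopifnot(target_fst >= 0, target_fst <= 0.9)
  if (!is.null(seed)) set.seed(seed)
  target_fst <- .bn_calibrate(target_fst)
  draw_freq <- function(p, F) {
    if (F == 0) return(rep(p, 2))
    a <- p * (1 - F) / F; b <- (1 - p) * (1 - F) / F
    stats::rbeta(2, a, b)
  }
  p_anc <- c(0.5, stats::runif(n_snps - 1, 0.05, 0.95))
  A1 <- matrix(0L, n1, n_snps); A2 <- matrix(0L, n2, n_snps)
  for (s in seq_len(n_snps)) {
    pq <- draw_freq(p_anc[s], target_fst)
    A1[, s] <- stats::rbinom(n1, 1, pq[1])
    A2[, s] <- stats::rbinom(n2, 1, pq[2])
  }
  pos <- sort(sample.int(1e6, n_snps))
  ids <- paste0("s", seq_len(n_snps))
  list(pop1 = haplotype_matrix(A1, pos, ids, rep("pop1", n1), "sim"),
       pop2 = haplotype_matrix(A2, pos, ids, rep("pop2", n2), "sim"),
       core_site = ids[1])
}

#' Surrogate genome-wide FST sample
#'
#' Right-skewed (gamma) sample standing in for a genome-wide empirical
#' FST distribution; the default mean 4.8e-3 echoes the chromosome-wide
#' average of the JPT/CHB scan the package emulates.
#'
#' @param n_snps sample size.
#' @param mean_fst target mean (default 4.8e-3).
#' @param shape gamma shape (default 0.35, strongly right-skewed).
#' @param seed optional seed.
#' @return numeric vector of surrogate FST values (clamped to [0, 1)).
#' @export
surrogate_empirical_fst <- function(n_snps, mean_fst = 4.8e-3,
                                    shape = 0.35, seed = NULL) {
  stopifnot(n_snps >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rgamma(n_snps, shape = shape, scale = mean_fst / shape)
  pmin(x, 0.999)
}

## neutral SFS conditioned on (n, S): Kingman tree + S mutations placed
## proportionally to branch length (used by the neutrality-test nulls)
sim_neutral_sfs <- function(n, S) {
  m <- simulate_coalescent(coalescent_config(n = n, fixed_s = S))
  sfs_counts(m)
}
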