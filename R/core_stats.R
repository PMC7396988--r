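## Frequency- and haplotype-based population-genetic statistics.

#' Hudson's FST for one site
#'
#' Hudson-type FST estimator (Bhatia et al. 2013 "Hudson" form) from two
#' per-site allele-frequency summaries, using haplotype counts as sample
#' sizes:
#' \deqn{F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'                     {p_1(1-p_2) + p_2(1-p_1)}}
#' When both populations are monomorphic for the same allele the denominator
#' is zero and the estimate is undefined (`NA`, flagged); such sites are
#' excluded from scans.
#'
#' @param a,b [site_freq()] objects (may be vectorized).
#' @param clamp if `TRUE`, negative estimates are reported as 0 in `fst`
#'   (the raw value is kept in `fst_raw`).
#' @return A data.frame with columns `fst`, `fst_raw`, `clamped`,
#'   `undefined`.
#' @examples
#' hudson_fst(site_freq(131, 208), site_freq(51, 206))$fst  # 0.2547...
#' @export
hudson_fst <- function(a, b, clamp = TRUE) {
  stopifnot(inherits(a, "site_freq"), inherits(b, "site_freq"))
  raw <- hudson_fst_raw(a$freq, a$n, b$freq, b$n)
  undef <- !is.finite(raw)
  fst <- raw
  clamped <- rep(FALSE, length(raw))
  if (clamp) {
    clamped <- !undef & raw < 0
    fst[clamped] <- 0
  }
  data.frame(fst = fst, fst_raw = raw, clamped = clamped, undefined = undef)
}

## vectorized core; NA where the between-population heterozygosity is 0
hudson_fst_raw <- function(p1, n1, p2, n2) {
  if (any(n1 < 2) || any(n2 < 2)) stop("invalid sample size: n must be >= 2")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Sitewise Hudson FST scan over two populations
#'
#' Applies [hudson_fst()] at every shared site of two phased panels,
#' dropping sites inside excluded regions (e.g. the MHC,
#' chr6:25,726,291-33,368,333).
#'
#' @param matrixA,matrixB [haplotype_matrix()] objects sharing site lists.
#' @param exclusions optional data.frame with columns `chrom`, `start`,
#'   `end` (1-based inclusive) of regions to drop.
#' @param clamp passed to [hudson_fst()].
#' @return data.frame: `site_id`, `chrom`, `pos`, `p1`, `p2`, `fst`,
#'   `fst_raw`, `clamped`, `undefined`.
#' @export
fst_scan <- function(matrixA, matrixB, exclusions = NULL, clamp = TRUE) {
  if (!identical(matrixA$site_ids, matrixB$site_ids) ||
      !identical(matrixA$positions, matrixB$positions)) {
    stop("site lists of the two panels are not aligned")
  }
  keep <- rep(TRUE, n_site(matrixA))
  if (!is.null(exclusions) && nrow(exclusions)) {
    for (k in seq_len(nrow(exclusions))) {
      if (exclusions$chrom[k] != matrixA$chrom) next
      keep <- keep & !(matrixA$positions >= exclusions$start[k] &
                       matrixA$positions <= exclusions$end[k])
    }
  }
  idx <- which(keep)
  p1 <- derived_freq(matrixA)[idx]
  p2 <- derived_freq(matrixB)[idx]
  f <- hudson_fst(site_freq(p1 * n_hap(matrixA), n_hap(matrixA)),
                  site_freq(p2 * n_hap(matrixB), n_hap(matrixB)),
                  clamp = clamp)
  cbind(data.frame(site_id = matrixA$site_ids[idx], chrom = matrixA$chrom,
                   pos = matrixA$positions[idx], p1 = p1, p2 = p2),
        f)
}

#' Empirical percentile of a site in an FST scan
#'
#' @param scan output of [fst_scan()].
#' @param site a site id present in the scan.
#' @return list with `fst`, `rank` (1 = highest) and `percentile` (fraction
#'   of defined sites with FST <= this site's).
#' @export
fst_rank <- function(scan, site) {
  ok <- !scan$undefined
  i <- match(site, scan$site_id)
  if (is.na(i)) stop("site not found in scan (it may fall in an excluded region)")
  v <- scan$fst[ok]
  list(fst = scan$fst[i],
       rank = sum(v > scan$fst[i]) + 1L,
       percentile = mean(v <= scan$fst[i]))
}

#' Mean FST in non-overlapping windows
#'
#' @param scan output of [fst_scan()], sorted by position.
#' @param window_bp window width in bp; windows tile from the first site.
#' @return data.frame `start`, `end`, `n_sites`, `mean_fst` (NA for empty
#'   windows), `rank` (1 = highest mean), ordered by position.
#' @export
block_fst <- function(scan, window_bp) {
  stopifnot(window_bp > 0)
  if (is.unsorted(scan$pos)) stop("scan must be sorted by position")
  ok <- !scan$undefined
  first <- min(scan$pos)
  win <- floor((scan$pos - first) / window_bp)
  all_win <- seq(0, max(win))
  mean_fst <- rep(NA_real_, length(all_win))
  n_sites <- integer(length(all_win))
  agg <- tapply(scan$fst[ok], win[ok], mean)
  cnt <- table(win)
  n_sites[as.integer(names(cnt)) + 1L] <- as.integer(cnt)
  mean_fst[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  out <- data.frame(start = first + all_win * window_bp,
                    end = first + (all_win + 1) * window_bp - 1,
                    n_sites = n_sites, mean_fst = mean_fst)
  out$rank <- rank(-out$mean_fst, ties.method = "min", na.last = "keep")
  out
}

#' Nucleotide diversity
#'
#' Per-site nucleotide diversity over a span:
#' \eqn{\pi = \sum_j 2 p_j (1-p_j)\, n/(n-1) / L}, identical to the mean
#' pairwise Hamming distance divided by `L`. `L` defaults to the number of
#' sites in the span; pass `L` explicitly (region length in bp) when the
#' matrix holds only variant sites and a per-bp diversity is wanted (as for
#' dating). The sampling variance is Nei's (1987, eq. 10.7) estimator,
#' used by [compare_pi_ztest()].
#'
#' @param m a [haplotype_matrix()] (>= 2 haplotypes).
#' @param start,end optional bp bounds restricting the span.
#' @param L denominator length; default: number of sites in the span.
#' @return list `pi`, `var_pi`, `n`, `L`, class `diversity_result`.
#' @export
nucleotide_diversity <- function(m, start = NULL, end = NULL, L = NULL) {
  if (n_hap(m) < 2) stop("need >= 2 haplotypes")
  if (!is.null(start) || !is.null(end)) m <- restrict_region(m, start, end)
  if (n_site(m) == 0) stop("span contains zero sites")
  if (is.null(L)) L <- n_site(m)
  n <- n_hap(m)
  p <- derived_freq(m)
  pi <- sum(2 * p * (1 - p)) * n / (n - 1) / L
  var_pi <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  structure(list(pi = pi, var_pi = var_pi, n = n, L = L),
            class = "diversity_result")
}

#' Mean cross-group pairwise diversity
#'
#' Average per-site Hamming distance between all pairs with one haplotype
#' from each group; the input to [divergence_time()].
#'
#' @param m a [haplotype_matrix()].
#' @param groupA,groupB row indices of the two groups.
#' @param L denominator length (default: number of sites in `m`).
#' @return per-site mean pairwise difference between groups.
#' @export
divergence_pi <- function(m, groupA, groupB, L = NULL) {
  if (is.null(L)) L <- n_site(m)
  A <- m$alleles[groupA, , drop = FALSE]
  B <- m$alleles[groupB, , drop = FALSE]
  ## sum over sites of cross-group mismatches: cA*(nB-cB) + cB*(nA-cA)
  cA <- colSums(A); cB <- colSums(B)
  nA <- nrow(A); nB <- nrow(B)
  sum(cA * (nB - cB) + cB * (nA - cA)) / (nA * nB) / L
}

#' z test comparing two diversity estimates
#'
#' \eqn{z = (\pi_a - \pi_b)/\sqrt{V_a + V_b}} with a two-sided normal
#' p-value.
#'
#' @param a,b `diversity_result` objects from [nucleotide_diversity()].
#' @return list `z`, `p_value`, `diff`.
#' @export
compare_pi_ztest <- function(a, b) {
  v <- a$var_pi + b$var_pi
  d <- a$pi - b$pi
  if (v == 0) {
    if (d != 0) stop("zero combined variance with unequal pi")
    return(list(z = 0, p_value = 1, diff = 0))
  }
  z <- d / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), diff = d)
}

## unfolded site frequency spectrum counts: xi[i] = # sites with derived
## count i, i = 1..n-1 (monomorphic columns contribute nothing)
sfs_counts <- function(m) {
  n <- n_hap(m)
  cnt <- colSums(m$alleles)
  tabulate(cnt[cnt > 0 & cnt < n], nbins = n - 1)
}

#' Tajima's D
#'
#' Tajima (1989) D from the number of segregating sites and mean pairwise
#' diversity, with the standard a1, a2, b1, b2, c1, c2, e1, e2 constants.
#' p-values come from a coalescent null conditioned on (n, S) simulated by
#' the in-package engine (default), or from Tajima's beta approximation
#' (`p_method = "beta"`).
#'
#' @param m a [haplotype_matrix()] with >= 4 haplotypes.
#' @param start,end optional bp bounds.
#' @param p_method `"coalescent"`, `"beta"` or `"none"`.
#' @param n_reps replicates for the coalescent null.
#' @return list `statistic`, `p_value`, `S`, `n`, `method`.
#' @export
tajimas_d <- function(m, start = NULL, end = NULL,
                      p_method = c("coalescent", "beta", "none"),
                      n_reps = 2000) {
  p_method <- match.arg(p_method)
  if (!is.null(start) || !is.null(end)) m <- restrict_region(m, start, end)
  n <- n_hap(m)
  if (n < 4) stop("need >= 4 haplotypes")
  xi <- sfs_counts(m)
  S <- sum(xi)
  if (S == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, S = 0L, n = n,
                method = "tajimas_d"))
  }
  D <- tajima_d_from_sfs(xi, n)
  p <- switch(p_method,
    none = NA_real_,
    beta = tajima_beta_p(D, n),
    coalescent = {
      null <- null_neutrality_stats(n, S, n_reps)
      empirical_p_two_sided(D, null$D)
    })
  list(statistic = D, p_value = p, S = S, n = n, method = "tajimas_d")
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_from_sfs <- function(xi, n) {
  S <- sum(xi)
  i <- seq_along(xi)
  theta_pi <- sum(2 * i * (n - i) * xi) / (n * (n - 1))
  k <- tajima_constants(n)
  (theta_pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

## Tajima (1989) beta approximation for the distribution of D
tajima_beta_p <- function(D, n) {
  k <- tajima_constants(n)
  dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  dmax <- ((n + 1) / (2 * n) - 1 / k$a1) / sqrt(k$e2)
  alpha <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
  beta <- (1 + dmin * dmax) * dmin / (dmax - dmin)
  x <- (D - dmin) / (dmax - dmin)
  x <- min(max(x, 0), 1)
  lo <- stats::pbeta(x, beta, alpha)
  2 * min(lo, 1 - lo)
}

#' Normalized Fay and Wu's H
#'
#' Zeng et al. (2006) normalization: \eqn{(\theta_\pi - \theta_L)} divided
#' by the square root of its variance estimator, where
#' \eqn{\theta_L = \sum_i i\,\xi_i/(n-1)}. The unnormalized Fay & Wu H
#' (\eqn{\theta_\pi - \theta_H}) equals twice \eqn{\theta_\pi - \theta_L}
#' and is also reported. Requires polarized (ancestral/derived) sites,
#' which the [haplotype_matrix()] coding guarantees.
#'
#' @inheritParams tajimas_d
#' @return list `statistic` (normalized H), `H_unnorm`, `p_value`, `S`,
#'   `n`, `method`.
#' @export
fay_wu_h_norm <- function(m, start = NULL, end = NULL,
                          p_method = c("coalescent", "none"),
                          n_reps = 2000) {
  p_method <- match.arg(p_method)
  if (!is.null(start) || !is.null(end)) m <- restrict_region(m, start, end)
  n <- n_hap(m)
  if (n < 4) stop("need >= 4 haplotypes")
  xi <- sfs_counts(m)
  S <- sum(xi)
  if (S == 0) {
    return(list(statistic = NA_real_, H_unnorm = NA_real_,
                p_value = NA_real_, S = 0L, n = n, method = "fay_wu_h"))
  }
  H <- faywu_h_from_sfs(xi, n)
  p <- if (p_method == "none") NA_real_ else {
    null <- null_neutrality_stats(n, S, n_reps)
    empirical_p_two_sided(H$norm, null$H)
  }
  list(statistic = H$norm, H_unnorm = H$unnorm, p_value = p, S = S, n = n,
       method = "fay_wu_h")
}

faywu_h_from_sfs <- function(xi, n) {
  S <- sum(xi)
  i <- seq_along(xi)
  theta_pi <- sum(2 * i * (n - i) * xi) / (n * (n - 1))
  theta_L <- sum(i * xi) / (n - 1)
  a1 <- sum(1 / seq_len(n - 1))
  bn <- sum(1 / seq_len(n - 1)^2)
  bn1 <- bn + 1 / n^2
  theta_w <- S / a1
  theta2 <- S * (S - 1) / (a1^2 + bn)
  v <- (n - 2) / (6 * (n - 1)) * theta_w +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * theta2
  diff <- theta_pi - theta_L
  list(norm = if (v > 0) diff / sqrt(v) else 0, unnorm = 2 * diff)
}

## shared coalescent null for Tajima's D and normalized H, conditioned on
## (n, S); memoised per call chain via an environment cache
.null_cache <- new.env(parent = emptyenv())

null_neutrality_stats <- function(n, S, n_reps = 2000, use_cache = TRUE) {
  key <- sprintf("n%d_S%d_r%d", n, S, n_reps)
  if (use_cache && !is.null(.null_cache[[key]])) return(.null_cache[[key]])
  D <- numeric(n_reps); H <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    xi <- sim_neutral_sfs(n, S)
    D[r] <- tajima_d_from_sfs(xi, n)
    H[r] <- faywu_h_from_sfs(xi, n)$norm
  }
  out <- list(D = D, H = H)
  if (use_cache) .null_cache[[key]] <- out
  out
}

empirical_p_two_sided <- function(obs, null) {
  lo <- (sum(null <= obs) + 1) / (length(null) + 1)
  hi <- (sum(null >= obs) + 1) / (length(null) + 1)
  min(1, 2 * min(lo, hi))
}

empirical_p_low <- function(obs, null) {
  (sum(null <= obs) + 1) / (length(null) + 1)
}

#' H12 haplotype homozygosity
#'
#' With haplotype-class frequencies \eqn{p_1 \ge p_2 \ge \dots}:
#' \eqn{H12 = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2}. Pooling the two most
#' frequent classes makes the statistic sensitive to both hard and soft
#' sweeps.
#'
#' @param window a [haplotype_matrix()] (the window).
#' @return H12 value in (0, 1].
#' @export
h12 <- function(window) {
  if (n_hap(window) < 1) stop("empty window")
  key <- apply(window$alleles, 1, paste, collapse = "")
  p <- sort(as.numeric(table(key)) / length(key), decreasing = TRUE)
  if (length(p) == 1) return(1)
  (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
}

#' Sliding-window H12 scan
#'
#' @param m a [haplotype_matrix()].
#' @param window_snps number of SNPs per window.
#' @param step step between window starts, in SNPs.
#' @return list: `track` data.frame (`start_bp`, `end_bp`, `center_bp`,
#'   `h12`) and empirical summary `mean`, `lower95`, `upper95` lines.
#' @export
h12_scan <- function(m, window_snps, step = 1) {
  if (step <= 0) stop("step must be positive")
  if (window_snps > n_site(m)) stop("window larger than matrix")
  starts <- seq(1, n_site(m) - window_snps + 1, by = step)
  vals <- vapply(starts, function(s) h12(m[, s:(s + window_snps - 1)]),
                 numeric(1))
  track <- data.frame(
    start_bp = m$positions[starts],
    end_bp = m$positions[starts + window_snps - 1],
    center_bp = (m$positions[starts] + m$positions[starts + window_snps - 1]) / 2,
    h12 = vals)
  list(track = track, mean = mean(vals),
       lower95 = as.numeric(stats::quantile(vals, 0.025)),
       upper95 = as.numeric(stats::quantile(vals, 0.975)))
}

#' Extended haplotype homozygosity (EHH)
#'
#' EHH at position x is the probability that two randomly drawn carriers of
#' the core allele are identical at every retained site between the core
#' and x (inclusive). Sites with MAF below `maf_min` are dropped before the
#' computation. EHH equals 1 at the core and is non-increasing away from
#' it.
#'
#' @param m a [haplotype_matrix()].
#' @param core_site site id or position of the core site.
#' @param core_allele 0 (ancestral) or 1 (derived): which carriers to track.
#' @param maf_min minor-allele-frequency filter (default 0.05).
#' @return data.frame `pos`, `distance_bp`, `distance_sites`, `side`,
#'   `ehh`, ordered by position.
#' @export
ehh <- function(m, core_site, core_allele = 1, maf_min = 0.05) {
  core <- site_index(m, core_site)
  keep <- maf(m) >= maf_min
  keep[core] <- TRUE
  sub <- m[, which(keep)]
  core2 <- which(which(keep) == core)
  carriers <- which(sub$alleles[, core2] == core_allele)
  if (length(carriers) < 2) stop("core allele carried by < 2 haplotypes")
  A <- sub$alleles[carriers, , drop = FALSE]
  nc <- nrow(A)
  ehh_dir <- function(idx) {
    ## cumulative haplotype-class refinement away from the core
    grp <- rep(1L, nc)
    out <- numeric(length(idx))
    for (k in seq_along(idx)) {
      grp <- as.integer(interaction(grp, A[, idx[k]], drop = TRUE))
      cnt <- tabulate(grp)
      out[k] <- sum(cnt * (cnt - 1)) / (nc * (nc - 1))
    }
    out
  }
  right <- seq(core2, ncol(A))
  left <- rev(seq(1, core2))
  e_r <- ehh_dir(right)
  e_l <- ehh_dir(left)
  out <- rbind(
    data.frame(pos = sub$positions[rev(left)], side = "left",
               ehh = rev(e_l),
               distance_sites = rev(seq_along(left) - 1)),
    data.frame(pos = sub$positions[right], side = "right", ehh = e_r,
               distance_sites = seq_along(right) - 1))
  out <- out[!duplicated(out$pos), ]
  out$distance_bp <- abs(out$pos - sub$positions[core2])
  out[order(out$pos), c("pos", "distance_bp", "distance_sites", "side", "ehh")]
}

#' nSL scores
#'
#' For each retained site, the unstandardized score is
#' \eqn{\ln(SL_A/SL_D)} where \eqn{SL_\bullet} is, over all haplotype pairs
#' within the ancestral (A) or derived (D) allele class, the mean number of
#' consecutive segregating sites around the focal site over which the pair
#' is identical (the focal site counts; extension stops at the first
#' mismatch or at the window cap). Scores are standardized within
#' derived-frequency bins (20 equal-width bins). No recombination map is
#' used; distance is measured in segregating sites.
#'
#' @param m a [haplotype_matrix()].
#' @param maf_min minor-allele-frequency filter (default 0.01).
#' @param max_window cap on the number of SNPs a pair may extend over in
#'   each direction (`Inf` = unlimited; the scan settings 100 / 1500 /
#'   unlimited are all accepted).
#' @param n_bins frequency bins for standardization.
#' @return data.frame `site_id`, `pos`, `freq`, `sl_a`, `sl_d`, `nsl_raw`,
#'   `nsl` (standardized; NA where an allele class has < 2 members),
#'   `significant` (|nsl| > 1.96).
#' @export
nsl <- function(m, maf_min = 0.01, max_window = Inf, n_bins = 20) {
  p <- derived_freq(m)
  keep <- pmin(p, 1 - p) >= maf_min
  S <- n_site(m)
  n <- n_hap(m)
  pairs <- utils::combn(n, 2)
  ## per pair: positions (site indices) of mismatches, then for each focal
  ## site the shared tract length = gap between flanking mismatches
  tract <- matrix(0, nrow = ncol(pairs), ncol = S)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    mm <- which(m$alleles[i, ] != m$alleles[j, ])
    left <- c(0L, mm)[findInterval(seq_len(S), c(0L, mm) + 0.5) ]
    ## left = index of nearest mismatch at or before each site (0 if none)
    nxt <- c(mm, S + 1L)[findInterval(seq_len(S), mm + 0.5) + 1L]
    len <- nxt - left - 1L
    len[seq_len(S) %in% mm] <- 0L
    if (is.finite(max_window)) {
      lo <- pmax(left + 1L, seq_len(S) - as.integer(max_window))
      hi <- pmin(nxt - 1L, seq_len(S) + as.integer(max_window))
      len2 <- hi - lo + 1L
      len2[seq_len(S) %in% mm] <- 0L
      len <- len2
    }
    tract[k, ] <- len
  }
  sl_a <- rep(NA_real_, S); sl_d <- rep(NA_real_, S)
  for (s in which(keep)) {
    anc <- m$alleles[, s] == 0
    ia <- which(anc[pairs[1, ]] & anc[pairs[2, ]])
    id <- which(!anc[pairs[1, ]] & !anc[pairs[2, ]])
    if (length(ia) >= 1 && sum(anc) >= 2) sl_a[s] <- mean(tract[ia, s])
    if (length(id) >= 1 && sum(!anc) >= 2) sl_d[s] <- mean(tract[id, s])
  }
  raw <- log(sl_a / sl_d)
  raw[!is.finite(raw)] <- NA_real_
  ## standardize within derived-frequency bins
  bin <- cut(p, breaks = seq(0, 1, length.out = n_bins + 1),
             include.lowest = TRUE)
  std <- rep(NA_real_, S)
  for (b in levels(bin)) {
    idx <- which(bin == b & !is.na(raw))
    if (length(idx) >= 2 && stats::sd(raw[idx]) > 0) {
      std[idx] <- (raw[idx] - mean(raw[idx])) / stats::sd(raw[idx])
    } else if (length(idx) >= 1) {
      std[idx] <- 0
    }
  }
  data.frame(site_id = m$site_ids, pos = m$positions, freq = p,
             sl_a = sl_a, sl_d = sl_d, nsl_raw = raw, nsl = std,
             significant = !is.na(std) & abs(std) > 1.96)
}

#' Population branch statistic
#'
#' Branch lengths from pairwise FST via \eqn{T = -\ln(1 - F_{ST})};
#' \eqn{PBS_a = (T_{ab} + T_{ao} - T_{bo})/2} (and symmetrically for b).
#' Negative values are clamped to 0; FST = 1 yields an infinite branch.
#'
#' @param fst_ab,fst_ao,fst_bo pairwise FST values (vectorized) among
#'   populations a, b and outgroup o, each in [0, 1).
#' @param clamp clamp negative PBS at 0 (default TRUE).
#' @return data.frame `pbs_a`, `pbs_b`.
#' @export
pbs <- function(fst_ab, fst_ao, fst_bo, clamp = TRUE) {
  tt <- function(f) ifelse(f >= 1, Inf, -log(1 - f))
  t_ab <- tt(fst_ab); t_ao <- tt(fst_ao); t_bo <- tt(fst_bo)
  a <- (t_ab + t_ao - t_bo) / 2
  b <- (t_ab + t_bo - t_ao) / 2
  if (clamp) {
    a <- pmax(a, 0); b <- pmax(b, 0)
  }
  data.frame(pbs_a = a, pbs_b = b)
}

#' Pairwise linkage disequilibrium (D' and r-squared)
#'
#' From phased haplotype counts: \eqn{D = p_{AB} - p_A p_B};
#' \eqn{D' = |D|/D_{max}} with the standard \eqn{D_{max}};
#' \eqn{r^2 = D^2/(p_A q_A p_B q_B)}. Alleles are counted on the derived
#' (1) allele at each site.
#'
#' @param m a [haplotype_matrix()].
#' @param siteA,siteB site ids or positions; both must be polymorphic.
#' @return list `d`, `d_prime`, `r2`.
#' @export
d_prime_r2 <- function(m, siteA, siteB) {
  .ld_pair(m$alleles[, site_index(m, siteA)],
           m$alleles[, site_index(m, siteB)])
}

## LD from two allele vectors (internal; callers index columns directly)
.ld_pair <- function(a, b) {
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) stop("monomorphic site")
  D <- mean(a == 1 & b == 1) - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(d = D,
       d_prime = if (dmax == 0) 0 else abs(D) / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' LD block around an anchor site
#'
#' Sites with MAF below `maf_min` are removed, then the block is the
#' maximal contiguous run of retained sites containing the anchor in which
#' every adjacent pair satisfies D' > `dprime_min` (adjacent-pair chaining;
#' a configurable, documented stand-in for confidence-interval block
#' callers).
#'
#' @param m a [haplotype_matrix()].
#' @param anchor_site site id or position; must pass the MAF filter.
#' @param dprime_min D' threshold (default 0.98).
#' @param maf_min MAF filter (default 0.05).
#' @return list `start_index`, `end_index` (site indices in `m`),
#'   `start_bp`, `end_bp`, `n_sites`, `site_ids`.
#' @export
find_ld_block <- function(m, anchor_site, dprime_min = 0.98, maf_min = 0.05) {
  anchor <- site_index(m, anchor_site)
  if (maf(m)[anchor] < maf_min) stop("anchor fails the MAF filter")
  retained <- which(maf(m) >= maf_min)
  a <- match(anchor, retained)
  dp_adj <- function(i, j) .ld_pair(m$alleles[, retained[i]],
                                    m$alleles[, retained[j]])$d_prime
  lo <- a
  while (lo > 1 && dp_adj(lo - 1, lo) > dprime_min) lo <- lo - 1
  hi <- a
  while (hi < length(retained) && dp_adj(hi, hi + 1) > dprime_min) hi <- hi + 1
  idx <- retained[lo:hi]
  list(start_index = idx[1], end_index = idx[length(idx)],
       start_bp = m$positions[idx[1]], end_bp = m$positions[idx[length(idx)]],
       n_sites = length(idx), site_ids = m$site_ids[idx])
}

#' Core region by r-squared with an anchor
#'
#' The maximal contiguous run of sites containing the anchor in which every
#' site has r-squared > `r2_min` with the anchor.
#'
#' @param m a [haplotype_matrix()].
#' @param anchor_site site id or position (polymorphic).
#' @param r2_min threshold (default 0.75).
#' @return list `start_index`, `end_index`, `start_bp`, `end_bp`,
#'   `n_sites`.
#' @export
select_core_region <- function(m, anchor_site, r2_min = 0.75) {
  anchor <- site_index(m, anchor_site)
  r2_with <- function(j) {
    if (j == anchor) return(1)
    p <- derived_freq(m)[j]
    if (p %in% c(0, 1)) return(0)
    .ld_pair(m$alleles[, anchor], m$alleles[, j])$r2
  }
  lo <- anchor
  while (lo > 1 && r2_with(lo - 1) > r2_min) lo <- lo - 1
  hi <- anchor
  while (hi < n_site(m) && r2_with(hi + 1) > r2_min) hi <- hi + 1
  list(start_index = lo, end_index = hi,
       start_bp = m$positions[lo], end_bp = m$positions[hi],
       n_sites = hi - lo + 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment,
#' \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} \min(1, m\,p_{(j)}/j)}.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
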