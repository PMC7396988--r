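## Haplotype census across populations and post-call ancient-DNA site
## filters (consensus haploidization, ancient-singleton removal).

#' Haplotype census by population and core allele
#'
#' Collapses identical haplotype sequences, tags each distinct haplotype
#' by the populations it occurs in (population-specific vs shared) and by
#' its allele at the core site, and reports per-class counts and
#' fractions.
#'
#' @param m a [haplotype_matrix()] with >= 2 populations labelled.
#' @param core_site site id or position of the core site.
#' @return list `table` (data.frame: `haplotype` key, per-population
#'   counts, `shared`, `core_allele`), `n_distinct`, `n_specific` (named
#'   by population), `n_shared`, `core_fraction_specific` (fraction of
#'   each population's specific haplotypes carrying the derived core
#'   allele).
#' @export
haplotype_census <- function(m, core_site) {
  pops <- unique(m$pop_labels)
  if (length(pops) < 2) stop("need >= 2 labelled populations")
  core <- site_index(m, core_site)
  key <- apply(m$alleles, 1, paste, collapse = "")
  uk <- unique(key)
  tab <- data.frame(haplotype = uk, stringsAsFactors = FALSE)
  for (p in pops) {
    tab[[p]] <- vapply(uk, function(k) sum(key == k & m$pop_labels == p),
                       integer(1))
  }
  occ <- as.matrix(tab[, pops, drop = FALSE]) > 0
  tab$shared <- rowSums(occ) > 1
  tab$core_allele <- vapply(uk, function(k)
    m$alleles[match(k, key), core], integer(1))
  n_specific <- vapply(pops, function(p)
    sum(occ[, p] & !tab$shared), integer(1))
  core_frac <- vapply(pops, function(p) {
    idx <- occ[, p] & !tab$shared
    if (!any(idx)) return(NA_real_)
    mean(tab$core_allele[idx] == 1)
  }, numeric(1))
  list(table = tab, n_distinct = length(uk),
       n_specific = n_specific, n_shared = sum(tab$shared),
       core_fraction_specific = core_frac)
}

#' Ancient-sample per-site genotype record(s)
#'
#' @param position bp position.
#' @param alleles character vector of the two alleles (e.g. c("T", "C")).
#' @param depth total read depth.
#' @param allele_depths length-2 read depths per allele (sum <= depth).
#' @param genotype_quality,mapping_quality,base_quality phred-style
#'   qualities (>= 0).
#' @param in_1kgp is the site in the reference SNP panel?
#' @return list of class `ancient_site_record`.
#' @export
ancient_site_record <- function(position, alleles, depth, allele_depths,
                                genotype_quality, mapping_quality = 60,
                                base_quality = 30, in_1kgp = TRUE) {
  stopifnot(length(allele_depths) == 2, depth >= sum(allele_depths),
            genotype_quality >= 0, mapping_quality >= 0, base_quality >= 0)
  structure(list(position = position, alleles = alleles, depth = depth,
                 allele_depths = allele_depths,
                 genotype_quality = genotype_quality,
                 mapping_quality = mapping_quality,
                 base_quality = base_quality, in_1kgp = in_1kgp),
            class = "ancient_site_record")
}

#' Site-filter policy for an ancient sample
#'
#' Preset policies mirror the study's published thresholds:
#' \itemize{
#'   \item `IK002`: drop MQ < 20 or BQ < 10; keep depth > 2 and GQ > 1;
#'     consensus-haploid.
#'   \item `FUN23` (high coverage): keep GQ > 30 and depth > 30; diploid.
#'   \item `FUN5` (low coverage): keep GQ > 20; consensus-haploid.
#' }
#' All policies restrict to sites present in the reference SNP panel.
#'
#' @param sample one of "IK002", "FUN23", "FUN5", or "custom".
#' @param min_mq,min_bq,min_depth,min_gq thresholds (exclusive bounds: a
#'   record passes when quality >= min_mq etc. as encoded below); only
#'   needed for "custom".
#' @param ploidy "diploid" or "consensus-haploid".
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(sample = c("IK002", "FUN23", "FUN5", "custom"),
                          min_mq = 0, min_bq = 0, min_depth = 0,
                          min_gq = 0, ploidy = "consensus-haploid") {
  sample <- match.arg(sample)
  pol <- switch(sample,
    IK002 = list(min_mq = 20, min_bq = 10, min_depth = 3, min_gq = 2,
                 ploidy = "consensus-haploid"),
    FUN23 = list(min_mq = 0, min_bq = 0, min_depth = 31, min_gq = 31,
                 ploidy = "diploid"),
    FUN5 = list(min_mq = 0, min_bq = 0, min_depth = 0, min_gq = 21,
                ploidy = "consensus-haploid"),
    custom = list(min_mq = min_mq, min_bq = min_bq, min_depth = min_depth,
                  min_gq = min_gq, ploidy = ploidy))
  stopifnot(pol$min_mq >= 0, pol$min_bq >= 0, pol$min_depth >= 0,
            pol$min_gq >= 0)
  structure(c(list(sample = sample), pol), class = "filter_policy")
}

#' Apply a site-filter policy to ancient records
#'
#' Rules (thresholds from [filter_policy()]): a site is rejected with a
#' machine-readable reason when it is absent from the reference panel,
#' its mapping quality or base quality falls below the policy minimum, or
#' its depth / genotype quality does. The paper's strict inequalities
#' (e.g. "depth > 2", "GQ > 30") are encoded as inclusive minima of
#' threshold + 1.
#'
#' @param records list of [ancient_site_record()] objects.
#' @param policy a [filter_policy()].
#' @return list `kept` (records), `rejected` (data.frame `position`,
#'   `reason`).
#' @export
filter_ancient_sites <- function(records, policy) {
  stopifnot(inherits(policy, "filter_policy"))
  reasons <- character(0); pos <- numeric(0)
  kept <- list()
  for (rec in records) {
    stopifnot(inherits(rec, "ancient_site_record"))
    reason <- NULL
    if (!rec$in_1kgp) reason <- "not-in-reference-panel"
    else if (rec$mapping_quality < policy$min_mq) reason <- "mapping-quality"
    else if (rec$base_quality < policy$min_bq) reason <- "base-quality"
    else if (rec$depth < policy$min_depth) reason <- "depth"
    else if (rec$genotype_quality < policy$min_gq) reason <- "genotype-quality"
    if (is.null(reason)) {
      kept <- c(kept, list(rec))
    } else {
      reasons <- c(reasons, reason); pos <- c(pos, rec$position)
    }
  }
  list(kept = kept,
       rejected = data.frame(position = pos, reason = reasons))
}

#' Consensus haploidization of a biallelic record
#'
#' Returns the allele with the deeper coverage; equal depths (or zero
#' total depth) yield a missing call (`NA`) so the output is
#' deterministic.
#'
#' @param record an [ancient_site_record()] passing filters.
#' @return single allele (character) or `NA_character_`.
#' @export
consensus_haploidize <- function(record) {
  stopifnot(inherits(record, "ancient_site_record"))
  ad <- record$allele_depths
  if (sum(ad) == 0 || ad[1] == ad[2]) return(NA_character_)
  record$alleles[which.max(ad)]
}

#' Remove singletons unique to the ancient samples
#'
#' Under the infinite-sites assumption, a derived allele observed in
#' exactly one ancient sample and in no haplotype of the modern panel is
#' treated as post-mortem damage or sequencing error and removed (set to
#' the ancestral state) from all ancient sequences.
#'
#' @param ancient_calls matrix or data.frame (samples x sites) of 0/1
#'   derived-allele calls aligned to the panel's sites (NA = missing).
#' @param panel a [haplotype_matrix()] with the same site columns.
#' @return list `calls` (cleaned matrix), `removed_sites` (column
#'   indices).
#' @export
remove_ancient_singletons <- function(ancient_calls, panel) {
  calls <- as.matrix(ancient_calls)
  if (ncol(calls) != n_site(panel)) {
    stop("ancient calls are not aligned to the panel sites")
  }
  anc_derived <- colSums(calls == 1, na.rm = TRUE)
  panel_derived <- colSums(panel$alleles)
  drop <- which(anc_derived == 1 & panel_derived == 0)
  if (length(drop)) calls[, drop][calls[, drop] == 1] <- 0L
  list(calls = calls, removed_sites = drop)
}
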