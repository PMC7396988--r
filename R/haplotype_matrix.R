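#' Phased haplotype matrix
#'
#' The substrate of every statistic in the package: a binary matrix of
#' phased haplotypes (rows) by biallelic sites (columns), coded 0 for the
#' ancestral and 1 for the derived allele, together with physical positions,
#' site identifiers and a population label per haplotype.
#'
#' Invariants enforced at construction: no missing entries, strictly
#' increasing positions, one population label per haplotype, all entries in
#' \{0, 1\}.
#'
#' @param alleles integer or logical matrix, haplotypes x sites; 0 =
#'   ancestral, 1 = derived.
#' @param positions integer vector of 1-based physical coordinates (bp),
#'   strictly increasing, one per site.
#' @param site_ids character vector of site identifiers (e.g. rsIDs);
#'   defaults to `"s<position>"`.
#' @param pop_labels character vector, one population tag per haplotype;
#'   defaults to `"pop1"`.
#' @param chrom single chromosome name.
#' @return An object of class `haplotype_matrix`.
#' @examples
#' m <- haplotype_matrix(rbind(c(0, 1), c(1, 1)), positions = c(100, 200))
#' n_hap(m)
#' @export
haplotype_matrix <- function(alleles, positions, site_ids = NULL,
                             pop_labels = NULL, chrom = "1") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (anyNA(alleles)) stop("haplotype matrix must not contain missing entries")
  if (!all(alleles %in% c(0L, 1L))) {
    stop("haplotype matrix entries must be 0 (ancestral) or 1 (derived)")
  }
  positions <- as.numeric(positions)
  if (length(positions) != ncol(alleles)) {
    stop("need one position per site")
  }
  if (ncol(alleles) > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (is.null(site_ids)) {
    site_ids <- if (length(positions)) {
      paste0("s", format(positions, scientific = FALSE, trim = TRUE))
    } else character(0)
  }
  site_ids <- as.character(site_ids)
  if (length(site_ids) != ncol(alleles)) stop("need one site_id per site")
  if (is.null(pop_labels)) pop_labels <- rep("pop1", nrow(alleles))
  pop_labels <- as.character(pop_labels)
  if (length(pop_labels) != nrow(alleles)) stop("need one pop label per haplotype")
  structure(
    list(alleles = alleles, positions = positions, site_ids = site_ids,
         pop_labels = pop_labels, chrom = as.character(chrom)[1]),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf(
    "haplotype_matrix: %d haplotypes x %d sites on chr%s (%s-%s)\n",
    nrow(x$alleles), ncol(x$alleles), x$chrom,
    format(min(x$positions), big.mark = ","),
    format(max(x$positions), big.mark = ",")))
  tab <- table(x$pop_labels)
  cat("populations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of haplotypes / sites
#' @param m a [haplotype_matrix()].
#' @return integer count.
#' @export
n_hap <- function(m) nrow(m$alleles)

#' @rdname n_hap
#' @export
n_site <- function(m) ncol(m$alleles)

#' Subset a haplotype matrix
#'
#' @param x a [haplotype_matrix()].
#' @param i haplotype (row) index; missing keeps all.
#' @param j site (column) index; missing keeps all.
#' @param ... ignored.
#' @return A `haplotype_matrix` restricted to the selected haplotypes/sites.
#' @export
`[.haplotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$alleles))
  if (missing(j)) j <- seq_len(ncol(x$alleles))
  haplotype_matrix(x$alleles[i, j, drop = FALSE], x$positions[j],
                   x$site_ids[j], x$pop_labels[i], x$chrom)
}

#' Locate a site by id or position
#' @param m a [haplotype_matrix()].
#' @param site a site id (character) or physical position (numeric).
#' @return column index of the site.
#' @export
site_index <- function(m, site) {
  if (is.character(site)) {
    idx <- match(site, m$site_ids)
  } else {
    idx <- match(as.numeric(site), m$positions)
  }
  if (is.na(idx)) stop("site not found: ", site)
  idx
}

#' Derived-allele frequencies per site
#' @param m a [haplotype_matrix()].
#' @return numeric vector of derived-allele frequencies.
#' @export
derived_freq <- function(m) colMeans(m$alleles)

#' Minor-allele frequencies per site
#' @param m a [haplotype_matrix()].
#' @return numeric vector, `pmin(p, 1 - p)` of the derived frequency.
#' @export
maf <- function(m) {
  p <- derived_freq(m)
  pmin(p, 1 - p)
}

#' Restrict to sites within a physical region
#' @param m a [haplotype_matrix()].
#' @param start,end inclusive bp bounds; `NULL` keeps that side open.
#' @return A `haplotype_matrix` restricted to the region's sites.
#' @export
restrict_region <- function(m, start = NULL, end = NULL) {
  keep <- rep(TRUE, n_site(m))
  if (!is.null(start)) keep <- keep & m$positions >= start
  if (!is.null(end)) keep <- keep & m$positions <= end
  if (!any(keep)) stop("no sites within region")
  m[, which(keep)]
}

#' Per-site derived-allele count summary
#'
#' Represents the allele-frequency evidence at one site: derived count,
#' haplotype sample size and frequency.
#'
#' @param derived_count number of haplotypes carrying the derived allele.
#' @param n haplotype sample size (>= 2).
#' @return list with `derived_count`, `n`, `freq`, class `site_freq`.
#' @examples
#' site_freq(131, 208)$freq
#' @export
site_freq <- function(derived_count, n) {
  n <- as.numeric(n)
  derived_count <- as.numeric(derived_count)
  if (any(n < 2)) stop("invalid sample size: n must be >= 2")
  if (any(derived_count < 0 | derived_count > n)) {
    stop("derived_count must be in [0, n]")
  }
  structure(list(derived_count = derived_count, n = n,
                 freq = derived_count / n), class = "site_freq")
}
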