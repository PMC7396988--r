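## Minimal VCF 4.2 serialization for phased biallelic haplotype panels.
## A purpose-built subset reader/writer is used here (rather than a
## heavyweight VCF stack) so that CLI and tests start instantly; the
## reader enforces the ingest policies: multi-allelic records, indels,
## records without an ancestral-allele (AA) annotation and unphased or
## missing genotypes are dropped with a warning.

#' Write a haplotype matrix as VCF
#'
#' Emits a VCF 4.2 file with phased GT fields and an INFO/AA ancestral
#' allele annotation; haplotypes are paired into pseudo-diploid samples
#' (an odd haplotype count adds a final haploid sample). REF is the
#' ancestral allele ("A"), ALT the derived ("G") unless allele labels are
#' supplied.
#'
#' @param m a [haplotype_matrix()].
#' @param path output file path.
#' @param ref,alt allele labels (defaults "A"/"G").
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path, ref = "A", alt = "G") {
  n <- n_hap(m)
  n_dip <- n %/% 2
  odd <- n %% 2 == 1
  sample_names <- c(if (n_dip) paste0("S", seq_len(n_dip)),
                    if (odd) "Shap")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  gt_rows <- vapply(seq_len(n_site(m)), function(s) {
    a <- m$alleles[, s]
    gts <- character(0)
    if (n_dip) {
      gts <- paste(a[seq(1, 2 * n_dip, by = 2)],
                   a[seq(2, 2 * n_dip, by = 2)], sep = "|")
    }
    if (odd) gts <- c(gts, as.character(a[n]))
    paste(gts, collapse = "\t")
  }, character(1))
  body <- paste(m$chrom, format(m$positions, scientific = FALSE, trim = TRUE),
                m$site_ids, ref, alt, ".", "PASS",
                paste0("AA=", ref), "GT", gt_rows, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype matrix
#'
#' Parses the subset of VCF 4.2 emitted by [write_vcf()] (and 1KGP-style
#' phased panels): biallelic SNV records with phased GT and an INFO/AA
#' ancestral-allele annotation. Records that are multi-allelic, indels,
#' lack a usable AA, or contain unphased/missing genotypes are dropped
#' with one summary warning. Alleles are polarized so 1 = derived.
#'
#' @param path VCF file path (uncompressed text).
#' @param panel optional data.frame (`sample_id`, `pop`) assigning a
#'   population to each VCF sample; haplotypes inherit their sample's
#'   label.
#' @return a [haplotype_matrix()].
#' @export
read_vcf <- function(path, panel = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("malformed VCF: missing #CHROM header line")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  if (length(cols) < 10) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  data_lines <- lines[seq.int(hdr + 1, length(lines))]
  data_lines <- data_lines[nzchar(data_lines)]
  dropped <- c(multiallelic = 0L, indel = 0L, no_aa = 0L, badgt = 0L)
  pos <- numeric(0); ids <- character(0); rows <- list()
  chrom <- NA_character_
  for (ln in seq_along(data_lines)) {
    f <- strsplit(data_lines[ln], "\t")[[1]]
    if (length(f) != length(cols)) {
      stop(sprintf("malformed VCF record at data line %d: %d fields, expected %d",
                   ln, length(f), length(cols)))
    }
    ref <- f[4]; alt <- f[5]
    if (grepl(",", alt)) { dropped["multiallelic"] <- dropped["multiallelic"] + 1L; next }
    if (nchar(ref) != 1 || nchar(alt) != 1) { dropped["indel"] <- dropped["indel"] + 1L; next }
    aa <- sub(".*AA=([^;]*).*", "\\1", f[8])
    aa <- toupper(aa)
    if (identical(aa, toupper(f[8])) && !grepl("AA=", f[8])) aa <- ""
    if (!aa %in% c(toupper(ref), toupper(alt))) { dropped["no_aa"] <- dropped["no_aa"] + 1L; next }
    gt_field <- match("GT", strsplit(f[9], ":")[[1]])
    gts <- vapply(f[-(1:9)], function(x) strsplit(x, ":")[[1]][gt_field],
                  character(1), USE.NAMES = FALSE)
    if (any(grepl("/", gts)) || any(grepl("\\.", gts))) {
      dropped["badgt"] <- dropped["badgt"] + 1L; next
    }
    al <- as.integer(unlist(strsplit(gts, "|", fixed = TRUE)))
    if (anyNA(al) || any(al > 1)) { dropped["badgt"] <- dropped["badgt"] + 1L; next }
    if (aa == toupper(alt)) al <- 1L - al   # polarize: 1 = derived
    chrom <- f[1]
    pos <- c(pos, as.numeric(f[2])); ids <- c(ids, f[3])
    rows <- c(rows, list(al))
  }
  if (any(dropped > 0)) {
    msg <- paste(sprintf("%s=%d", names(dropped)[dropped > 0],
                         dropped[dropped > 0]), collapse = ", ")
    warning("dropped records at ingest: ", msg)
  }
  if (!length(rows)) stop("no usable records in VCF")
  A <- do.call(cbind, rows)
  ## haplotypes per sample: infer from the first record's GT arity
  n_hap_per <- lengths(strsplit(
    vapply(strsplit(data_lines[1], "\t")[[1]][-(1:9)],
           function(x) strsplit(x, ":")[[1]][1], character(1)),
    "|", fixed = TRUE))
  hap_sample <- rep(samples, times = n_hap_per)
  pop <- rep("pop1", length(hap_sample))
  if (!is.null(panel)) {
    idx <- match(hap_sample, panel$sample_id)
    if (anyNA(idx)) stop("panel is missing samples: ",
                         paste(unique(hap_sample[is.na(idx)]), collapse = ", "))
    pop <- panel$pop[idx]
  }
  ord <- order(pos)
  haplotype_matrix(A[, ord, drop = FALSE], pos[ord], ids[ord], pop, chrom)
}
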