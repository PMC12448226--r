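#' Percentage share of one chromosome among significant loci
#'
#' @param counts named vector (or table) of per-chromosome significant-locus
#'   counts.
#' @param chrom chromosome of interest.
#' @param digits decimals in the percentage (default 1, matching the
#'   reporting style for chromosome shares).
#' @return 100 * counts[chrom] / sum(counts), rounded; 0 when the total is 0.
#' @export
chromosome_share <- function(counts, chrom, digits = 1L) {
  cnt <- as.numeric(counts)
  names(cnt) <- names(counts)
  total <- sum(cnt)
  if (total == 0) return(round(0, digits))
  val <- if (chrom %in% names(cnt)) cnt[[chrom]] else 0
  round(100 * val / total, digits)
}

#' Overlap of significant-locus sets between two transects
#'
#' Loci are keyed by (chrom, pos); percentages are each transect's share of
#' shared outliers, rounded to the nearest integer.
#'
#' @param setA,setB data.frames with columns chrom, pos.
#' @return list(n_shared, pctA, pctB).
#' @export
overlap_between_transects <- function(setA, setB) {
  ka <- unique(locus_key(setA$chrom, setA$pos))
  kb <- unique(locus_key(setB$chrom, setB$pos))
  shared <- length(intersect(ka, kb))
  list(n_shared = shared,
       pctA = if (length(ka)) round(100 * shared / length(ka)) else 0,
       pctB = if (length(kb)) round(100 * shared / length(kb)) else 0)
}

#' Match outlier loci to gene models with flanked intervals
#'
#' A locus hits a gene when its position falls inside the gene's flanked
#' search interval (1-based inclusive) on the same chromosome.
#'
#' @param loci data.frame with chrom, pos.
#' @param genes data.frame from [read_gff_genes()] (gene_id, chrom,
#'   search_start, search_end).
#' @return sorted unique gene ids hit.
#' @export
match_genes <- function(loci, genes) {
  hits <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    any(loci$chrom == genes$chrom[i] &
          loci$pos >= genes$search_start[i] &
          loci$pos <= genes$search_end[i])
  }))
  sort(unique(genes$gene_id[hits]))
}

#' Cross-transect gene-set overlap
#'
#' @param genesA,genesB character vectors of gene ids with restricted
#'   introgression in each transect.
#' @return list(n_a, n_b, n_shared, n_unique): unique = union minus shared.
#' @export
gene_overlap <- function(genesA, genesB) {
  a <- unique(genesA); b <- unique(genesB)
  shared <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_shared = shared,
       n_unique = length(union(a, b)) - shared)
}

#' Percentage of outlier loci inside a genomic region
#'
#' @param loci data.frame with chrom, pos.
#' @param chrom,start,end region (1-based inclusive).
#' @return integer-rounded percentage.
#' @export
region_share <- function(loci, chrom, start, end) {
  if (!nrow(loci)) return(0)
  inside <- loci$chrom == chrom & loci$pos >= start & loci$pos <= end
  round(100 * sum(inside) / nrow(loci))
}

#' Per-transect introgression report
#'
#' Assembles the reporting arithmetic for one transect's genomic-cline fits:
#' outlier counts, per-chromosome shares, steepness summaries and gene hits.
#'
#' @param fits data.frame from [fit_genomic_clines()].
#' @param genes optional data.frame from [read_gff_genes()].
#' @param transect transect name.
#' @return list of class `transect_report`.
#' @export
transect_report <- function(fits, genes = NULL, transect = "transect") {
  s <- summarize_steepness(fits)
  sig <- fits[fits$significant, , drop = FALSE]
  shares <- if (nrow(sig)) {
    counts <- table(sig$chrom)
    sapply(names(counts), function(ch) chromosome_share(counts, ch))
  } else numeric(0)
  hits <- if (!is.null(genes) && nrow(sig)) match_genes(sig, genes) else character(0)
  out <- list(transect = transect, n_tested = s$n_tested,
              n_significant = s$n_significant,
              per_chrom = s$per_chrom, chrom_shares = shares,
              n_v_gt_10 = s$n_v_gt_10, mean_v = s$mean_v_significant,
              gene_hits = hits)
  class(out) <- "transect_report"
  out
}

#' @export
print.inversion_call <- function(x, ...) {
  cat(sprintf("inversion_call: %s:%d-%d (%.1f Mb), groups: %s\n",
              x$chrom, x$start_bp, x$end_bp, x$length_mb,
              paste(names(table(x$haplotype_groups)),
                    table(x$haplotype_groups), sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
print.transect_report <- function(x, ...) {
  cat(sprintf("transect_report '%s': %d/%d significant, mean v %.2f, %d with v > 10\n",
              x$transect, x$n_significant, x$n_tested,
              ifelse(is.na(x$mean_v), NA, x$mean_v), x$n_v_gt_10))
  invisible(x)
}
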