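#' PCA on a genotype matrix
#'
#' Optionally thins loci to one per window, imputes missing genotypes by the
#' locus mean, mean-centres each locus and eigendecomposes the sample
#' covariance of the centred genotypes.
#'
#' @param gm a [genotype_matrix()].
#' @param thin_bp thinning window (0 disables thinning; default 10 kb).
#' @param k number of principal coordinates to return.
#' @return list of class `pca_result`: coords (samples x k), explained
#'   (variance fractions), samples.
#' @export
pca_genotypes <- function(gm, thin_bp = 10000L, k = 10L) {
  if (length(gm$samples) < 2) stop("PCA needs at least 2 samples")
  if (thin_bp > 0) gm <- thin_by_window(gm, thin_bp)
  X <- gm$counts
  all_miss <- colSums(!is.na(X)) == 0
  if (any(all_miss)) {
    warning(sprintf("%d all-missing locus(i) dropped before PCA", sum(all_miss)))
    X <- X[, !all_miss, drop = FALSE]
  }
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  Xc <- sweep(X, 2, colMeans(X))
  pc <- stats::prcomp(Xc, center = FALSE)
  k <- min(k, ncol(pc$x))
  ev <- pc$sdev^2
  out <- list(coords = pc$x[, seq_len(k), drop = FALSE],
              explained = ev / sum(ev), samples = gm$samples)
  class(out) <- "pca_result"
  out
}

# per-locus Weir & Cockerham (1984) two-population variance components from
# diploid entries; haploid (hemizygous) entries are excluded
wc_components <- function(cA, cB, plA, plB) {
  comp1 <- function(cnt, pl) {
    dip <- !is.na(cnt) & !is.na(pl) & pl == 2L
    n <- colSums(dip)
    p <- ifelse(n > 0, colSums(cnt * dip, na.rm = TRUE) / (2 * n), NA)
    hobs <- ifelse(n > 0, colSums((cnt == 1L) & dip, na.rm = TRUE) / n, NA)
    list(n = n, p = p, h = hobs)
  }
  A <- comp1(cA, plA); B <- comp1(cB, plB)
  r <- 2
  nbar <- (A$n + B$n) / 2
  ok <- A$n >= 2 & B$n >= 2
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  mono <- pbar %in% c(0, 1)
  a[!ok | mono] <- NA; b[!ok | mono] <- NA; cc[!ok | mono] <- NA
  list(a = a, b = b, c = cc)
}

#' Per-SNP Weir and Cockerham F_ST between two populations
#'
#' The 1984 theta-hat from variance components a, b, c for two populations
#' of diploids; may be negative. Missing genotypes are excluded from sample
#' sizes; hemizygous (ploidy 1) entries are excluded. Loci monomorphic
#' across both populations are undefined (NA), not zero.
#'
#' @param gm a [genotype_matrix()].
#' @param samplesA,samplesB sample ids of the two populations.
#' @param components also return the a, b, c components.
#' @return data.frame: chrom, pos, fst (and a, b, c when requested).
#' @export
wc_fst_snp <- function(gm, samplesA, samplesB, components = FALSE) {
  ia <- match(samplesA, gm$samples); ib <- match(samplesB, gm$samples)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id")
  comp <- wc_components(gm$counts[ia, , drop = FALSE],
                        gm$counts[ib, , drop = FALSE],
                        gm$ploidy[ia, , drop = FALSE],
                        gm$ploidy[ib, , drop = FALSE])
  fst <- comp$a / (comp$a + comp$b + comp$c)
  out <- data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos, fst = fst,
                    stringsAsFactors = FALSE)
  if (components) {
    out$a <- comp$a; out$b <- comp$b; out$c <- comp$c
  }
  out
}

#' Windowed Weir-Cockerham F_ST (ratio of sums)
#'
#' Sliding windows of `window` bp advancing by `step` bp, anchored at
#' position `anchor` (default 1); only windows lying fully inside the
#' chromosome are emitted. The window estimate is the sum of per-SNP a
#' components divided by the sum of (a + b + c) — a ratio of sums, not a
#' mean of per-SNP ratios.
#'
#' @param gm a [genotype_matrix()].
#' @param samplesA,samplesB the two populations.
#' @param window,step window and step sizes in bp (defaults 25 kb / 5 kb).
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the last SNP position per chromosome.
#' @param anchor start of the first window.
#' @return data.frame: chrom, start, end, n_snps, fst (NA where n_snps = 0).
#' @export
wc_fst_windowed <- function(gm, samplesA, samplesB, window = 25000L,
                            step = 5000L, chrom_lengths = NULL, anchor = 1L) {
  snp <- wc_fst_snp(gm, samplesA, samplesB, components = TRUE)
  chroms <- unique(snp$chrom)
  out <- lapply(chroms, function(ch) {
    rows <- snp[snp$chrom == ch, ]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else max(rows$pos)
    starts <- seq(anchor, len - window + 1L, by = step)
    if (!length(starts)) return(NULL)
    res <- lapply(starts, function(s) {
      inw <- rows$pos >= s & rows$pos <= s + window - 1L
      hasab <- inw & !is.na(rows$a)
      n <- sum(inw)
      denom <- sum(rows$a[hasab] + rows$b[hasab] + rows$c[hasab])
      fst <- if (n == 0 || !any(hasab) || denom == 0) NA_real_ else
        sum(rows$a[hasab]) / denom
      data.frame(chrom = ch, start = s, end = s + window - 1L,
                 n_snps = n, fst = fst, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-individual inbreeding coefficient F
#'
#' Method-of-moments F_IS per individual:
#' `F = (O_hom - E_hom) / (L_used - E_hom)` where, over the individual's
#' non-missing diploid loci, `E_hom = sum_l (1 - 2 p_l (1 - p_l) n_l / (n_l - 1))`
#' with p_l the sample allele frequency and n_l the number of diploid
#' individuals with data at locus l. Strongly negative for inversion
#' heterozygotes over the inverted region.
#'
#' @param gm a [genotype_matrix()].
#' @param loci optional logical/integer subset of loci.
#' @return named numeric vector per sample.
#' @export
individual_inbreeding_F <- function(gm, loci = NULL) {
  if (!is.null(loci)) gm <- gm_subset(gm, loci = loci)
  cnt <- gm$counts
  dip <- !is.na(cnt) & gm$ploidy == 2L
  nl <- colSums(dip)
  p <- ifelse(nl > 0, colSums(cnt * dip, na.rm = TRUE) / (2 * nl), NA)
  ehom_l <- ifelse(nl >= 2, 1 - 2 * p * (1 - p) * nl / (nl - 1), NA)
  usable <- !is.na(ehom_l)
  use <- dip[, usable, drop = FALSE]
  eh <- use %*% ehom_l[usable]
  ohom <- rowSums((cnt[, usable, drop = FALSE] != 1L) & use, na.rm = TRUE)
  lused <- rowSums(use)
  f <- as.vector((ohom - eh) / (lused - eh))
  names(f) <- gm$samples
  f
}

#' Least-admixed sample filter
#'
#' Keeps samples with hybrid index < `h_lo` or > `h_hi` and interspecific
#' heterozygosity below `het_max` — the filter used to pick near-parental
#' individuals for windowed differentiation scans.
#'
#' @param h hybrid indices (named or plain vector).
#' @param het interspecific heterozygosity, aligned with `h`.
#' @param h_lo,h_hi,het_max thresholds (defaults 0.1, 0.9, 0.1).
#' @return list(p0_side, p1_side): indices of the retained samples.
#' @export
select_least_admixed <- function(h, het, h_lo = 0.1, h_hi = 0.9,
                                 het_max = 0.1) {
  stopifnot(length(h) == length(het))
  list(p0_side = which(h < h_lo & het < het_max),
       p1_side = which(h > h_hi & het < het_max))
}

#' Assign mitotypes by nearest reference-clade centroid in PCA space
#'
#' PCA on the mtDNA variants; each sample is assigned the clade of the
#' nearest centroid of the allopatric reference samples in the top-2 PC
#' plane. Exact ties break deterministically toward the earlier clade in
#' `ref_clades` order and are flagged.
#'
#' @param mt_gm [genotype_matrix()] of mtDNA variants (haploid).
#' @param ref_clades named list: clade label -> reference sample ids.
#' @return data.frame: sample, mitotype, tied.
#' @export
assign_mitotype <- function(mt_gm, ref_clades) {
  pc <- pca_genotypes(mt_gm, thin_bp = 0, k = 2)
  co <- pc$coords
  if (ncol(co) < 2) co <- cbind(co, 0)
  cent <- t(vapply(ref_clades, function(ids) {
    colMeans(co[match(ids, pc$samples), , drop = FALSE])
  }, numeric(2)))
  d2 <- outer(seq_len(nrow(co)), seq_len(nrow(cent)),
              Vectorize(function(i, j) sum((co[i, ] - cent[j, ])^2)))
  best <- apply(d2, 1, which.min)
  tied <- apply(d2, 1, function(r) sum(r == min(r)) > 1)
  data.frame(sample = pc$samples,
             mitotype = names(ref_clades)[best],
             tied = tied, stringsAsFactors = FALSE)
}
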