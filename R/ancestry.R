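#' Select species-diagnostic loci from two parental reference panels
#'
#' Retains loci at which every observed allele copy in panel A carries one
#' allele and every observed copy in panel B the other (per-SNP F_ST = 1
#' after missing-data exclusion), then thins to at most one locus per
#' `thin_bp` window to reduce physical linkage. The allele fixed in panel B
#' is recorded as the P1-derived allele.
#'
#' @param gmA,gmB [genotype_matrix()] objects for the two allopatric panels,
#'   over identical or overlapping locus sets.
#' @param thin_bp thinning window in bp (default 10 kb).
#' @return data.frame of class `diagnostic_panel` with columns chrom, pos,
#'   ref, alt, p1_allele ("ref" or "alt").
#' @export
select_diagnostic <- function(gmA, gmB, thin_bp = 10000L) {
  keyA <- locus_key(gmA$loci$chrom, gmA$loci$pos)
  keyB <- locus_key(gmB$loci$chrom, gmB$loci$pos)
  shared <- intersect(keyA, keyB)
  if (!length(shared)) stop("panels share no loci")
  ia <- match(shared, keyA); ib <- match(shared, keyB)
  altA <- colSums(gmA$counts[, ia, drop = FALSE], na.rm = TRUE)
  nA <- colSums(gmA$ploidy[, ia, drop = FALSE] *
                  !is.na(gmA$counts[, ia, drop = FALSE]), na.rm = TRUE)
  altB <- colSums(gmB$counts[, ib, drop = FALSE], na.rm = TRUE)
  nB <- colSums(gmB$ploidy[, ib, drop = FALSE] *
                  !is.na(gmB$counts[, ib, drop = FALSE]), na.rm = TRUE)
  fixed_alt_B <- nA > 0 & nB > 0 & altA == 0 & altB == nB
  fixed_alt_A <- nA > 0 & nB > 0 & altA == nA & altB == 0
  keep <- fixed_alt_A | fixed_alt_B
  if (!any(keep)) {
    stop("no diagnostic loci found; larger or less admixed reference panels needed")
  }
  loci <- gmA$loci[ia[keep], , drop = FALSE]
  p1 <- ifelse(fixed_alt_B[keep], "alt", "ref")
  ord <- order(match(loci$chrom, unique(gmA$loci$chrom)), loci$pos)
  loci <- loci[ord, , drop = FALSE]
  p1 <- p1[ord]
  # thin via the shared window rule
  gm_thin <- thin_by_window(
    genotype_matrix(matrix(0L, 1, nrow(loci)), loci, "x"), thin_bp)
  keep2 <- locus_key(loci$chrom, loci$pos) %in%
    locus_key(gm_thin$loci$chrom, gm_thin$loci$pos)
  panel <- data.frame(loci[keep2, c("chrom", "pos", "ref", "alt")],
                      p1_allele = p1[keep2], stringsAsFactors = FALSE)
  rownames(panel) <- NULL
  class(panel) <- c("diagnostic_panel", "data.frame")
  panel
}

#' P1-allele copy counts at panel loci
#'
#' Orients genotype counts to the P1-derived allele at each panel locus.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a panel from [select_diagnostic()].
#' @return list(counts, ploidy): samples x panel-loci matrices of P1-allele
#'   copy counts and allele copies with data.
#' @export
p1_counts <- function(gm, panel) {
  idx <- match(locus_key(panel$chrom, panel$pos),
               locus_key(gm$loci$chrom, gm$loci$pos))
  if (anyNA(idx)) stop("panel loci missing from genotype matrix")
  cnt <- gm$counts[, idx, drop = FALSE]
  pl <- gm$ploidy[, idx, drop = FALSE]
  flip <- panel$p1_allele == "ref"
  if (any(flip)) {
    cnt[, flip] <- pl[, flip] - cnt[, flip]
  }
  pl[is.na(cnt)] <- NA_integer_
  list(counts = cnt, ploidy = pl)
}

#' Bayesian hybrid-index estimation
#'
#' Estimates each sample's hybrid index h (the proportion of its diagnostic
#' allele copies derived from P1) by random-walk Metropolis on logit(h).
#' Each non-missing allele copy is the P1 allele independently with
#' probability h; the prior is Beta(a, b) (Jeffreys by default). Hemizygous
#' Z entries of females contribute a single allele copy. The proposal step
#' adapts during burn-in toward a 20-50% acceptance rate.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a `diagnostic_panel`.
#' @param burn,keep MCMC burn-in and retained iterations (defaults 5,000 and
#'   10,000).
#' @param seed RNG seed.
#' @param prior Beta prior shape parameters c(a, b).
#' @param keep_draws return the retained draws matrix (keep x samples).
#' @return data.frame of class `hybrid_index_posterior`: sample, h_mean,
#'   h_lo, h_hi (central 95% credible interval), n_copies_used, flagged
#'   (TRUE when a sample had no data and the posterior equals the prior).
#'   Draws are attached as attribute "draws" when requested.
#' @export
estimate_hybrid_index <- function(gm, panel, burn = 5000L, keep = 10000L,
                                  seed = NULL, prior = c(0.5, 0.5),
                                  keep_draws = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  pc <- p1_counts(gm, panel)
  k <- rowSums(pc$counts, na.rm = TRUE)
  n <- rowSums(pc$ploidy, na.rm = TRUE)
  ns <- length(k)
  a <- prior[1]; b <- prior[2]
  # log posterior of theta = logit(h), including the Jacobian h(1-h)
  lp <- function(theta) {
    h <- expit(theta)
    (k + a) * log(h) + (n - k + b) * log1p(-h)
  }
  theta <- rep(0, ns)
  cur <- lp(theta)
  step <- rep(1, ns)
  acc_win <- rep(0, ns)
  total <- burn + keep
  adapt_every <- 50L
  all_h <- matrix(NA_real_, keep, ns)
  for (it in seq_len(total)) {
    prop <- theta + stats::rnorm(ns, 0, step)
    new <- lp(prop)
    acc <- log(stats::runif(ns)) < new - cur
    theta[acc] <- prop[acc]
    cur[acc] <- new[acc]
    if (it <= burn) {
      acc_win <- acc_win + acc
      if (it %% adapt_every == 0) {
        rate <- acc_win / adapt_every
        step[rate < 0.2] <- step[rate < 0.2] * 0.7
        step[rate > 0.5] <- step[rate > 0.5] * 1.4
        acc_win[] <- 0
      }
    } else {
      all_h[it - burn, ] <- expit(theta)
    }
  }
  hm <- colMeans(all_h)
  ci <- apply(all_h, 2, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(sample = gm$samples, h_mean = hm,
                    h_lo = ci[1, ], h_hi = ci[2, ],
                    n_copies_used = n, flagged = n == 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (any(out$flagged)) {
    warning(sprintf("%d sample(s) with no diagnostic data: posterior equals the prior",
                    sum(out$flagged)))
  }
  if (keep_draws) {
    colnames(all_h) <- gm$samples
    attr(out, "draws") <- all_h
  }
  class(out) <- c("hybrid_index_posterior", "data.frame")
  out
}

#' Interspecific heterozygosity
#'
#' Fraction of an individual's non-missing diploid diagnostic loci at which
#' it carries one allele from each parental species (genotype count 1).
#' Hemizygous Z entries of females are excluded. An F1 hybrid has
#' heterozygosity 1; pure parentals have 0.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a `diagnostic_panel`.
#' @return named numeric vector per sample; NA (with a warning) for samples
#'   with no diploid diagnostic data.
#' @export
interspecific_heterozygosity <- function(gm, panel) {
  pc <- p1_counts(gm, panel)
  use <- !is.na(pc$counts) & pc$ploidy == 2L
  nhet <- rowSums(pc$counts == 1L & use, na.rm = TRUE)
  nuse <- rowSums(use)
  het <- ifelse(nuse > 0, nhet / nuse, NA_real_)
  names(het) <- gm$samples
  if (anyNA(het)) {
    warning(sprintf("%d sample(s) with no diploid diagnostic data", sum(is.na(het))))
  }
  het
}

#' Classify samples into coarse hybrid categories
#'
#' F1: interspecific heterozygosity >= `f1_het` and |h - 0.5| <= `f1_h_dev`.
#' Parental-like: h < `parental_h` (P0 side) or h > 1 - `parental_h` (P1
#' side) with heterozygosity < `parental_het` (the least-admixed filter).
#' Everything else is "admixed/backcross".
#'
#' @param h hybrid index (vector).
#' @param het interspecific heterozygosity (vector).
#' @param f1_het,f1_h_dev,parental_h,parental_het thresholds.
#' @return character vector of labels.
#' @export
classify_hybrid <- function(h, het, f1_het = 0.95, f1_h_dev = 0.05,
                            parental_h = 0.1, parental_het = 0.1) {
  stopifnot(length(h) == length(het))
  out <- rep("admixed/backcross", length(h))
  out[h < parental_h & het < parental_het] <- "parental-like-P0"
  out[h > 1 - parental_h & het < parental_het] <- "parental-like-P1"
  out[het >= f1_het & abs(h - 0.5) <= f1_h_dev] <- "F1"
  out
}
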