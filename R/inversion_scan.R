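#' @importFrom mclust Mclust mclustBIC
NULL

# likelihood-ratio test of a single-predictor logistic model: membership ~ g
logistic_lrt_score <- function(member, g) {
  ok <- !is.na(g)
  y <- member[ok]; gg <- g[ok]
  if (length(unique(gg)) < 2 || length(unique(y)) < 2) return(0)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, gg), y, family = stats::binomial()))
  null_dev <- fit$null.deviance
  lrt <- null_dev - fit$deviance
  if (!is.finite(lrt) || lrt < 0) lrt <- 0
  -log10(stats::pchisq(lrt, 1, lower.tail = FALSE))
}

#' SNP-PC association scores along one chromosome
#'
#' PCA on the chromosome's SNPs (no thinning), then for each SNP a
#' likelihood-ratio test of a logistic model of PC-halves membership
#' (coordinate above the median of each retained PC) on the genotype count.
#' The score is the maximum over PCs of -log10 p. Large inversions appear as
#' stepwise blocks of elevated scores; monomorphic SNPs score 0.
#'
#' @param gm a [genotype_matrix()] restricted to one chromosome.
#' @param k number of leading PCs tested (default 2).
#' @param membership optional list of fixed 0/1 membership vectors (one per
#'   tested PC) replacing the PC-halves split — useful for permutation
#'   null checks where genotypes are shuffled against a fixed partition.
#' @return data.frame: chrom, pos, score.
#' @export
snp_pc_association <- function(gm, k = 2L, membership = NULL) {
  if (length(unique(gm$loci$chrom)) != 1) {
    stop("snp_pc_association expects a single chromosome")
  }
  if (length(gm$samples) < 10) stop("need at least 10 samples")
  members <- if (is.null(membership)) {
    pc <- pca_genotypes(gm, thin_bp = 0, k = k)
    k <- min(k, ncol(pc$coords))
    lapply(seq_len(k), function(j) {
      as.numeric(pc$coords[, j] > stats::median(pc$coords[, j]))
    })
  } else membership
  score <- vapply(seq_len(nrow(gm$loci)), function(s) {
    g <- gm$counts[, s]
    max(vapply(members, logistic_lrt_score, numeric(1), g = g))
  }, numeric(1))
  data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos, score = score,
             stringsAsFactors = FALSE)
}

# least-squares two-changepoint segmentation: minimize the SSE of a
# three-segment piecewise-constant fit of the score track
two_changepoint_ls <- function(score) {
  n <- length(score)
  S <- c(0, cumsum(score))
  Q <- c(0, cumsum(score^2))
  segcost <- function(a, b) {
    # vectorized over equal-length a, b (1-based inclusive)
    s <- S[b + 1] - S[a]
    q <- Q[b + 1] - Q[a]
    q - s^2 / (b - a + 1)
  }
  best <- c(Inf, NA, NA)
  left <- segcost(rep(1, n), seq_len(n))  # cost of [1, i]
  for (i in seq_len(n - 2)) {
    j <- (i + 1):(n - 1)
    tot <- left[i] + segcost(rep(i + 1, length(j)), j) +
      segcost(j + 1, rep(n, length(j)))
    m <- which.min(tot)
    if (tot[m] < best[1]) best <- c(tot[m], i, j[m])
  }
  list(i = best[2], j = best[3])
}

#' Detect inversion boundaries from a score track
#'
#' Binary segmentation with two changepoints (least-squares cost on the
#' scores). The middle segment is called an inversion only if its mean score
#' exceeds the outside mean by `mean_factor` and it spans at least
#' `min_frac` of the chromosome extent. When a second qualifying region
#' remains after masking the first, the higher-mean region is returned with
#' a warning (single-call policy; rerun on masked input for nested calls).
#'
#' @param scores data.frame from [snp_pc_association()] (chrom, pos, score).
#' @param mean_factor required inside/outside mean-score ratio (default 3).
#' @param min_frac minimum spanned fraction of the chromosome extent
#'   (default 0.05).
#' @param chrom_length optional chromosome length for the extent; defaults
#'   to the SNP span.
#' @return list(start_bp, end_bp, inside_mean, outside_mean) or NULL when no
#'   region qualifies.
#' @export
detect_boundaries <- function(scores, mean_factor = 3, min_frac = 0.05,
                              chrom_length = NULL) {
  find_one <- function(sc) {
    n <- nrow(sc)
    if (n < 5) return(NULL)
    cp <- two_changepoint_ls(sc$score)
    if (is.na(cp$i)) return(NULL)
    inside <- (cp$i + 1):cp$j
    outside <- setdiff(seq_len(n), inside)
    im <- mean(sc$score[inside]); om <- mean(sc$score[outside])
    extent <- if (is.null(chrom_length)) diff(range(sc$pos)) else chrom_length
    span <- sc$pos[cp$j] - sc$pos[cp$i + 1]
    if (!(im > mean_factor * max(om, 1e-12)) || span < min_frac * extent) {
      return(NULL)
    }
    list(start_bp = sc$pos[cp$i + 1], end_bp = sc$pos[cp$j],
         inside_mean = im, outside_mean = om)
  }
  first <- find_one(scores)
  if (is.null(first)) return(NULL)
  masked <- scores
  inreg <- masked$pos >= first$start_bp & masked$pos <= first$end_bp
  masked$score[inreg] <- first$outside_mean
  second <- find_one(masked)
  if (!is.null(second)) {
    warning("multiple qualifying regions; returning the higher-mean region")
    if (second$inside_mean > first$inside_mean) return(second)
  }
  first
}

#' Inversion length in Mb
#'
#' Defined as (end - start) / 1e6, rounded to one decimal — matching the
#' convention of reporting breakpoint subtractions directly.
#'
#' @param start_bp,end_bp boundary positions (1-based bp).
#' @export
inversion_length_mb <- function(start_bp, end_bp) {
  stopifnot(end_bp > start_bp)
  round((end_bp - start_bp) / 1e6, 1)
}

#' Assign inversion haplotype groups within a called region
#'
#' PCA on the region's SNPs; 1-D Gaussian-mixture clustering (BIC over 1-3
#' components) on PC1. With three clusters, the middle cluster is labelled
#' AB (inversion heterozygotes) and the outer clusters AA and BB in PC1
#' order. The AB group is validated against per-individual inbreeding F
#' computed over the region: heterozygotes should show the lowest mean F,
#' and the call is flagged when they do not.
#'
#' @param gm a [genotype_matrix()] restricted to the called region.
#' @param g_max maximum number of mixture components considered.
#' @return list: groups (named per-sample labels), group_mean_F, n_groups,
#'   f_ok (TRUE when AB has the lowest mean F, NA with < 3 groups), pc1.
#' @export
assign_haplotype_groups <- function(gm, g_max = 3L) {
  pc <- pca_genotypes(gm, thin_bp = 0, k = 1)
  pc1 <- pc$coords[, 1]
  # equal-variance mixture: robust when one haplotype group is very small
  mc <- mclust::Mclust(pc1, G = seq_len(g_max), modelNames = "E",
                       verbose = FALSE)
  if (is.null(mc)) mc <- mclust::Mclust(pc1, G = 1, verbose = FALSE)
  ng <- mc$G
  ord <- order(mc$parameters$mean)
  lab_all <- c("AA", "AB", "BB")
  labels <- switch(ng, c("AA"), c("AA", "BB"), lab_all)
  if (ng < 3) {
    warning(sprintf("only %d inversion haplotype cluster(s) supported by BIC", ng))
  }
  grp <- labels[match(mc$classification, ord)]
  names(grp) <- gm$samples
  f <- individual_inbreeding_F(gm)
  gmf <- tapply(f, grp, mean)
  f_ok <- if (ng == 3) {
    is.finite(gmf[["AB"]]) && gmf[["AB"]] == min(gmf)
  } else NA
  if (isFALSE(f_ok)) {
    warning("heterozygote (AB) group does not have the lowest mean F")
  }
  list(groups = grp, group_mean_F = gmf, n_groups = ng, f_ok = f_ok,
       pc1 = pc1)
}

#' Full inversion scan on one chromosome
#'
#' Runs [snp_pc_association()], [detect_boundaries()] and (when a region is
#' called) [assign_haplotype_groups()] on the region.
#'
#' @param gm a [genotype_matrix()] restricted to one chromosome.
#' @param k PCs tested.
#' @param ... passed to [detect_boundaries()].
#' @return list of class `inversion_call`: chrom, start_bp, end_bp,
#'   length_mb, score_track, haplotype_groups, group_mean_F, f_ok; or NULL
#'   when no inversion is detected.
#' @export
inversion_scan <- function(gm, k = 2L, ...) {
  track <- snp_pc_association(gm, k = k)
  bounds <- detect_boundaries(track, ...)
  if (is.null(bounds)) return(NULL)
  reg <- gm_chrom(gm, gm$loci$chrom[1], bounds$start_bp, bounds$end_bp)
  hap <- assign_haplotype_groups(reg)
  out <- list(chrom = gm$loci$chrom[1],
              start_bp = bounds$start_bp, end_bp = bounds$end_bp,
              length_mb = inversion_length_mb(bounds$start_bp, bounds$end_bp),
              score_track = track,
              haplotype_groups = hap$groups,
              group_mean_F = hap$group_mean_F,
              f_ok = hap$f_ok)
  class(out) <- "inversion_call"
  out
}
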