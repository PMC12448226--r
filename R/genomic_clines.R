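#' Genomic cline function
#'
#' Probability that an allele copy at a locus is P1-derived, given the
#' carrier's genome-wide hybrid index h, cline steepness v and centre c:
#' `phi = logistic(v * (logit(h) - logit(c)))`. At v = 1, c = 0.5 the cline
#' is the identity (the locus tracks the genome-wide average transition);
#' v > 1 steepens the transition around the centre, the signature of
#' restricted introgression. Boundary values h = 0 and h = 1 map to 0 and 1
#' by continuity.
#'
#' @param h hybrid index in [0, 1] (vectorized).
#' @param v cline steepness, > 0.
#' @param centre hybrid-index value at which locus ancestry probability is
#'   1/2, in (0, 1).
#' @export
phi <- function(h, v, centre) {
  stopifnot(v > 0, centre > 0, centre < 1)
  out <- expit(v * (logit(h) - logit(centre)))
  out[h <= 0] <- 0
  out[h >= 1] <- 1
  out
}

# log-likelihood of (ln v, logit centre) for one locus:
# k_i ~ Binomial(n_i, phi(h_i, v, c))
gc_loglik <- function(lnv, lgt_c, k, n, h) {
  p <- phi(h, exp(lnv), expit(lgt_c))
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(k * log(p) + (n - k) * log1p(-p))
}

#' Fit a Bayesian genomic cline for one locus
#'
#' Metropolis-Hastings on (ln v, logit centre) with independent
#' Normal(0, 1.5^2) priors on both transformed parameters. Each of a
#' sample's allele copies at the locus is the P1 allele with probability
#' `phi(h_i, v, centre)`. `p_v` is the two-sided MCMC tail probability that
#' ln v differs from 0, i.e. `2 * min(Pr(ln v > 0), Pr(ln v < 0))` over
#' retained draws; a locus is called `significant_restricted` when the
#' posterior mean v exceeds 1 and p_v < 0.05.
#'
#' @param k P1-allele copy counts per sample at the locus.
#' @param n allele copies with data per sample (0 allowed; such samples are
#'   ignored).
#' @param h per-sample genome-wide hybrid index (plugged in as fixed).
#' @param burn,keep MCMC iterations (defaults 5,000 / 10,000).
#' @param seed RNG seed.
#' @param prior_sd prior SD on ln v and logit centre.
#' @return list: v_mean, v_median, v_lo, v_hi, centre_mean, p_v,
#'   significant_restricted, n_used, draws (keep x 2 matrix of v, centre).
#' @export
fit_genomic_cline <- function(k, n, h, burn = 5000L, keep = 10000L,
                              seed = NULL, prior_sd = 1.5) {
  if (!is.null(seed)) set.seed(seed)
  use <- !is.na(k) & !is.na(n) & n > 0 & !is.na(h)
  k <- k[use]; n <- n[use]; h <- h[use]
  if (length(k) < 20) {
    warning("fewer than 20 samples with data; cline fit will be weak")
  }
  info <- h > 0 & h < 1
  if (sum(k[info]) == 0 || sum(k[info]) == sum(n[info])) {
    warning("locus monomorphic among admixed samples; expect a wide interval")
  }
  lp <- function(par) {
    gc_loglik(par[1], par[2], k, n, h) +
      stats::dnorm(par[1], 0, prior_sd, log = TRUE) +
      stats::dnorm(par[2], 0, prior_sd, log = TRUE)
  }
  par <- c(0, 0)
  cur <- lp(par)
  step <- c(0.4, 0.4)
  acc_win <- c(0L, 0L)
  total <- burn + keep
  draws <- matrix(NA_real_, keep, 2)
  for (it in seq_len(total)) {
    for (j in 1:2) {
      prop <- par
      prop[j] <- par[j] + stats::rnorm(1, 0, step[j])
      new <- lp(prop)
      if (log(stats::runif(1)) < new - cur) {
        par <- prop; cur <- new
        if (it <= burn) acc_win[j] <- acc_win[j] + 1L
      }
    }
    if (it <= burn && it %% 50L == 0L) {
      rate <- acc_win / 50
      step[rate < 0.2] <- step[rate < 0.2] * 0.7
      step[rate > 0.5] <- step[rate > 0.5] * 1.4
      acc_win[] <- 0L
    }
    if (it > burn) draws[it - burn, ] <- par
  }
  v <- exp(draws[, 1])
  centre <- expit(draws[, 2])
  p_v <- 2 * min(mean(draws[, 1] > 0), mean(draws[, 1] < 0))
  v_mean <- mean(v)
  list(v_mean = v_mean,
       v_median = unname(stats::median(v)),
       v_lo = unname(stats::quantile(v, 0.025)),
       v_hi = unname(stats::quantile(v, 0.975)),
       centre_mean = mean(centre),
       p_v = p_v,
       significant_restricted = v_mean > 1 && p_v < 0.05,
       n_used = length(k),
       draws = cbind(v = v, centre = centre))
}

#' Fit genomic clines for every locus of a diagnostic panel
#'
#' @param gm a [genotype_matrix()].
#' @param panel a `diagnostic_panel` (see [select_diagnostic()]).
#' @param h per-sample hybrid index, aligned with `gm$samples` (e.g.
#'   `h_mean` from [estimate_hybrid_index()]).
#' @param burn,keep,seed,prior_sd passed to [fit_genomic_cline()]; per-locus
#'   seeds are derived from `seed`.
#' @return data.frame: chrom, pos, v_mean, v_lo, v_hi, centre_mean, p_v,
#'   significant.
#' @export
fit_genomic_clines <- function(gm, panel, h, burn = 5000L, keep = 10000L,
                               seed = 1L, prior_sd = 1.5) {
  stopifnot(length(h) == length(gm$samples))
  pc <- p1_counts(gm, panel)
  res <- lapply(seq_len(nrow(panel)), function(j) {
    f <- fit_genomic_cline(pc$counts[, j], pc$ploidy[, j], h,
                           burn = burn, keep = keep,
                           seed = seed + j, prior_sd = prior_sd)
    data.frame(chrom = panel$chrom[j], pos = panel$pos[j],
               v_mean = f$v_mean, v_lo = f$v_lo, v_hi = f$v_hi,
               centre_mean = f$centre_mean, p_v = f$p_v,
               significant = f$significant_restricted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summaries of cline steepness over significant loci
#'
#' @param fits data.frame from [fit_genomic_clines()].
#' @return list: n_tested, n_significant, mean_v_significant, n_v_gt_10,
#'   per_chrom (significant counts by chromosome).
#' @export
summarize_steepness <- function(fits) {
  sig <- fits[fits$significant, , drop = FALSE]
  per_chrom <- if (nrow(sig)) table(sig$chrom) else table(character(0))
  list(n_tested = nrow(fits),
       n_significant = nrow(sig),
       mean_v_significant = if (nrow(sig)) mean(sig$v_mean) else NA_real_,
       n_v_gt_10 = sum(sig$v_mean > 10),
       per_chrom = per_chrom)
}
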