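test_that("diagnostic selection keeps fixed loci and respects thinning", {
  # locus 1 fixed 0 in A / 2 in B; locus 2 has a heterozygote in A;
  # locus 3 fixed 2 in A / 0 in B (reversed orientation)
  gmA <- simple_gm(rbind(c(0L, 0L, 2L), c(0L, 1L, 2L)),
                   pos = c(1000L, 20000L, 40000L))
  gmB <- simple_gm(rbind(c(2L, 2L, 0L), c(2L, 2L, 0L)),
                   pos = c(1000L, 20000L, 40000L), samples = c("b1", "b2"))
  panel <- select_diagnostic(gmA, gmB)
  expect_equal(panel$pos, c(1000L, 40000L))
  expect_equal(panel$p1_allele, c("alt", "ref"))
})

test_that("diagnostic selection errors when nothing qualifies", {
  gmA <- simple_gm(rbind(c(0L, 1L), c(1L, 0L)))
  gmB <- simple_gm(rbind(c(0L, 1L), c(1L, 0L)), samples = c("b1", "b2"))
  expect_error(select_diagnostic(gmA, gmB), "reference panels")
})

test_that("synthetic panels yield exactly the planted diagnostic count", {
  cfg <- synth_config(seed = 8, L_diag = 500, L_background = 0)
  panel <- panel_from_cfg(cfg)
  expect_equal(nrow(panel), 500L)
})

test_that("posterior mean matches the Beta-binomial closed form", {
  # k of n allele copies P1 with Beta(0.5, 0.5) prior -> mean (k+0.5)/(n+1)
  cases <- list(c(k = 5, n = 40), c(k = 20, n = 40), c(k = 37, n = 40),
                c(k = 0, n = 60), c(k = 150, n = 200))
  for (cs in cases) {
    L <- cs[["n"]] / 2
    counts <- integer(L)
    left <- cs[["k"]]
    for (i in seq_len(L)) {
      counts[i] <- min(left, 2L)
      left <- left - counts[i]
    }
    gm <- class_gm(data.frame(chrom = "c1", pos = seq_len(L) * 1000L,
                              ref = "A", alt = "G", p1_allele = "alt"),
                   counts)
    panel <- data.frame(chrom = "c1", pos = seq_len(L) * 1000L,
                        ref = "A", alt = "G", p1_allele = "alt",
                        stringsAsFactors = FALSE)
    hi <- estimate_hybrid_index(gm, panel, burn = 1000, keep = 4000, seed = 2)
    exact <- (cs[["k"]] + 0.5) / (cs[["n"]] + 1)
    expect_lt(abs(hi$h_mean - exact), 0.02)
  }
})

test_that("boundary samples and F1s are estimated correctly", {
  cfg <- synth_config(seed = 4, L_diag = 1000, L_background = 0)
  panel <- panel_from_cfg(cfg)
  gm <- class_gm(panel, make_hybrid_class("P1", nrow(panel)))
  hi <- estimate_hybrid_index(gm, panel, burn = 1000, keep = 3000, seed = 7)
  expect_gt(hi$h_mean, 0.99)
  gm0 <- class_gm(panel, make_hybrid_class("P0", nrow(panel)))
  hi0 <- estimate_hybrid_index(gm0, panel, burn = 1000, keep = 3000, seed = 7)
  expect_lt(hi0$h_mean, 0.01)
  f1 <- class_gm(panel, make_hybrid_class("F1", nrow(panel)))
  hif1 <- estimate_hybrid_index(f1, panel, burn = 1000, keep = 3000, seed = 7)
  expect_lt(abs(hif1$h_mean - 0.5), 0.02)
  expect_true(hif1$h_lo < 0.5 && hif1$h_hi > 0.5)
})

test_that("swapping panel orientation maps h to 1 - h", {
  cfg <- synth_config(seed = 6, n_transect = 25, L_diag = 200,
                      L_background = 0)
  tra <- make_transect(cfg)
  panel <- panel_from_cfg(cfg)
  flipped <- panel
  flipped$p1_allele <- ifelse(panel$p1_allele == "alt", "ref", "alt")
  h1 <- estimate_hybrid_index(tra$gm, panel, burn = 800, keep = 2000,
                              seed = 3)$h_mean
  h2 <- estimate_hybrid_index(tra$gm, flipped, burn = 800, keep = 2000,
                              seed = 3)$h_mean
  expect_lt(max(abs(h1 - (1 - h2))), 0.03)
})

test_that("posterior mean is monotone in the P1-copy fraction", {
  L <- 50
  panel <- data.frame(chrom = "c1", pos = seq_len(L) * 1000L,
                      ref = "A", alt = "G", p1_allele = "alt",
                      stringsAsFactors = FALSE)
  counts <- rbind(rep(0L, L), rep(1L, L), rep(2L, L))
  counts[2, 1:10] <- 0L
  gm <- simple_gm(counts)
  hi <- estimate_hybrid_index(gm, panel, burn = 800, keep = 2000, seed = 5)
  expect_true(all(diff(hi$h_mean) > 0))
})

test_that("hybrid index recovers the generating ancestry on a transect", {
  cfg <- synth_config(seed = 14, n_transect = 60, L_diag = 1000,
                      L_background = 0)
  tra <- make_transect(cfg)
  panel <- panel_from_cfg(cfg)
  hi <- estimate_hybrid_index(tra$gm, panel, burn = 800, keep = 2000,
                              seed = 4)
  expect_lt(mean(abs(hi$h_mean - tra$samples$q_true)), 0.03)
})

test_that("interspecific heterozygosity matches hybrid-class expectations", {
  cfg <- synth_config(seed = 4, L_diag = 400, L_background = 0)
  panel <- panel_from_cfg(cfg)
  f1 <- class_gm(panel, make_hybrid_class("F1", nrow(panel)))
  expect_equal(unname(interspecific_heterozygosity(f1, panel)), 1)
  p0 <- class_gm(panel, make_hybrid_class("P0", nrow(panel)))
  expect_equal(unname(interspecific_heterozygosity(p0, panel)), 0)
  set.seed(11)
  L <- 10000
  bigpanel <- data.frame(chrom = "c1", pos = seq_len(L) * 1000L,
                         ref = "A", alt = "G", p1_allele = "alt",
                         stringsAsFactors = FALSE)
  f2 <- class_gm(bigpanel, make_hybrid_class("F2", L))
  expect_lt(abs(interspecific_heterozygosity(f2, bigpanel) - 0.5),
            3 * sqrt(0.25 / L))
})

test_that("female Z loci are excluded from heterozygosity", {
  panel <- data.frame(chrom = "Z_1", pos = c(1000L, 2000L),
                      ref = "A", alt = "G", p1_allele = "alt",
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(matrix(c(1L, 1L), 1), panel[1:4], "f1",
                        matrix(c(2L, 1L), 1))
  expect_equal(unname(interspecific_heterozygosity(gm, panel)), 1)
})

test_that("hybrid classification follows the threshold rules", {
  expect_equal(classify_hybrid(0.5, 1.0), "F1")
  expect_equal(classify_hybrid(0.95, 0.05), "parental-like-P1")
  expect_equal(classify_hybrid(0.05, 0.05), "parental-like-P0")
  expect_equal(classify_hybrid(0.7, 0.4), "admixed/backcross")
  expect_equal(classify_hybrid(0.95, 0.15), "admixed/backcross")
})
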