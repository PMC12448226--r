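test_that("PCA separates the parental panels on PC1", {
  cfg <- synth_config(seed = 2, L_diag = 300, L_background = 0)
  pan <- make_parental_panels(cfg)
  nuclear <- which(pan$gm$loci$chrom != "MT")
  pc <- pca_genotypes(gm_subset(pan$gm, loci = nuclear), thin_bp = 10000)
  labels <- pan$samples$population_label
  pc1 <- pc$coords[, 1]
  expect_true(max(pc1[labels == "allopatric-P0"]) <
                min(pc1[labels == "allopatric-P1"]) ||
              min(pc1[labels == "allopatric-P0"]) >
                max(pc1[labels == "allopatric-P1"]))
  expect_gt(pc$explained[1], 0.9)
})

test_that("duplicated samples get identical coordinates", {
  set.seed(40)
  counts <- matrix(rbinom(80, 2, 0.4), 8, 10)
  counts[8, ] <- counts[1, ]
  gm <- simple_gm(counts)
  pc <- pca_genotypes(gm, thin_bp = 0, k = 3)
  expect_equal(pc$coords[1, ], pc$coords[8, ], tolerance = 1e-10)
})

test_that("admixed transect samples fall between the panels on PC1", {
  cfg <- synth_config(seed = 13, n_transect = 40, L_diag = 300,
                      L_background = 0)
  pan <- make_parental_panels(cfg)
  tra <- make_transect(cfg)
  nuclear <- which(pan$gm$loci$chrom != "MT")
  gm <- gm_subset(gm_rbind(pan$gm, tra$gm), loci = nuclear)
  pc <- pca_genotypes(gm, thin_bp = 0, k = 2)
  lab <- c(pan$samples$population_label, tra$samples$population_label)
  pr <- ancestry_proxy(pc$coords[, 1], lab == "allopatric-P0",
                       lab == "allopatric-P1")
  mid <- tra$samples$q_true > 0.35 & tra$samples$q_true < 0.65
  expect_true(all(pr[lab == "transect"][mid] > 0.1 &
                    pr[lab == "transect"][mid] < 0.9))
})

test_that("per-SNP Weir-Cockerham matches an independent implementation", {
  set.seed(41)
  for (i in 1:10) {
    gA <- rbinom(10, 2, 0.9)
    gB <- rbinom(10, 2, 0.1)
    gm <- simple_gm(matrix(c(gA, gB), 20, 1), pos = 100L)
    got <- wc_fst_snp(gm, sprintf("s%03d", 1:10), sprintf("s%03d", 11:20),
                      components = TRUE)
    want <- wc84_oracle(gA, gB)
    expect_equal(got$fst, want$fst, tolerance = 1e-12)
    expect_equal(got$a, want$a, tolerance = 1e-12)
    expect_equal(got$b, want$b, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
  }
})

test_that("fixed differences give F_ST 1 and monomorphic loci NA", {
  gm <- simple_gm(rbind(matrix(0L, 5, 3), matrix(2L, 5, 3)))
  f <- wc_fst_snp(gm, sprintf("s%03d", 1:5), sprintf("s%03d", 6:10))
  expect_equal(f$fst, rep(1, 3))
  gmono <- simple_gm(matrix(2L, 10, 1))
  expect_true(is.na(wc_fst_snp(gmono, sprintf("s%03d", 1:5),
                               sprintf("s%03d", 6:10))$fst))
  # identical allele distributions: estimator noise at or below zero
  gsame <- simple_gm(matrix(rep(c(0L, 1L, 2L, 1L, 0L), 2), 10, 1))
  expect_lte(wc_fst_snp(gsame, sprintf("s%03d", 1:5),
                        sprintf("s%03d", 6:10))$fst, 0)
})

test_that("windowed F_ST uses ratio-of-sums over fully-inside windows", {
  # window arithmetic: chromosome of length 100,000 -> 16 windows
  set.seed(42)
  pos <- sort(sample.int(99000L, 60))
  counts <- rbind(matrix(rbinom(30 * 60, 2, 0.85), 30),
                  matrix(rbinom(30 * 60, 2, 0.15), 30))
  gm <- simple_gm(counts, pos = pos)
  win <- wc_fst_windowed(gm, sprintf("s%03d", 1:30), sprintf("s%03d", 31:60),
                         chrom_lengths = c(c1 = 100000L))
  expect_equal(nrow(win), floor((100000 - 25000) / 5000) + 1)
  expect_equal(win$start, seq(1L, 75001L, by = 5000L))
  # ratio-of-sums equals the oracle's ratio of summed components, and
  # differs from the mean of per-SNP ratios on heterogeneous windows
  snp <- wc_fst_snp(gm, sprintf("s%03d", 1:30), sprintf("s%03d", 31:60),
                    components = TRUE)
  for (w in c(1, 5, 12)) {
    inw <- snp$pos >= win$start[w] & snp$pos <= win$end[w]
    expect_equal(win$fst[w],
                 sum(snp$a[inw]) / sum(snp$a[inw] + snp$b[inw] + snp$c[inw]))
  }
  expect_equal(win$n_snps, vapply(seq_len(nrow(win)), function(w) {
    sum(pos >= win$start[w] & pos <= win$end[w])
  }, integer(1)))
})

test_that("all-fixed windows give windowed F_ST of exactly 1", {
  gm <- simple_gm(rbind(matrix(0L, 6, 10), matrix(2L, 6, 10)),
                  pos = seq(1000L, 10000L, by = 1000L))
  win <- wc_fst_windowed(gm, sprintf("s%03d", 1:6), sprintf("s%03d", 7:12),
                         window = 10000L, step = 10000L,
                         chrom_lengths = c(c1 = 10000L))
  expect_equal(win$fst, 1)
})

test_that("individual inbreeding F flags heterozygote excess and deficit", {
  # 20 individuals at p ~ 0.5; one all-heterozygous, one all-homozygous
  set.seed(43)
  counts <- matrix(rbinom(20 * 60, 2, 0.5), 20, 60)
  counts[1, ] <- 1L
  counts[2, ] <- ifelse(rbinom(60, 1, 0.5) == 1, 2L, 0L)
  gm <- simple_gm(counts)
  f <- individual_inbreeding_F(gm)
  expect_lt(f[[1]], -0.5)
  expect_gt(f[[2]], 0.7)
  expect_true(all(f[[1]] < f[3:20]))
})

test_that("least-admixed filter applies the exact thresholds", {
  h <- c(0.05, 0.5, 0.95, 0.95, 0.101)
  het <- c(0.05, 0.9, 0.15, 0.05, 0.05)
  sel <- select_least_admixed(h, het)
  expect_equal(sel$p0_side, 1L)
  expect_equal(sel$p1_side, 4L)
  # idempotent on the kept subset
  keep <- sort(c(sel$p0_side, sel$p1_side))
  sel2 <- select_least_admixed(h[keep], het[keep])
  expect_equal(length(sel2$p0_side) + length(sel2$p1_side), length(keep))
})

test_that("mitotypes are assigned to the nearest reference clade", {
  cfg <- synth_config(seed = 17, n_transect = 40, L_diag = 50,
                      L_background = 0)
  pan <- make_parental_panels(cfg)
  tra <- make_transect(cfg)
  mt_idx <- which(pan$gm$loci$chrom == "MT")
  mt_gm <- gm_subset(gm_rbind(pan$gm, tra$gm), loci = mt_idx)
  refs <- split(pan$samples$sample_id, pan$samples$mitotype)
  got <- assign_mitotype(mt_gm, refs)
  # every reference sample recovers its own clade
  ref_rows <- match(pan$samples$sample_id, got$sample)
  expect_equal(got$mitotype[ref_rows], pan$samples$mitotype)
  # transect samples recover their generating clade
  tra_rows <- match(tra$samples$sample_id, got$sample)
  expect_gt(mean(got$mitotype[tra_rows] == tra$samples$mitotype), 0.95)
})
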