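test_that("VCF reader keeps only biallelic SNPs", {
  f <- write_tmp_vcf(c(
    vcf_header(),
    vcf_rec("c1", 100, "A", "G", c("0/1", "1/1")),
    vcf_rec("c1", 200, "A", "G,T", c("0/1", "0/2")),
    vcf_rec("c1", 300, "C", "T", c("0/0", "0/1")),
    vcf_rec("c1", 400, "C", "TT", c("0/0", "0/1"))
  ))
  gm <- read_vcf_biallelic(f)
  expect_equal(nrow(gm$loci), 2L)
  expect_equal(gm$loci$pos, c(100L, 300L))
  expect_equal(unname(gm$counts[, 1]), c(1L, 2L))
})

test_that("female Z genotypes are coerced to ploidy 1", {
  f <- write_tmp_vcf(c(
    vcf_header(c("M1", "F1")),
    vcf_rec("Z_1", 100, "A", "G", c("0/0", "0/0")),
    vcf_rec("Z_1", 200, "A", "G", c("1/1", "1/1")),
    vcf_rec("Z_1", 300, "A", "G", c("0/1", "0/1"))
  ))
  expect_warning(
    gm <- read_vcf_biallelic(f, sex_map = c(M1 = "M", F1 = "F")),
    "heterozygous female Z")
  expect_equal(unname(gm$counts["F1", ]), c(0L, 1L, NA))
  expect_equal(unname(gm$ploidy["F1", ]), c(1L, 1L, 1L))
  expect_equal(unname(gm$counts["M1", ]), c(0L, 2L, 1L))
  expect_equal(unname(gm$ploidy["M1", ]), c(2L, 2L, 2L))
  # no female ever keeps a count of 2 on Z
  expect_true(all(gm$counts["F1", ] <= 1, na.rm = TRUE))
})

test_that("unknown sex on Z becomes missing with a warning", {
  f <- write_tmp_vcf(c(
    vcf_header(c("M1", "U1")),
    vcf_rec("Z_1", 100, "A", "G", c("0/0", "0/1"))
  ))
  expect_warning(gm <- read_vcf_biallelic(f, sex_map = c(M1 = "M")),
                 "unknown sex")
  expect_true(is.na(gm$counts["U1", 1]))
  expect_true(is.na(gm$ploidy["U1", 1]))
})

test_that("unsorted VCF errors naming the first offending record", {
  f <- write_tmp_vcf(c(
    vcf_header(),
    vcf_rec("c1", 500, "A", "G", c("0/0", "0/0")),
    vcf_rec("c1", 100, "A", "G", c("0/0", "0/0"))
  ))
  expect_error(read_vcf_biallelic(f), "c1:100")
})

test_that("write then read round-trips genotype counts exactly", {
  cfg <- synth_config(seed = 5, n_transect = 20, L_diag = 60,
                      L_background = 30)
  tra <- make_transect(cfg)
  sex <- setNames(tra$samples$sex, tra$samples$sample_id)
  path <- write_vcf_gm(tra$gm, tempfile(fileext = ".vcf"))
  back <- read_vcf_biallelic(path, sex_map = sex)
  expect_equal(back$loci$pos, tra$gm$loci$pos)
  expect_equal(unname(back$counts), unname(tra$gm$counts))
  expect_equal(unname(back$ploidy), unname(tra$gm$ploidy))
})

test_that("window thinning keeps the lowest-position locus per window", {
  gm <- simple_gm(matrix(0L, 2, 2), pos = c(1000L, 9000L))
  expect_equal(thin_by_window(gm, 10000)$loci$pos, 1000L)
  gm2 <- simple_gm(matrix(0L, 2, 2), pos = c(9999L, 10001L))
  expect_equal(thin_by_window(gm2, 10000)$loci$pos, c(9999L, 10001L))
})

test_that("thinning matches a brute-force window scan and is idempotent", {
  set.seed(31)
  pos <- sort(sample.int(1000000L, 100))
  gm <- simple_gm(matrix(0L, 2, 100), pos = pos)
  th <- thin_by_window(gm, 10000)
  # brute force: enumerate windows, keep min-position locus of each
  expected <- sort(vapply(split(pos, (pos - 1) %/% 10000),
                          min, numeric(1)))
  expect_equal(th$loci$pos, as.integer(expected))
  again <- thin_by_window(th, 10000)
  expect_identical(again$loci$pos, th$loci$pos)
  expect_identical(again$counts, th$counts)
})

test_that("GFF gene reader applies and clamps flanks, filters features", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t10000\t12000\t.\t+\t.\tID=g1",
    "c1\tsrc\tmRNA\t10000\t12000\t.\t+\t.\tID=t1;Parent=g1",
    "c1\tsrc\texon\t10000\t11000\t.\t+\t.\tParent=t1",
    "c1\tsrc\tgene\t2000\t3000\t.\t-\t.\tID=g2",
    "c1\tsrc\tCDS\t10000\t11000\t.\t+\t0\tParent=t1"
  ), f)
  genes <- read_gff_genes(f, flank_bp = 5000)
  expect_equal(nrow(genes), 2L)
  expect_equal(genes$search_start[genes$gene_id == "g1"], 5000L)
  expect_equal(genes$search_end[genes$gene_id == "g1"], 17000L)
  expect_equal(genes$search_start[genes$gene_id == "g2"], 1L)
  expect_equal(genes$search_end[genes$gene_id == "g2"], 8000L)
})

test_that("malformed GFF lines error with the line number", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1",
               "c1\tsrc\tgene\t100"), f)
  expect_error(read_gff_genes(f), "line 3")
})

test_that("genotype matrix validation rejects bad input", {
  expect_error(simple_gm(matrix(0L, 2, 2), pos = c(500L, 100L)), "unsorted")
  expect_error(genotype_matrix(matrix(3L, 1, 1),
                               data.frame(chrom = "c1", pos = 1L,
                                          ref = "A", alt = "G"),
                               "s1", matrix(2L, 1, 1)),
               "exceeds ploidy")
})
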