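# shared fixture builders (all generated in code; nothing on disk)

simple_gm <- function(counts, chrom = "c1", pos = NULL, ploidy = NULL,
                      samples = NULL) {
  counts <- as.matrix(counts)
  L <- ncol(counts)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  if (is.null(samples)) samples <- sprintf("s%03d", seq_len(nrow(counts)))
  genotype_matrix(counts,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  samples, ploidy)
}

# split a parental-panels object into P0 / P1 genotype matrices
split_panels <- function(pan) {
  list(A = gm_subset(pan$gm, pan$samples$sample_id[
         pan$samples$population_label == "allopatric-P0"]),
       B = gm_subset(pan$gm, pan$samples$sample_id[
         pan$samples$population_label == "allopatric-P1"]))
}

# one-sample genotype matrix over a panel's loci from a hybrid-class draw
class_gm <- function(panel, counts, sample_id = "H1") {
  genotype_matrix(matrix(as.integer(counts), 1),
                  data.frame(chrom = panel$chrom, pos = panel$pos,
                             ref = panel$ref, alt = panel$alt,
                             stringsAsFactors = FALSE),
                  sample_id)
}

# nuclear diagnostic panel from a synth_config layout (alt allele = P1);
# mtDNA variants are mitotyping input, not part of the nuclear panel
panel_from_cfg <- function(cfg) {
  pan <- make_parental_panels(cfg)
  sp <- split_panels(pan)
  nuclear <- which(sp$A$loci$chrom != "MT")
  select_diagnostic(gm_subset(sp$A, loci = nuclear),
                    gm_subset(sp$B, loci = nuclear))
}

# independent Weir & Cockerham (1984) two-population per-locus estimator,
# written directly from the published variance-component formulas
wc84_oracle <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB); r <- 2
  p1 <- mean(gA) / 2; p2 <- mean(gB) / 2
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# planted-inversion fixture: flat ancestry background (the within-species
# allopatric setting of the original scans) + a 3-state block
inversion_cfg <- function(seed, start = 1.5e6, end = 3.5e6,
                          freqs = c(0.3, 0.2, 0.5), n = 100) {
  synth_config(seed = seed, cline_width_km = 1e7, n_transect = n,
               inversion = list(chrom = "Z_1", start = start, end = end,
                                freqs = freqs))
}

write_tmp_vcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

vcf_header <- function(samples = c("A1", "A2")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_rec <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
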