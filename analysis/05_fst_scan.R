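#!/usr/bin/env Rscript
# Windowed differentiation scan: pick the least-admixed individuals in each
# transect (hybrid index < 0.1 or > 0.9, heterozygosity < 0.1), then
# Weir-Cockerham F_ST in 25 kb sliding windows with a 5 kb step.

suppressMessages(library(hzclines))

for (tr in c("east", "west")) {
  st <- read_sample_table(sprintf("results/data/%s/samples.tsv", tr))
  gm <- read_vcf_biallelic(sprintf("results/data/%s/synthetic.vcf.gz", tr),
                           sex_map = setNames(st$sex, st$sample_id))
  hi <- read.delim(sprintf("results/hybrid_index_%s.tsv", tr))
  sel <- select_least_admixed(hi$h_mean, hi$het)
  a <- gm$samples[sel$p0_side]
  b <- gm$samples[sel$p1_side]
  cat(sprintf("%s: least-admixed subsets n = %d (P0 side) / %d (P1 side)\n",
              tr, length(a), length(b)))
  nuclear <- which(gm$loci$chrom != "MT")
  win <- wc_fst_windowed(gm_subset(gm, loci = nuclear), a, b)
  path <- sprintf("results/fst_windows_%s.tsv", tr)
  hdr <- "# Weir-Cockerham F_ST, 25 kb windows / 5 kb step, 1-based inclusive"
  writeLines(hdr, path)
  suppressWarnings(
    write.table(win, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  done <- win[!is.na(win$fst), ]
  cat(sprintf("  %d windows with data; mean F_ST %.3f; wrote %s\n",
              nrow(done), mean(done$fst), path))
}
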