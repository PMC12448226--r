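#' @importFrom vcfR read.vcfR write.vcf extract.gt
#' @importFrom methods new
NULL

#' Genotype matrix container
#'
#' Samples-by-loci container for biallelic SNP genotypes coded as counts of the
#' alternate allele, with per-entry ploidy (2 for autosomal/diploid entries, 1
#' for hemizygous Z entries in females, NA where ploidy is unknown). Missing
#' genotypes are NA.
#'
#' @param counts integer matrix, samples x loci; NA for missing genotypes.
#' @param loci data.frame with columns chrom, pos, ref, alt; loci must be
#'   grouped by chromosome and sorted by position within each chromosome.
#' @param samples character vector of sample ids (rownames of `counts`).
#' @param ploidy integer matrix, same shape as `counts`, entries in {1, 2, NA}.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts, loci, samples, ploidy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(ploidy)) ploidy <- matrix(2L, nrow(counts), ncol(counts))
  stopifnot(
    nrow(counts) == length(samples),
    ncol(counts) == nrow(loci),
    all(dim(ploidy) == dim(counts)),
    all(c("chrom", "pos", "ref", "alt") %in% names(loci))
  )
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (any(loci$pos < 1L)) stop("positions must be >= 1")
  # chromosome blocks contiguous and sorted within
  rl <- rle(as.character(loci$chrom))
  if (anyDuplicated(rl$values)) stop("loci of a chromosome must be contiguous")
  bad <- which(diff(loci$pos) < 0 & loci$chrom[-1] == loci$chrom[-nrow(loci)])
  if (length(bad)) {
    stop(sprintf("loci unsorted within chromosome at %s:%d",
                 loci$chrom[bad[1] + 1], loci$pos[bad[1] + 1]))
  }
  over <- which(!is.na(counts) & !is.na(ploidy) & counts > ploidy)
  if (length(over)) stop("genotype count exceeds ploidy")
  rownames(counts) <- samples
  rownames(ploidy) <- samples
  structure(list(counts = counts, loci = as.data.frame(loci),
                 samples = as.character(samples), ploidy = ploidy),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci on %d chromosome(s)\n",
              length(x$samples), nrow(x$loci),
              length(unique(x$loci$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm a `genotype_matrix`.
#' @param samples sample ids or indices to keep (default all).
#' @param loci logical or integer index over loci (default all).
#' @export
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_along(gm$samples) else {
    if (is.character(samples)) match(samples, gm$samples) else samples
  }
  if (anyNA(si)) stop("unknown sample id")
  li <- if (is.null(loci)) seq_len(nrow(gm$loci)) else if (is.logical(loci)) which(loci) else loci
  genotype_matrix(gm$counts[si, li, drop = FALSE],
                  gm$loci[li, , drop = FALSE],
                  gm$samples[si],
                  gm$ploidy[si, li, drop = FALSE])
}

#' Restrict a genotype matrix to one chromosome (optionally a region)
#' @param gm a `genotype_matrix`.
#' @param chrom chromosome name.
#' @param start,end optional 1-based inclusive bounds.
#' @export
gm_chrom <- function(gm, chrom, start = NULL, end = NULL) {
  keep <- gm$loci$chrom == chrom
  if (!is.null(start)) keep <- keep & gm$loci$pos >= start
  if (!is.null(end)) keep <- keep & gm$loci$pos <= end
  gm_subset(gm, loci = keep)
}

#' Bind two genotype matrices that share an identical locus table
#' @param a,b `genotype_matrix` objects over the same loci.
#' @export
gm_rbind <- function(a, b) {
  stopifnot(identical(a$loci$chrom, b$loci$chrom), identical(a$loci$pos, b$loci$pos))
  genotype_matrix(rbind(a$counts, b$counts), a$loci,
                  c(a$samples, b$samples), rbind(a$ploidy, b$ploidy))
}

parse_gt_counts <- function(gt) {
  # "0/1", "0|1", "1", "./.", "." -> alt count + coded ploidy
  gt <- sub(":.*", "", gt)
  alleles <- strsplit(gt, "[/|]")
  n <- lengths(alleles)
  flat <- suppressWarnings(as.integer(unlist(alleles)))
  cnt <- vapply(split(flat, rep(seq_along(n), n)), function(a) {
    if (anyNA(a)) NA_integer_ else sum(a)
  }, integer(1))
  list(count = cnt, coded_ploidy = n)
}

#' Read biallelic SNPs from a VCF
#'
#' Keeps only biallelic SNP records. On Z chromosomes, female genotypes are
#' coerced to ploidy 1: a diploid-coded homozygote becomes a single allele
#' copy and a diploid-coded heterozygote (a genotyping artifact in a
#' hemizygous female) becomes missing; the number of such coercions is
#' reported in a warning. Samples of unknown sex get missing genotypes with
#' unknown ploidy at Z loci.
#'
#' @param path VCF file (plain or gzipped).
#' @param sex_map optional named character vector mapping sample id to
#'   "M"/"F"/"U". When NULL, all samples are treated as diploid everywhere.
#' @param z_chroms chromosome names treated as Z (hemizygous in females).
#' @return A [genotype_matrix()].
#' @export
read_vcf_biallelic <- function(path, sex_map = NULL,
                               z_chroms = c("Z", "Z_1")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- as.integer(fix$POS)
  # sortedness: per chromosome non-decreasing, chromosome blocks contiguous
  rl <- rle(fix$CHROM)
  if (anyDuplicated(rl$values)) {
    dup <- rl$values[duplicated(rl$values)][1]
    idx <- which(fix$CHROM == dup)
    idx <- idx[which(diff(idx) > 1)[1] + 1]
    stop(sprintf("VCF not sorted: chromosome block for %s is not contiguous (record %s:%s)",
                 dup, fix$CHROM[idx], fix$POS[idx]))
  }
  same <- fix$CHROM[-1] == fix$CHROM[-length(pos)]
  bad <- which(same & diff(pos) < 0)
  if (length(bad)) {
    stop(sprintf("VCF not sorted: record %s:%d follows position %d",
                 fix$CHROM[bad[1] + 1], pos[bad[1] + 1], pos[bad[1]]))
  }
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  samples <- colnames(gt)
  nl <- nrow(fix); ns <- length(samples)
  counts <- matrix(NA_integer_, ns, nl)
  ploidy <- matrix(2L, ns, nl)
  if (nl > 0) {
    parsed <- parse_gt_counts(as.vector(gt))  # locus-major
    cnt <- matrix(parsed$count, nl, ns)
    cpl <- matrix(parsed$coded_ploidy, nl, ns)
    counts <- t(cnt)
    ploidy <- t(cpl)
    ploidy[ploidy > 2L] <- 2L
    is_z <- fix$CHROM %in% z_chroms
    if (any(is_z)) {
      sex <- if (is.null(sex_map)) setNames(rep("M", ns), samples) else {
        s <- sex_map[samples]
        s[is.na(s)] <- "U"
        s
      }
      zcols <- which(is_z)
      n_het_dropped <- 0L
      for (i in which(sex == "F")) {
        ci <- counts[i, zcols]
        pl <- ploidy[i, zcols]
        dip <- !is.na(ci) & pl == 2L
        het <- dip & ci == 1L
        n_het_dropped <- n_het_dropped + sum(het)
        ci[het] <- NA_integer_
        ci[dip & ci == 2L] <- 1L
        counts[i, zcols] <- ci
        ploidy[i, zcols] <- 1L
      }
      if (n_het_dropped > 0) {
        warning(sprintf("%d diploid-coded heterozygous female Z genotypes set to missing",
                        n_het_dropped))
      }
      if (any(sex == "U")) {
        counts[sex == "U", zcols] <- NA_integer_
        ploidy[sex == "U", zcols] <- NA_integer_
        warning(sprintf("%d sample(s) of unknown sex: Z genotypes set to missing with unknown ploidy",
                        sum(sex == "U")))
      }
    }
  }
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(counts, loci, samples, ploidy)
}

#' Write a genotype matrix as VCF
#'
#' Counts are encoded as unphased diploid GT fields ("0/0", "0/1", "1/1"),
#' haploid entries as "0"/"1", missing as "./." (or "." for haploid).
#' Output is bgzip/gzip-compressed (`.vcf.gz` appended unless present).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return The path written, invisibly.
#' @export
write_vcf_gm <- function(gm, path) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  nl <- nrow(gm$loci)
  code1 <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(NA_character_, nl, length(gm$samples))
  for (i in seq_along(gm$samples)) {
    ci <- gm$counts[i, ]
    pl <- gm$ploidy[i, ]
    g <- ifelse(is.na(pl) | pl == 2L,
                ifelse(is.na(ci), "./.", code1[as.character(ci)]),
                ifelse(is.na(ci), ".", as.character(ci)))
    gt[, i] <- g
  }
  colnames(gt) <- gm$samples
  gt <- cbind(FORMAT = rep("GT", nl), gt)
  fix <- cbind(CHROM = as.character(gm$loci$chrom),
               POS = as.character(gm$loci$pos),
               ID = rep(NA_character_, nl),
               REF = gm$loci$ref, ALT = gm$loci$alt,
               QUAL = rep(NA_character_, nl),
               FILTER = rep("PASS", nl), INFO = rep(NA_character_, nl))
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  out <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}

#' Thin loci to at most one per fixed-origin window
#'
#' Windows are `[k*window_bp + 1, (k+1)*window_bp]` per chromosome (first
#' window starts at position 1); the lowest-position locus in each nonempty
#' window is retained.
#'
#' @param gm a [genotype_matrix()].
#' @param window_bp window size in bp (> 0); default 10 kb, the spacing used
#'   to reduce physical linkage among diagnostic SNPs.
#' @export
thin_by_window <- function(gm, window_bp = 10000L) {
  stopifnot(window_bp > 0)
  if (nrow(gm$loci) == 0) return(gm)
  win <- (gm$loci$pos - 1L) %/% as.integer(window_bp)
  key <- paste(gm$loci$chrom, win)
  keep <- !duplicated(key)  # loci sorted by pos within chrom, so first = lowest
  gm_subset(gm, loci = keep)
}

#' Read gene models from GFF3 and attach flanked search intervals
#'
#' Keeps `gene` features only. Each gene's search interval is
#' `[max(1, start - flank_bp), end + flank_bp]`, 1-based inclusive, to
#' capture potential regulatory substitutions around the reading frame.
#'
#' @param path GFF3 file.
#' @param flank_bp flank added on both sides (default 5,000 bp).
#' @return data.frame with gene_id, chrom, start, end, strand,
#'   search_start, search_end.
#' @export
read_gff_genes <- function(path, flank_bp = 5000L) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                 which(body)[nf != 9][1], nf[nf != 9][1]))
  }
  m <- do.call(rbind, fields)
  is_gene <- m[, 3] == "gene"
  m <- m[is_gene, , drop = FALSE]
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end) || any(start > end)) {
    stop("malformed GFF3 gene coordinates")
  }
  id <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  noid <- !grepl("ID=", m[, 9])
  id[noid] <- paste0("gene", which(noid))
  data.frame(gene_id = id, chrom = m[, 1], start = start, end = end,
             strand = m[, 7],
             search_start = pmax(1L, start - as.integer(flank_bp)),
             search_end = end + as.integer(flank_bp),
             stringsAsFactors = FALSE)
}

#' Read a sample metadata table
#'
#' Tab-separated with header; expects columns sample_id, population_label and
#' (for transect samples) latitude/longitude; optional sex and mitotype.
#'
#' @param path TSV file.
#' @export
read_sample_table <- function(path) {
  st <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population_label") %in% names(st))) {
    stop("sample table needs sample_id and population_label columns")
  }
  if (anyDuplicated(st$sample_id)) stop("duplicate sample ids in sample table")
  st
}

#' Write a sample metadata table
#' @param st data.frame as from [read_sample_table()].
#' @param path output TSV path.
#' @export
write_sample_table <- function(st, path) {
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
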