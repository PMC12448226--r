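#' Configuration for the synthetic hybrid-zone dataset
#'
#' Defines the statistical structure the analysis pipeline assumes: two
#' allopatric parental panels fixed for alternative alleles at diagnostic
#' loci, admixed transect samples whose genome-wide ancestry follows a
#' sigmoid cline along a 1-D transect, an mtDNA haplotype system with three
#' clades, and an optional Z-linked recombination-suppressed inversion block
#' segregating as three multilocus states.
#'
#' @param n_p0,n_p1 allopatric panel sizes (defaults 15 and 11, the panel
#'   sizes of the chickadee system this generator emulates).
#' @param n_transect number of admixed transect samples.
#' @param L_diag number of species-diagnostic loci.
#' @param L_background number of non-diagnostic loci.
#' @param chroms data.frame with columns name, length, is_z.
#' @param transect_km transect length in km.
#' @param cline_center_km,cline_width_km geography of the simulated
#'   genome-wide ancestry cline (sigmoid centre and width, km).
#' @param q_concentration Beta concentration of per-sample ancestry around
#'   the sigmoid expectation (larger = tighter).
#' @param F_bg Balding-Nichols drift parameter for background allele
#'   frequencies between the panels (0 = shared frequencies).
#' @param inversion optional list(chrom, start, end, freqs) where freqs are
#'   the probabilities of the AA/AB/BB inversion haplotype-pair states among
#'   transect samples.
#' @param mt_clades labels of the three mtDNA clades; the first is the
#'   P0-side clade, the second the P1-side clade carried by this transect,
#'   the third an out-of-transect P1 clade present in the P1 panel.
#' @param mt_variants number of haploid mtDNA variants emitted on a "MT"
#'   pseudo-chromosome.
#' @param noise_rate per-genotype flip probability applied inside the
#'   inversion block and to mtDNA patterns (genotyping-error stand-in).
#' @param seed RNG seed; a fixed seed fixes every emitted object exactly.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_p0 = 15L, n_p1 = 11L, n_transect = 120L,
                         L_diag = 1000L, L_background = 400L,
                         chroms = data.frame(
                           name = c("chr1", "chr2", "Z_1"),
                           length = c(6e6, 4e6, 5e6),
                           is_z = c(FALSE, FALSE, TRUE)),
                         transect_km = 100, cline_center_km = 50,
                         cline_width_km = 20, q_concentration = 50,
                         F_bg = 0.05, inversion = NULL,
                         mt_clades = c("P0_mt", "P1_east", "P1_west"),
                         mt_variants = 30L, noise_rate = 0.01,
                         seed = 1L) {
  stopifnot(n_p0 > 0, n_p1 > 0, n_transect > 0, L_diag > 0,
            L_background >= 0, transect_km > 0, cline_width_km >= 0,
            length(mt_clades) == 3)
  if (!is.null(inversion)) {
    stopifnot(inversion$chrom %in% chroms$name,
              inversion$start >= 1,
              inversion$end <= chroms$length[chroms$name == inversion$chrom],
              length(inversion$freqs) == 3,
              abs(sum(inversion$freqs) - 1) < 1e-8)
  }
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# Deterministic locus layout shared by panels and transect: positions,
# diagnostic flags, background panel frequencies, mtDNA clade patterns and
# sex assignments. Uses its own RNG substream so every generator sees the
# same layout for the same config.
synth_layout <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  nch <- nrow(cfg$chroms)
  # diagnostic loci: 10kb grid (one per thinning window) spread over chroms
  per <- diff(round(seq(0, cfg$L_diag, length.out = nch + 1)))
  diag_loci <- do.call(rbind, lapply(seq_len(nch), function(i) {
    if (per[i] == 0) return(NULL)
    pos <- 1L + (seq_len(per[i]) - 1L) * 10000L
    stopifnot(max(pos) <= cfg$chroms$length[i])
    data.frame(chrom = cfg$chroms$name[i], pos = pos, stringsAsFactors = FALSE)
  }))
  diag_loci$diagnostic <- TRUE
  bg <- NULL
  if (cfg$L_background > 0) {
    perb <- diff(round(seq(0, cfg$L_background, length.out = nch + 1)))
    bg <- do.call(rbind, lapply(seq_len(nch), function(i) {
      if (perb[i] == 0) return(NULL)
      data.frame(chrom = cfg$chroms$name[i],
                 pos = sort(sample.int(cfg$chroms$length[i] - 3L, perb[i])) + 3L,
                 stringsAsFactors = FALSE)
    }))
    bg$diagnostic <- FALSE
  }
  loci <- rbind(diag_loci, bg)
  loci <- loci[order(match(loci$chrom, cfg$chroms$name), loci$pos), ]
  dup <- duplicated(locus_key(loci$chrom, loci$pos))
  loci <- loci[!dup, ]
  L <- nrow(loci)
  ra <- t(vapply(seq_len(L), function(i) sample(c("A", "C", "G", "T"), 2), character(2)))
  loci$ref <- ra[, 1]; loci$alt <- ra[, 2]
  # background allele frequencies: Balding-Nichols around a shared ancestral p
  p_anc <- stats::runif(L, 0.1, 0.9)
  Fst <- cfg$F_bg
  draw_bn <- function() {
    if (Fst <= 0) return(p_anc)
    stats::rbeta(L, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst)
  }
  pA <- draw_bn(); pB <- draw_bn()
  is_diag <- loci$diagnostic
  pA[is_diag] <- 0; pB[is_diag] <- 1  # alt allele is the P1-derived allele
  # mtDNA clade patterns: three distinct presence/absence patterns + structure
  M <- cfg$mt_variants
  pat <- matrix(0L, 3, M)
  third <- max(1L, M %/% 3L)
  pat[2, seq_len(2 * third)] <- 1L                 # P1 clades share a block
  pat[3, seq_len(2 * third)] <- 1L
  pat[3, (2 * third + 1):M] <- 1L                  # east/west P1 split block
  rownames(pat) <- cfg$mt_clades
  is_z <- cfg$chroms$is_z[match(loci$chrom, cfg$chroms$name)]
  list(loci = loci, pA = pA, pB = pB, mt_pat = pat, is_z = is_z)
}

mt_loci_df <- function(cfg) {
  data.frame(chrom = "MT", pos = seq_len(cfg$mt_variants) * 100L,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

# genotypes for one set of samples given per-locus alt-allele probabilities
draw_genotypes <- function(p, ploidy) {
  # p: samples x loci matrix of alt-allele probabilities, ploidy same shape
  n <- length(p)
  matrix(stats::rbinom(n, as.vector(ploidy), as.vector(p)), nrow(p), ncol(p))
}

assign_sexes <- function(n) rep(c("M", "F"), length.out = n)

#' Generate the two allopatric parental panels
#'
#' Diagnostic loci are fixed for the reference allele (count 0) in the P0
#' panel and for the alternate allele in the P1 panel; background loci are
#' drawn from Balding-Nichols panel frequencies. The P1 panel carries two
#' mtDNA clades (east and west) to mirror intraspecific mtDNA structure.
#'
#' @param cfg a [synth_config()].
#' @return list(gm = genotype_matrix including an "MT" haploid
#'   pseudo-chromosome, samples = sample table).
#' @export
make_parental_panels <- function(cfg) {
  lay <- synth_layout(cfg)
  set.seed(cfg$seed + 1L)
  n0 <- cfg$n_p0; n1 <- cfg$n_p1
  ids <- c(sprintf("P0_%02d", seq_len(n0)), sprintf("P1_%02d", seq_len(n1)))
  sex <- c(assign_sexes(n0), assign_sexes(n1))
  L <- nrow(lay$loci)
  ploidy <- matrix(2L, n0 + n1, L)
  ploidy[, lay$is_z][sex == "F", ] <- 1L
  p <- rbind(matrix(lay$pA, n0, L, byrow = TRUE),
             matrix(lay$pB, n1, L, byrow = TRUE))
  counts <- draw_genotypes(p, ploidy)
  # mtDNA: P0 panel all first clade; P1 panel split east/west
  mt_clade <- c(rep(cfg$mt_clades[1], n0),
                rep(cfg$mt_clades[2:3], length.out = n1))
  mt <- lay$mt_pat[mt_clade, , drop = FALSE]
  flip <- matrix(stats::runif(length(mt)) < cfg$noise_rate, nrow(mt))
  mt[flip] <- 1L - mt[flip]
  loci <- rbind(lay$loci[, c("chrom", "pos", "ref", "alt")], mt_loci_df(cfg))
  counts <- cbind(counts, mt)
  ploidy <- cbind(ploidy, matrix(1L, n0 + n1, ncol(mt)))
  gm <- genotype_matrix(counts, loci, ids, ploidy)
  samples <- data.frame(
    sample_id = ids,
    population_label = c(rep("allopatric-P0", n0), rep("allopatric-P1", n1)),
    latitude = NA_real_, longitude = NA_real_, sex = sex,
    mitotype = mt_clade, stringsAsFactors = FALSE)
  list(gm = gm, samples = samples,
       diagnostic = lay$loci$diagnostic)
}

#' Draw one sample's diagnostic genotypes for a named hybrid class
#'
#' Counts are on the P1-allele scale (0 = homozygous P0). F1 individuals are
#' heterozygous at every diagnostic locus; F2 draw {0,1,2} with Mendelian
#' probabilities 1/4, 1/2, 1/4; first-generation backcrosses draw the two
#' classes adjacent to their recurrent parent with probability 1/2 each; a
#' late backcross of generation `g` carries each allele copy from P1 with
#' probability 2^-g.
#'
#' @param class one of "P0","P1","F1","F2","BC1_P0","BC1_P1","late_backcross".
#' @param L number of diagnostic loci.
#' @param g backcross generation (late_backcross only).
#' @return integer vector of P1-allele counts, length L.
#' @export
make_hybrid_class <- function(class, L, g = NULL) {
  switch(class,
    P0 = rep(0L, L),
    P1 = rep(2L, L),
    F1 = rep(1L, L),
    F2 = sample(0:2, L, replace = TRUE, prob = c(0.25, 0.5, 0.25)),
    BC1_P0 = sample(0:1, L, replace = TRUE),
    BC1_P1 = sample(1:2, L, replace = TRUE),
    late_backcross = {
      if (is.null(g)) stop("late_backcross needs a generation g")
      stats::rbinom(L, 2L, 2^(-g))
    },
    stop(sprintf("unknown hybrid class '%s'", class))
  )
}

#' Generate an admixed transect
#'
#' Each sample receives a position x on [0, transect_km]; its genome-wide
#' ancestry proportion q is drawn (Beta) around the sigmoid
#' 1/(1 + exp(-4 (x - c) / w)). Each diagnostic allele copy is P1-derived
#' independently with probability q; background loci interpolate panel
#' frequencies; the mtDNA clade is P1-type with probability q; and an
#' optional inversion block overrides diagnostic genotypes inside its region
#' with one of three non-recombined haplotype-pair states drawn per sample.
#'
#' @param cfg a [synth_config()].
#' @return list(gm, samples) where samples carries x_km, q_true, the true
#'   mitotype and (if configured) the true inversion state.
#' @export
make_transect <- function(cfg) {
  lay <- synth_layout(cfg)
  set.seed(cfg$seed + 2L)
  n <- cfg$n_transect
  ids <- sprintf("T_%03d", seq_len(n))
  sex <- assign_sexes(n)
  x <- sort(stats::runif(n, 0, cfg$transect_km))
  mu <- if (cfg$cline_width_km <= 0) as.numeric(x > cfg$cline_center_km) else
    expit(4 * (x - cfg$cline_center_km) / cfg$cline_width_km)
  k <- cfg$q_concentration
  eps <- 1e-6
  mu <- pmin(pmax(mu, eps), 1 - eps)
  q <- stats::rbeta(n, mu * k, (1 - mu) * k)
  L <- nrow(lay$loci)
  ploidy <- matrix(2L, n, L)
  ploidy[, lay$is_z][sex == "F", ] <- 1L
  p <- matrix(lay$pA, n, L, byrow = TRUE) +
    q * (matrix(lay$pB, n, L, byrow = TRUE) - matrix(lay$pA, n, L, byrow = TRUE))
  counts <- draw_genotypes(p, ploidy)
  inv_state <- rep(NA_character_, n)
  if (!is.null(cfg$inversion)) {
    inv <- cfg$inversion
    in_reg <- lay$loci$chrom == inv$chrom & lay$loci$pos >= inv$start &
      lay$loci$pos <= inv$end & lay$loci$diagnostic
    states <- c("AA", "AB", "BB")
    inv_state <- sample(states, n, replace = TRUE, prob = inv$freqs)
    hap_count <- c(AA = 0L, AB = 1L, BB = 2L)[inv_state]
    for (i in seq_len(n)) {
      pl <- ploidy[i, in_reg]
      if (all(pl == 1L)) {
        # hemizygous female: one haplotype copy, B with the implied allele freq
        hap <- stats::rbinom(1, 1, inv$freqs[3] + inv$freqs[2] / 2)
        g <- rep(hap, sum(in_reg))
        inv_state[i] <- if (hap == 1L) "B" else "A"
      } else {
        g <- rep(hap_count[i], sum(in_reg))
      }
      flip <- stats::runif(length(g)) < cfg$noise_rate
      if (any(flip)) {
        g[flip] <- (g[flip] + sample.int(2L, sum(flip), replace = TRUE)) %%
          (pl[flip] + 1L)
      }
      counts[i, in_reg] <- pmin(g, pl)
    }
  }
  mt_is_p1 <- stats::rbinom(n, 1, q) == 1
  mt_clade <- ifelse(mt_is_p1, cfg$mt_clades[2], cfg$mt_clades[1])
  mt <- lay$mt_pat[mt_clade, , drop = FALSE]
  flip <- matrix(stats::runif(length(mt)) < cfg$noise_rate, nrow(mt))
  mt[flip] <- 1L - mt[flip]
  loci <- rbind(lay$loci[, c("chrom", "pos", "ref", "alt")], mt_loci_df(cfg))
  counts <- cbind(counts, mt)
  ploidy <- cbind(ploidy, matrix(1L, n, ncol(mt)))
  gm <- genotype_matrix(counts, loci, ids, ploidy)
  # toy lat/lon consistent with x: transect along a meridian
  lat0 <- 40
  samples <- data.frame(
    sample_id = ids, population_label = "transect",
    latitude = lat0 + x / 111.195, longitude = -90,
    sex = sex, mitotype = mt_clade, x_km = x, q_true = q,
    inv_state = inv_state, stringsAsFactors = FALSE)
  list(gm = gm, samples = samples, diagnostic = lay$loci$diagnostic)
}

#' Generate a toy GFF3 of gene models for annotation tests
#'
#' Places `n_genes` non-overlapping genes per chromosome, deterministic given
#' the config seed.
#'
#' @param cfg a [synth_config()].
#' @param n_genes genes per chromosome.
#' @export
make_toy_genes <- function(cfg, n_genes = 5L) {
  set.seed(cfg$seed + 3L)
  do.call(rbind, lapply(seq_len(nrow(cfg$chroms)), function(i) {
    len <- cfg$chroms$length[i]
    span <- len %/% (n_genes + 1L)
    start <- (seq_len(n_genes) - 1L) * span + span %/% 4L + 1L
    end <- start + span %/% 3L
    data.frame(gene_id = sprintf("%s_g%02d", cfg$chroms$name[i], seq_len(n_genes)),
               chrom = cfg$chroms$name[i], start = start, end = pmin(end, len),
               strand = rep(c("+", "-"), length.out = n_genes),
               stringsAsFactors = FALSE)
  }))
}

#' Write a complete synthetic dataset (VCF + metadata TSV + GFF3)
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pan <- make_parental_panels(cfg)
  tra <- make_transect(cfg)
  gm <- gm_rbind(pan$gm, tra$gm)
  vcf <- file.path(dir, "synthetic.vcf")
  vcf <- write_vcf_gm(gm, vcf)
  common <- c("sample_id", "population_label", "latitude", "longitude",
              "sex", "mitotype")
  meta <- rbind(cbind(pan$samples[common], x_km = NA_real_, q_true = NA_real_,
                      inv_state = NA_character_),
                tra$samples[c(common, "x_km", "q_true", "inv_state")])
  meta_path <- file.path(dir, "samples.tsv")
  write_sample_table(meta, meta_path)
  genes <- make_toy_genes(cfg)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               sprintf("%s\thzclines\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$start, genes$end, genes$strand,
                       genes$gene_id)), gff)
  list(vcf = vcf, samples = meta_path, gff = gff)
}
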