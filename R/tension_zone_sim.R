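#' Tension-zone simulation configuration
#'
#' Forward-time individual-based stepping-stone model of a 1-D hybrid zone:
#' D demes of N diploids with L unlinked diagnostic loci, nearest-neighbour
#' migration, viability selection against ancestry-heterozygous genotypes
#' (underdominance) plus an ecotonal term penalizing mismatch with the side
#' of a moving environmental boundary, and soft selection (each deme
#' contributes exactly N offspring).
#'
#' @param D number of demes (>= 10).
#' @param N diploid individuals per deme.
#' @param L unlinked diagnostic loci under selection.
#' @param L_neutral additional unlinked neutral loci, used to measure
#'   genome-wide background ancestry (the reference against which
#'   per-locus genomic clines are fitted).
#' @param s selection coefficient against heterozygous loci (>= 0); an
#'   individual heterozygous at a fraction H of its selected loci has
#'   fitness factor (1 - s)^(H * L).
#' @param s_env ecotonal coefficient (>= 0): fitness factor
#'   (1 - s_env)^(fraction of allele copies mismatching the boundary side).
#' @param m probability an individual migrates to an adjacent deme per
#'   generation (reflecting edges), in [0, 0.5].
#' @param r environmental boundary movement rate (demes/generation, >= 0).
#' @param G generations to simulate.
#' @param seed RNG seed; a fixed seed fixes the whole trajectory.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(D = 40L, N = 50L, L = 10L, L_neutral = 10L, s = 0,
                       s_env = 0, m = 0.1, r = 0, G = 100L, seed = 1L) {
  stopifnot(D >= 10, N >= 2, L >= 1, L_neutral >= 0, s >= 0, s < 1,
            s_env >= 0, s_env < 1, m >= 0, m <= 0.5, r >= 0, G >= 0)
  cfg <- list(D = as.integer(D), N = as.integer(N), L = as.integer(L),
              L_neutral = as.integer(L_neutral),
              s = s, s_env = s_env, m = m, r = r, G = as.integer(G),
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Initialize a secondary-contact zone
#'
#' Demes left of the midpoint are fixed for allele 0 at every locus
#' (selected and neutral), demes right of it for allele 2 (two P1 copies);
#' the environmental boundary starts at the midpoint.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_state`: generation, deme (per individual),
#'   geno (individuals x L allele counts), boundary0.
#' @export
init_zone <- function(cfg) {
  set.seed(cfg$seed)
  deme <- rep(seq_len(cfg$D), each = cfg$N)
  half <- cfg$D / 2
  geno <- matrix(ifelse(deme > half, 2L, 0L), length(deme),
                 cfg$L + cfg$L_neutral)
  st <- list(generation = 0L, deme = deme, geno = geno,
             boundary0 = half + 0.5)
  class(st) <- "sim_state"
  st
}

boundary_at <- function(state, cfg) state$boundary0 + cfg$r * state$generation

#' Advance the simulation one generation
#'
#' Generation cycle: (1) migration — each individual moves to a uniformly
#' chosen adjacent deme with probability m, staying put when the move would
#' leave the habitat (reflecting edges); (2) viability selection — fitness
#' `(1 - s)^(number of heterozygous loci) * (1 - s_env)^(mismatch fraction)`
#' where the mismatch fraction is the share of allele copies not matching
#' the side of the moving boundary the deme is on; (3) reproduction —
#' within-deme random mating with fitness-proportional parent sampling
#' (with replacement), free recombination among loci, exactly N offspring
#' per deme. An empty post-migration deme draws parents from the nearest
#' occupied deme.
#'
#' @param state a `sim_state`.
#' @param cfg the [sim_config()].
#' @return the next `sim_state`.
#' @export
step_zone <- function(state, cfg) {
  D <- cfg$D; N <- cfg$N; L <- cfg$L
  Ltot <- cfg$L + cfg$L_neutral
  sel <- seq_len(L)
  n_ind <- length(state$deme)
  # migration
  deme <- state$deme
  move <- stats::runif(n_ind) < cfg$m
  dir <- sample(c(-1L, 1L), n_ind, replace = TRUE)
  target <- deme + ifelse(move, dir, 0L)
  target[target < 1L | target > D] <- deme[target < 1L | target > D]
  # selection weights
  b <- boundary_at(state, cfg)
  het <- rowSums(state$geno[, sel, drop = FALSE] == 1L)
  p1_copies <- rowSums(state$geno[, sel, drop = FALSE])
  left_of_b <- target < b
  mismatch <- ifelse(left_of_b, p1_copies, 2L * L - p1_copies) / (2 * L)
  w <- (1 - cfg$s)^het * (1 - cfg$s_env)^mismatch
  # reproduction: N offspring per deme, parents sampled with prob ~ fitness
  new_geno <- matrix(0L, D * N, Ltot)
  occupied <- sort(unique(target))
  for (d in seq_len(D)) {
    src <- d
    if (!(d %in% occupied)) src <- occupied[which.min(abs(occupied - d))]
    pool <- which(target == src)
    wts <- w[pool]
    if (all(wts == 0)) wts <- rep(1, length(pool))
    p1 <- pool[sample.int(length(pool), N, replace = TRUE, prob = wts)]
    p2 <- pool[sample.int(length(pool), N, replace = TRUE, prob = wts)]
    g1 <- state$geno[p1, , drop = FALSE]
    g2 <- state$geno[p2, , drop = FALSE]
    off <- matrix(stats::rbinom(N * Ltot, 1L, as.vector(g1) / 2), N, Ltot) +
      matrix(stats::rbinom(N * Ltot, 1L, as.vector(g2) / 2), N, Ltot)
    new_geno[(d - 1L) * N + seq_len(N), ] <- off
  }
  structure(list(generation = state$generation + 1L,
                 deme = rep(seq_len(D), each = N),
                 geno = new_geno, boundary0 = state$boundary0),
            class = "sim_state")
}

#' Run a tension-zone simulation
#'
#' @param cfg a [sim_config()].
#' @param record_at generations at which to record the per-deme P1 allele
#'   frequency profile over the selected loci (optional).
#' @return final `sim_state`, with any recorded profiles attached as
#'   attribute "profiles" (matrix: recorded generation x deme).
#' @export
run_zone <- function(cfg, record_at = NULL) {
  st <- init_zone(cfg)
  profiles <- if (length(record_at)) {
    matrix(NA_real_, length(record_at), cfg$D,
           dimnames = list(as.character(record_at), NULL))
  } else NULL
  sel <- seq_len(cfg$L)
  grab <- function(st) {
    tapply(rowSums(st$geno[, sel, drop = FALSE]) / (2 * cfg$L),
           st$deme, mean)[as.character(seq_len(cfg$D))]
  }
  if (!is.null(profiles) && 0 %in% record_at) profiles["0", ] <- grab(st)
  for (g in seq_len(cfg$G)) {
    st <- step_zone(st, cfg)
    if (!is.null(profiles) && g %in% record_at) {
      profiles[as.character(g), ] <- grab(st)
    }
  }
  if (!is.null(profiles)) attr(st, "profiles") <- profiles
  st
}

#' Convert a simulation state to a genotype matrix + sample table
#'
#' Loci are placed on a synthetic chromosome "sim1" at 1 Mb spacing
#' (unlinked by construction), selected loci first, then neutral loci; deme
#' index doubles as the transect position in km.
#'
#' @param state a `sim_state`.
#' @param cfg the [sim_config()].
#' @export
sim_to_genotype_matrix <- function(state, cfg) {
  n <- length(state$deme)
  ids <- sprintf("sim_%04d", seq_len(n))
  Ltot <- cfg$L + cfg$L_neutral
  loci <- data.frame(chrom = "sim1", pos = seq_len(Ltot) * 1000000L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(state$geno, loci, ids)
  samples <- data.frame(sample_id = ids, population_label = "sim",
                        latitude = NA_real_, longitude = NA_real_,
                        sex = "U", x_km = as.numeric(state$deme),
                        stringsAsFactors = FALSE)
  list(gm = gm, samples = samples)
}

# width of the selected-loci ancestry profile via the geographic cline model
sim_cline_width <- function(state, cfg, burn = 1000L, keep = 2000L,
                            seed = 1L) {
  h <- rowSums(state$geno[, seq_len(cfg$L), drop = FALSE]) / (2 * cfg$L)
  fit <- fit_geographic_cline(as.numeric(state$deme), h, "none",
                              burn = burn, keep = keep, seed = seed)
  fit$model$width
}

#' Steepness-vs-selection/movement experiment grid
#'
#' For every (s, r) cell: simulate the zone, take each individual's true
#' P1-allele fraction over all loci (selected + neutral) as its genome-wide
#' background hybrid index — the same construction the empirical pipeline
#' uses — fit a Bayesian genomic cline per selected locus against it, and
#' average the posterior median steepness v over loci and replicates (the
#' median is used because the right-skewed posterior of v inflates the mean
#' for weakly informed loci); also fit a geographic cline (no tails) to the
#' final selected-loci ancestry profile for the zone width. The base
#' configuration should have L_neutral well above L so the background is
#' dominated by neutral diffusion, and s_env > 0 for zone movement to
#' matter (movement acts through the ecotonal term).
#'
#' @param s_values,r_values grid values for selection strength and boundary
#'   movement rate.
#' @param replicates replicate simulations per cell.
#' @param cfg_base a [sim_config()] providing all other parameters.
#' @param burn,keep MCMC iterations for the per-locus cline fits.
#' @param sample_max at most this many individuals (sampled evenly along the
#'   zone) enter the cline fits, to bound runtime.
#' @return data.frame: s, r, rep, v_bar, width.
#' @export
run_experiment_grid <- function(s_values, r_values, replicates = 2L,
                                cfg_base = sim_config(),
                                burn = 500L, keep = 1000L,
                                sample_max = 200L) {
  stopifnot(cfg_base$L_neutral >= 1)
  cells <- expand.grid(s = s_values, r = r_values, rep = seq_len(replicates))
  res <- lapply(seq_len(nrow(cells)), function(i) {
    s <- cells$s[i]; r <- cells$r[i]; repi <- cells$rep[i]
    cfg <- cfg_base
    cfg$s <- s; cfg$r <- r
    cfg$seed <- cfg_base$seed + 1000L * i
    st <- run_zone(cfg)
    h <- rowSums(st$geno) / (2 * ncol(st$geno))
    idx <- if (length(h) > sample_max) {
      round(seq(1, length(h), length.out = sample_max))
    } else seq_along(h)
    vs <- vapply(seq_len(cfg$L), function(l) {
      fit_genomic_cline(st$geno[idx, l], rep(2L, length(idx)), h[idx],
                        burn = burn, keep = keep,
                        seed = cfg$seed + l)$v_median
    }, numeric(1))
    width <- sim_cline_width(st, cfg, seed = cfg$seed)
    data.frame(s = s, r = r, rep = repi, v_bar = mean(vs), width = width)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
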