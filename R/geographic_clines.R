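KM_PER_DEG <- 111.195  # pi * 6371 / 180

#' Project sampling coordinates onto a transect line
#'
#' Orthogonal projection in a local equirectangular plane (longitudes scaled
#' by the cosine of the line's mean latitude), returning the signed distance
#' in km of each point's foot from the line's start. Adequate for transects
#' spanning a few degrees of latitude.
#'
#' @param lat,lon sample coordinates, decimal degrees (vectorized).
#' @param line numeric c(lat1, lon1, lat2, lon2): the transect endpoints.
#' @return numeric vector of distances (km) along the line from its start.
#' @export
project_to_transect <- function(lat, lon, line) {
  stopifnot(length(line) == 4)
  if (line[1] == line[3] && line[2] == line[4]) stop("line endpoints must be distinct")
  mlat <- (line[1] + line[3]) / 2
  sx <- KM_PER_DEG * cos(mlat * pi / 180)
  px <- (lon - line[2]) * sx
  py <- (lat - line[1]) * KM_PER_DEG
  dx <- (line[4] - line[2]) * sx
  dy <- (line[3] - line[1]) * KM_PER_DEG
  len <- sqrt(dx^2 + dy^2)
  (px * dx + py * dy) / len
}

#' Geographic cline model
#'
#' Sigmoid cline in an ancestry proxy along a transect, with optional
#' exponential introgression tails. The central shape is
#' `S(x) = 1 / (1 + exp(-4 (x - c) / w))`; `w` is the inverse of the maximum
#' slope. A left tail replaces the shape for `x <= c - deltaL` with
#' `S(c - deltaL) * exp(4 tauL (x - (c - deltaL)) / (w (1 + exp(-4 deltaL / w))))`
#' (continuous at the junction); the right tail is the mirror image.
#' `tail_config` is one of "none", "left", "right", "mirror" (both tails
#' share delta and tau) or "both" (independent tails).
#'
#' @param pmin,pmax proxy values at the cline ends (pmin < pmax).
#' @param centre cline centre (km).
#' @param width cline width (km, > 0).
#' @param tail_config tail configuration.
#' @param deltaL,tauL,deltaR,tauR tail parameters: distance from the centre
#'   where the tail begins (>= 0) and tail-slope ratio in (0, 1].
#' @param decreasing TRUE for a cline falling with x (the mirror image of
#'   the canonical increasing shape, with tails swapped); pmin < pmax always.
#' @return list of class `geo_cline_model`.
#' @export
geo_cline_model <- function(pmin = 0, pmax = 1, centre, width,
                            tail_config = "none",
                            deltaL = NA, tauL = NA, deltaR = NA, tauR = NA,
                            decreasing = FALSE) {
  stopifnot(pmin < pmax, width > 0,
            tail_config %in% c("none", "left", "right", "mirror", "both"))
  m <- list(pmin = pmin, pmax = pmax, centre = centre, width = width,
            tail_config = tail_config, deltaL = deltaL, tauL = tauL,
            deltaR = deltaR, tauR = tauR, decreasing = decreasing)
  class(m) <- "geo_cline_model"
  m
}

swap_tail_config <- function(tc) {
  switch(tc, left = "right", right = "left", tc)
}

# shape in [0, 1]; decreasing clines are the reflection of the canonical
# increasing shape about the centre, which swaps the tail sides
shape_eval <- function(x, centre, width, tail_config, deltaL, tauL,
                       deltaR, tauR, decreasing = FALSE) {
  if (!decreasing) {
    cline_shape(x, centre, width, tail_config, deltaL, tauL, deltaR, tauR)
  } else {
    cline_shape(2 * centre - x, centre, width, swap_tail_config(tail_config),
                deltaR, tauR, deltaL, tauL)
  }
}

cline_shape <- function(x, centre, width, tail_config,
                        deltaL, tauL, deltaR, tauR) {
  S <- function(z) 1 / (1 + exp(-4 * (z - centre) / width))
  out <- S(x)
  left_on <- tail_config %in% c("left", "mirror", "both")
  right_on <- tail_config %in% c("right", "mirror", "both")
  if (tail_config == "mirror") {
    deltaR <- deltaL; tauR <- tauL
  }
  if (left_on) {
    xl <- centre - deltaL
    i <- x <= xl
    out[i] <- S(xl) *
      exp(4 * tauL * (x[i] - xl) / (width * (1 + exp(-4 * deltaL / width))))
  }
  if (right_on) {
    xr <- centre + deltaR
    i <- x >= xr
    out[i] <- 1 - (1 - S(xr)) *
      exp(-4 * tauR * (x[i] - xr) / (width * (1 + exp(-4 * deltaR / width))))
  }
  out
}

#' Expected proxy value under a geographic cline model
#'
#' @param x transect distance(s), km.
#' @param model a [geo_cline_model()].
#' @export
cline_value <- function(x, model) {
  sh <- shape_eval(x, model$centre, model$width, model$tail_config,
                   model$deltaL, model$tauL, model$deltaR, model$tauR,
                   isTRUE(model$decreasing))
  model$pmin + (model$pmax - model$pmin) * sh
}

#' Ancestry proxy on [0, 1] from PC1 scores (or any ancestry score)
#'
#' Affinely rescales scores so the allopatric P0 panel mean maps to 0 and
#' the P1 panel mean to 1, resolving the sign ambiguity of PC1. Passing
#' per-sample hybrid indices through leaves them essentially unchanged
#' (panel means near 0 and 1).
#'
#' @param score per-sample scores (PC1 coordinates or hybrid indices).
#' @param idx_p0,idx_p1 indices (or logical masks) of the allopatric
#'   reference samples of each side.
#' @export
ancestry_proxy <- function(score, idx_p0, idx_p1) {
  m0 <- mean(score[idx_p0]); m1 <- mean(score[idx_p1])
  if (m0 == m1) stop("reference panels have equal mean scores")
  (score - m0) / (m1 - m0)
}

n_params <- function(tail_config) {
  # pmin, pmax, centre, width, sigma (+2 per independent tail pair)
  5L + switch(tail_config, none = 0L, left = 2L, right = 2L,
              mirror = 2L, both = 4L)
}

#' Fit a geographic cline by Metropolis-Hastings
#'
#' Gaussian observation model around [cline_value()] with an estimated
#' residual SD; componentwise adaptive random-walk MH over the free
#' parameters of the chosen tail configuration. AICc is computed from the
#' maximum log-likelihood visited; the width support interval collects the
#' widths of all draws within two log-likelihood units of that maximum.
#'
#' The cline orientation (rising or falling with x) is detected from the
#' rank correlation of x and y, so reversing the transect direction maps the
#' centre to (length - centre) and leaves the width unchanged.
#'
#' @param x transect distances (km).
#' @param y ancestry proxy per sample.
#' @param tail_config one of "none", "left", "right", "mirror", "both".
#' @param burn,keep MCMC iterations.
#' @param seed RNG seed.
#' @return list of class `geo_cline_fit`: model, sigma, logL (maximum),
#'   AICc, width_interval, n, draws (data.frame of retained parameters and
#'   per-draw log-likelihood).
#' @export
fit_geographic_cline <- function(x, y, tail_config = "none",
                                 burn = 2000L, keep = 4000L, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  if (stats::sd(y) == 0) stop("all proxy values identical: no cline to fit")
  if (!is.null(seed)) set.seed(seed)
  decreasing <- suppressWarnings(
    stats::cor(x, y, method = "spearman")) < 0
  xr <- range(x)
  span <- diff(xr)
  has_l <- tail_config %in% c("left", "mirror", "both")
  has_r <- tail_config %in% c("right", "both")
  # parameter vector (transformed): pmin, pmax, centre, ln width, ln sigma,
  # then ln deltaL, logit tauL, ln deltaR, logit tauR as configured
  nm <- c("pmin", "pmax", "centre", "lnw", "lnsig",
          if (has_l) c("lndL", "ltauL"), if (has_r) c("lndR", "ltauR"))
  init <- c(min(y), max(y), mean(xr), log(span / 4),
            log(max(stats::sd(y) / 4, 1e-3)),
            if (has_l) c(log(span / 4), 0), if (has_r) c(log(span / 4), 0))
  names(init) <- nm
  unpack <- function(par) {
    dL <- if (has_l) exp(par[["lndL"]]) else NA
    tL <- if (has_l) expit(par[["ltauL"]]) else NA
    dR <- if (has_r) exp(par[["lndR"]]) else if (has_l && tail_config == "mirror") exp(par[["lndL"]]) else NA
    tR <- if (has_r) expit(par[["ltauR"]]) else if (has_l && tail_config == "mirror") expit(par[["ltauL"]]) else NA
    list(pmin = par[["pmin"]], pmax = par[["pmax"]], centre = par[["centre"]],
         width = exp(par[["lnw"]]), sigma = exp(par[["lnsig"]]),
         deltaL = dL, tauL = tL, deltaR = dR, tauR = tR)
  }
  loglik <- function(par) {
    p <- unpack(par)
    if (p$pmin >= p$pmax) return(-Inf)
    if (p$centre < xr[1] - span || p$centre > xr[2] + span) return(-Inf)
    if (p$width > 10 * span) return(-Inf)
    mu <- p$pmin + (p$pmax - p$pmin) *
      shape_eval(x, p$centre, p$width, tail_config,
                 p$deltaL, p$tauL, p$deltaR, p$tauR, decreasing)
    sum(stats::dnorm(y, mu, p$sigma, log = TRUE))
  }
  # weak priors keep the posterior proper without constraining the fit
  logprior <- function(par) {
    stats::dnorm(par[["pmin"]], 0, 10, log = TRUE) +
      stats::dnorm(par[["pmax"]], 1, 10, log = TRUE) +
      stats::dnorm(par[["centre"]], mean(xr), 10 * span, log = TRUE) +
      stats::dnorm(par[["lnw"]], log(span / 4), 3, log = TRUE) +
      stats::dnorm(par[["lnsig"]], init[["lnsig"]], 3, log = TRUE) +
      (if (has_l) stats::dnorm(par[["lndL"]], log(span / 4), 3, log = TRUE) +
         stats::dlogis(par[["ltauL"]], log = TRUE) else 0) +
      (if (has_r) stats::dnorm(par[["lndR"]], log(span / 4), 3, log = TRUE) +
         stats::dlogis(par[["ltauR"]], log = TRUE) else 0)
  }
  par <- init
  curL <- loglik(par)
  cur <- curL + logprior(par)
  np <- length(par)
  step <- rep(0.2, np)
  step[3] <- span / 20
  acc_win <- rep(0L, np)
  total <- burn + keep
  draws <- matrix(NA_real_, keep, np)
  drawL <- numeric(keep)
  for (it in seq_len(total)) {
    for (j in seq_len(np)) {
      prop <- par
      prop[j] <- par[j] + stats::rnorm(1, 0, step[j])
      newL <- loglik(prop)
      new <- newL + logprior(prop)
      if (is.finite(new) && log(stats::runif(1)) < new - cur) {
        par <- prop; cur <- new; curL <- newL
        if (it <= burn) acc_win[j] <- acc_win[j] + 1L
      }
    }
    if (it <= burn && it %% 50L == 0L) {
      rate <- acc_win / 50
      step[rate < 0.2] <- step[rate < 0.2] * 0.7
      step[rate > 0.5] <- step[rate > 0.5] * 1.4
      acc_win[] <- 0L
    }
    if (it > burn) {
      draws[it - burn, ] <- par
      drawL[it - burn] <- curL
    }
  }
  colnames(draws) <- nm
  best <- which.max(drawL)
  pbest <- unpack(draws[best, ])
  kpar <- n_params(tail_config)
  nn <- length(x)
  logL <- drawL[best]
  aicc <- -2 * logL + 2 * kpar + 2 * kpar * (kpar + 1) / max(nn - kpar - 1, 1)
  widths <- exp(draws[, "lnw"])
  support <- drawL >= logL - 2
  width_interval <- range(widths[support])
  model <- geo_cline_model(pbest$pmin, pbest$pmax, pbest$centre, pbest$width,
                           tail_config, pbest$deltaL, pbest$tauL,
                           pbest$deltaR, pbest$tauR, decreasing)
  fit <- list(model = model, sigma = pbest$sigma, logL = logL, AICc = aicc,
              width_interval = width_interval, n = nn,
              draws = data.frame(draws, logL = drawL))
  class(fit) <- "geo_cline_fit"
  fit
}

#' Fit all five tail configurations and select the best
#'
#' @param x,y as in [fit_geographic_cline()].
#' @param configs tail configurations to fit.
#' @param ... passed to [fit_geographic_cline()].
#' @return list(fits = named list of fits, best = name of the selected
#'   configuration).
#' @export
fit_geographic_clines <- function(x, y,
                                  configs = c("none", "left", "right",
                                              "mirror", "both"), ...) {
  fits <- lapply(configs, function(cf) fit_geographic_cline(x, y, cf, ...))
  names(fits) <- configs
  list(fits = fits, best = select_model(fits))
}

#' Select the best-supported cline model by AICc
#'
#' Lowest AICc wins; exact ties break toward fewer parameters.
#'
#' @param fits named list of `geo_cline_fit` objects.
#' @return name of the selected fit.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  aicc <- vapply(fits, function(f) f$AICc, numeric(1))
  kpar <- vapply(fits, function(f) n_params(f$model$tail_config), integer(1))
  ord <- order(aicc, kpar)
  names(fits)[ord[1]] %||% as.character(ord[1])
}
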