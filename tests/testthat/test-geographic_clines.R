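test_that("transect projection matches planar geometry", {
  line <- c(40, -90, 41, -90)  # due north, ~111.2 km
  expect_equal(project_to_transect(40, -90, line), 0)
  # perpendicular displacement does not change the along-line distance
  d1 <- project_to_transect(40.5, -90, line)
  d2 <- project_to_transect(40.5, -89.5, line)
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_equal(d1, 111.195 / 2, tolerance = 1e-6)
  # independent planar computation on a small tilted triangle
  km <- 111.195
  mlat <- 40.5
  sx <- km * cos(mlat * pi / 180)
  p <- c((40.3 - 40) * km, (-89.7 - (-90)) * sx)     # (y, x) of the point
  d <- c((41 - 40) * km, (-89.5 - (-90)) * sx)       # direction vector
  expected <- sum(p * d) / sqrt(sum(d^2))
  got <- project_to_transect(40.3, -89.7, c(40, -90, 41, -89.5))
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("ancestry proxy anchors the reference panels at 0 and 1", {
  score <- c(-5, -5.2, 4.8, 5.2, 0.1)
  pr <- ancestry_proxy(score, 1:2, 3:4)
  expect_equal(mean(pr[1:2]), 0)
  expect_equal(mean(pr[3:4]), 1)
  # hybrid indices pass through nearly unchanged
  h <- c(0, 0, 1, 1, 0.42)
  expect_equal(ancestry_proxy(h, 1:2, 3:4), h)
})

test_that("cline_value has the defining centre, slope and continuity", {
  m <- geo_cline_model(0.1, 0.9, 50, 20)
  expect_equal(cline_value(50, m), 0.5)
  slope <- (cline_value(50 + 1e-5, m) - cline_value(50 - 1e-5, m)) / 2e-5
  expect_equal(slope, (0.9 - 0.1) / 20, tolerance = 1e-6)
  # junction continuity for a left tail, to machine precision
  mt <- geo_cline_model(0, 1, 50, 20, "left", deltaL = 12, tauL = 0.3)
  xl <- 50 - 12
  expect_equal(cline_value(xl - 1e-12, mt), cline_value(xl, mt),
               tolerance = 1e-9)
  # and for the mirrored right side
  mm <- geo_cline_model(0, 1, 50, 20, "mirror", deltaL = 12, tauL = 0.3)
  xr <- 50 + 12
  expect_equal(cline_value(xr + 1e-12, mm), cline_value(xr, mm),
               tolerance = 1e-9)
})

test_that("cline_value is nondecreasing in x for admissible models", {
  x <- seq(-50, 150, by = 0.5)
  set.seed(30)
  for (i in 1:20) {
    tc <- sample(c("none", "left", "right", "mirror", "both"), 1)
    m <- geo_cline_model(0, 1, runif(1, 20, 80), runif(1, 2, 40), tc,
                         deltaL = runif(1, 0, 30), tauL = runif(1, 0.05, 1),
                         deltaR = runif(1, 0, 30), tauR = runif(1, 0.05, 1))
    expect_true(all(diff(cline_value(x, m)) >= -1e-12))
  }
})

test_that("centre and width are recovered from synthetic transects", {
  set.seed(31)
  x <- runif(150, 0, 100)
  truth <- geo_cline_model(0, 1, 50, 20)
  y <- cline_value(x, truth) + rnorm(150, 0, 0.06)
  f <- fit_geographic_cline(x, y, "none", seed = 32)
  expect_lt(abs(f$model$centre - 50), 3)
  expect_lt(abs(f$model$width - 20) / 20, 0.3)
  expect_true(f$width_interval[1] <= f$model$width &&
                f$model$width <= f$width_interval[2])
})

test_that("reversing the transect reflects the centre, keeps the width", {
  set.seed(33)
  x <- runif(120, 0, 100)
  y <- cline_value(x, geo_cline_model(0, 1, 30, 15)) + rnorm(120, 0, 0.05)
  f <- fit_geographic_cline(x, y, "none", seed = 34)
  r <- fit_geographic_cline(100 - x, y, "none", seed = 34)
  expect_lt(abs((100 - r$model$centre) - f$model$centre), 2)
  expect_lt(abs(r$model$width - f$model$width) / f$model$width, 0.15)
})

test_that("identical proxies are rejected", {
  expect_error(fit_geographic_cline(1:20, rep(0.5, 20), "none"),
               "identical")
})

test_that("model selection prefers the generating tail structure", {
  set.seed(35)
  x <- runif(200, 0, 100)
  truth <- geo_cline_model(0, 1, 60, 20, "left", deltaL = 10, tauL = 0.3)
  wins <- 0L
  seeds <- 1:5
  for (s in seeds) {
    set.seed(300 + s)
    y <- cline_value(x, truth) + rnorm(200, 0, 0.04)
    fn <- fit_geographic_cline(x, y, "none", burn = 1500, keep = 3000,
                               seed = 400 + s)
    fl <- fit_geographic_cline(x, y, "left", burn = 1500, keep = 3000,
                               seed = 500 + s)
    if (fl$AICc < fn$AICc) wins <- wins + 1L
  }
  expect_gt(wins, length(seeds) / 2)
})

test_that("AICc ties break toward fewer parameters", {
  fmirror <- list(AICc = 100, model = list(tail_config = "mirror"))
  fboth <- list(AICc = 100, model = list(tail_config = "both"))
  expect_equal(select_model(list(both = fboth, mirror = fmirror)), "mirror")
  expect_equal(select_model(list(only = fboth)), "only")
})
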