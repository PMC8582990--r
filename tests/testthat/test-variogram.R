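test_that("model semivariances match their closed forms", {
  bc <- variogram_model("exponential", 0.01, 0.05, 10000)
  expect_equal(model_gamma(bc, 1e12), 0.06, tolerance = 1e-12)
  expect_equal(model_gamma(bc, 10000), 0.01 + 0.05 * (1 - exp(-3)),
               tolerance = 1e-12)
  sph <- variogram_model("spherical", 0.02, 0.05, 15000)
  expect_identical(model_gamma(sph, 2 * 15000), 0.07)
  gau <- variogram_model("gaussian", 0.015, 0.05, 15000)
  for (m in list(bc, sph, gau)) {
    expect_identical(model_gamma(m, 0), 0)
    # sill reached within 1e-6 by ten ranges
    expect_equal(model_gamma(m, 10 * m$range), m$nugget + m$psill,
                 tolerance = 1e-6)
    # monotone non-decreasing
    g <- model_gamma(m, seq(1e-9, 5 * m$range, length.out = 400))
    expect_true(all(diff(g) >= -1e-14))
  }
  expect_error(model_gamma(bc, -1), ">= 0")
})

test_that("empirical semivariogram reproduces hand-computed cases", {
  # two wells with equal values
  e0 <- empirical_semivariogram(rbind(c(0, 0), c(100, 0)), c(1, 1),
                                bin_width = 100, max_lag = 150,
                                min_pairs = 1)
  expect_equal(e0$gamma, 0)
  # two wells, values 0 and 1: gamma = 0.5
  e1 <- empirical_semivariogram(rbind(c(0, 0), c(100, 0)), c(0, 1),
                                bin_width = 100, max_lag = 150,
                                min_pairs = 1)
  expect_equal(e1$gamma, 0.5)
  expect_equal(e1$np, 1L)
  # three collinear wells at 0/100/200 m, values 0/1/3
  e2 <- empirical_semivariogram(cbind(c(0, 100, 200), 0), c(0, 1, 3),
                                bin_width = 100, max_lag = 200,
                                min_pairs = 1)
  expect_equal(e2$gamma, c((1 + 4) / (2 * 2), 9 / 2))
  expect_equal(e2$np, c(2L, 1L))
  expect_error(
    empirical_semivariogram(rbind(c(0, 0), c(1000, 0)), c(0, 1),
                            bin_width = 10, max_lag = 100, min_pairs = 1),
    "max_lag")
})

test_that("empirical semivariogram agrees with the brute-force pair loop", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(10:50, 1)
    xy <- cbind(runif(n, 0, 5000), runif(n, 0, 5000))
    z <- rnorm(n)
    bw <- 700; ml <- 4000
    got <- empirical_semivariogram(xy, z, bin_width = bw, max_lag = ml,
                                   min_pairs = 1)
    want <- brute_semivariogram(xy, z, bin_width = bw, max_lag = ml)
    expect_equal(got$gamma, want$gamma, tolerance = 1e-12)
    expect_equal(got$np, as.integer(want$np))
    expect_equal(got$lag, want$lag, tolerance = 1e-12)
  }
})

test_that("duplicate locations are excluded from the bins", {
  xy <- rbind(c(0, 0), c(0, 0), c(100, 0))
  e <- empirical_semivariogram(xy, c(0, 4, 1), bin_width = 100,
                               max_lag = 150, min_pairs = 1)
  # only the two h=100 pairs survive: (0-1)^2 and (4-1)^2
  expect_equal(e$np, 2L)
  expect_equal(e$gamma, (1 + 9) / (2 * 2))
})

test_that("noiseless model curves are recovered to high precision", {
  for (kind in c("exponential", "spherical", "gaussian")) {
    truth <- variogram_model(kind, 0.01, 0.05, 12000)
    lag <- seq(1500, 30000, length.out = 10)
    emp <- structure(
      data.frame(lag = lag, gamma = model_gamma(truth, lag), np = 100L),
      class = c("empirical_variogram", "data.frame"))
    fit <- fit_variogram_model(emp, kind)
    expect_equal(fit$nugget, truth$nugget, tolerance = 1e-5)
    expect_equal(fit$psill, truth$psill, tolerance = 1e-5)
    expect_equal(fit$range, truth$range, tolerance = 1e-4)
    expect_true(attr(fit, "range_identifiable"))
  }
})

test_that("flat empirical variograms flag an unidentifiable range", {
  emp <- structure(
    data.frame(lag = c(1000, 2000, 3000, 4000), gamma = rep(0.04, 4),
               np = 50L),
    class = c("empirical_variogram", "data.frame"))
  fit <- fit_variogram_model(emp, "exponential")
  expect_equal(fit$nugget + fit$psill, 0.04, tolerance = 1e-9)
  expect_false(attr(fit, "range_identifiable"))
})

test_that("fit is invariant to scaling every pair count", {
  set.seed(8)
  truth <- variogram_model("exponential", 0.015, 0.05, 15000)
  lag <- seq(1000, 25000, length.out = 12)
  gam <- model_gamma(truth, lag) * exp(rnorm(12, 0, 0.05))
  np <- sample(30:300, 12)
  mk <- function(mult) structure(
    data.frame(lag = lag, gamma = gam, np = np * mult),
    class = c("empirical_variogram", "data.frame"))
  f1 <- fit_variogram_model(mk(1L), "exponential")
  f7 <- fit_variogram_model(mk(7L), "exponential")
  expect_equal(f1$nugget, f7$nugget, tolerance = 1e-6)
  expect_equal(f1$psill, f7$psill, tolerance = 1e-6)
  expect_equal(f1$range, f7$range, tolerance = 1e-6)
})

test_that("variogram models round-trip through JSON", {
  m <- variogram_model("gaussian", 0.02, 0.05, 15000)
  f <- tempfile(fileext = ".json")
  write_variogram_json(m, f)
  m2 <- read_variogram_json(f)
  expect_equal(m2[c("kind", "nugget", "psill", "range")],
               m[c("kind", "nugget", "psill", "range")])
})
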