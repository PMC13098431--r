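test_that("histogram placement matches a brute-force per-sample loop", {
  set.seed(51)
  x <- runif(500, -3, 7)
  y <- runif(500, 0, 12)
  h <- cv_histogram(x, y, binwidth_x = 0.5, binwidth_y = 1)
  expect_equal(sum(h$counts), 500)
  brute <- matrix(0L, length(h$breaks_x) - 1, length(h$breaks_y) - 1)
  for (s in seq_along(x)) {
    ix <- max(which(h$breaks_x <= x[s] + 1e-15))
    iy <- max(which(h$breaks_y <= y[s] + 1e-15))
    ix <- min(ix, nrow(brute)); iy <- min(iy, ncol(brute))
    brute[ix, iy] <- brute[ix, iy] + 1L
  }
  expect_equal(h$counts, brute, ignore_attr = TRUE)
})

test_that("bins are half-open with the stated edge conventions", {
  h <- cv_histogram(c(1.2, 1.2, 1.2, 1.2), binwidth_x = 0.5)
  expect_equal(sum(h$counts == 4), 1L)
  expect_equal(sum(h$counts), 4L)
  # a sample exactly on an interior edge counts in the upper bin
  h2 <- cv_histogram(c(0.1, 0.5), binwidth_x = 0.5)
  expect_equal(h2$counts, c(1L, 1L))
  expect_error(cv_histogram(numeric(0), binwidth_x = 1), "empty")
})

test_that("dihedral binning is periodic", {
  set.seed(53)
  x <- runif(1000, -180, 180)
  h1 <- cv_histogram(x, binwidth_x = 5, circular_x = TRUE)
  h2 <- cv_histogram(x + 360, binwidth_x = 5, circular_x = TRUE)
  h3 <- cv_histogram(x - 720, binwidth_x = 5, circular_x = TRUE)
  expect_identical(h1$counts, h2$counts)
  expect_identical(h1$counts, h3$counts)
})

test_that("the PMF reference, masking and closed forms are exact", {
  x <- rep(c(0.25, 0.75, 1.25), times = c(10, 10, 10))
  h <- cv_histogram(x, binwidth_x = 0.5)
  s <- pmf(h, temperature = 333)
  expect_true(all(s$F[!s$mask] == 0))  # uniform counts: F = 0 everywhere

  # counts in ratio e differ by exactly kB*T
  h2 <- h
  h2$counts <- c(exp(1) * 1e6, 1e6, 0)
  s2 <- pmf(h2, temperature = 333)
  kBT <- 0.0019872041 * 333
  expect_equal(s2$F[2] - s2$F[1], kBT, tolerance = 1e-12)
  expect_equal(s2$F[2] - s2$F[1], 0.662, tolerance = 5e-3)
  expect_true(is.na(s2$F[3]) && s2$mask[3])

  # only count ratios enter: rescaling all counts changes nothing
  h3 <- h2
  h3$counts <- h2$counts * 7.5
  expect_equal(pmf(h3, 333)$F, s2$F)

  # adding a constant count to every (occupied) bin compresses the contrast
  h4 <- h2
  h4$counts <- c(exp(1) * 1e6, 1e6, 2e5)
  before <- max(pmf(h4, 333)$F, na.rm = TRUE)
  h4$counts <- h4$counts + 5e5
  expect_lt(max(pmf(h4, 333)$F, na.rm = TRUE), before)

  h5 <- h
  h5$counts <- rep(0L, 3)
  expect_error(pmf(h5), "empty")
  expect_error(pmf(h, temperature = -1), "positive")
})

test_that("a von Mises sample reproduces its analytic 1D PMF", {
  set.seed(57)
  mu <- 40; kappa <- 2
  x <- rvonmises(2e5, mu, kappa)
  s <- pmf(cv_histogram(x, binwidth_x = 5, circular_x = TRUE),
           temperature = 333)
  kBT <- 0.0019872041 * 333
  analytic <- kBT * kappa * (1 - cos((s$centers_x - mu) * pi / 180))
  good <- !s$mask & s$counts > 100
  resid <- (s$F - analytic)[good]
  resid <- resid - mean(resid)  # PMF is defined up to an additive constant
  expect_lt(sqrt(mean(resid^2)), 0.05)
})

test_that("basin detection finds planted wells and respects max_F", {
  # two Gaussian wells separated by a high barrier
  cx <- seq(0.125, 9.875, by = 0.25)
  grid <- expand.grid(x = cx, y = cx)
  dens <- exp(-((grid$x - 2)^2 + (grid$y - 3)^2) / 0.5) +
    exp(-((grid$x - 7)^2 + (grid$y - 8)^2) / 0.5)
  h <- cv_histogram(grid$x[1], grid$y[1], binwidth_x = 0.25,
                    binwidth_y = 0.25)  # template for the class shape
  h$breaks_x <- h$breaks_y <- seq(0, 10, by = 0.25)
  h$centers_x <- h$centers_y <- cx
  h$counts <- matrix(round(1e6 * dens), length(cx), length(cx))
  s <- pmf(h, temperature = 333)
  basins <- find_basins(s, max_F = 3)
  expect_equal(nrow(basins), 2L)
  expect_lt(min(abs(basins$x - 2)), 0.25 + 1e-9)
  expect_lt(min(abs(basins$y[order(basins$x)][1] - 3)), 0.25 + 1e-9)
  expect_lt(min(abs(basins$x - 7)), 0.25 + 1e-9)

  expect_equal(nrow(find_basins(s, max_F = -1)), 0L)

  # single well
  h1 <- h
  h1$counts <- matrix(round(1e6 * exp(-((grid$x - 5)^2 + (grid$y - 5)^2))),
                      length(cx), length(cx))
  b1 <- find_basins(pmf(h1), max_F = 1)
  expect_equal(nrow(b1), 1L)
  expect_lt(abs(b1$x - 5), 0.25)

  # duality: basins of the flipped surface are the peaks of the original
  s_flip <- s
  mx <- max(s$F, na.rm = TRUE)
  s_flip$F <- mx - s$F
  peaks <- find_basins(s_flip, max_F = 0.5)
  expect_gte(nrow(peaks), 1L)
  expect_true(all(s$F[cbind(peaks$ix, peaks$iy)] >= mx - 0.5))
})

test_that("wrapped-histogram modes land on the planted torsion mode", {
  m <- circular_mode(rep(130, 50), binwidth = 5)
  expect_equal(m$mode, 132.5)        # centre of the [130, 135) bin
  expect_equal(m$half_width, 2.5)

  set.seed(61)
  x <- rvonmises(1e4, 170, 8)
  m2 <- circular_mode(x, binwidth = 5)
  expect_lte(abs(((m2$mode - 170 + 180) %% 360) - 180), 5)

  # ties break towards the smaller absolute angle, then the smaller signed one
  m3 <- circular_mode(c(31, 171), binwidth = 5)  # bins at 32.5 and 172.5 tie
  expect_equal(m3$mode, 32.5)
  m4 <- circular_mode(c(-101, 101), binwidth = 5)  # equal |centre|: -102.5
  expect_equal(m4$mode, -102.5)
  expect_error(circular_mode(numeric(0)), "empty")
})

test_that("circular statistics handle antipodal and concentrated samples", {
  anti <- circular_stats(c(90, -90))
  expect_equal(anti$resultant_length, 0, tolerance = 1e-12)
  expect_false(anti$mean_defined)
  expect_true(is.na(anti$mean))

  same <- circular_stats(rep(77, 10))
  expect_equal(same$resultant_length, 1, tolerance = 1e-12)
  expect_equal(same$mean, 77, tolerance = 1e-9)

  set.seed(63)
  n <- 2e4
  x <- rvonmises(n, 10, 2)
  st <- circular_stats(x)
  expected_R <- besselI(2, 1) / besselI(2, 0)
  se <- sqrt((1 - expected_R^2) / n)  # conservative dispersion scale
  expect_lt(abs(st$resultant_length - expected_R), 3 * se + 0.01)
  expect_lt(abs(st$mean - 10), 3)
})
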