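test_that("FWHM/sigma relation is exact on a noiseless spot", {
  # expected counts (no Poisson draw) from a sigma = 28 nm Gaussian
  sigma <- 28; px <- 10; np <- 21
  edges <- (0:np) * px
  ctr <- np * px / 2
  g <- diff(pnorm(edges, ctr, sigma))
  patch <- 5000 * outer(g, g)
  stack <- structure(list(patches = list(patch), pixel_nm = px),
                     class = "spot_stack")
  est <- estimate_resolution(stack)
  expect_equal(est$fwhm_nm, 2 * sqrt(2 * log(2)) * 28, tolerance = 1e-3)
  expect_equal(2 * sqrt(2 * log(2)), 2.35482, tolerance = 1e-5)
})

test_that("91 noisy spots at 66 nm FWHM are recovered within 5%", {
  stack <- simulate_spot_stack(91, fwhm = 66, photons = 500,
                               background = 0.5, pixel_size = 20, seed = 12)
  est <- estimate_resolution(stack)
  expect_equal(est$n_spots, 91L)
  expect_lt(abs(est$fwhm_nm - 66) / 66, 0.05)
  expect_true(is.finite(est$se_nm) && est$se_nm > 0)
})

test_that("the resolution estimate is stable under pixel-size and ordering changes", {
  s1 <- simulate_spot_stack(60, fwhm = 66, photons = 800, background = 0,
                            pixel_size = 20, seed = 5)
  e1 <- estimate_resolution(s1)
  s2 <- simulate_spot_stack(60, fwhm = 66, photons = 800, background = 0,
                            pixel_size = 40, seed = 5)
  e2 <- estimate_resolution(s2)
  expect_lt(abs(e1$fwhm_nm - e2$fwhm_nm) / e1$fwhm_nm, 0.06)
  # spot order is irrelevant
  s3 <- s1; s3$patches <- rev(s3$patches)
  e3 <- estimate_resolution(s3)
  expect_equal(e3$fwhm_nm, e1$fwhm_nm, tolerance = 1e-6)
  # a constant added background is co-fitted away
  s4 <- simulate_spot_stack(60, fwhm = 66, photons = 800, background = 3,
                            pixel_size = 20, seed = 5)
  e4 <- estimate_resolution(s4)
  expect_lt(abs(e4$fwhm_nm - 66) / 66, 0.06)
})

test_that("a peakless stack is an error, not a number", {
  flat <- structure(list(patches = list(matrix(5, 15, 15)), pixel_nm = 20),
                    class = "spot_stack")
  expect_error(estimate_resolution(flat), "peak")
})

test_that("spot simulation obeys its photon budget and patch constraint", {
  stack <- simulate_spot_stack(200, fwhm = 66, photons = 400,
                               background = 1, pixel_size = 20, seed = 3)
  totals <- vapply(stack$patches, sum, 0)
  npix <- length(stack$patches[[1]])
  expect_lt(abs(mean(totals) - (400 + npix)),
            3 * sd(totals) / sqrt(length(totals)) + 3)
  expect_error(simulate_spot_stack(5, fwhm = 66, pixel_size = 20,
                                   patch_px = 5),
               "too small")
})

test_that("bleach traces are exponential with frame-aligned sampling", {
  # mean -> 0+: every emitter spans exactly one frame
  tr <- simulate_bleach_traces(500, mean_lifetime = 1e-6, seed = 1)
  expect_true(all(tr$n_frames == 1L))
  # mean = 1: multi-frame fraction ~ exp(-1)
  tr2 <- simulate_bleach_traces(1e4, mean_lifetime = 1, seed = 2)
  frac <- mean(tr2$n_frames >= 2)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 1e4)
  expect_lt(abs(frac - exp(-1)), 3 * se)
})

test_that("survival inversion returns tau = 1 when s = e^-1 and flags degenerate cases", {
  spans <- c(rep(1L, 1000 - round(1000 * exp(-1))),
             rep(2L, round(1000 * exp(-1))))
  est <- estimate_lifetime(data.frame(n_frames = spans))
  expect_equal(est$mean_frames, -1 / log(mean(spans >= 2)), tolerance = 1e-12)
  expect_equal(est$mean_frames, 1, tolerance = 0.01)
  # all single-frame: upper bound with flag
  est0 <- estimate_lifetime(data.frame(n_frames = rep(1L, 100)))
  expect_true(est0$flagged)
  expect_equal(est0$mean_frames, -1 / log(1 / 100))
  # all multi-frame: undefined, flagged
  est1 <- estimate_lifetime(data.frame(n_frames = rep(3L, 100)))
  expect_true(est1$flagged)
  expect_true(is.na(est1$mean_frames))
})

test_that("the lifetime estimator recovers the sub-frame study value", {
  tau <- 0.7845
  est <- vapply(1:40, function(i)
    estimate_lifetime(simulate_bleach_traces(1885, tau, seed = i))$mean_frames,
    0)
  se_mean <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - tau), 3 * se_mean)
})

test_that("lifetime estimator bias vanishes with n on simulated traces", {
  tau <- 1.7
  bias <- vapply(c(100, 1000, 10000), function(n) {
    est <- vapply(1:10, function(i)
      estimate_lifetime(simulate_bleach_traces(n, tau,
                                               seed = 7000 + 13 * n + i)
      )$mean_frames, 0)
    abs(mean(est) - tau)
  }, 0)
  expect_lt(bias[3], 0.05)
  expect_lt(bias[3], bias[1] + 0.05)
})

test_that("frame-linked localization tables give the same survival fraction", {
  # emitters far apart; spans encoded as consecutive-frame detections
  set.seed(9)
  n <- 300
  tr <- simulate_bleach_traces(n, 0.9, seed = 31)
  xs <- runif(n, 0, 2e5); ys <- runif(n, 0, 2e5)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- tr$n_frames[i]
    data.frame(frame = seq_len(k) - 1L,
               x = xs[i] + rnorm(k, 0, 5), y = ys[i] + rnorm(k, 0, 5))
  }))
  tb <- localization_table(rows, frame_interval = 1)
  est <- estimate_lifetime(tb, link_radius = 100)
  expect_equal(est$n, n)
  expect_equal(est$survival, mean(tr$n_frames >= 2), tolerance = 1e-9)
})
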