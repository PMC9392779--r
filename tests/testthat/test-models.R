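p_lin <- function() growth_params(0.01, 0.05, 400, 3000, 500, A0 = 0.03,
                                  kind = "A_lin")
p_par <- function() growth_params(0.01, 4e-4, 200, 2000, 300, A0 = 0.0314,
                                  kind = "A_par")

test_that("piecewise rates match their closed forms at the switch points", {
  p <- p_lin()
  expect_equal(growth_rate(p, 3000), 0.05 / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(growth_rate(p, 399.999), 0.01)
  expect_equal(growth_rate(p, 400), 0.05)
  # saturated tail is numerically dead
  expect_lt(growth_rate(p, 3000 + 10 * 500), 1e-15 * 0.05)
  # A_par middle branch is r2 t / 2 exactly
  q <- p_par()
  tt <- seq(200, 1999, by = 111)
  expect_equal(growth_rate(q, tt), 0.5 * 4e-4 * tt)
  # non-negative everywhere
  tt <- seq(-100, 6000, by = 7)
  expect_true(all(growth_rate(p, tt) >= 0))
  expect_true(all(growth_rate(q, tt) >= 0))
})

test_that("integration reproduces closed forms for constant and parabolic phases", {
  # single constant phase: A = A0 + r1 (t - t0)
  p <- growth_params(0.02, 0, 1e9, 1e9, 100, A0 = 1, kind = "A_lin")
  t <- seq(0, 2000, by = 20)
  expect_equal(integrate_model(p, t), 1 + 0.02 * t, tolerance = 1e-12)
  # parabolic middle phase: A(t) - A(t0) = r2 (t^2 - t0^2) / 4
  q <- p_par()
  t <- seq(200, 2000, by = 20)
  A <- integrate_model(q, t, A0 = 5)
  expect_equal(A, 5 + 4e-4 * (t^2 - 200^2) / 4, tolerance = 1e-6)
})

test_that("default integration matches a 1e4-step fine integrator to 1e-4", {
  for (mk in list(p_lin, p_par)) {
    p <- mk()
    t <- seq(0, 4000, length.out = 120)
    coarse <- integrate_model(p, t)
    fine <- integrate_model(p, t, substeps = ceiling(1e4 / (length(t) - 1)))
    expect_lt(max(abs(coarse - fine) / pmax(fine, 1e-12)), 1e-4)
    expect_true(all(diff(coarse) >= -1e-12))
  }
})

test_that("noiseless parameter recovery is within 1%", {
  p <- p_lin()
  cv <- sim_growth_curve(p, seq(0, 4000, by = 20))
  f <- fit_growth_curve(cv, "A_lin")
  expect_true(f$converged)
  got <- unlist(f$params)[c("r1", "r2", "t0", "t1", "tau")]
  want <- c(0.01, 0.05, 400, 3000, 500)
  expect_lt(max(abs(got - want) / want), 0.01)
})

test_that("noisy recovery: rates within 10% median error, ~2 SE coverage", {
  p <- p_lin()
  t <- seq(0, 4000, by = 40)
  nrep <- 12
  rel <- matrix(NA, nrep, 2)
  cover <- 0
  for (i in seq_len(nrep)) {
    cv <- sim_growth_curve(p, t, noise_cv = 0.05, seed = 100 + i)
    f <- fit_growth_curve(cv, "A_lin")
    rel[i, ] <- c(f$params$r1 / 0.01, f$params$r2 / 0.05) - 1
    cover <- cover +
      (abs(f$params$r1 - 0.01) <= 2 * f$se["r1"]) +
      (abs(f$params$r2 - 0.05) <= 2 * f$se["r2"])
  }
  expect_lt(median(abs(rel[, 1])), 0.10)
  expect_lt(median(abs(rel[, 2])), 0.10)
  expect_gte(cover / (2 * nrep), 0.75)
})

test_that("a flat curve collapses to zero rates", {
  cv <- growth_curve(data.frame(t = seq(0, 2000, 100),
                                area_um2 = rep(5, 21)),
                     frame_interval = 100)
  f <- fit_growth_curve(cv, "A_lin")
  expect_lt(f$params$r1 * 2000 / 5, 0.01)
  expect_lt(f$params$r2 * 2000 / 5, 0.01)
})

test_that("fits are equivariant under area scaling", {
  p <- p_lin()
  t <- seq(0, 4000, by = 40)
  cv1 <- sim_growth_curve(p, t, noise_cv = 0.03, seed = 7)
  f1 <- fit_growth_curve(cv1, "A_lin")
  c_scale <- 12.5
  cv2 <- growth_curve(data.frame(t = cv1$t,
                                 area_um2 = cv1$area_um2 * c_scale),
                      frame_interval = 40)
  f2 <- fit_growth_curve(cv2, "A_lin")
  expect_equal(f2$params$r1, c_scale * f1$params$r1, tolerance = 1e-4)
  expect_equal(f2$params$r2, c_scale * f1$params$r2, tolerance = 1e-4)
  expect_equal(f2$params$A0, c_scale * f1$params$A0, tolerance = 1e-3)
  expect_equal(f2$params$t0, f1$params$t0, tolerance = 1e-4)
  expect_equal(f2$params$t1, f1$params$t1, tolerance = 1e-4)
  expect_equal(f2$params$tau, f1$params$tau, tolerance = 1e-4)
})

test_that("morphology classification picks the generating model", {
  cv_a <- sim_growth_curve(p_lin(), seq(0, 4000, 40), noise_cv = 0.02,
                           seed = 1)
  cl_a <- classify_morphology(cv_a)
  expect_equal(cl_a$morphology, "anisotropic")
  cv_i <- sim_growth_curve(p_par(), seq(0, 3000, 30), noise_cv = 0.02,
                           seed = 2)
  cl_i <- classify_morphology(cv_i)
  expect_equal(cl_i$morphology, "isotropic")
  expect_named(cl_i$fits, c("A_lin", "A_par"))
})

test_that("rate extraction emits per-phase records with metadata intact", {
  cv <- sim_growth_curve(p_lin(), seq(0, 4000, 40), noise_cv = 0.02,
                         seed = 3)
  f <- fit_growth_curve(cv, "A_lin")
  rec <- extract_rates(f, "anisotropic", temperature = 37, aggregate_id = 9L)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$phase, c("linear", "branching"))
  expect_equal(rec$temperature_C, c(37, 37))
  expect_equal(rec$aggregate_id, c(9L, 9L))
  expect_equal(rec$rate, c(f$params$r1, f$params$r2))

  cvp <- sim_growth_curve(p_par(), seq(0, 3000, 30), noise_cv = 0.02,
                          seed = 4)
  fp <- fit_growth_curve(cvp, "A_par")
  rec_i <- extract_rates(fp, "isotropic", temperature = 45)
  expect_equal(nrow(rec_i), 1L)
  expect_equal(rec_i$phase, "isotropic")
  expect_equal(rec_i$rate, fp$params$r1)
  # morphology/model mismatch is an error
  expect_error(extract_rates(fp, "anisotropic"), "A_lin")
})

test_that("invalid parameter combinations are rejected", {
  expect_error(growth_params(-0.01, 0.05, 0, 10, 5), "non-negative")
  expect_error(growth_params(0.01, 0.05, 10, 5, 5), "t0 <= t1")
  expect_error(growth_params(0.01, 0.05, 0, 10, 0), "tau")
  expect_error(growth_params(NaN, 0.05, 0, 10, 5), "non-finite")
})
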