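test_that("zero growth keeps every event inside the core footprint", {
  cfg <- simulation_config("isotropic", r1 = 0, r2 = 0, t0 = 100, t1 = 200,
                           n_frames = 50, loc_sigma = 0, seed = 3,
                           label_density = 2000)
  sim <- simulate_aggregate(cfg)
  ev <- sim$truth$events
  expect_gt(nrow(ev), 10)
  expect_true(all(sqrt(ev$x^2 + ev$y^2) <= 100 + 1e-9))
  expect_equal(diff(range(sim$truth$area_curve$area_um2)), 0)
  # anisotropic zero growth likewise
  cfga <- simulation_config("anisotropic", r1 = 0, r2 = 0, t0 = 100,
                            t1 = 200, n_frames = 50, loc_sigma = 0,
                            seed = 4, label_density = 2000)
  eva <- simulate_aggregate(cfga)$truth$events
  expect_true(all(sqrt(eva$x^2 + eva$y^2) <= 100 + 1e-9))
})

test_that("ground-truth areas equal the generating model at every frame", {
  cfg <- simulation_config("isotropic", r1 = 0.01, r2 = 4e-4, t0 = 200,
                           t1 = 2000, tau = 300, frame_interval = 20,
                           n_frames = 150, seed = 5)
  sim <- simulate_aggregate(cfg)
  tr <- sim$truth
  ref <- integrate_model(tr$params, tr$area_curve$t,
                         substeps = 200)
  expect_lt(max(abs(tr$area_curve$area_um2 - ref) / ref), 1e-3)
})

test_that("area curves satisfy their generating ODE by finite differences", {
  for (morph in c("isotropic", "anisotropic")) {
    cfg <- simulation_config(morph, n_frames = 150, seed = 6)
    tr <- simulate_aggregate(cfg)$truth
    t <- tr$area_curve$t; A <- tr$area_curve$area_um2
    mid <- (t[-1] + t[-length(t)]) / 2
    dAdt <- diff(A) / diff(t)
    model <- growth_rate(tr$params, mid)
    # away from the rate discontinuity at t0
    keep <- abs(mid - cfg$t0) > cfg$frame_interval
    denom <- pmax(model[keep], max(model) * 1e-3)
    expect_lt(max(abs(dAdt[keep] - model[keep]) / denom), 0.005)
  }
})

test_that("event counts follow the Poisson labeling law across seeds", {
  cfg0 <- simulation_config("isotropic", n_frames = 60, label_density = 50,
                            t0 = 100, t1 = 700, tau = 150)
  totals <- vapply(1:100, function(s) {
    cfg <- simulation_config("isotropic", n_frames = 60, label_density = 50,
                             t0 = 100, t1 = 700, tau = 150, seed = s)
    nrow(simulate_aggregate(cfg)$truth$events)
  }, 0)
  A_final <- simulate_aggregate(cfg0)$truth$area_curve$area_um2[60]
  expected <- 50 * A_final
  # mean of 100 Poisson draws: SE = sqrt(lambda/100)
  expect_lt(abs(mean(totals) - expected), 3 * sqrt(expected / 100))
  # per-frame counts likewise Poisson around label_density * dA
  tr <- simulate_aggregate(cfg0)$truth
  dA <- diff(tr$area_curve$area_um2)
  counts <- vapply(1:100, function(s) {
    cfg <- simulation_config("isotropic", n_frames = 60, label_density = 50,
                             t0 = 100, t1 = 700, tau = 150, seed = 2000 + s)
    ev <- simulate_aggregate(cfg)$truth$events
    sum(ev$frame == 30L)
  }, 0)
  lam <- 50 * dA[30]
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 100))
})

test_that("morphologies separate by aspect ratio of true positions", {
  iso <- simulate_aggregate(simulation_config("isotropic", n_frames = 100,
                                              loc_sigma = 0, seed = 8))
  ev <- iso$truth$events
  sv <- prcomp(cbind(ev$x, ev$y))$sdev
  expect_lt(sv[1] / sv[2], 1.3)
  # anisotropic, phase 1 only (t < t0 = 400 s -> first 20 frames)
  ani <- simulate_aggregate(simulation_config("anisotropic", n_frames = 20,
                                              loc_sigma = 0, seed = 9))
  eva <- ani$truth$events
  sva <- prcomp(cbind(eva$x, eva$y))$sdev
  expect_gt(sva[1] / sva[2], 2)
})

test_that("seeded simulations are bit-reproducible", {
  cfg <- simulation_config("anisotropic", n_frames = 40, seed = 10)
  s1 <- simulate_aggregate(cfg)
  s2 <- simulate_aggregate(cfg)
  expect_identical(as.data.frame(s1$table), as.data.frame(s2$table))
  expect_identical(s1$truth$area_curve, s2$truth$area_curve)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config("isotropic", r1 = -1), "non-negative")
  expect_error(simulation_config("isotropic", r1 = NaN), "non-finite")
  expect_error(simulation_config("isotropic", label_density = 0),
               "label_density")
  expect_error(simulation_config("isotropic", tau = 0), "tau")
})

test_that("ground truth survives the JSON sidecar", {
  sim <- simulate_aggregate(simulation_config("isotropic", n_frames = 20,
                                              seed = 11))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim, path)
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(gt$morphology, "isotropic")
  expect_equal(gt$area_curve$area_um2, sim$truth$area_curve$area_um2,
               tolerance = 1e-12)
})
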