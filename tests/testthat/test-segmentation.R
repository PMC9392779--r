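test_that("collinear points yield the obvious chain tree", {
  pts <- cbind(c(0, 100, 200, 300), 0)
  g <- build_knn_emst(pts, k = 3)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$edges$length, rep(100, 3))
})

test_that("kNN-approximate EMST matches the exact MST when k >= n - 1", {
  # brute-force Prim oracle over 50 random instances
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    pts <- cbind(runif(n, 0, 5000), runif(n, 0, 5000))
    g <- build_knn_emst(pts, k = n - 1)
    expect_equal(sum(g$edges$length), prim_mst_weight(pts),
                 tolerance = 1e-9)
    expect_equal(nrow(g$edges), n - 1L)
  }
})

test_that("small k still recovers the exact tree on typical point clouds", {
  pts <- disk_points(50, radius = 1000, seed = 77)
  g <- build_knn_emst(pts, k = 30)
  expect_equal(sum(g$edges$length), prim_mst_weight(pts), tolerance = 1e-9)
})

test_that("two blobs connect through exactly one long bridge", {
  b1 <- disk_points(10, radius = 100, center = c(0, 0), seed = 1)
  b2 <- disk_points(10, radius = 100, center = c(1000, 0), seed = 2)
  g <- build_knn_emst(rbind(b1, b2), k = 9)
  long <- g$edges$length > 500
  expect_equal(sum(long), 1L)
  expect_equal(g$edges$length[long],
               min(as.matrix(dist(rbind(b1, b2)))[1:10, 11:20]),
               tolerance = 1e-9)
})

test_that("percentile cut separates components exactly at the interpolated quantile", {
  # path graph: nineteen unit edges and one of length 10; P95 = 1.45
  pts <- cbind(c(0, cumsum(c(rep(1, 19), 10))), 0)
  g <- build_knn_emst(pts, k = 20)
  expect_equal(sort(g$edges$length)[20], 10)
  cl <- cut_tree_at_percentile(g, 95)
  expect_length(cl, 2L)
  expect_setequal(lengths(lapply(cl, `[[`, "members")), c(20L, 1L))
  # all-equal edges: nothing exceeds the percentile
  g2 <- build_knn_emst(cbind(0:9 * 100, 0), k = 9)
  expect_length(cut_tree_at_percentile(g2, 95), 1L)
  # single node: one singleton cluster
  g3 <- build_knn_emst(cbind(0, 0), k = 1)
  expect_length(cut_tree_at_percentile(g3, 95), 1L)
})

test_that("cluster size filter keeps >= min_size and re-indexes deterministically", {
  mkcl <- function(id, members)
    structure(list(id = id, members = members, bbox = c(0, 0, 0, 0)),
              class = "aggregate_cluster")
  cl <- list(mkcl(1, 1:99), mkcl(2, 100:249), mkcl(3, 250:349))
  f <- filter_clusters(cl, min_size = 100)
  expect_equal(vapply(f, function(c) length(c$members), 0L), c(150L, 100L))
  expect_equal(vapply(f, `[[`, 0L, "id"), 1:2)
  expect_equal(f[[1]]$members, 100:249)
  expect_length(filter_clusters(list(), 100), 0L)
  # min_size = 1 keeps everything, re-ordered by size
  f1 <- filter_clusters(cl, min_size = 1)
  expect_equal(vapply(f1, function(c) length(c$members), 0L),
               c(150L, 100L, 99L))
})

test_that("segmentation is invariant under rigid motions", {
  pts <- rbind(disk_points(120, 300, c(0, 0), seed = 4),
               disk_points(110, 300, c(8000, 0), seed = 5))
  tb <- mk_table(pts[, 1], pts[, 2])
  cl0 <- segment_aggregates(tb, knn = 10, min_size = 50)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- pts %*% t(R) + matrix(c(500, -300), nrow(pts), 2, byrow = TRUE)
  cl1 <- segment_aggregates(mk_table(rot[, 1], rot[, 2]),
                            knn = 10, min_size = 50)
  expect_equal(lapply(cl0, `[[`, "members"), lapply(cl1, `[[`, "members"))
})

test_that("frame membership keeps the cumulative largest connected subgroup", {
  # chain within cutoff is fully retained
  tb <- mk_table(x = 0:9 * 300, y = 0, frame = 0:9)
  cl <- structure(list(id = 1L, members = 1:10, bbox = c(0, 2700, 0, 0)),
                  class = "aggregate_cluster")
  fm <- frame_membership(cl, tb, 9, k = 3, cutoff = 400)
  expect_equal(fm$members, 1:10)
  # cumulative: at frame 4 only the first five points exist
  fm4 <- frame_membership(cl, tb, 4, k = 3, cutoff = 400)
  expect_equal(fm4$members, 1:5)
  # main group of 60 beats satellite of 40 at 600 nm
  main <- disk_points(60, radius = 150, center = c(0, 0), seed = 11)
  sat <- disk_points(40, radius = 100, center = c(900, 0), seed = 12)
  tb2 <- mk_table(c(main[, 1], sat[, 1]), c(main[, 2], sat[, 2]))
  cl2 <- structure(list(id = 1L, members = 1:100, bbox = c(0, 0, 0, 0)),
                   class = "aggregate_cluster")
  fm2 <- frame_membership(cl2, tb2, 0, k = 10, cutoff = 400)
  expect_setequal(fm2$members, 1:60)
  # a 500 nm outlier is excluded
  pts3 <- rbind(disk_points(30, 100, c(0, 0), seed = 13), c(800, 0))
  tb3 <- mk_table(pts3[, 1], pts3[, 2])
  cl3 <- structure(list(id = 1L, members = 1:31, bbox = c(0, 0, 0, 0)),
                   class = "aggregate_cluster")
  fm3 <- frame_membership(cl3, tb3, 0, k = 10, cutoff = 400)
  expect_setequal(fm3$members, 1:30)
  # monotone information: membership only uses frames <= f
  expect_error(frame_membership(cl, tb, 99), "outside")
})

test_that("two well-separated simulated aggregates segment into exactly two clusters", {
  mk <- function(core, seed)
    simulate_aggregate(simulation_config(
      "isotropic", n_frames = 40, seed = seed, core_position = core,
      label_density = 100, bg_rate = 20, bg_margin = 20000))
  s1 <- mk(c(0, 0), 1)
  s2 <- mk(c(40000, 0), 2)
  d1 <- as.data.frame(s1$table); d2 <- as.data.frame(s2$table)
  d1$src <- 1L; d2$src <- 2L
  d1$isagg <- d1$id <= nrow(s1$truth$events)
  d2$isagg <- d2$id <= nrow(s2$truth$events)
  tb <- localization_table(rbind(d1, d2), frame_interval = 20)
  cls <- segment_aggregates(tb)
  expect_length(cls, 2L)
  for (s in 1:2) {
    agg_rows <- which(tb$src == s & tb$isagg)
    best <- max(vapply(cls, function(c)
      length(intersect(c$members, agg_rows)), 0L))
    expect_gte(best / length(agg_rows), 0.99)
  }
})
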