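# Independent oracles used across tests.

# Exact Euclidean MST total weight by Prim's algorithm on the full distance
# matrix (independent of the package's kNN/igraph route).
prim_mst_weight <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(pts))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  key <- d[1, ]
  total <- 0
  for (step in seq_len(n - 1)) {
    key[in_tree] <- Inf
    v <- which.min(key)
    total <- total + key[v]
    in_tree[v] <- TRUE
    key <- pmin(key, d[v, ])
  }
  unname(total)
}

# Uniform points in a disk (radius nm), seeded.
disk_points <- function(n, radius = 1000, center = c(0, 0), seed = 1) {
  set.seed(seed)
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# A minimal in-memory localization table.
mk_table <- function(x, y, frame = 0L, intensity = 100,
                     frame_interval = 20, temperature = NA_real_) {
  localization_table(
    data.frame(frame = as.integer(frame), x = x, y = y,
               intensity = intensity),
    frame_interval = frame_interval, temperature = temperature)
}

# Noisy model-generated growth curve (multiplicative area noise).
sim_growth_curve <- function(params, t, noise_cv = 0, seed = NULL,
                             frame_interval = 20) {
  if (!is.null(seed)) set.seed(seed)
  A <- integrate_model(params, t)
  if (noise_cv > 0) A <- A * (1 + rnorm(length(A), 0, noise_cv))
  growth_curve(data.frame(t = t, area_um2 = A),
               frame_interval = frame_interval)
}
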