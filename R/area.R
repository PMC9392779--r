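## Gaussian-mixture area estimation.
##
## The aggregate's occupied area at a frame is read off a Gaussian mixture
## fit to its member localizations: one component for every 5 points but at
## least 25 components (capped at n/2 so the fit stays identifiable), full
## covariances. The area is the region where the fitted density exceeds the
## average probability density of the fit, evaluated on a 20 nm grid over
## the padded bounding box.
##
## With ~5 points per component an unregularized EM collapses onto its
## clusters and the density becomes a forest of spikes; every covariance
## therefore carries an additive ridge of (mean nearest-neighbor spacing)^2,
## which floors the component width at the sampling scale of the data and
## makes the mixture a smooth occupancy density. The averaging support for
## the threshold is the evaluation grid: for a near-uniform cloud the grid
## mean sits well below the interior plateau (most of the padded box is
## empty), so the thresholded region recovers the full support; averaging
## over the member points instead would place the threshold in the middle
## of the plateau fluctuations and halve the area of any uniform cloud.

## Mean distance to the k-th nearest neighbor. k = 4 by default: robust to
## the near-duplicate points produced by emitters detected in several
## consecutive frames (a first-NN spacing collapses to the localization
## jitter for those, which would undersmooth the mixture).
.mean_knn_dist <- function(pts, k = 4L) {
  n <- nrow(pts)
  k <- min(k, n - 1L)
  nn <- numeric(n)
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    dx <- outer(pts[idx, 1], pts[, 1], "-")
    dy <- outer(pts[idx, 2], pts[, 2], "-")
    d2 <- dx * dx + dy * dy
    d2[cbind(seq_along(idx), idx)] <- Inf
    nn[idx] <- sqrt(apply(d2, 1, function(v) sort.int(v, partial = k)[k]))
  }
  mean(nn)
}

## seeded k-means++ center selection
.kmeanspp_centers <- function(pts, G) {
  n <- nrow(pts)
  ctr <- matrix(NA_real_, G, 2)
  ctr[1, ] <- pts[sample.int(n, 1), ]
  d2 <- (pts[, 1] - ctr[1, 1])^2 + (pts[, 2] - ctr[1, 2])^2
  for (g in seq_len(G)[-1]) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    pick <- sample.int(n, 1, prob = p)
    ctr[g, ] <- pts[pick, ]
    d2 <- pmin(d2, (pts[, 1] - ctr[g, 1])^2 + (pts[, 2] - ctr[g, 2])^2)
  }
  ctr
}

## EM for a 2-D Gaussian mixture with per-component full covariances and an
## additive ridge. Deterministic given `seed`.
.gmm_em <- function(pts, G, seed, ridge, max_iter = 60L, tol = 1e-6) {
  n <- nrow(pts)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  km <- suppressWarnings(stats::kmeans(pts, centers = .kmeanspp_centers(pts, G),
                                       iter.max = 30L))
  mu <- km$centers
  pi_g <- pmax(km$size, 1) / sum(pmax(km$size, 1))
  Sig <- array(0, c(2, 2, G))
  for (g in seq_len(G)) {
    idx <- which(km$cluster == g)
    S <- if (length(idx) >= 3) stats::cov(pts[idx, , drop = FALSE])
         else matrix(0, 2, 2)
    if (any(!is.finite(S))) S <- matrix(0, 2, 2)
    Sig[, , g] <- S + diag(2) * ridge
  }
  comp_logdens <- function(mu, Sig) {
    out <- matrix(0, n, G)
    for (g in seq_len(G)) {
      S <- Sig[, , g]
      dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
      dx <- pts[, 1] - mu[g, 1]; dy <- pts[, 2] - mu[g, 2]
      q <- (S[2, 2] * dx^2 - 2 * S[1, 2] * dx * dy + S[1, 1] * dy^2) / dt
      out[, g] <- -log(2 * pi) - 0.5 * log(dt) - 0.5 * q
    }
    out
  }
  ll_old <- -Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    ld <- comp_logdens(mu, Sig) +
      matrix(log(pi_g), n, G, byrow = TRUE)
    m <- apply(ld, 1, max)
    w <- exp(ld - m)
    sw <- rowSums(w)
    ll <- sum(m + log(sw))
    R <- w / sw
    Nk <- colSums(R) + 1e-12
    pi_g <- Nk / n
    mu <- t(R) %*% pts / Nk
    for (g in seq_len(G)) {
      dx <- pts[, 1] - mu[g, 1]; dy <- pts[, 2] - mu[g, 2]
      r <- R[, g]
      Sig[, , g] <- matrix(c(sum(r * dx * dx), sum(r * dx * dy),
                             sum(r * dx * dy), sum(r * dy * dy)), 2) / Nk[g] +
        diag(2) * ridge
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(pi = pi_g, mu = mu, Sig = Sig, loglik = ll, iterations = it)
}

## mixture density at arbitrary points
.gmm_density <- function(fit, P) {
  G <- length(fit$pi)
  dens <- numeric(nrow(P))
  for (g in seq_len(G)) {
    S <- fit$Sig[, , g]
    dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
    dx <- P[, 1] - fit$mu[g, 1]; dy <- P[, 2] - fit$mu[g, 2]
    q <- (S[2, 2] * dx^2 - 2 * S[1, 2] * dx * dy + S[1, 1] * dy^2) / dt
    dens <- dens + fit$pi[g] * exp(-log(2 * pi) - 0.5 * log(dt) - 0.5 * q)
  }
  dens
}

#' Number of mixture components for an aggregate of n points
#'
#' One component for every 5 points, but not fewer than 25 and never more
#' than n/2 (so each component can hold at least two points).
#'
#' @param n_points number of member localizations.
#' @return integer component count.
#' @export
gmm_component_count <- function(n_points) {
  pmin(pmax(25L, n_points %/% 5L), n_points %/% 2L)
}

#' Estimate an aggregate's area from a Gaussian mixture density
#'
#' Fits a full-covariance Gaussian mixture (component rule:
#' [gmm_component_count()]) to the member localizations and returns the area
#' of the region where the fitted density exceeds its average over the
#' evaluation grid (bounding box padded by 3x the largest component SD,
#' `grid_pixel` nm pixels). Singular fits are retried with a 10x ridge,
#' then flagged.
#'
#' @param points two-column matrix/data.frame of nm coordinates (>= 50
#'   points; below that the component rule is ill-posed and the frame is
#'   recorded as a gap).
#' @param grid_pixel evaluation grid pixel in nm.
#' @param seed integer seed controlling the (k-means++ style) mixture
#'   initialization; the whole estimate is reproducible given the seed.
#' @return object of class `area_estimate`: list with `area_um2`,
#'   `n_points`, `n_components`, `threshold` (density, 1/nm^2),
#'   `flagged`.
#' @export
estimate_area_gmm <- function(points, grid_pixel = 20, seed = 1L) {
  pts <- .coords(points)
  n <- nrow(pts)
  if (n < 50) stop("need at least 50 points for a GMM area estimate")
  G <- gmm_component_count(n)
  ## smoothing scale ~ inter-point spacing; mean 4th-NN distance / 2
  ## approximates the first-NN spacing of a duplicate-free point set
  ridge0 <- max(.mean_knn_dist(pts, 4L) / 2, grid_pixel / 4)^2
  fit <- NULL; flagged <- FALSE
  for (mult in c(1, 10, 100)) {
    fit <- tryCatch(.gmm_em(pts, G, seed = seed, ridge = ridge0 * mult),
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$loglik)) {
      if (mult > 1) flagged <- TRUE
      break
    }
  }
  if (is.null(fit) || !is.finite(fit$loglik))
    stop("mixture fit failed even with increased regularization")
  sdmax <- sqrt(max(vapply(seq_len(G), function(g) {
    S <- fit$Sig[, , g]
    h <- (S[1, 1] + S[2, 2]) / 2
    h + sqrt(max(h^2 - (S[1, 1] * S[2, 2] - S[1, 2]^2), 0))
  }, 0)))
  pad <- 3 * sdmax
  xs <- seq(min(pts[, 1]) - pad, max(pts[, 1]) + pad, by = grid_pixel)
  ys <- seq(min(pts[, 2]) - pad, max(pts[, 2]) + pad, by = grid_pixel)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  dg <- .gmm_density(fit, grid)
  thr <- mean(dg)
  structure(list(area_um2 = sum(dg >= thr) * (grid_pixel / 1000)^2,
                 n_points = n, n_components = G, threshold = thr,
                 flagged = flagged),
            class = "area_estimate")
}

#' Build a growth curve for one aggregate
#'
#' For each requested frame, refines the aggregate's cumulative membership
#' ([frame_membership()]) and estimates its area
#' ([estimate_area_gmm()]); time is `frame * frame_interval`. Frames with
#' fewer than `min_points` refined members are recorded as gaps. No
#' smoothing is applied: jumps and fluctuations from the mixture fitting
#' and segmentation are accepted as-is and left to the model fit.
#'
#' @param cluster an `aggregate_cluster` that passed the size filter.
#' @param table the source [localization_table()] (must carry a
#'   `frame_interval`).
#' @param frames integer vector of frames to evaluate (default: every frame
#'   from the cluster's first detection to the last table frame).
#' @param refine_k,refine_cutoff per-frame refinement parameters (see
#'   [frame_membership()]).
#' @param min_points minimum refined members for an area estimate.
#' @param grid_pixel area-grid pixel in nm.
#' @param seed seed for the mixture initializations (one deterministic
#'   sub-seed per frame).
#' @return object of class `growth_curve`: data.frame with columns `frame`,
#'   `t` (s), `area_um2`, `n_points`, plus attributes `aggregate_id`,
#'   `frame_interval`, `skipped_frames`.
#' @export
build_growth_curve <- function(cluster, table, frames = NULL,
                               refine_k = 10, refine_cutoff = 400,
                               min_points = 50, grid_pixel = 20, seed = 1L) {
  stopifnot(inherits(cluster, "aggregate_cluster"),
            inherits(table, "localization_table"))
  frame_interval <- attr(table, "frame_interval")
  if (is.na(frame_interval))
    stop("table carries no frame_interval; kinetics undefined")
  if (is.null(frames)) {
    f0 <- min(table$frame[cluster$members])
    frames <- seq.int(f0, max(table$frame))
  }
  rows <- list(); skipped <- integer(0)
  for (f in frames) {
    fm <- frame_membership(cluster, table, f, k = refine_k,
                           cutoff = refine_cutoff)
    if (length(fm$members) < min_points) {
      skipped <- c(skipped, f)
      next
    }
    est <- estimate_area_gmm(cbind(table$x[fm$members], table$y[fm$members]),
                             grid_pixel = grid_pixel,
                             seed = seed + as.integer(f))
    rows[[length(rows) + 1L]] <- data.frame(frame = f,
                                            t = f * frame_interval,
                                            area_um2 = est$area_um2,
                                            n_points = est$n_points)
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(frame = integer(0), t = numeric(0),
                        area_um2 = numeric(0), n_points = integer(0))
  growth_curve(df, frame_interval = frame_interval,
               aggregate_id = cluster$id, skipped_frames = skipped)
}

#' Construct a growth curve object
#'
#' @param data data.frame with columns `t` (s, strictly increasing) and
#'   `area_um2` (finite), optionally `frame` and `n_points`.
#' @param frame_interval seconds per frame.
#' @param aggregate_id identifier carried to rate records.
#' @param skipped_frames frames recorded as gaps.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(data, frame_interval = NA_real_, aggregate_id = 1L,
                         skipped_frames = integer(0)) {
  stopifnot(is.data.frame(data), all(c("t", "area_um2") %in% names(data)))
  if (nrow(data)) {
    stopifnot(all(diff(data$t) > 0), all(is.finite(data$area_um2)))
  }
  structure(data, frame_interval = frame_interval,
            aggregate_id = aggregate_id, skipped_frames = skipped_frames,
            class = c("growth_curve", "data.frame"))
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf(
    "growth_curve (aggregate %s): %d frames, t %g-%g s, area %.3g-%.3g um^2\n",
    attr(x, "aggregate_id"), nrow(x),
    if (nrow(x)) min(x$t) else NA, if (nrow(x)) max(x$t) else NA,
    if (nrow(x)) min(x$area_um2) else NA,
    if (nrow(x)) max(x$area_um2) else NA))
  invisible(x)
}

#' @export
plot.growth_curve <- function(x, ...) {
  plot(x$t, x$area_um2, xlab = "time (s)", ylab = expression(area ~ (mu * m^2)),
       pch = 16, cex = 0.6, ...)
  invisible(x)
}
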