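## Synthetic spherulite-growth simulator.
##
## Generates localization-event movies of growing aggregates with known
## ground truth so every downstream stage (segmentation, area estimation,
## model fitting, Arrhenius analysis) is testable without microscope data.
## The generator emulates the acquisition physics of real-time binding /
## photobleaching localization recordings: per frame, the number of newly
## bound labeled monomers is Poisson with mean proportional to the newly
## grown area of the generating growth model; each emitter stays on for a
## continuous exponential on-time (detected in every frame overlapping it,
## frame-aligned) and each detection carries isotropic Gaussian
## localization jitter.

#' Simulation configuration for one growing aggregate
#'
#' Defaults reflect the study conditions the pipeline targets: 20 s frame
#' intervals, a 200 nm-diameter condensate core, sub-frame (0.7845 frame)
#' bleaching lifetimes, and growth parameters of the order observed for
#' insulin spherulites. Isotropic growth follows the `A_par` model
#' (`r2` is the parabolic coefficient, um^2/s^2); anisotropic growth
#' follows `A_lin` (`r2` in um^2/s).
#'
#' @param morphology `"isotropic"` or `"anisotropic"`.
#' @param r1 first-phase area growth rate, um^2/s.
#' @param r2 second-phase rate (um^2/s for anisotropic, um^2/s^2 for
#'   isotropic).
#' @param t0,t1 phase-switch and saturation-onset times, s.
#' @param tau saturation time constant, s.
#' @param core_position core center `(x, y)` in nm.
#' @param frame_interval s per frame.
#' @param n_frames number of frames.
#' @param label_density expected events per um^2 of newly grown area.
#' @param loc_sigma localization jitter SD, nm.
#' @param bleach_lifetime mean emitter on-time, frames.
#' @param intensity_mean mean detected photons per localization.
#' @param core_diameter core footprint diameter, nm.
#' @param bg_rate expected non-specific background binding events per frame
#'   over the field of view (uniformly placed over the aggregate's bounding
#'   box padded by `bg_margin` nm; background emitters bleach like any
#'   other). Default 0: pure-aggregate movies, so ground-truth event counts
#'   are exactly the Poisson labeling counts.
#' @param bg_margin padding of the background field around the aggregate
#'   bounding box, nm.
#' @param branch_rate branch spawn intensity coefficient: expected branches
#'   per um of newly grown segment per um of distance from the core (the
#'   spawn rate increases linearly with distance, so branching gets denser
#'   away from the core).
#' @param branch_angle_deg half-range of the branch angle relative to the
#'   parent direction (uniform in +/- this value).
#' @param seed integer RNG seed.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(morphology = c("isotropic", "anisotropic"),
                              r1 = 0.01,
                              r2 = if (morphology[1] == "isotropic") 4e-4
                                   else 0.05,
                              t0 = if (morphology[1] == "isotropic") 200
                                   else 400,
                              t1 = if (morphology[1] == "isotropic") 2000
                                   else 3000,
                              tau = if (morphology[1] == "isotropic") 300
                                    else 500,
                              core_position = c(0, 0),
                              frame_interval = 20, n_frames = 300,
                              label_density = 50, loc_sigma = 10,
                              bleach_lifetime = 0.7845,
                              intensity_mean = 500,
                              core_diameter = 200,
                              bg_rate = 0, bg_margin = 5000,
                              branch_rate = 2, branch_angle_deg = 70,
                              seed = 1L) {
  morphology <- match.arg(morphology)
  num <- c(r1 = r1, r2 = r2, t0 = t0, t1 = t1, tau = tau,
           frame_interval = frame_interval, label_density = label_density,
           loc_sigma = loc_sigma, bleach_lifetime = bleach_lifetime)
  if (any(!is.finite(num))) stop("non-finite simulation parameter")
  if (r1 < 0 || r2 < 0) stop("growth rates must be non-negative")
  if (!(0 <= t0 && t0 <= t1)) stop("need 0 <= t0 <= t1")
  if (tau <= 0 || frame_interval <= 0) stop("tau and frame_interval must be positive")
  if (label_density <= 0) stop("label_density must be positive")
  if (loc_sigma < 0) stop("loc_sigma must be non-negative")
  if (bleach_lifetime <= 0) stop("bleach_lifetime must be positive")
  if (n_frames < 1) stop("need at least one frame")
  if (bg_rate < 0) stop("bg_rate must be non-negative")
  structure(list(morphology = morphology, r1 = r1, r2 = r2, t0 = t0,
                 t1 = t1, tau = tau, core_position = core_position,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 label_density = label_density, loc_sigma = loc_sigma,
                 bleach_lifetime = bleach_lifetime,
                 intensity_mean = intensity_mean,
                 core_diameter = core_diameter,
                 bg_rate = bg_rate, bg_margin = bg_margin,
                 branch_rate = branch_rate,
                 branch_angle_deg = branch_angle_deg,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.rot <- function(theta) matrix(c(cos(theta), sin(theta),
                                 -sin(theta), cos(theta)), 2, 2)

#' Simulate a localization movie of one growing aggregate
#'
#' The ground-truth area follows the configured growth model
#' (`A_par` for isotropic, `A_lin` for anisotropic; see [growth_rate()]),
#' starting from the core footprint area. Per frame, `Poisson(label_density
#' * newly grown area)` emitters appear: isotropic growth places them
#' uniformly in the newly grown annulus of a disk of area `A(t)`;
#' anisotropic growth places them on the newly grown portions of an
#' elongating two-armed linear core that, after `t0`, spawns branches as a
#' spatial Poisson process along new segments with a rate increasing
#' linearly with distance from the core (branch angle uniform within
#' `+/- branch_angle_deg` of the parent direction). Every emitter persists
#' for a continuous exponential on-time (mean `bleach_lifetime` frames,
#' frame-aligned sampling) and yields one localization row, with
#' independent Gaussian jitter of SD `loc_sigma`, in each frame it is on.
#'
#' @param config a [simulation_config()].
#' @return list of class `replom_sim` with elements `table`
#'   (a [localization_table()]) and `truth` (list: `area_curve` data.frame
#'   `t`/`area_um2`, `events` data.frame of per-emitter emission frame and
#'   true nm position, `morphology`, `params` ([growth_params()]),
#'   `config`).
#' @export
simulate_aggregate <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  iso <- config$morphology == "isotropic"
  w <- config$core_diameter
  A0 <- pi * (w / 2 / 1000)^2
  params <- growth_params(config$r1, config$r2, config$t0, config$t1,
                          config$tau, A0 = A0,
                          kind = if (iso) "A_par" else "A_lin")
  times <- (seq_len(config$n_frames) - 1L) * config$frame_interval
  areas <- if (length(times) > 1) integrate_model(params, times, A0) else A0
  dA <- c(A0, diff(areas))
  n_new <- stats::rpois(config$n_frames, config$label_density * dA)
  cx <- config$core_position[1]; cy <- config$core_position[2]

  ev_frame <- integer(0); ev_x <- numeric(0); ev_y <- numeric(0)

  if (iso) {
    radii <- sqrt(areas / pi) * 1000  # nm
    for (f in seq_len(config$n_frames)) {
      n <- n_new[f]
      if (n == 0) next
      r_in <- if (f == 1) 0 else radii[f - 1]
      r <- sqrt(stats::runif(n, r_in^2, radii[f]^2))
      th <- stats::runif(n, 0, 2 * pi)
      ev_frame <- c(ev_frame, rep.int(f - 1L, n))
      ev_x <- c(ev_x, cx + r * cos(th))
      ev_y <- c(ev_y, cy + r * sin(th))
    }
  } else {
    ## active tips: position (nm), unit direction, distance from core (nm)
    theta <- stats::runif(1, 0, 2 * pi)
    dirs <- rbind(c(cos(theta), sin(theta)), c(-cos(theta), -sin(theta)))
    tips <- data.frame(x = c(cx, cx), y = c(cy, cy),
                       dx = dirs[, 1], dy = dirs[, 2],
                       dist = c(0, 0))
    max_tips <- 64L
    for (f in seq_len(config$n_frames)) {
      n <- n_new[f]
      if (f == 1) {
        ## core seeding: uniform in the core disk
        if (n > 0) {
          r <- (w / 2) * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
          ev_frame <- c(ev_frame, rep.int(0L, n))
          ev_x <- c(ev_x, cx + r * cos(th)); ev_y <- c(ev_y, cy + r * sin(th))
        }
        next
      }
      dl <- dA[f] * 1e6 / (nrow(tips) * w)  # nm advance per tip
      if (dl <= 0) next
      ## place this frame's events uniformly over the newly grown segments
      if (n > 0) {
        tip_of <- sample.int(nrow(tips), n, replace = TRUE)
        a <- stats::runif(n, 0, dl)
        b <- stats::runif(n, -w / 2, w / 2)
        ev_frame <- c(ev_frame, rep.int(f - 1L, n))
        ev_x <- c(ev_x, tips$x[tip_of] + a * tips$dx[tip_of] -
                    b * tips$dy[tip_of])
        ev_y <- c(ev_y, tips$y[tip_of] + a * tips$dy[tip_of] +
                    b * tips$dx[tip_of])
      }
      ## spawn branches on the newly grown portions (phase 2 only); the
      ## spawn rate grows linearly with distance from the core
      new_tips <- NULL
      if (times[f] >= config$t0 && nrow(tips) < max_tips) {
        lam <- config$branch_rate * ((tips$dist + dl / 2) / 1000) * (dl / 1000)
        ns <- stats::rpois(nrow(tips), lam)
        for (ti in which(ns > 0)) {
          for (s in seq_len(ns[ti])) {
            if (nrow(tips) + NROW(new_tips) >= max_tips) break
            at <- stats::runif(1, 0, dl)
            ang <- stats::runif(1, -1, 1) * config$branch_angle_deg * pi / 180
            d <- .rot(ang) %*% c(tips$dx[ti], tips$dy[ti])
            px <- tips$x[ti] + at * tips$dx[ti]
            py <- tips$y[ti] + at * tips$dy[ti]
            new_tips <- rbind(new_tips,
                              data.frame(x = px, y = py, dx = d[1], dy = d[2],
                                         dist = sqrt((px - cx)^2 +
                                                       (py - cy)^2)))
          }
        }
      }
      ## advance tips
      tips$x <- tips$x + dl * tips$dx
      tips$y <- tips$y + dl * tips$dy
      tips$dist <- tips$dist + dl
      if (!is.null(new_tips)) tips <- rbind(tips, new_tips)
    }
  }

  n_ev <- length(ev_frame)
  events <- data.frame(id = seq_len(n_ev), frame = ev_frame,
                       x = ev_x, y = ev_y)
  ## non-specific background binding over the padded field of view
  n_bg_total <- 0L
  if (config$bg_rate > 0) {
    bx <- range(c(ev_x, cx)) + c(-1, 1) * config$bg_margin
    by <- range(c(ev_y, cy)) + c(-1, 1) * config$bg_margin
    n_bg <- stats::rpois(config$n_frames, config$bg_rate)
    n_bg_total <- sum(n_bg)
    ev_frame <- c(ev_frame, rep.int(seq_len(config$n_frames) - 1L, n_bg))
    ev_x <- c(ev_x, stats::runif(n_bg_total, bx[1], bx[2]))
    ev_y <- c(ev_y, stats::runif(n_bg_total, by[1], by[2]))
    n_ev <- n_ev + n_bg_total
  }
  ## bleaching: frame-aligned continuous exponential on-times
  on_frames <- if (n_ev)
    pmax(ceiling(stats::rexp(n_ev, rate = 1 / config$bleach_lifetime)), 1L)
  else integer(0)
  last <- pmin(ev_frame + on_frames - 1L, config$n_frames - 1L)
  reps <- last - ev_frame + 1L
  ridx <- rep.int(seq_len(n_ev), reps)
  det_frame <- ev_frame[ridx] +
    (sequence(reps) - 1L)
  n_det <- length(ridx)
  table <- localization_table(
    data.frame(frame = as.integer(det_frame),
               x = ev_x[ridx] + stats::rnorm(n_det, 0, config$loc_sigma),
               y = ev_y[ridx] + stats::rnorm(n_det, 0, config$loc_sigma),
               intensity = stats::rpois(n_det, config$intensity_mean),
               uncertainty = config$loc_sigma,
               id = as.integer(ridx)),
    frame_interval = config$frame_interval)
  structure(list(table = table,
                 truth = list(area_curve = data.frame(t = times,
                                                      area_um2 = areas),
                              events = events,
                              n_background = n_bg_total,
                              morphology = config$morphology,
                              params = params,
                              config = config)),
            class = "replom_sim")
}

#' @export
print.replom_sim <- function(x, ...) {
  cat(sprintf("replom_sim (%s): %d emitters, %d localizations, %d frames\n",
              x$truth$morphology, nrow(x$truth$events), nrow(x$table),
              x$truth$config$n_frames))
  invisible(x)
}

#' Specification of a per-temperature rate ensemble
#'
#' @param Ea activation energy, kJ/mol (>= 0).
#' @param lnA log Arrhenius prefactor (rate in um^2/s).
#' @param temperatures absolute temperatures, K.
#' @param n_per_temperature rates per temperature (scalar or one per
#'   temperature, each >= 2).
#' @param rate_scatter_cv coefficient of variation of the log-normal
#'   per-aggregate rate scatter.
#' @param seed integer RNG seed.
#' @return object of class `arrhenius_sim_spec`.
#' @export
arrhenius_sim_spec <- function(Ea, lnA, temperatures, n_per_temperature,
                               rate_scatter_cv = 0.3, seed = 1L) {
  if (!length(temperatures)) stop("empty temperature list")
  if (any(temperatures <= 0)) stop("temperatures must be positive (K)")
  if (Ea < 0) stop("Ea must be non-negative")
  n <- rep_len(n_per_temperature, length(temperatures))
  if (any(n < 2)) stop("need n_per_temperature >= 2")
  if (rate_scatter_cv < 0) stop("rate_scatter_cv must be non-negative")
  structure(list(Ea = Ea, lnA = lnA, temperatures = temperatures,
                 n_per_temperature = as.integer(n),
                 rate_scatter_cv = rate_scatter_cv, seed = as.integer(seed)),
            class = "arrhenius_sim_spec")
}

#' Simulate a per-temperature growth-rate ensemble
#'
#' For each temperature `T`, draws `n_per_temperature` rates log-normally:
#' `ln(rate) ~ Normal(lnA - Ea/(R T), sdlog)` with
#' `sdlog = sqrt(log(1 + cv^2))`, so the mean ln-rate lies exactly on the
#' Arrhenius line and `cv = 0` reproduces it without noise.
#'
#' @param spec an [arrhenius_sim_spec()].
#' @param phase,morphology labels carried into the records.
#' @return a `rate_records` data.frame (see [extract_rates()]).
#' @export
simulate_rate_ensemble <- function(spec, phase = "linear",
                                   morphology = "anisotropic") {
  stopifnot(inherits(spec, "arrhenius_sim_spec"))
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$rate_scatter_cv^2))
  out <- do.call(rbind, lapply(seq_along(spec$temperatures), function(i) {
    TK <- spec$temperatures[i]
    n <- spec$n_per_temperature[i]
    mu <- spec$lnA - spec$Ea * 1000 / (.R_GAS * TK)
    data.frame(aggregate_id = seq_len(n), morphology = morphology,
               phase = phase,
               rate = exp(stats::rnorm(n, mu, sdlog)),
               rate_se = NA_real_, units = "um^2/s",
               temperature_C = TK - 273.15, flagged = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("rate_records", "data.frame")
  out
}

#' Simulate a stack of single-emitter spots
#'
#' Each spot is a square pixel patch of Poisson counts drawn from an
#' isotropic 2-D Gaussian point-spread function (SD `fwhm / 2.3548`),
#' pixel-integrated, centered at the patch center plus a uniform sub-pixel
#' offset, on a uniform background.
#'
#' @param n_spots number of spots.
#' @param fwhm true full width at half maximum, nm.
#' @param photons mean photons per spot.
#' @param background mean background photons per pixel.
#' @param pixel_size pixel pitch, nm.
#' @param patch_px patch side length in pixels (odd; default just over
#'   4x FWHM). A patch smaller than 3x FWHM is rejected.
#' @param seed integer RNG seed.
#' @return object of class `spot_stack`: `patches` (list of count
#'   matrices), `pixel_nm`, `centers_nm` (true centers, one row per spot,
#'   relative to the patch origin).
#' @export
simulate_spot_stack <- function(n_spots, fwhm, photons = 500, background = 0,
                                pixel_size = 20, patch_px = NULL, seed = 1L) {
  stopifnot(n_spots >= 1, fwhm > 0, pixel_size > 0, photons > 0,
            background >= 0)
  if (is.null(patch_px)) {
    patch_px <- ceiling(4 * fwhm / pixel_size)
    if (patch_px %% 2 == 0) patch_px <- patch_px + 1L
  }
  if (patch_px * pixel_size < 3 * fwhm)
    stop("patch (", patch_px, " px) too small to contain 3x FWHM")
  set.seed(seed)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  edges <- (0:patch_px) * pixel_size
  mid <- patch_px * pixel_size / 2
  patches <- vector("list", n_spots)
  centers <- matrix(0, n_spots, 2)
  for (s in seq_len(n_spots)) {
    ctr <- mid + stats::runif(2, -0.5, 0.5) * pixel_size
    centers[s, ] <- ctr
    gx <- diff(stats::pnorm(edges, ctr[1], sigma))
    gy <- diff(stats::pnorm(edges, ctr[2], sigma))
    lambda <- photons * outer(gy, gx) + background
    patches[[s]] <- matrix(stats::rpois(length(lambda), lambda),
                           nrow = patch_px)
  }
  structure(list(patches = patches, pixel_nm = pixel_size,
                 centers_nm = centers),
            class = "spot_stack")
}

#' @export
print.spot_stack <- function(x, ...) {
  cat(sprintf("spot_stack: %d spots, %d x %d px patches at %g nm/px\n",
              length(x$patches), nrow(x$patches[[1]]), ncol(x$patches[[1]]),
              x$pixel_nm))
  invisible(x)
}

#' Simulate photobleaching on-time traces
#'
#' Emitter on-times are continuous exponential with the given mean (in
#' frame units); each emitter turns on at a frame boundary and is detected
#' in every frame its on interval overlaps, so an emitter with on-time `e`
#' spans `ceiling(e)` consecutive frames.
#'
#' @param n number of emitters (>= 1).
#' @param mean_lifetime mean on-time, frames (> 0).
#' @param seed integer RNG seed.
#' @return data.frame of class `bleach_traces`: `id`, `first_frame`,
#'   `n_frames` (frames spanned), `on_time` (continuous truth, frames).
#' @export
simulate_bleach_traces <- function(n, mean_lifetime, seed = 1L) {
  stopifnot(n >= 1, mean_lifetime > 0)
  set.seed(seed)
  e <- stats::rexp(n, rate = 1 / mean_lifetime)
  out <- data.frame(id = seq_len(n), first_frame = 0L,
                    n_frames = pmax(ceiling(e), 1L), on_time = e)
  class(out) <- c("bleach_traces", "data.frame")
  out
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param sim a `replom_sim` from [simulate_aggregate()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  stopifnot(inherits(sim, "replom_sim"))
  tr <- sim$truth
  jsonlite::write_json(
    list(morphology = tr$morphology,
         params = c(unclass(tr$params), kind = attr(tr$params, "kind")),
         area_curve = tr$area_curve,
         events = tr$events,
         config = unclass(tr$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
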