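## Neighbor-density computation and super-resolution map rendering.
##
## Rendering follows the usual SMLM convention for density maps: every
## localization carries the number of other localizations within a fixed
## radius (100 nm by default), and the map shows that count at the
## localization's position.

#' Per-localization neighbor counts
#'
#' For each localization, counts the number of *other* localizations within
#' Euclidean distance `radius` (2-D disk; the localization itself is
#' excluded, so an isolated event reads zero density).
#'
#' @param table a [localization_table()] (or a 2-column matrix of nm
#'   coordinates).
#' @param radius neighborhood radius in nm.
#' @return integer vector of counts, one per localization.
#' @export
local_neighbor_density <- function(table, radius = 100) {
  stopifnot(radius > 0)
  pts <- .coords(table)
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  counts <- integer(n)
  r2 <- radius^2
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    dx <- outer(pts[idx, 1], pts[, 1], "-")
    dy <- outer(pts[idx, 2], pts[, 2], "-")
    counts[idx] <- rowSums(dx * dx + dy * dy <= r2) - 1L
  }
  counts
}

.coords <- function(x) {
  if (inherits(x, "localization_table") || is.data.frame(x))
    cbind(x$x, x$y)
  else as.matrix(x)
}

#' Render a neighbor-density map
#'
#' Rasterizes localizations onto a pixel grid covering their bounding box;
#' each localization carries its neighbor count (see
#' [local_neighbor_density()]) and overlapping localizations accumulate by
#' maximum, preserving the per-localization density semantics. Pixels use
#' half-open bins `[k*pixel, (k+1)*pixel)`.
#'
#' @param table a [localization_table()].
#' @param pixel pixel size in nm.
#' @param radius neighbor-count radius in nm.
#' @param clip optional upper display clip; counts above it are saturated
#'   (presentation only, e.g. 0-1000 or 0-400 pseudocolor ranges).
#' @return object of class `density_map`: a numeric matrix (rows = y) with
#'   attributes `pixel_nm`, `origin_nm` (xmin, ymin) and `radius_nm`.
#' @export
render_density_map <- function(table, pixel = 20, radius = 100, clip = NULL) {
  stopifnot(pixel > 0)
  pts <- .coords(table)
  if (nrow(pts) == 0) stop("cannot render an empty table")
  counts <- local_neighbor_density(pts, radius = radius)
  if (!is.null(clip)) counts <- pmin(counts, clip)
  origin <- c(min(pts[, 1]), min(pts[, 2]))
  cx <- floor((pts[, 1] - origin[1]) / pixel) + 1L
  cy <- floor((pts[, 2] - origin[2]) / pixel) + 1L
  map <- matrix(0, nrow = max(cy), ncol = max(cx))
  ## max-accumulate: process in increasing count order so the last write wins
  ord <- order(counts)
  map[cbind(cy[ord], cx[ord])] <- counts[ord]
  structure(map, pixel_nm = pixel, origin_nm = origin, radius_nm = radius,
            class = c("density_map", "matrix", "array"))
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d x %d px (%g nm/px), radius %g nm, max %g\n",
              nrow(x), ncol(x), attr(x, "pixel_nm"), attr(x, "radius_nm"),
              max(x)))
  invisible(x)
}

#' Write a density map as 32-bit float TIFF plus JSON sidecar
#'
#' The TIFF stores counts normalized to `[0, 1]`; the sidecar records the
#' normalization maximum, pixel size, origin and radius so the map can be
#' reconstructed exactly.
#'
#' @param map a `density_map` from [render_density_map()].
#' @param path output TIFF path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  mx <- max(map, 1)
  tiff::writeTIFF(unclass(map) / mx, path, bits.per.sample = 32L,
                  reduce = FALSE)
  sidecar <- list(pixel_nm = attr(map, "pixel_nm"),
                  origin_nm = attr(map, "origin_nm"),
                  radius_nm = attr(map, "radius_nm"),
                  max_count = mx,
                  nrow = nrow(map), ncol = ncol(map))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
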