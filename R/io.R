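#' Construct a localization table
#'
#' A localization table is the universal pipeline input: one row per detected
#' single-emitter event, with the acquisition frame index, coordinates in nm,
#' photon count and (optionally) the localization uncertainty reported by the
#' localizer.
#'
#' @param data data.frame with columns `frame` (integer, >= 0), `x`, `y`
#'   (nm), and optionally `intensity` (photons), `uncertainty` (nm), `id`.
#'   Extra columns are kept untouched.
#' @param frame_interval acquisition interval in seconds per frame (`NA` if
#'   kinetics are not needed).
#' @param temperature incubation temperature in degrees Celsius (optional
#'   metadata carried through to rate records).
#' @return object of class `localization_table` (a data.frame sorted by
#'   frame, with `frame_interval` and `temperature` attributes).
#' @export
localization_table <- function(data, frame_interval = NA_real_,
                               temperature = NA_real_) {
  stopifnot(is.data.frame(data))
  req <- c("frame", "x", "y")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("localization table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(data)) {
    bad <- which(!is.finite(data$x) | !is.finite(data$y))
    if (length(bad))
      stop("localization coordinates must be finite (first bad row: ",
           bad[1], ")")
    if (any(data$frame < 0)) stop("frame indices must be non-negative")
  }
  if (!is.na(frame_interval) && frame_interval <= 0)
    stop("frame_interval must be positive")
  if (!"intensity" %in% names(data)) data$intensity <- NA_real_
  if (!"uncertainty" %in% names(data)) data$uncertainty <- NA_real_
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))
  data <- data[order(data$frame), , drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            frame_interval = frame_interval,
            temperature = temperature,
            class = c("localization_table", "data.frame"))
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("localization_table: %d localizations, frames %s-%s\n",
              nrow(x),
              if (nrow(x)) min(x$frame) else "-",
              if (nrow(x)) max(x$frame) else "-"))
  if (!is.na(attr(x, "frame_interval")))
    cat(sprintf("  frame interval: %g s\n", attr(x, "frame_interval")))
  if (!is.na(attr(x, "temperature")))
    cat(sprintf("  temperature: %g degC\n", attr(x, "temperature")))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

## Header tokens of the de-facto SMLM table dialect: a bare name with an
## optional bracketed unit, e.g. `x [nm]` or `intensity [photon]`.
.parse_header_token <- function(tok) {
  tok <- trimws(gsub('^"|"$', "", tok))
  m <- regmatches(tok, regexec("^(.*?)\\s*\\[(.*)\\]$", tok))[[1]]
  if (length(m) == 3) list(name = tolower(trimws(m[2])), unit = tolower(m[3]))
  else list(name = tolower(tok), unit = "")
}

.length_unit_to_nm <- function(unit) {
  if (unit == "" || unit == "nm") return(1)
  if (unit %in% c("um", "µm", "micron", "microns")) return(1000)
  stop("unsupported length unit in header: [", unit, "]")
}

#' Read a delimited localization table
#'
#' Reads the comma-separated localization-table dialect written by standard
#' SMLM localizers: a quoted header whose tokens carry bracketed units
#' (`frame,"x [nm]","y [nm]","intensity [photon]","uncertainty [nm]"`),
#' one row per localization. Coordinates are normalized to nm on read
#' (`[um]` columns are multiplied by 1000). Unknown columns are preserved.
#'
#' @param path file path.
#' @param frame_interval,temperature metadata attached to the table (see
#'   [localization_table()]).
#' @return a [localization_table()].
#' @export
read_localizations <- function(path, frame_interval = NA_real_,
                               temperature = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  toks <- scan(text = header, what = character(), sep = ",", quiet = TRUE)
  parsed <- lapply(toks, .parse_header_token)
  nm <- vapply(parsed, `[[`, "", "name")
  df <- utils::read.csv(path, skip = 1L, header = FALSE,
                        col.names = make.names(nm, unique = TRUE),
                        check.names = FALSE)
  names(df) <- make.names(nm, unique = TRUE)
  col_of <- function(want) {
    hit <- which(nm == want)
    if (length(hit)) hit[1] else NA_integer_
  }
  ix <- col_of("x"); iy <- col_of("y"); ifr <- col_of("frame")
  bad <- c("x", "y", "frame")[is.na(c(ix, iy, ifr))]
  if (length(bad))
    stop("file ", path, ": missing required column(s) ",
         paste(bad, collapse = ", "),
         " in header: ", paste(toks, collapse = " | "))
  out <- data.frame(
    frame = as.integer(df[[ifr]]),
    x = df[[ix]] * .length_unit_to_nm(parsed[[ix]]$unit),
    y = df[[iy]] * .length_unit_to_nm(parsed[[iy]]$unit))
  ii <- col_of("intensity")
  if (!is.na(ii)) out$intensity <- df[[ii]]
  iu <- col_of("uncertainty")
  if (!is.na(iu)) out$uncertainty <- df[[iu]] *
      .length_unit_to_nm(parsed[[iu]]$unit)
  iid <- col_of("id")
  if (!is.na(iid)) out$id <- as.integer(df[[iid]])
  extra <- setdiff(seq_along(nm), c(ix, iy, ifr, ii, iu, iid))
  for (j in extra) out[[names(df)[j]]] <- df[[j]]
  localization_table(out, frame_interval = frame_interval,
                     temperature = temperature)
}

#' Write a localization table
#'
#' Writes the dialect read by [read_localizations()]: comma-separated with a
#' quoted, unit-bearing header; coordinates in nm.
#'
#' @param table a [localization_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  stopifnot(inherits(table, "localization_table"))
  core <- c("frame", "x", "y", "intensity", "uncertainty", "id")
  extra <- setdiff(names(table), core)
  hdr <- c("frame", "\"x [nm]\"", "\"y [nm]\"", "\"intensity [photon]\"",
           "\"uncertainty [nm]\"", "id",
           if (length(extra)) paste0("\"", extra, "\""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  df <- as.data.frame(table)[, c(core, extra), drop = FALSE]
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Filter localizations by photon count
#'
#' Removes poor-quality detections below a photon-count threshold, preserving
#' row order. Applying the same filter twice is a no-op.
#'
#' @param table a [localization_table()].
#' @param min_intensity minimum photon count retained (>= 0).
#' @return filtered [localization_table()].
#' @export
filter_by_intensity <- function(table, min_intensity) {
  stopifnot(inherits(table, "localization_table"), min_intensity >= 0)
  keep <- !is.na(table$intensity) & table$intensity >= min_intensity
  if (min_intensity == 0) keep <- keep | is.na(table$intensity)
  out <- as.data.frame(table)[keep, , drop = FALSE]
  localization_table(out,
                     frame_interval = attr(table, "frame_interval"),
                     temperature = attr(table, "temperature"))
}
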