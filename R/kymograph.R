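#' Kymograph container
#'
#' A kymograph is the primary image object of confocal line-scanning
#' experiments on stretched DNA tethers: rows are successive scan lines
#' (time), columns are position along the DNA. A `Kymograph` holds one
#' intensity matrix per fluorescence channel plus the physical metadata
#' needed to convert pixel indices to micrometres and scan lines to seconds.
#'
#' The physical position of column `c` (0-based) is
#' `(c + 0.5 + origin_offset) * pixel_size_nm / 1000` micrometres, so
#' coordinates are preserved when saturated bead columns are cropped away
#' (`origin_offset` records how many columns were removed on the left).
#'
#' @param channels Named list of numeric matrices, all with identical
#'   dimensions, finite and non-negative.
#' @param pixel_size_nm Pixel size along the DNA, nanometres (> 0).
#' @param line_time_s Time per scan line, seconds (> 0).
#' @param origin_offset Pixel index of column 0 relative to the uncropped
#'   image (default 0).
#' @return An object of class `Kymograph`.
#' @examples
#' k <- Kymograph(list(eGFP = matrix(0, 10, 20)), pixel_size_nm = 100,
#'                line_time_s = 0.25)
#' dim(k$channels$eGFP)
#' @export
Kymograph <- function(channels, pixel_size_nm, line_time_s,
                      origin_offset = 0) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("'channels' must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m),
                 logical(1))))
    stop("every channel must be a numeric matrix")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share an identical shape")
  for (nm in names(channels)) {
    m <- channels[[nm]]
    if (any(!is.finite(m)) || any(m < 0))
      stop(sprintf("channel '%s' contains non-finite or negative intensities",
                   nm))
    storage.mode(channels[[nm]]) <- "double"
  }
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  stop_if_not_scalar_pos(line_time_s, "line_time_s")
  structure(list(channels = channels,
                 pixel_size_nm = pixel_size_nm,
                 line_time_s = line_time_s,
                 origin_offset = as.numeric(origin_offset)),
            class = "Kymograph")
}

#' @export
print.Kymograph <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "Kymograph: %d line(s) x %d px, %d channel(s) [%s]\n",
    d[1], d[2], length(x$channels), paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel size %g nm, line time %g s, origin offset %g px\n",
              x$pixel_size_nm, x$line_time_s, x$origin_offset))
  invisible(x)
}

#' @export
dim.Kymograph <- function(x) dim(x$channels[[1]])

#' Physical column centres of a kymograph, in micrometres
#' @param kymo A [Kymograph].
#' @return Numeric vector, one value per column.
#' @export
column_positions_um <- function(kymo) {
  stopifnot(inherits(kymo, "Kymograph"))
  w <- ncol(kymo$channels[[1]])
  ((seq_len(w) - 1) + 0.5 + kymo$origin_offset) * kymo$pixel_size_nm / 1000
}

#' Single-particle trajectory
#'
#' Time-ordered sub-pixel positions of one tracked particle in physical
#' units. Positions are in micrometres along the tether, times in seconds.
#'
#' @param time_s Strictly increasing numeric vector of times (s).
#' @param position_um Positions (um), same length as `time_s` (>= 2 samples).
#' @param id Trajectory identifier (scalar).
#' @param channel Channel name the trajectory was tracked in.
#' @param frame Optional integer source scan-line indices.
#' @return A data frame of class `Trajectory` with columns `frame`,
#'   `time_s`, `position_um` and attributes `id` and `channel`.
#' @export
Trajectory <- function(time_s, position_um, id = 1L, channel = "eGFP",
                       frame = NULL) {
  time_s <- as.numeric(time_s); position_um <- as.numeric(position_um)
  if (length(time_s) < 2L) stop("a Trajectory needs at least 2 samples")
  if (length(position_um) != length(time_s))
    stop("'time_s' and 'position_um' must have equal length")
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(position_um))) stop("positions must be finite")
  if (is.null(frame)) frame <- seq_along(time_s) - 1L
  out <- data.frame(frame = as.integer(frame), time_s = time_s,
                    position_um = position_um)
  attr(out, "id") <- id
  attr(out, "channel") <- channel
  class(out) <- c("Trajectory", "data.frame")
  out
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %s (%s): %d samples, %.3g-%.3g s\n",
              format(attr(x, "id")), attr(x, "channel"), nrow(x),
              min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Force-extension curve
#'
#' Ordered (distance, force) samples from a single optical-tweezers pull.
#' Distances must be strictly increasing within the pull.
#'
#' @param distance_um Strictly increasing distances (um).
#' @param force_pN Finite forces (pN), same length.
#' @return A data frame of class `ForceExtensionCurve`.
#' @export
ForceExtensionCurve <- function(distance_um, force_pN) {
  distance_um <- as.numeric(distance_um); force_pN <- as.numeric(force_pN)
  if (length(distance_um) != length(force_pN))
    stop("'distance_um' and 'force_pN' must have equal length")
  if (any(diff(distance_um) <= 0))
    stop("distances must be strictly increasing within a pull")
  if (any(!is.finite(force_pN))) stop("forces must be finite")
  out <- data.frame(distance_um = distance_um, force_pN = force_pN)
  class(out) <- c("ForceExtensionCurve", "data.frame")
  out
}
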