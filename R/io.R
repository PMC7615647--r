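#' Write a kymograph as multi-page TIFF plus JSON sidecar
#'
#' One uncompressed grayscale page per channel, in the declared channel
#' order, with metadata (`pixel_size_nm`, `line_time_s`, `channels`,
#' `origin_offset`) in a JSON sidecar `<path>.json` rather than TIFF tags,
#' for bit-exact portability.
#'
#' @param kymo A [Kymograph].
#' @param path Output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @param format TIFF sample format, `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @seealso [read_kymograph()]
#' @export
write_kymograph <- function(kymo, path, format = c("float32", "uint16")) {
  stopifnot(inherits(kymo, "Kymograph"))
  format <- match.arg(format)
  write_tiff_pages(kymo$channels, path, format = format)
  meta <- list(pixel_size_nm = kymo$pixel_size_nm,
               line_time_s = kymo$line_time_s,
               channels = as.list(names(kymo$channels)),
               origin_offset = kymo$origin_offset)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a kymograph from a multi-page TIFF
#'
#' Metadata is taken from the JSON sidecar written by [write_kymograph()],
#' or supplied explicitly (explicit arguments win; metadata is never
#' inferred from the image). The number of declared channel names must
#' match the page count.
#'
#' @param path TIFF file with one grayscale page per channel.
#' @param pixel_size_nm,line_time_s Physical metadata; required if no
#'   sidecar is present.
#' @param channels Character vector of channel names in page order.
#' @param origin_offset Pixel origin offset (default from sidecar, else 0).
#' @return A [Kymograph].
#' @export
read_kymograph <- function(path, pixel_size_nm = NULL, line_time_s = NULL,
                           channels = NULL, origin_offset = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  pixel_size_nm <- pixel_size_nm %||% meta$pixel_size_nm
  line_time_s <- line_time_s %||% meta$line_time_s
  channels <- channels %||% unlist(meta$channels)
  origin_offset <- origin_offset %||% (meta$origin_offset %||% 0)
  if (is.null(pixel_size_nm) || is.null(line_time_s) || is.null(channels))
    stop("pixel_size_nm, line_time_s and channel names must come from the ",
         "JSON sidecar or be given explicitly; they are never inferred")
  pages <- read_tiff_pages(path)
  if (length(pages) != length(channels))
    stop(sprintf("channel mismatch: %d page(s) in file, %d name(s) declared",
                 length(pages), length(channels)))
  names(pages) <- channels
  Kymograph(pages, pixel_size_nm = as.numeric(pixel_size_nm),
            line_time_s = as.numeric(line_time_s),
            origin_offset = as.numeric(origin_offset))
}

#' Write trajectories to CSV
#'
#' Columns `trajectory_id,channel,frame,time_s,position_um`, one row per
#' sample, numeric values at full double precision. [read_trajectories()]
#' inverts it exactly. An empty list yields a header-only file.
#'
#' @param trajs List of [Trajectory] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  stopifnot(is.list(trajs))
  rows <- lapply(trajs, function(tr) {
    stopifnot(inherits(tr, "Trajectory"))
    data.frame(trajectory_id = attr(tr, "id"), channel = attr(tr, "channel"),
               frame = tr$frame, time_s = tr$time_s,
               position_um = tr$position_um)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(trajectory_id = character(), channel = character(),
                         frame = integer(), time_s = numeric(),
                         position_um = numeric())
  write_csv_full(out, path)
}

#' Read trajectories from CSV
#'
#' @param path CSV written by [write_trajectories()].
#' @return List of [Trajectory] objects, in order of first appearance.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, colClasses = c(
    trajectory_id = "character", channel = "character", frame = "integer",
    time_s = "numeric", position_um = "numeric"))
  if (nrow(df) == 0L) return(list())
  ids <- unique(df$trajectory_id)
  lapply(ids, function(id) {
    d <- df[df$trajectory_id == id, ]
    Trajectory(d$time_s, d$position_um, id = type.convert(id, as.is = TRUE),
               channel = d$channel[1], frame = d$frame)
  })
}

#' Read a force-extension curve from CSV
#'
#' Requires columns `distance_um` and `force_pN`. Rows with missing values
#' are dropped with a message; out-of-order distances are an error (samples
#' are never silently reordered).
#'
#' @param path CSV file.
#' @return A [ForceExtensionCurve].
#' @export
read_fec <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("distance_um", "force_pN") %in% names(df)))
    stop("force-extension CSV must have columns 'distance_um' and 'force_pN'")
  bad <- !is.finite(df$distance_um) | !is.finite(df$force_pN)
  if (any(bad)) {
    message(sprintf("read_fec: dropped %d row(s) with missing values",
                    sum(bad)))
    df <- df[!bad, ]
  }
  ForceExtensionCurve(df$distance_um, df$force_pN)
}

#' Write a force-extension curve to CSV
#' @param curve A [ForceExtensionCurve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fec <- function(curve, path) {
  stopifnot(inherits(curve, "ForceExtensionCurve"))
  write_csv_full(as.data.frame(curve), path)
}

#' Default run configuration
#'
#' All tunables of the pipeline in one nested list, each with the
#' experiment's stated value as default where one exists: 100-nm pixels,
#' 0.25-s lines, 3-frame localization window, window-51/order-3
#' Savitzky-Golay smoothing, 0.25-2-s MSD fitting window, 0.01-um^2/s
#' static threshold, 7-s dwell bins, 60-s nucleation window, 200-nt
#' position bins over a 5,374-nt gap, and eWLC parameters Lp = 100 nm,
#' S = 1000 pN, T = 297 K, 0.34 nm/bp.
#'
#' @param ... Named overrides for any top-level section, e.g.
#'   `tracking = list(sg_window = 31)` (merged field-by-field).
#' @return Nested list of class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    imaging = list(pixel_size_nm = 100, line_time_s = 0.25),
    tracking = list(window_frames = 3L, detect_threshold_sd = 3,
                    max_step_um = 0.5, max_gap_frames = 3L,
                    min_track_frames = 10L, sg_window = 51L, sg_order = 3L,
                    overlap_radius_px = 3, fit_halfwidth_px = 5L,
                    sigma_bounds_px = c(0.7, 3), min_amplitude_sd = 5),
    diffusion = list(fit_window_s = c(0.25, 2.0), convention = "paper",
                     static_threshold = 0.01, alpha_directed_margin = 0.2,
                     min_fit_samples = 10L, min_fit_duration_s = 2.5),
    kinetics = list(detect_threshold_sd = 3, close_lines = 2L, close_px = 2L,
                    co_tolerance_lines = 1L, coloc_radius_px = 2,
                    dwell_bin_s = 7, nucleation_window_s = 60,
                    bin_nt = 200, gap_nt = 5374, junction_bins = 3L),
    photobleach = list(min_segment = 3L, min_step_sd = 2,
                       penalty_factor = 2),
    mechanics = list(Lp_nm = 100, S_pN = 1000, T_K = 297, rise_per_bp = 0.34,
                     fit_force_range_pN = c(2, 40), min_delta_Lc_nm = 10,
                     residual_threshold_nm = 100))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  validate_run_config(structure(cfg, class = "RunConfig"))
}

#' Validate a run configuration
#' @param cfg A `RunConfig` (or plain list with the same shape).
#' @return `cfg` invisibly-validated (errors on violation).
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("run config must declare a 'seed'")
  tr <- cfg$tracking
  if (tr$window_frames %% 2L != 1L) stop("window_frames must be odd")
  if (tr$sg_window %% 2L != 1L || tr$sg_window <= tr$sg_order)
    stop("sg_window must be odd and greater than sg_order")
  stop_if_not_scalar_pos(cfg$imaging$pixel_size_nm, "pixel_size_nm")
  stop_if_not_scalar_pos(cfg$imaging$line_time_s, "line_time_s")
  if (!is.structure_class(cfg, "RunConfig")) class(cfg) <- "RunConfig"
  cfg
}

is.structure_class <- function(x, cls) inherits(x, cls)

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @return For `read_run_config`, a validated `RunConfig`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- run_config()
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && is.list(base[[nm]]))
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  validate_run_config(base)
}

#' @rdname read_run_config
#' @param cfg A `RunConfig`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
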