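#' Video metadata for a scene-camera recording
#'
#' Describes the egocentric (scene-camera) video that gaze coordinates refer
#' to. Either `duration` or `n_frames` may be omitted and is derived from the
#' other; when both are given they must agree to within one frame.
#'
#' @param width,height Frame size in pixels (>= 1).
#' @param fps Frame rate in frames per second (> 0).
#' @param duration Recording length in seconds (>= 0).
#' @param n_frames Number of frames (>= 0).
#' @return An object of class `video_meta`.
#' @examples
#' video_meta(1088, 1080, fps = 30, duration = 336)
#' @export
video_meta <- function(width, height, fps, duration = NULL, n_frames = NULL) {
  if (width < 1 || height < 1) stop("frame dimensions must be >= 1")
  if (fps <= 0) stop("fps must be > 0")
  if (is.null(duration) && is.null(n_frames))
    stop("supply at least one of `duration`, `n_frames`")
  if (is.null(n_frames)) n_frames <- as.integer(round(duration * fps))
  if (is.null(duration)) duration <- n_frames / fps
  if (abs(n_frames - round(duration * fps)) > 1)
    stop(sprintf("n_frames (%d) inconsistent with duration * fps (%.1f)",
                 n_frames, duration * fps))
  structure(
    list(width = as.integer(width), height = as.integer(height),
         fps = fps, duration = duration, n_frames = as.integer(n_frames)),
    class = "video_meta"
  )
}

#' @export
print.video_meta <- function(x, ...) {
  cat(sprintf("<video_meta> %dx%d @ %g fps, %.3f s (%d frames)\n",
              x$width, x$height, x$fps, x$duration, x$n_frames))
  invisible(x)
}

#' Map a time in seconds to a video frame index
#'
#' Frame indices are zero-based: a time `t` maps to `floor(t * fps)`, capped
#' at `n_frames - 1` so that `t == duration` still returns the last frame.
#'
#' @param t Time(s) in seconds; must lie in `[0, duration]`. Vectorized.
#' @param meta A [video_meta()].
#' @return Integer frame index (0-based), same length as `t`.
#' @examples
#' m <- video_meta(640, 480, fps = 30, duration = 10)
#' frame_index_for_time(c(0, 1, 9.99), m)
#' @export
frame_index_for_time <- function(t, meta) {
  stopifnot(inherits(meta, "video_meta"))
  if (any(t < 0 | t > meta$duration))
    stop(sprintf("time outside [0, %g]: %g", meta$duration,
                 t[which(t < 0 | t > meta$duration)[1]]))
  pmin(as.integer(floor(t * meta$fps)), meta$n_frames - 1L)
}

#' Convert normalized gaze coordinates to pixel coordinates
#'
#' Normalized coordinates have their origin at the top-left of the frame,
#' x rightward and y downward (the common scene-camera export convention).
#' Pixels are 0-based: `px = min(floor(x_norm * width), width - 1)`, so the
#' mapping is total on the closed interval `[0, 1]`.
#'
#' @param x_norm,y_norm Normalized coordinates in `[0, 1]`. Vectorized.
#' @param meta A [video_meta()].
#' @param y_axis `"down"` (default) or `"up"`; some exporters place the
#'   normalized origin at the bottom-left, in which case y is flipped here.
#' @return A list with integer vectors `x_px`, `y_px` (0-based).
#' @export
norm_to_pixel <- function(x_norm, y_norm, meta, y_axis = c("down", "up")) {
  y_axis <- match.arg(y_axis)
  if (y_axis == "up") y_norm <- 1 - y_norm
  list(
    x_px = pmax(0L, pmin(as.integer(floor(x_norm * meta$width)),  meta$width  - 1L)),
    y_px = pmax(0L, pmin(as.integer(floor(y_norm * meta$height)), meta$height - 1L))
  )
}

#' Construct a gaze recording
#'
#' @param samples A data frame with numeric columns `t` (seconds, sorted
#'   non-decreasing), `x_norm`, `y_norm` in `[0, 1]` and optionally an
#'   integer `frame_index`.
#' @param rate_hz Nominal sampling rate in Hz (> 0), e.g. 200.
#' @param meta A [video_meta()].
#' @param n_clamped,n_dropped Bookkeeping from ingestion (see
#'   [load_gaze_csv()]).
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, rate_hz, meta, n_clamped = 0L, n_dropped = 0L) {
  stopifnot(is.data.frame(samples), rate_hz > 0, inherits(meta, "video_meta"))
  need <- c("t", "x_norm", "y_norm")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples missing column(s): ", paste(miss, collapse = ", "))
  if (is.unsorted(samples$t)) stop("samples must be sorted by t")
  if (nrow(samples) && any(samples$t < 0)) stop("timestamps must be >= 0")
  structure(
    list(samples = samples, rate_hz = rate_hz, meta = meta,
         n_clamped = as.integer(n_clamped), n_dropped = as.integer(n_dropped)),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %d samples @ %g Hz (%d clamped, %d dropped)\n",
              nrow(x$samples), x$rate_hz, x$n_clamped, x$n_dropped))
  invisible(x)
}

#' Read a gaze export from delimited text
#'
#' Reads a CSV/TSV export of per-sample gaze with a timestamp and normalized
#' X/Y, as produced by wearable eye-trackers. The delimiter is sniffed from
#' the header line (tab, semicolon, else comma). Column names are remapped
#' through `column_map`; the frame-index column is optional and, when
#' present, takes precedence downstream over the fps-based time mapping
#' (trusting the device's own synchronization).
#'
#' Samples slightly outside the frame are common around blinks; the
#' `clamp_policy` decides their fate:
#' \describe{
#'   \item{clamp}{coordinates are clipped into `[0, 1]` (default); the count
#'     of affected rows is kept in the returned recording and warned about.}
#'   \item{drop}{affected rows are removed.}
#'   \item{error}{any out-of-range coordinate aborts.}
#' }
#' Under `clamp`/`drop` the samples are additionally sorted by timestamp;
#' under `error`, non-monotone timestamps abort with the first offending
#' row index.
#'
#' @param path Path to the delimited file.
#' @param meta A [video_meta()] describing the matching scene video.
#' @param rate_hz Nominal sampling rate in Hz.
#' @param column_map Named character vector mapping the roles `t`, `x`, `y`
#'   and (optionally) `frame` to column names in the file.
#' @param clamp_policy One of `"clamp"`, `"drop"`, `"error"`.
#' @return A [gaze_recording()].
#' @export
load_gaze_csv <- function(path, meta, rate_hz,
                          column_map = c(t = "t", x = "x_norm", y = "y_norm",
                                         frame = "frame_index"),
                          clamp_policy = c("clamp", "drop", "error")) {
  clamp_policy <- match.arg(clamp_policy)
  if (!file.exists(path)) stop("gaze file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (role in c("t", "x", "y")) {
    col <- unname(column_map[[role]])
    if (is.null(col) || !col %in% names(raw))
      stop(sprintf("configuration error: required column '%s' (role '%s') not in file",
                   if (is.null(col)) role else col, role))
  }
  df <- data.frame(
    t = as.numeric(raw[[column_map[["t"]]]]),
    x_norm = as.numeric(raw[[column_map[["x"]]]]),
    y_norm = as.numeric(raw[[column_map[["y"]]]])
  )
  if (any(is.na(df$t))) stop("timestamps not parseable as numbers")
  fcol <- if ("frame" %in% names(column_map)) unname(column_map[["frame"]]) else NULL
  if (!is.null(fcol) && fcol %in% names(raw))
    df$frame_index <- as.integer(raw[[fcol]])

  oob <- df$x_norm < 0 | df$x_norm > 1 | df$y_norm < 0 | df$y_norm > 1
  n_clamped <- 0L; n_dropped <- 0L
  if (any(oob)) {
    if (clamp_policy == "error") {
      stop(sprintf("data error: out-of-range coordinates at row %d", which(oob)[1]))
    } else if (clamp_policy == "drop") {
      n_dropped <- sum(oob)
      df <- df[!oob, , drop = FALSE]
      warning(sprintf("dropped %d out-of-range gaze sample(s)", n_dropped))
    } else {
      n_clamped <- sum(oob)
      df$x_norm <- pmin(pmax(df$x_norm, 0), 1)
      df$y_norm <- pmin(pmax(df$y_norm, 0), 1)
      warning(sprintf("clamped %d out-of-range gaze sample(s) into [0,1]", n_clamped))
    }
  }
  if (is.unsorted(df$t)) {
    if (clamp_policy == "error") {
      bad <- which(diff(df$t) < 0)[1] + 1L
      stop(sprintf("data error: non-monotone timestamp at row %d", bad))
    }
    df <- df[order(df$t), , drop = FALSE]
  }
  rownames(df) <- NULL
  gaze_recording(df, rate_hz = rate_hz, meta = meta,
                 n_clamped = n_clamped, n_dropped = n_dropped)
}

#' Write a gaze recording back to CSV
#'
#' Round-trips with [load_gaze_csv()]: timestamps and coordinates are
#' written at full double precision.
#'
#' @param rec A [gaze_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  df <- rec$samples
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract frames from a directory of image files
#'
#' Video containers are expected to be pre-split into individual frames
#' named by zero-padded 0-based index (e.g. `frame_000041.png`); any PNG
#' file whose name contains the bare index also matches. Frames that exist
#' but cannot be decoded are reported with a warning and omitted from the
#' result rather than silently skipped.
#'
#' @param frames_dir Directory containing the frame images.
#' @param indices Integer vector of 0-based frame indices (may be empty).
#' @param meta Optional [video_meta()]; when given, every index must be
#'   `< n_frames` and decoded frames must match `height` x `width`.
#' @return Named list mapping `"<index>"` to an image array as returned by
#'   [png::readPNG()].
#' @export
extract_frames <- function(frames_dir, indices, meta = NULL) {
  indices <- as.integer(indices)
  if (!length(indices)) return(structure(list(), names = character(0)))
  if (!dir.exists(frames_dir)) stop("I/O error: no such directory: ", frames_dir)
  if (!is.null(meta) && any(indices >= meta$n_frames))
    stop(sprintf("range error: frame index %d >= n_frames (%d)",
                 max(indices), meta$n_frames))
  if (any(indices < 0)) stop("range error: negative frame index")
  files <- list.files(frames_dir, pattern = "\\.png$", full.names = TRUE)
  nums <- suppressWarnings(as.integer(sub("^.*?(\\d+)\\.png$", "\\1", basename(files))))
  out <- list()
  failed <- integer(0)
  for (idx in unique(indices)) {
    f <- files[which(nums == idx)][1]
    if (is.na(f)) { failed <- c(failed, idx); next }
    img <- tryCatch(png::readPNG(f), error = function(e) NULL)
    if (is.null(img)) { failed <- c(failed, idx); next }
    if (!is.null(meta) && (dim(img)[1] != meta$height || dim(img)[2] != meta$width))
      stop(sprintf("frame %d has shape %dx%d, expected %dx%d",
                   idx, dim(img)[1], dim(img)[2], meta$height, meta$width))
    out[[as.character(idx)]] <- img
  }
  if (length(failed))
    warning("frame(s) not decodable or missing: ", paste(failed, collapse = ", "))
  out
}
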