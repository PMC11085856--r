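#' Configuration for dispersion-threshold (IDT) fixation detection
#'
#' The dispersion threshold can be given directly in normalized scene-camera
#' units, or in degrees of visual angle, in which case it is divided by the
#' horizontal field of view (`fov_deg`) to obtain a normalized value; the
#' same isotropic factor applies to both axes. The default of 0.02 degrees
#' with a 100 ms minimum duration reproduces a published mobile-eye-tracking
#' setting; note that 0.02 degrees is far below the 0.5--1 degree range
#' typical for IDT and likely reflects an exporter-specific scaling -- it is
#' kept as-is rather than silently adjusted.
#'
#' @param dispersion_threshold Maximum dispersion of a fixation window
#'   (> 0), in `unit`.
#' @param unit `"degrees"` or `"normalized"`.
#' @param duration_threshold Minimum fixation duration in seconds (> 0);
#'   default 0.100.
#' @param fov_deg Horizontal field of view in degrees; required when
#'   `unit = "degrees"` at detection time.
#' @return An object of class `idt_config`.
#' @export
idt_config <- function(dispersion_threshold = 0.02,
                       unit = c("degrees", "normalized"),
                       duration_threshold = 0.100,
                       fov_deg = NULL) {
  unit <- match.arg(unit)
  if (dispersion_threshold <= 0 || duration_threshold <= 0)
    stop("thresholds must be > 0")
  structure(list(dispersion_threshold = dispersion_threshold, unit = unit,
                 duration_threshold = duration_threshold, fov_deg = fov_deg),
            class = "idt_config")
}

#' @rdname idt_config
#' @param cfg An `idt_config`.
#' @export
normalized_dispersion_threshold <- function(cfg) {
  stopifnot(inherits(cfg, "idt_config"))
  if (cfg$unit == "normalized") return(cfg$dispersion_threshold)
  if (is.null(cfg$fov_deg))
    stop("unit = 'degrees' requires fov_deg for degree->normalized conversion")
  cfg$dispersion_threshold / cfg$fov_deg
}

#' Dispersion of a gaze sample window
#'
#' The IDT dispersion measure: `(max x - min x) + (max y - min y)` over the
#' window, in the units of the coordinates (normalized here).
#'
#' @param x,y Coordinate vectors of equal, non-zero length.
#' @return A single non-negative number.
#' @examples
#' gaze_dispersion(c(0, 0.3), c(0, 0.4))  # 0.7
#' @export
gaze_dispersion <- function(x, y) {
  if (!length(x)) stop("argument error: empty window")
  stopifnot(length(x) == length(y))
  (max(x) - min(x)) + (max(y) - min(y))
}

#' Detect fixations with the dispersion-threshold (IDT) algorithm
#'
#' Classic IDT sweep: a window is initialized to cover the minimum duration;
#' if its dispersion is at or below the threshold it grows sample-by-sample
#' while dispersion stays within the threshold, a fixation is emitted
#' (centroid = mean of member coordinates) and the sweep continues after the
#' window; otherwise the window slides forward by one sample. Emitted
#' fixations are disjoint in time and ordered. A recording too short to span
#' the duration threshold yields zero fixations, not an error.
#'
#' @param rec A [gaze_recording()] with at least 2 samples.
#' @param cfg An [idt_config()].
#' @return A data frame of class `fixation_set` with columns `t_start`,
#'   `t_end`, `x_norm`, `y_norm` (centroid), `dispersion`, `n_samples`,
#'   `frame_index` (NA until [assign_frame()]).
#' @export
detect_fixations_idt <- function(rec, cfg = idt_config()) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(cfg, "idt_config"))
  s <- rec$samples
  n <- nrow(s)
  if (n < 2) stop("recording must have at least 2 samples")
  thr <- normalized_dispersion_threshold(cfg)
  dur <- cfg$duration_threshold
  tt <- s$t; xx <- s$x_norm; yy <- s$y_norm

  out <- vector("list", 64L); n_out <- 0L
  i <- 1L
  while (i <= n) {
    # smallest window starting at i that spans the duration threshold
    j <- i
    while (j <= n && tt[j] - tt[i] < dur) j <- j + 1L
    if (j > n) break
    xmin <- min(xx[i:j]); xmax <- max(xx[i:j])
    ymin <- min(yy[i:j]); ymax <- max(yy[i:j])
    if ((xmax - xmin) + (ymax - ymin) <= thr) {
      while (j + 1L <= n) {
        nx <- xx[j + 1L]; ny <- yy[j + 1L]
        x0 <- min(xmin, nx); x1 <- max(xmax, nx)
        y0 <- min(ymin, ny); y1 <- max(ymax, ny)
        if ((x1 - x0) + (y1 - y0) > thr) break
        xmin <- x0; xmax <- x1; ymin <- y0; ymax <- y1
        j <- j + 1L
      }
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- c(tt[i], tt[j], mean(xx[i:j]), mean(yy[i:j]),
                        (xmax - xmin) + (ymax - ymin), j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (n_out == 0L) {
    fx <- data.frame(t_start = numeric(0), t_end = numeric(0),
                     x_norm = numeric(0), y_norm = numeric(0),
                     dispersion = numeric(0), n_samples = integer(0),
                     frame_index = integer(0))
  } else {
    m <- do.call(rbind, out[seq_len(n_out)])
    fx <- data.frame(t_start = m[, 1], t_end = m[, 2],
                     x_norm = m[, 3], y_norm = m[, 4],
                     dispersion = m[, 5], n_samples = as.integer(m[, 6]),
                     frame_index = NA_integer_)
  }
  class(fx) <- c("fixation_set", "data.frame")
  fx
}

#' Assign a representative video frame to each fixation
#'
#' The representative frame is taken at the temporal midpoint of the
#' fixation (avoiding motion blur at fixation onset), via
#' [frame_index_for_time()].
#'
#' @param fixations A `fixation_set` (see [detect_fixations_idt()]).
#' @param meta A [video_meta()].
#' @return The fixation set with `frame_index` filled in.
#' @export
assign_frame <- function(fixations, meta) {
  stopifnot(inherits(fixations, "data.frame"))
  if (!nrow(fixations)) return(fixations)
  mid <- (fixations$t_start + fixations$t_end) / 2
  fixations$frame_index <- frame_index_for_time(mid, meta)
  fixations
}

#' Write detected fixations to CSV
#'
#' @param fixations A `fixation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixations_csv <- function(fixations, path) {
  cols <- c("t_start", "t_end", "x_norm", "y_norm", "dispersion",
            "n_samples", "frame_index")
  utils::write.csv(fixations[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}
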