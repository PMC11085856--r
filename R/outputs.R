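annotation_columns <- function() {
  c("frame_index", "t_start", "t_end", "x_norm", "y_norm", "x_px", "y_px",
    "mask_label", "box_label", "coverage", "x1", "y1", "x2", "y2",
    "confidence", "resolved_label", "merged_label", "branch")
}

#' Write the per-fixation annotation CSV
#'
#' One row per fixation, stable column order, UTF-8, comma-delimited with
#' '.' decimals. Optional box fields of unannotated-by-detector fixations
#' are serialized as empty strings. The file round-trips through
#' [read_annotations()] bit-identically.
#'
#' @param rows Annotation data frame (see [annotate_fixation()]); columns
#'   beyond the standard set are dropped, absent optional columns are
#'   filled with `NA`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(rows, path) {
  cols <- annotation_columns()
  for (cc in setdiff(cols, names(rows))) {
    fill <- if (cc %in% c("mask_label", "box_label", "resolved_label",
                          "merged_label", "branch")) NA_character_
            else NA_real_
    rows[[cc]] <- rep(fill, nrow(rows))
  }
  rows <- rows[, cols, drop = FALSE]
  num <- vapply(rows, is.double, logical(1))
  rows[num] <- lapply(rows[num], function(v)
    ifelse(is.na(v), NA, format(v, digits = 17, trim = TRUE, scientific = FALSE)))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE, na = "", quote = TRUE,
                   eol = "\n")
  invisible(path)
}

#' Read an annotation CSV back
#'
#' @param path Path written by [write_annotations()].
#' @return Annotation data frame with empty optional fields as `NA`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = c(frame_index = "integer"))
  for (cc in c("x_px", "y_px", "x1", "y1", "x2", "y2"))
    if (cc %in% names(df)) df[[cc]] <- as.integer(df[[cc]])
  df
}

# -- raster drawing helpers (0-based pixel coordinates) ----------------------

blend_region <- function(img, mask, rgb, alpha) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- (1 - alpha) * plane[mask] + alpha * rgb[ch]
    img[, , ch] <- plane
  }
  img
}

draw_box_outline <- function(img, x1, y1, x2, y2, rgb, thick = 1L) {
  h <- dim(img)[1]; w <- dim(img)[2]
  m <- matrix(FALSE, h, w)
  for (t in seq_len(thick) - 1L) {
    xs <- max(1L, x1 + 1L - t):min(w, x2 + t)
    ys <- max(1L, y1 + 1L - t):min(h, y2 + t)
    m[max(1L, y1 + 1L - t), xs] <- TRUE
    m[min(h, y2 + t), xs] <- TRUE
    m[ys, max(1L, x1 + 1L - t)] <- TRUE
    m[ys, min(w, x2 + t)] <- TRUE
  }
  blend_region(img, m, rgb, 1)
}

draw_disk <- function(img, x_px, y_px, radius, rgb) {
  h <- dim(img)[1]; w <- dim(img)[2]
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  m <- outer((ys - y_px)^2, (xs - x_px)^2, `+`) <= radius^2
  blend_region(img, m, rgb, 1)
}

#' Render an annotated frame
#'
#' Draws the fusion result onto a frame for visual inspection: the fixated
#' mask as a semi-transparent overlay, non-selected candidate boxes in
#' yellow, the selected box in cyan (visually distinct, thicker), and the
#' fixation point as a red dot. Deterministic for fixed inputs. Class-name
#' text is carried in the annotation CSV rather than burned into the
#' raster.
#'
#' @param frame H x W x 3 RGB array in `[0, 1]`.
#' @param annotation One-row data frame from [annotate_fixation()].
#' @param seg The frame's [semantic_segmentation()] (for the mask overlay);
#'   may be `NULL` to skip the overlay.
#' @param boxes The frame's detection data frame; candidates containing the
#'   fixation are drawn. May be `NULL`.
#' @param style Named list overriding colors/sizes: `mask_rgb`,
#'   `mask_alpha`, `candidate_rgb`, `selected_rgb`, `dot_rgb`, `dot_radius`.
#' @return The annotated RGB array.
#' @export
render_annotation <- function(frame, annotation, seg = NULL, boxes = NULL,
                              style = list()) {
  st <- utils::modifyList(list(
    mask_rgb = c(1, 0, 1), mask_alpha = 0.35,
    candidate_rgb = c(1, 1, 0), selected_rgb = c(0, 1, 1),
    dot_rgb = c(1, 0, 0), dot_radius = 3), style)
  img <- frame
  a <- annotation[1, ]
  if (!is.null(seg)) {
    mask <- mask_at_point(seg, a$x_px, a$y_px)
    img <- blend_region(img, unclass(mask), st$mask_rgb, st$mask_alpha)
  }
  if (!is.null(boxes) && nrow(boxes)) {
    contains <- boxes$x1 <= a$x_px & a$x_px <= boxes$x2 - 1L &
                boxes$y1 <= a$y_px & a$y_px <= boxes$y2 - 1L
    for (r in which(contains))
      img <- draw_box_outline(img, boxes$x1[r], boxes$y1[r], boxes$x2[r],
                              boxes$y2[r], st$candidate_rgb, thick = 1L)
  }
  if (!is.na(a$x1))
    img <- draw_box_outline(img, a$x1, a$y1, a$x2, a$y2, st$selected_rgb,
                            thick = 2L)
  img <- draw_disk(img, a$x_px, a$y_px, st$dot_radius, st$dot_rgb)
  img
}

#' Write a frame image as PNG
#'
#' @param img H x W x 3 RGB array in `[0, 1]`.
#' @param path Output path (conventionally `frame_<index>.png`).
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
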