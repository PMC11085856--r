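#' Binary mask of the fixated object
#'
#' Extracts from a total segmentation the mask containing a fixation pixel.
#' Two modes exist because "the mask of the fixated object" is ambiguous for
#' a class-level segmentation:
#' \describe{
#'   \item{component}{the 4-connected component of the point's class that
#'     contains the point (default). Restricting to the component prevents
#'     unrelated same-class regions elsewhere in the frame from inflating
#'     coverage for distant boxes.}
#'   \item{class}{all pixels sharing the point's class id.}
#' }
#'
#' @param seg A [semantic_segmentation()].
#' @param x_px,y_px 0-based pixel coordinates of the fixation, within the
#'   frame.
#' @param component_mode `"component"` or `"class"`.
#' @return A logical matrix of class `binary_mask` with attributes
#'   `source_label` (class name at the point) and `component_mode`.
#' @export
mask_at_point <- function(seg, x_px, y_px,
                          component_mode = c("component", "class")) {
  component_mode <- match.arg(component_mode)
  stopifnot(inherits(seg, "semantic_segmentation"))
  h <- nrow(seg$label_map); w <- ncol(seg$label_map)
  if (x_px < 0 || x_px >= w || y_px < 0 || y_px >= h)
    stop("fixation pixel outside frame bounds")
  id <- seg$label_map[y_px + 1L, x_px + 1L]
  target <- seg$label_map == id
  m <- if (component_mode == "class") target
       else connected_component4(target, y_px + 1L, x_px + 1L)
  structure(m, class = "binary_mask",
            source_label = seg$vocabulary[id], component_mode = component_mode)
}

# 4-connected component of `target` containing (row0, col0), by vectorized
# breadth-first frontier expansion over linear indices.
connected_component4 <- function(target, row0, col0) {
  h <- nrow(target); w <- ncol(target)
  comp <- matrix(FALSE, h, w)
  start <- (col0 - 1L) * h + row0
  comp[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    r <- ((frontier - 1L) %% h) + 1L
    up    <- frontier[r > 1L] - 1L
    down  <- frontier[r < h] + 1L
    left  <- frontier[frontier > h] - h
    right <- frontier[frontier <= h * (w - 1L)] + h
    nb <- unique(c(up, down, left, right))
    nb <- nb[target[nb] & !comp[nb]]
    comp[nb] <- TRUE
    frontier <- nb
  }
  comp
}

#' Mask coverage of a bounding box
#'
#' The box-selection criterion: the fraction of the box area occupied by
#' mask pixels,
#' \deqn{C = \frac{\sum_{(i,j) \in R} M_{i,j}}{(x_2 - x_1)(y_2 - y_1)},}
#' where `M` is the binary mask and `R` its restriction to the box. The
#' numerator and denominator are exact integer counts; the only floating
#' division is the final one, so `C` is exact for any mask/box pair.
#'
#' @param mask A logical matrix (e.g. from [mask_at_point()]).
#' @param box A list or one-row data frame with `x1,y1,x2,y2` (0-based,
#'   half-open, non-degenerate).
#' @return Coverage `C` in `[0, 1]`.
#' @examples
#' m <- matrix(FALSE, 20, 20); m[6:9, 4:9] <- TRUE   # 6 x 4 block
#' mask_coverage(m, list(x1 = 0, y1 = 0, x2 = 10, y2 = 10))  # 0.24
#' @export
mask_coverage <- function(mask, box) {
  x1 <- box$x1; y1 <- box$y1; x2 <- box$x2; y2 <- box$y2
  if (x2 <= x1 || y2 <= y1) stop("argument error: zero-area box")
  if (x1 < 0 || y1 < 0 || x2 > ncol(mask) || y2 > nrow(mask))
    stop("box outside mask dimensions")
  inside <- sum(mask[(y1 + 1L):y2, (x1 + 1L):x2])
  inside / ((x2 - x1) * (y2 - y1))
}

#' Candidate boxes for a fixation
#'
#' Keeps exactly the boxes that contain the fixation pixel (edge-inclusive
#' on the pixel grid: `x1 <= px <= x2 - 1`) and at least one pixel of the
#' fixated mask (`C > 0`), each paired with its coverage.
#'
#' @param boxes Detection data frame (`x1,y1,x2,y2,label,confidence`).
#' @param x_px,y_px 0-based fixation pixel.
#' @param mask Binary mask of the fixated object.
#' @return The subset of `boxes` with an added `coverage` column; possibly
#'   zero rows.
#' @export
candidate_boxes <- function(boxes, x_px, y_px, mask) {
  if (!nrow(boxes)) return(cbind(boxes, coverage = numeric(0)))
  contains <- boxes$x1 <= x_px & x_px <= boxes$x2 - 1L &
              boxes$y1 <= y_px & y_px <= boxes$y2 - 1L
  cand <- boxes[contains, , drop = FALSE]
  if (!nrow(cand)) return(cbind(cand, coverage = numeric(0)))
  cand$coverage <- vapply(seq_len(nrow(cand)),
                          function(r) mask_coverage(mask, cand[r, ]), numeric(1))
  cand <- cand[cand$coverage > 0, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Select the best candidate box
#'
#' The box with the greatest mask coverage wins. Ties are broken
#' deterministically: higher confidence, then smaller area, then lowest
#' `(x1, y1)` lexicographically.
#'
#' @param candidates Output of [candidate_boxes()].
#' @return A one-row data frame, or `NULL` when there are no candidates.
#' @export
select_box <- function(candidates) {
  if (is.null(candidates) || !nrow(candidates)) return(NULL)
  area <- (candidates$x2 - candidates$x1) * (candidates$y2 - candidates$y1)
  ord <- order(-candidates$coverage, -candidates$confidence, area,
               candidates$x1, candidates$y1)
  sel <- candidates[ord[1L], , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Annotate a single fixation against a frame's perception
#'
#' The full per-fixation fusion step: locate the fixated mask, filter and
#' rank candidate boxes by mask coverage, and resolve the mask label and the
#' selected box label into one final label through the rule cascade of
#' [resolve_label()]. Because the segmentation is total, every in-frame
#' fixation receives a non-empty mask label, and therefore a non-empty
#' resolved label -- no fixation is ever "background".
#'
#' @param x_norm,y_norm Normalized fixation coordinates.
#' @param frame_index 0-based frame index of the fixation.
#' @param perception A [perception_result()] for that frame.
#' @param meta A [video_meta()] (for the normalized-to-pixel conversion).
#' @param cfg A [resolution_config()].
#' @param merge_map Label merge map used during resolution (see
#'   [default_merge_map()]).
#' @param component_mode Mask mode passed to [mask_at_point()].
#' @return A one-row data frame with columns `frame_index`, `x_norm`,
#'   `y_norm`, `x_px`, `y_px`, `mask_label`, `box_label`, `coverage`,
#'   `x1,y1,x2,y2`, `confidence`, `resolved_label`, `merged_label`,
#'   `branch`. Box fields are `NA` when no candidate box exists.
#' @export
annotate_fixation <- function(x_norm, y_norm, frame_index, perception, meta,
                              cfg = resolution_config(),
                              merge_map = default_merge_map(),
                              component_mode = c("component", "class")) {
  component_mode <- match.arg(component_mode)
  stopifnot(inherits(perception, "perception_result"))
  px <- norm_to_pixel(x_norm, y_norm, meta)
  mask <- mask_at_point(perception$segmentation, px$x_px, px$y_px,
                        component_mode = component_mode)
  mask_label <- attr(mask, "source_label")
  cand <- candidate_boxes(perception$boxes, px$x_px, px$y_px, mask)
  sel <- select_box(cand)

  if (is.null(sel)) {
    box_label <- NA_character_; cov <- NA_real_; conf <- NA_real_
    bx <- rep(NA_integer_, 4)
  } else {
    box_label <- sel$label; cov <- sel$coverage; conf <- sel$confidence
    bx <- c(sel$x1, sel$y1, sel$x2, sel$y2)
  }
  res <- resolve_label(mask_label, box_label, coverage = cov,
                       confidence = conf, cfg = cfg, map = merge_map)
  data.frame(
    frame_index = as.integer(frame_index),
    x_norm = x_norm, y_norm = y_norm,
    x_px = px$x_px, y_px = px$y_px,
    mask_label = mask_label, box_label = box_label,
    coverage = cov,
    x1 = bx[1], y1 = bx[2], x2 = bx[3], y2 = bx[4],
    confidence = conf,
    resolved_label = as.character(res),
    merged_label = merge_label(as.character(res), merge_map),
    branch = attr(res, "branch"),
    stringsAsFactors = FALSE
  )
}
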