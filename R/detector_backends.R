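#' Semantic segmentation of a frame
#'
#' A dense, total labeling: exactly one class id per pixel, so the class
#' masks partition the frame (no pixel is unlabeled and no two masks
#' overlap).
#'
#' @param label_map Integer matrix (height x width) of class ids, 1-based
#'   into `vocabulary`.
#' @param vocabulary Character vector mapping class id to class name.
#' @return An object of class `semantic_segmentation`.
#' @export
semantic_segmentation <- function(label_map, vocabulary) {
  stopifnot(is.matrix(label_map))
  ids <- unique(as.integer(label_map))
  if (any(is.na(ids)) || any(ids < 1L) || any(ids > length(vocabulary)))
    stop("every label id must exist in the vocabulary")
  structure(list(label_map = label_map, vocabulary = as.character(vocabulary)),
            class = "semantic_segmentation")
}

#' @export
print.semantic_segmentation <- function(x, ...) {
  cat(sprintf("<semantic_segmentation> %dx%d, %d classes: %s\n",
              nrow(x$label_map), ncol(x$label_map), length(x$vocabulary),
              paste(x$vocabulary, collapse = ", ")))
  invisible(x)
}

#' Class name of the segmentation at a pixel
#'
#' @param seg A [semantic_segmentation()].
#' @param x_px,y_px 0-based pixel coordinates (vectorized).
#' @return Character vector of class names.
#' @export
seg_label_at <- function(seg, x_px, y_px) {
  seg$vocabulary[seg$label_map[cbind(y_px + 1L, x_px + 1L)]]
}

empty_boxes <- function(instance = FALSE) {
  df <- data.frame(x1 = integer(0), y1 = integer(0), x2 = integer(0),
                   y2 = integer(0), label = character(0),
                   confidence = numeric(0), stringsAsFactors = FALSE)
  if (instance) df$instance <- integer(0)
  df
}

#' Validate a set of detected boxes
#'
#' Boxes are half-open integer pixel rectangles `[x1, x2) x [y1, y2)` with a
#' class label and a confidence in `[0, 1]`. Unlike segmentation masks,
#' boxes may overlap freely and the set may be empty.
#'
#' @param boxes Data frame with columns `x1,y1,x2,y2,label,confidence`.
#' @param width,height Frame dimensions the boxes must lie within.
#' @return The validated data frame.
#' @export
validate_boxes <- function(boxes, width, height) {
  need <- c("x1", "y1", "x2", "y2", "label", "confidence")
  miss <- setdiff(need, names(boxes))
  if (length(miss)) stop("boxes missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(boxes)) return(boxes)
  with(boxes, {
    if (any(x1 < 0 | y1 < 0 | x2 > width | y2 > height))
      stop("box outside frame bounds")
    if (any(x1 >= x2 | y1 >= y2)) stop("zero-area box")
    if (any(confidence < 0 | confidence > 1)) stop("confidence outside [0, 1]")
  })
  boxes
}

#' Joint perception output for one frame
#'
#' @param segmentation A [semantic_segmentation()].
#' @param boxes A detection data frame (see [validate_boxes()]).
#' @param width,height Frame dimensions; default from the segmentation.
#' @return An object of class `perception_result`.
#' @export
perception_result <- function(segmentation, boxes,
                              width = ncol(segmentation$label_map),
                              height = nrow(segmentation$label_map)) {
  stopifnot(inherits(segmentation, "semantic_segmentation"))
  if (ncol(segmentation$label_map) != width || nrow(segmentation$label_map) != height)
    stop("segmentation dimensions disagree with frame dimensions")
  boxes <- validate_boxes(boxes, width, height)
  structure(list(segmentation = segmentation, boxes = boxes,
                 width = width, height = height),
            class = "perception_result")
}

#' Deterministic synthetic perception backend
#'
#' Stands behind the same contract a pretrained segmenter/detector pair
#' would: given a frame index it returns a full-coverage label map and a
#' list of labeled boxes. The output is a pure function of
#' `(scene, corruption, seed)` -- identical calls yield identical results --
#' which makes every downstream stage testable against known ground truth.
#' Real-model adapters can implement the same `perceive()` generic.
#'
#' @param scene A [scene_spec()] or preset name (see [scene_preset()]).
#' @param corruption Optional [corruption_spec()]; `NULL` means perfect
#'   perception (ground truth passed through).
#' @param seed Integer seed for the corruption model.
#' @return An object of class `synthetic_backend`.
#' @export
synthetic_backend <- function(scene, corruption = NULL, seed = 1L) {
  if (is.character(scene)) scene <- scene_preset(scene)
  stopifnot(inherits(scene, "scene_spec"))
  rendered <- render_scene(scene)
  perception <- if (is.null(corruption)) {
    perception_result(rendered$segmentation,
                      rendered$boxes[, c("x1", "y1", "x2", "y2", "label",
                                         "confidence")])
  } else {
    corrupt_perception(rendered, corruption, seed = seed)
  }
  structure(list(scene = scene, rendered = rendered, perception = perception,
                 corruption = corruption, seed = seed),
            class = "synthetic_backend")
}

#' Perceive a frame through a backend
#'
#' @param backend A perception backend (e.g. [synthetic_backend()]).
#' @param frame_index 0-based frame index.
#' @param ... Passed to methods.
#' @return A [perception_result()].
#' @export
perceive <- function(backend, frame_index, ...) UseMethod("perceive")

#' @rdname perceive
#' @export
perceive.synthetic_backend <- function(backend, frame_index, ...) {
  # the synthetic scene is static: every frame shows the same world
  backend$perception
}

#' @rdname perceive
#' @export
perceive.function <- function(backend, frame_index, ...) {
  res <- backend(frame_index, ...)
  stopifnot(inherits(res, "perception_result"))
  res
}
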