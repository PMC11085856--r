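#' Default split vocabularies for the synthetic backend
#'
#' The synthetic world deliberately mirrors the vocabulary asymmetry between
#' an urban-scene segmenter (Cityscapes-style classes) and an everyday-object
#' detector (COCO-style classes): each side has classes the other lacks, and
#' some classes (e.g. "tablet") exist in neither detector vocabulary and can
#' only ever be named by a neighbouring class.
#'
#' @return Character vector of class names.
#' @export
default_seg_vocab <- function() {
  c("road", "sidewalk", "building", "sky", "vegetation", "person", "rider",
    "car", "truck", "pole", "traffic sign")
}

#' @rdname default_seg_vocab
#' @export
default_det_vocab <- function() {
  c("person", "car", "truck", "bus", "bicycle", "cell phone", "laptop",
    "handbag")
}

#' Describe one object in a synthetic scene
#'
#' Geometry is in 0-based pixel coordinates. Rectangles are half-open
#' (`[x1, x2) x [y1, y2)`); ellipses are given by center and radii and
#' rasterized by center-of-pixel inclusion. `depth` orders occlusion: larger
#' is farther away, and the nearest object wins each contested pixel.
#'
#' `true_class` is the ground-truth identity used for evaluation.
#' `seg_class` is what the segmenter's vocabulary calls this object (the
#' segmentation is total, so an object outside the segmenter's vocabulary
#' must be painted as some in-vocabulary class, e.g. a tablet as "person").
#' `det_class` is the detector's name for it, or `NA` if the detector cannot
#' see this object class at all (then no ground-truth box is emitted).
#'
#' @param shape `"rect"` or `"ellipse"`.
#' @param x1,y1,x2,y2 Rectangle coordinates (required for `"rect"`).
#' @param cx,cy,rx,ry Ellipse center and radii (required for `"ellipse"`).
#' @param depth Unique depth rank (larger = farther).
#' @param true_class Ground-truth class name.
#' @param seg_class Segmenter vocabulary name (default `true_class`).
#' @param det_class Detector vocabulary name or `NA`.
#' @param det_confidence Confidence attached to the ground-truth box.
#' @return A list of class `scene_object`.
#' @export
scene_object <- function(shape = c("rect", "ellipse"),
                         x1 = NULL, y1 = NULL, x2 = NULL, y2 = NULL,
                         cx = NULL, cy = NULL, rx = NULL, ry = NULL,
                         depth, true_class,
                         seg_class = true_class, det_class = NA_character_,
                         det_confidence = 0.9) {
  shape <- match.arg(shape)
  if (shape == "rect") {
    stopifnot(!is.null(x1), !is.null(y1), !is.null(x2), !is.null(y2))
    if (x1 >= x2 || y1 >= y2) stop("spec error: degenerate rectangle")
  } else {
    stopifnot(!is.null(cx), !is.null(cy), !is.null(rx), !is.null(ry))
    if (rx <= 0 || ry <= 0) stop("spec error: degenerate ellipse")
  }
  structure(list(shape = shape, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                 cx = cx, cy = cy, rx = rx, ry = ry,
                 depth = depth, true_class = true_class,
                 seg_class = seg_class, det_class = det_class,
                 det_confidence = det_confidence),
            class = "scene_object")
}

#' Describe a synthetic scene
#'
#' @param width,height Frame size in pixels.
#' @param background Class name painted where no object is.
#' @param objects List of [scene_object()]s with unique depth ranks.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width, height, background = "sky", objects = list()) {
  depths <- vapply(objects, `[[`, numeric(1), "depth")
  if (anyDuplicated(depths)) stop("spec error: depth ranks must be unique")
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = background, objects = objects),
            class = "scene_spec")
}

# Pre-occlusion logical mask of one object on the frame grid.
object_mask <- function(obj, width, height, inflate = 0) {
  m <- matrix(FALSE, height, width)
  if (obj$shape == "rect") {
    x1 <- max(0L, as.integer(obj$x1 - inflate)); x2 <- min(width,  as.integer(obj$x2 + inflate))
    y1 <- max(0L, as.integer(obj$y1 - inflate)); y2 <- min(height, as.integer(obj$y2 + inflate))
    if (x1 < x2 && y1 < y2) m[(y1 + 1):y2, (x1 + 1):x2] <- TRUE
  } else {
    rx <- max(obj$rx + inflate, 0.5); ry <- max(obj$ry + inflate, 0.5)
    xs <- (0:(width - 1)) + 0.5; ys <- (0:(height - 1)) + 0.5
    dx2 <- ((xs - obj$cx) / rx)^2
    dy2 <- ((ys - obj$cy) / ry)^2
    m <- outer(dy2, dx2, `+`) <= 1
  }
  m
}

check_in_frame <- function(obj, width, height) {
  if (obj$shape == "rect") {
    ok <- obj$x1 >= 0 && obj$y1 >= 0 && obj$x2 <= width && obj$y2 <= height
  } else {
    ok <- obj$cx - obj$rx >= 0 && obj$cx + obj$rx <= width &&
          obj$cy - obj$ry >= 0 && obj$cy + obj$ry <= height
  }
  if (!ok) stop(sprintf("spec error: object '%s' extends outside the %dx%d frame",
                        obj$true_class, width, height))
}

#' Render a synthetic scene to ground truth
#'
#' Rasterizes the scene with the painter's algorithm (objects painted from
#' farthest to nearest, so the nearest object wins every contested pixel).
#' Bounding boxes are each object's full pre-occlusion extent -- boxes of
#' objects at different depths may therefore overlap even though masks never
#' do, exactly the geometry that makes mask-coverage box selection
#' necessary.
#'
#' @param spec A [scene_spec()].
#' @param seg_label_override Optional character vector (one entry per
#'   object) replacing each object's `seg_class` at paint time; used by the
#'   corruption model.
#' @param inflate Optional per-object geometry inflation in pixels (scalar
#'   or vector); negative shrinks. Used by the corruption model to emulate
#'   mask dilation/erosion.
#' @return A list of class `rendered_scene`: `segmentation` (a
#'   [semantic_segmentation()]), `boxes` (ground-truth detection data frame
#'   with columns `x1,y1,x2,y2,label,confidence,instance`), `instance_map`
#'   (integer matrix, 0 = background), `truth` (per-instance data frame),
#'   `frame` (H x W x 3 RGB array) and the `spec`.
#' @export
render_scene <- function(spec, seg_label_override = NULL, inflate = 0) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width; h <- spec$height
  objs <- spec$objects
  n <- length(objs)
  if (length(inflate) == 1L) inflate <- rep(inflate, n)
  seg_names <- vapply(objs, `[[`, character(1), "seg_class")
  if (!is.null(seg_label_override)) seg_names <- seg_label_override
  for (o in objs) check_in_frame(o, w, h)

  vocab <- unique(c(spec$background, seg_names))
  label_map <- matrix(match(spec$background, vocab), h, w)
  instance_map <- matrix(0L, h, w)
  ord <- order(vapply(objs, `[[`, numeric(1), "depth"), decreasing = TRUE)
  pre_masks <- vector("list", n)
  for (k in seq_len(n)) pre_masks[[k]] <- object_mask(objs[[k]], w, h, inflate[k])
  for (k in ord) {
    m <- pre_masks[[k]]
    label_map[m] <- match(seg_names[k], vocab)
    instance_map[m] <- k
  }

  boxes <- list()
  for (k in seq_len(n)) {
    if (is.na(objs[[k]]$det_class)) next
    m <- pre_masks[[k]]
    if (!any(m)) next
    rows <- which(rowSums(m) > 0); cols <- which(colSums(m) > 0)
    boxes[[length(boxes) + 1L]] <- data.frame(
      x1 = min(cols) - 1L, y1 = min(rows) - 1L,
      x2 = max(cols), y2 = max(rows),
      label = objs[[k]]$det_class, confidence = objs[[k]]$det_confidence,
      instance = k, stringsAsFactors = FALSE)
  }
  boxes <- if (length(boxes)) do.call(rbind, boxes) else empty_boxes(instance = TRUE)

  truth <- data.frame(
    instance = seq_len(n),
    true_class = vapply(objs, `[[`, character(1), "true_class"),
    seg_class = seg_names,
    det_class = vapply(objs, `[[`, character(1), "det_class"),
    depth = vapply(objs, `[[`, numeric(1), "depth"),
    visible_px = vapply(seq_len(n), function(k) sum(instance_map == k), integer(1)),
    stringsAsFactors = FALSE)

  structure(list(
    segmentation = semantic_segmentation(label_map, vocab),
    boxes = boxes, instance_map = instance_map, truth = truth,
    frame = scene_frame(label_map, instance_map, vocab), spec = spec),
    class = "rendered_scene")
}

# Flat-shaded RGB render: deterministic palette keyed by class name plus a
# small per-instance tint so adjacent same-class instances are discernible.
scene_frame <- function(label_map, instance_map, vocab) {
  pal <- class_palette(vocab)
  h <- nrow(label_map); w <- ncol(label_map)
  img <- array(0, dim = c(h, w, 3))
  tint <- (instance_map %% 5L) * 0.02
  for (ch in 1:3) {
    img[, , ch] <- matrix(pal[label_map, ch], h, w) + tint
  }
  pmin(pmax(img, 0), 1)
}

class_palette <- function(vocab) {
  base <- c(road = "#4d4d4d", sidewalk = "#8c8c8c", building = "#b06040",
            sky = "#87ceeb", vegetation = "#2e8b57", person = "#d2691e",
            rider = "#dc143c", car = "#1e5abf", truck = "#274e13",
            pole = "#777733", `traffic sign` = "#e6c800", bus = "#7030a0",
            bicycle = "#00a0a0", `cell phone` = "#101010", tablet = "#202040",
            laptop = "#303030", handbag = "#703030")
  cols <- ifelse(vocab %in% names(base), base[vocab], "#909090")
  t(grDevices::col2rgb(cols) / 255)
}

#' Ground-truth class at a pixel
#'
#' @param rendered A [render_scene()] result.
#' @param x_px,y_px 0-based pixel coordinates (vectorized).
#' @return Character vector of `true_class` names (the background class
#'   where no object is present).
#' @export
truth_class_at <- function(rendered, x_px, y_px) {
  inst <- rendered$instance_map[cbind(y_px + 1L, x_px + 1L)]
  ifelse(inst == 0L, rendered$spec$background,
         rendered$truth$true_class[pmax(inst, 1L)])
}

#' Plan a synthetic gaze stream
#'
#' A gaze plan is a sequence of dwell targets: the simulated eye rests on
#' each target for its dwell duration with isotropic Gaussian jitter, and
#' moves between consecutive targets along a straight line over
#' `saccade_duration` seconds.
#'
#' @param targets Data frame with columns `x`, `y` (normalized target
#'   coordinates) and `duration` (seconds > 0).
#' @param rate_hz Sampling rate in Hz (default 200, a common mobile
#'   eye-tracker rate).
#' @param noise_sigma Jitter standard deviation in normalized units.
#' @param saccade_duration Transition time between targets in seconds.
#' @return A list of class `gaze_plan`.
#' @export
gaze_plan <- function(targets, rate_hz = 200, noise_sigma = 0.002,
                      saccade_duration = 0.040) {
  stopifnot(is.data.frame(targets), all(c("x", "y", "duration") %in% names(targets)))
  if (any(targets$duration <= 0)) stop("dwell durations must be > 0")
  if (rate_hz <= 0) stop("rate_hz must be > 0")
  structure(list(targets = targets, rate_hz = rate_hz,
                 noise_sigma = noise_sigma, saccade_duration = saccade_duration),
            class = "gaze_plan")
}

#' Simulate a gaze recording from a plan
#'
#' Deterministic given `(plan, seed)`. The global sample count is
#' `round(total_duration * rate_hz)`; each sample's position comes from the
#' dwell or saccade segment its timestamp falls into.
#'
#' @param plan A [gaze_plan()].
#' @param seed Integer seed.
#' @param meta Optional [video_meta()]; defaults to a 320x240, 30 fps video
#'   spanning the plan.
#' @return A [gaze_recording()].
#' @export
simulate_gaze <- function(plan, seed = 1L, meta = NULL) {
  stopifnot(inherits(plan, "gaze_plan"))
  tg <- plan$targets
  k <- nrow(tg)
  # schedule: dwell_1, sacc_1, dwell_2, ..., dwell_k
  seg_t0 <- numeric(0); seg_t1 <- numeric(0); seg_type <- character(0)
  seg_i <- integer(0)
  t <- 0
  for (i in seq_len(k)) {
    seg_t0 <- c(seg_t0, t); t <- t + tg$duration[i]
    seg_t1 <- c(seg_t1, t); seg_type <- c(seg_type, "dwell"); seg_i <- c(seg_i, i)
    if (i < k && plan$saccade_duration > 0) {
      seg_t0 <- c(seg_t0, t); t <- t + plan$saccade_duration
      seg_t1 <- c(seg_t1, t); seg_type <- c(seg_type, "saccade"); seg_i <- c(seg_i, i)
    }
  }
  total <- t
  n <- round(total * plan$rate_hz)
  ts <- (seq_len(n) - 1L) / plan$rate_hz
  seg_of <- findInterval(ts, seg_t0)
  withr::with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    for (s in seq_along(seg_t0)) {
      in_s <- which(seg_of == s)
      if (!length(in_s)) next
      i <- seg_i[s]
      if (seg_type[s] == "dwell") {
        x[in_s] <- tg$x[i] + stats::rnorm(length(in_s), 0, plan$noise_sigma)
        y[in_s] <- tg$y[i] + stats::rnorm(length(in_s), 0, plan$noise_sigma)
      } else {
        frac <- (ts[in_s] - seg_t0[s]) / (seg_t1[s] - seg_t0[s])
        x[in_s] <- tg$x[i] + frac * (tg$x[i + 1] - tg$x[i])
        y[in_s] <- tg$y[i] + frac * (tg$y[i + 1] - tg$y[i])
      }
    }
  })
  x <- pmin(pmax(x, 0), 1); y <- pmin(pmax(y, 0), 1)
  if (is.null(meta)) meta <- video_meta(320, 240, fps = 30, duration = total)
  gaze_recording(data.frame(t = ts, x_norm = x, y_norm = y),
                 rate_hz = plan$rate_hz, meta = meta)
}

#' Corruption model for the synthetic perception backend
#'
#' Emulates realistic failure modes of pretrained perception models on
#' egocentric footage: missed detections, label swaps (e.g. a tablet whose
#' dark reflective screen reads as a person), box localization jitter,
#' spurious detections and mask boundary dilation/erosion.
#'
#' @param miss_prob Probability a ground-truth box is dropped.
#' @param box_swap_prob Probability a surviving box's label is swapped.
#' @param box_swap_table Named character vector: box label -> replacement.
#'   Labels not in the table swap to a random other detector class.
#' @param seg_swap_prob Probability an object's segmentation label is
#'   repainted as another class.
#' @param seg_swap_table Named character vector: object `true_class` ->
#'   replacement segmenter class; otherwise a random other class is used.
#' @param jitter_px Uniform box-corner jitter amplitude in pixels.
#' @param false_positive_rate Expected number of spurious boxes per frame
#'   (Poisson).
#' @param morph_px Mask dilation (> 0) or erosion (< 0) radius in pixels,
#'   applied to object geometry before re-rendering so the corrupted
#'   segmentation still partitions the frame.
#' @return A list of class `corruption_spec`.
#' @export
corruption_spec <- function(miss_prob = 0, box_swap_prob = 0,
                            box_swap_table = NULL,
                            seg_swap_prob = 0, seg_swap_table = NULL,
                            jitter_px = 0, false_positive_rate = 0,
                            morph_px = 0) {
  for (p in c(miss_prob, box_swap_prob, seg_swap_prob))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  if (false_positive_rate < 0) stop("false_positive_rate must be >= 0")
  structure(list(miss_prob = miss_prob, box_swap_prob = box_swap_prob,
                 box_swap_table = box_swap_table,
                 seg_swap_prob = seg_swap_prob, seg_swap_table = seg_swap_table,
                 jitter_px = jitter_px,
                 false_positive_rate = false_positive_rate,
                 morph_px = morph_px),
            class = "corruption_spec")
}

#' Apply a corruption model to rendered ground truth
#'
#' Deterministic given `(rendered, cspec, seed)`. With an all-zero
#' corruption spec the output equals the ground truth exactly.
#'
#' @param rendered A [render_scene()] result.
#' @param cspec A [corruption_spec()].
#' @param seed Integer seed.
#' @param seg_vocab,det_vocab Vocabularies used for random swaps and false
#'   positives.
#' @return A [perception_result()].
#' @export
corrupt_perception <- function(rendered, cspec, seed = 1L,
                               seg_vocab = default_seg_vocab(),
                               det_vocab = default_det_vocab()) {
  stopifnot(inherits(rendered, "rendered_scene"), inherits(cspec, "corruption_spec"))
  spec <- rendered$spec
  w <- spec$width; h <- spec$height
  n <- length(spec$objects)
  withr::with_seed(seed, {
    # --- segmentation ---
    seg <- rendered$segmentation
    if (cspec$seg_swap_prob > 0 || cspec$morph_px != 0) {
      seg_names <- rendered$truth$seg_class
      if (cspec$seg_swap_prob > 0) {
        for (k in seq_len(n)) {
          if (stats::runif(1) < cspec$seg_swap_prob) {
            tc <- rendered$truth$true_class[k]
            tab <- cspec$seg_swap_table
            seg_names[k] <- if (!is.null(tab) && tc %in% names(tab)) tab[[tc]]
                            else sample(setdiff(seg_vocab, seg_names[k]), 1)
          }
        }
      }
      seg <- render_scene(spec, seg_label_override = seg_names,
                          inflate = cspec$morph_px)$segmentation
    }
    # --- boxes ---
    bx <- rendered$boxes
    if (nrow(bx)) {
      keep <- stats::runif(nrow(bx)) >= cspec$miss_prob
      bx <- bx[keep, , drop = FALSE]
    }
    if (nrow(bx) && cspec$box_swap_prob > 0) {
      for (r in seq_len(nrow(bx))) {
        if (stats::runif(1) < cspec$box_swap_prob) {
          tab <- cspec$box_swap_table
          lb <- bx$label[r]
          bx$label[r] <- if (!is.null(tab) && lb %in% names(tab)) tab[[lb]]
                         else sample(setdiff(det_vocab, lb), 1)
        }
      }
    }
    if (nrow(bx) && cspec$jitter_px > 0) {
      j <- cspec$jitter_px
      for (col in c("x1", "x2")) bx[[col]] <- bx[[col]] + round(stats::runif(nrow(bx), -j, j))
      for (col in c("y1", "y2")) bx[[col]] <- bx[[col]] + round(stats::runif(nrow(bx), -j, j))
      bx$x1 <- pmin(pmax(bx$x1, 0L), w - 1L); bx$y1 <- pmin(pmax(bx$y1, 0L), h - 1L)
      bx$x2 <- pmin(pmax(bx$x2, bx$x1 + 1L), w); bx$y2 <- pmin(pmax(bx$y2, bx$y1 + 1L), h)
    }
    if (cspec$false_positive_rate > 0) {
      n_fp <- stats::rpois(1, cspec$false_positive_rate)
      if (n_fp > 0) {
        fx1 <- sample.int(w - 8L, n_fp); fy1 <- sample.int(h - 8L, n_fp)
        fp <- data.frame(
          x1 = fx1, y1 = fy1,
          x2 = pmin(fx1 + sample(8:60, n_fp, replace = TRUE), w),
          y2 = pmin(fy1 + sample(8:60, n_fp, replace = TRUE), h),
          label = sample(det_vocab, n_fp, replace = TRUE),
          confidence = stats::runif(n_fp, 0.2, 0.7),
          instance = NA_integer_, stringsAsFactors = FALSE)
        bx <- rbind(bx, fp)
      }
    }
  })
  rownames(bx) <- NULL
  perception_result(seg, bx[, c("x1", "y1", "x2", "y2", "label", "confidence")],
                    width = w, height = h)
}

#' Preset synthetic scenes
#'
#' Two regimes are shipped. `"exp1"` emulates a controlled street recording:
#' few objects, little occlusion, both vocabularies covering most of what is
#' fixated. `"exp2"` emulates a busy crossing seen during real wayfinding:
#' many layered objects, heavy occlusion, handheld devices, and deliberate
#' vocabulary gaps (a bus the segmenter can only call "car", a tablet
#' neither detector vocabulary contains, a bicycle outside the segmenter
#' vocabulary).
#'
#' @param name `"exp1"` or `"exp2"`.
#' @return A [scene_spec()] (320 x 240 pixels).
#' @export
scene_preset <- function(name = c("exp1", "exp2")) {
  name <- match.arg(name)
  if (name == "exp1") {
    objects <- list(
      scene_object("rect", x1 = 0, y1 = 0, x2 = 320, y2 = 130, depth = 90,
                   true_class = "building"),
      scene_object("rect", x1 = 0, y1 = 150, x2 = 320, y2 = 240, depth = 95,
                   true_class = "road"),
      scene_object("rect", x1 = 0, y1 = 130, x2 = 320, y2 = 150, depth = 94,
                   true_class = "sidewalk"),
      scene_object("rect", x1 = 30, y1 = 140, x2 = 130, y2 = 200, depth = 50,
                   true_class = "car", det_class = "car", det_confidence = 0.92),
      scene_object("ellipse", cx = 220, cy = 170, rx = 18, ry = 45, depth = 30,
                   true_class = "person", det_class = "person",
                   det_confidence = 0.88),
      scene_object("rect", x1 = 228, y1 = 178, x2 = 244, y2 = 198, depth = 20,
                   true_class = "cell phone", seg_class = "person",
                   det_class = "cell phone", det_confidence = 0.74)
    )
    scene_spec(320, 240, background = "sky", objects = objects)
  } else {
    objects <- list(
      scene_object("rect", x1 = 0, y1 = 0, x2 = 320, y2 = 120, depth = 96,
                   true_class = "building"),
      scene_object("rect", x1 = 0, y1 = 155, x2 = 320, y2 = 240, depth = 98,
                   true_class = "road"),
      scene_object("rect", x1 = 0, y1 = 120, x2 = 320, y2 = 155, depth = 97,
                   true_class = "sidewalk"),
      scene_object("rect", x1 = 245, y1 = 40, x2 = 320, y2 = 130, depth = 85,
                   true_class = "vegetation"),
      scene_object("rect", x1 = 8, y1 = 40, x2 = 16, y2 = 160, depth = 60,
                   true_class = "pole"),
      scene_object("rect", x1 = 0, y1 = 24, x2 = 28, y2 = 44, depth = 59,
                   true_class = "traffic sign"),
      scene_object("rect", x1 = 190, y1 = 100, x2 = 310, y2 = 180, depth = 70,
                   true_class = "bus", seg_class = "car", det_class = "bus",
                   det_confidence = 0.85),
      scene_object("rect", x1 = 120, y1 = 120, x2 = 230, y2 = 190, depth = 55,
                   true_class = "truck", det_class = "truck",
                   det_confidence = 0.83),
      scene_object("rect", x1 = 30, y1 = 140, x2 = 110, y2 = 195, depth = 50,
                   true_class = "car", det_class = "car", det_confidence = 0.9),
      scene_object("ellipse", cx = 70, cy = 175, rx = 14, ry = 40, depth = 30,
                   true_class = "person", det_class = "person",
                   det_confidence = 0.9),
      scene_object("ellipse", cx = 150, cy = 170, rx = 12, ry = 36, depth = 28,
                   true_class = "rider", det_class = "person",
                   det_confidence = 0.8),
      scene_object("rect", x1 = 292, y1 = 150, x2 = 316, y2 = 200, depth = 45,
                   true_class = "bicycle", seg_class = "car",
                   det_class = "bicycle", det_confidence = 0.7),
      scene_object("ellipse", cx = 255, cy = 180, rx = 15, ry = 42, depth = 25,
                   true_class = "person", det_class = "person",
                   det_confidence = 0.9),
      scene_object("rect", x1 = 240, y1 = 185, x2 = 276, y2 = 212, depth = 20,
                   true_class = "tablet", seg_class = "person",
                   det_class = "cell phone", det_confidence = 0.72),
      scene_object("rect", x1 = 62, y1 = 186, x2 = 78, y2 = 202, depth = 18,
                   true_class = "cell phone", seg_class = "person",
                   det_class = "cell phone", det_confidence = 0.76)
    )
    scene_spec(320, 240, background = "sky", objects = objects)
  }
}

#' Read a scene specification from YAML
#'
#' The YAML mirrors [scene_spec()]: top-level `width`, `height`,
#' `background` and a list `objects` of [scene_object()] fields.
#'
#' @param path YAML file path.
#' @return A [scene_spec()].
#' @export
read_scene_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  objects <- lapply(y$objects, function(o) do.call(scene_object, o))
  scene_spec(y$width, y$height,
             background = if (is.null(y$background)) "sky" else y$background,
             objects = objects)
}
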