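# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: explicit loops, no shared helpers.

brute_dispersion <- function(x, y) {
  xmax <- x[1]; xmin <- x[1]; ymax <- y[1]; ymin <- y[1]
  for (i in seq_along(x)) {
    if (x[i] > xmax) xmax <- x[i]
    if (x[i] < xmin) xmin <- x[i]
    if (y[i] > ymax) ymax <- y[i]
    if (y[i] < ymin) ymin <- y[i]
  }
  (xmax - xmin) + (ymax - ymin)
}

# Per-pixel count of mask pixels inside a half-open 0-based box.
brute_coverage <- function(mask, x1, y1, x2, y2) {
  count <- 0L
  for (py in 0:(nrow(mask) - 1)) {
    for (px in 0:(ncol(mask) - 1)) {
      if (px >= x1 && px < x2 && py >= y1 && py < y2 && mask[py + 1, px + 1])
        count <- count + 1L
    }
  }
  count / ((x2 - x1) * (y2 - y1))
}

# Exhaustive argmax with the documented tie chain: coverage desc, confidence
# desc, area asc, then (x1, y1) ascending.
brute_select <- function(cands) {
  if (!nrow(cands)) return(NULL)
  best <- 1L
  better <- function(a, b) {
    if (cands$coverage[a] != cands$coverage[b])
      return(cands$coverage[a] > cands$coverage[b])
    if (cands$confidence[a] != cands$confidence[b])
      return(cands$confidence[a] > cands$confidence[b])
    area_a <- (cands$x2[a] - cands$x1[a]) * (cands$y2[a] - cands$y1[a])
    area_b <- (cands$x2[b] - cands$x1[b]) * (cands$y2[b] - cands$y1[b])
    if (area_a != area_b) return(area_a < area_b)
    if (cands$x1[a] != cands$x1[b]) return(cands$x1[a] < cands$x1[b])
    cands$y1[a] < cands$y1[b]
  }
  for (i in seq_len(nrow(cands))[-1]) if (better(i, best)) best <- i
  cands[best, , drop = FALSE]
}

# Metrics recomputed straight from label vectors, never touching a
# confusion matrix.
reference_metrics <- function(pred, truth) {
  pred[is.na(pred)] <- "none"
  classes <- sort(unique(c(pred, truth)))
  prec <- rec <- f1 <- sup <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- sum(pred == cl & truth == cl)
    prec[k] <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
    rec[k] <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
    sup[k] <- sum(truth == cl)
  }
  keep <- sup > 0
  list(accuracy = mean(pred == truth),
       macro = c(precision = mean(prec[keep]), recall = mean(rec[keep]),
                 f1 = mean(f1[keep])),
       weighted = c(precision = sum(prec[keep] * sup[keep]) / sum(sup[keep]),
                    recall = sum(rec[keep] * sup[keep]) / sum(sup[keep]),
                    f1 = sum(f1[keep] * sup[keep]) / sum(sup[keep])))
}

random_mask <- function(h, w, p = NULL) {
  if (is.null(p)) p <- stats::runif(1, 0.05, 0.95)
  matrix(stats::runif(h * w) < p, h, w)
}

random_box <- function(w, h) {
  x1 <- sample(0:(w - 2), 1); x2 <- sample((x1 + 1):w, 1)
  y1 <- sample(0:(h - 2), 1); y2 <- sample((y1 + 1):h, 1)
  list(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

# Gaze plan with 7 well-separated planted fixations plus, optionally, a
# too-short dwell that the duration threshold must reject.
planted_plan <- function(short_dwell = FALSE, noise_sigma = 0.002) {
  tg <- data.frame(
    x = c(0.10, 0.80, 0.20, 0.90, 0.50, 0.12, 0.70),
    y = c(0.10, 0.20, 0.80, 0.90, 0.10, 0.50, 0.60),
    duration = c(0.15, 0.20, 0.12, 0.25, 0.30, 0.18, 0.14))
  if (short_dwell)
    tg <- rbind(tg, data.frame(x = 0.45, y = 0.85, duration = 0.09))
  gaze_plan(tg, rate_hz = 200, noise_sigma = noise_sigma,
            saccade_duration = 0.04)
}

# Detection-only baseline: of the boxes containing the point, take the most
# confident (then smallest); no segmentation knowledge.
det_only_label <- function(boxes, x_px, y_px) {
  if (!nrow(boxes)) return(NA_character_)
  inb <- boxes$x1 <= x_px & x_px <= boxes$x2 - 1 &
         boxes$y1 <= y_px & y_px <= boxes$y2 - 1
  if (!any(inb)) return(NA_character_)
  cand <- boxes[inb, , drop = FALSE]
  area <- (cand$x2 - cand$x1) * (cand$y2 - cand$y1)
  cand$label[order(-cand$confidence, area)][1]
}

# Fusion-benefit experiment: one corrupted busy scene, n fixation points,
# accuracies of fused, segmentation-only and detection-only predictions
# against scene ground truth, all under merged labels.
fusion_benefit_run <- function(seed, n_fix = 200) {
  sc <- scene_preset("exp2")
  rendered <- render_scene(sc)
  perc <- corrupt_perception(rendered,
                             corruption_spec(miss_prob = 0.3,
                                             seg_swap_prob = 0.15),
                             seed = seed)
  meta <- video_meta(sc$width, sc$height, fps = 30, duration = 10)
  rcfg <- resolution_config(priority = c("tablet", "cell phone", "laptop"))
  mm <- default_merge_map()
  pts <- withr::with_seed(seed + 10000L, {
    list(x = sample.int(sc$width, n_fix, replace = TRUE) - 1L,
         y = sample.int(sc$height, n_fix, replace = TRUE) - 1L)
  })
  truth <- merge_label(truth_class_at(rendered, pts$x, pts$y), mm)
  seg_pred <- merge_label(seg_label_at(perc$segmentation, pts$x, pts$y), mm)
  fused <- det_pred <- character(n_fix)
  for (i in seq_len(n_fix)) {
    a <- annotate_fixation((pts$x[i] + 0.5) / sc$width,
                           (pts$y[i] + 0.5) / sc$height, 0L, perc, meta,
                           cfg = rcfg, merge_map = mm)
    fused[i] <- a$merged_label
    det_pred[i] <- det_only_label(perc$boxes, pts$x[i], pts$y[i])
  }
  det_pred <- merge_label(det_pred, mm)
  c(fusion = mean(fused == truth),
    seg = mean(seg_pred == truth),
    det = mean(!is.na(det_pred) & det_pred == truth))
}
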