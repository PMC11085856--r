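# Tiny two-layer scene: a near "person" partially occluding a far "car",
# both over a "road" background.
occlusion_scene <- function() {
  scene_spec(40, 30, background = "road", objects = list(
    scene_object("rect", x1 = 5, y1 = 5, x2 = 25, y2 = 20, depth = 10,
                 true_class = "car", det_class = "car"),
    scene_object("rect", x1 = 15, y1 = 8, x2 = 35, y2 = 28, depth = 5,
                 true_class = "person", det_class = "person")))
}

test_that("an empty scene renders an all-background map with no boxes", {
  r <- render_scene(scene_spec(20, 10, background = "sky"))
  expect_equal(unique(as.vector(r$segmentation$label_map)), 1L)
  expect_equal(r$segmentation$vocabulary[1], "sky")
  expect_equal(nrow(r$boxes), 0)
  expect_true(all(r$instance_map == 0L))
})

test_that("a single rectangle's mask equals its box interior", {
  r <- render_scene(scene_spec(20, 10, background = "road", objects = list(
    scene_object("rect", x1 = 3, y1 = 2, x2 = 8, y2 = 6, depth = 1,
                 true_class = "car", det_class = "car"))))
  expect_length(unique(as.vector(r$segmentation$label_map)), 2)
  b <- r$boxes
  expect_equal(unlist(b[1, c("x1", "y1", "x2", "y2")], use.names = FALSE),
               c(3, 2, 8, 6))
  inside <- r$instance_map == 1L
  expect_equal(sum(inside), (8 - 3) * (6 - 2))
  expect_equal(seg_label_at(r$segmentation, 3L, 2L), "car")
  expect_equal(seg_label_at(r$segmentation, 8L, 6L), "road")
})

test_that("the painter's algorithm gives every contested pixel to the nearest object", {
  r <- render_scene(occlusion_scene())
  # per-pixel oracle: explicit depth comparison at every pixel
  spec <- occlusion_scene()
  for (py in 0:29) for (px in 0:39) {
    expect_label <- "road"; best_depth <- Inf
    for (o in spec$objects) {
      if (px >= o$x1 && px < o$x2 && py >= o$y1 && py < o$y2 &&
          o$depth < best_depth) {
        best_depth <- o$depth; expect_label <- o$seg_class
      }
    }
    got <- r$segmentation$vocabulary[r$segmentation$label_map[py + 1, px + 1]]
    if (got != expect_label)
      fail(sprintf("pixel (%d,%d): got %s, expected %s", px, py, got,
                   expect_label))
  }
  succeed()
})

test_that("boxes keep full pre-occlusion extents so they overlap while masks cannot", {
  r <- render_scene(occlusion_scene())
  expect_equal(nrow(r$boxes), 2)
  box_area <- sum((r$boxes$x2 - r$boxes$x1) * (r$boxes$y2 - r$boxes$y1))
  mask_area <- sum(r$instance_map > 0)
  expect_lt(mask_area, box_area)  # the occluded part is counted only in boxes
  # every visible instance pixel lies inside that instance's truth box
  for (k in 1:2) {
    b <- r$boxes[r$boxes$instance == k, ]
    idx <- which(r$instance_map == k, arr.ind = TRUE)
    expect_true(all(idx[, "col"] - 1 >= b$x1 & idx[, "col"] - 1 < b$x2))
    expect_true(all(idx[, "row"] - 1 >= b$y1 & idx[, "row"] - 1 < b$y2))
  }
})

test_that("segmentation always partitions the frame and ids stay in vocabulary", {
  for (preset in c("exp1", "exp2")) {
    r <- render_scene(scene_preset(preset))
    lm <- r$segmentation$label_map
    expect_false(any(is.na(lm)))
    expect_true(all(lm >= 1 & lm <= length(r$segmentation$vocabulary)))
  }
})

test_that("preset regimes encode the split-vocabulary asymmetry", {
  r <- render_scene(scene_preset("exp2"))
  seg_classes <- r$truth$seg_class
  det_classes <- r$truth$det_class[!is.na(r$truth$det_class)]
  expect_true("building" %in% seg_classes)      # segmenter-only class
  expect_false("building" %in% det_classes)
  expect_true("cell phone" %in% det_classes)    # detector-only class
  expect_false("cell phone" %in% seg_classes)
  # a class absent from both vocabularies can only be named by a neighbour
  expect_true("tablet" %in% r$truth$true_class)
  expect_false("tablet" %in% c(seg_classes, det_classes))
})

test_that("out-of-frame geometry is rejected", {
  expect_error(render_scene(scene_spec(20, 10, objects = list(
    scene_object("rect", x1 = 15, y1 = 5, x2 = 25, y2 = 9, depth = 1,
                 true_class = "car")))), "spec error")
  expect_error(scene_spec(20, 10, objects = list(
    scene_object("rect", 1, 1, 2, 2, depth = 1, true_class = "a"),
    scene_object("rect", 3, 3, 4, 4, depth = 1, true_class = "b"))),
    "unique")
})

test_that("noiseless single-target gaze is constant and counts match the schedule", {
  plan <- gaze_plan(data.frame(x = 0.3, y = 0.7, duration = 0.15),
                    rate_hz = 200, noise_sigma = 0)
  rec <- simulate_gaze(plan, seed = 1)
  expect_equal(nrow(rec$samples), 30)  # round(0.15 * 200)
  expect_true(all(rec$samples$x_norm == 0.3))
  expect_true(all(rec$samples$y_norm == 0.7))

  plan2 <- gaze_plan(data.frame(x = c(0.2, 0.8), y = c(0.2, 0.8),
                                duration = c(0.15, 0.2)),
                     rate_hz = 200, noise_sigma = 0, saccade_duration = 0.05)
  rec2 <- simulate_gaze(plan2, seed = 1)
  expect_equal(nrow(rec2$samples), round((0.15 + 0.05 + 0.2) * 200))
})

test_that("gaze simulation is a pure function of plan and seed", {
  plan <- planted_plan()
  a <- simulate_gaze(plan, seed = 21)
  b <- simulate_gaze(plan, seed = 21)
  expect_identical(a$samples, b$samples)
  c <- simulate_gaze(plan, seed = 22)
  expect_false(identical(a$samples, c$samples))
})

test_that("an all-zero corruption spec is the identity on perception", {
  r <- render_scene(occlusion_scene())
  p <- corrupt_perception(r, corruption_spec(), seed = 4)
  expect_identical(p$segmentation$label_map, r$segmentation$label_map)
  expect_equal(p$boxes$label, r$boxes$label)
  expect_equal(p$boxes$x1, r$boxes$x1)
})

test_that("miss_prob = 1 removes every box", {
  r <- render_scene(occlusion_scene())
  p <- corrupt_perception(r, corruption_spec(miss_prob = 1), seed = 4)
  expect_equal(nrow(p$boxes), 0)
})

test_that("a forced swap table relabels every matching box", {
  r <- render_scene(scene_spec(40, 30, background = "road", objects = list(
    scene_object("rect", 2, 2, 12, 10, depth = 1, true_class = "tablet",
                 seg_class = "person", det_class = "tablet"),
    scene_object("rect", 20, 12, 35, 25, depth = 2, true_class = "car",
                 det_class = "car"))))
  p <- corrupt_perception(r, corruption_spec(box_swap_prob = 1,
                                             box_swap_table = c(tablet = "person",
                                                                car = "car")),
                          seed = 4)
  expect_equal(sort(p$boxes$label), c("car", "person"))
})

test_that("corruption is deterministic per seed and respects box invariants", {
  r <- render_scene(scene_preset("exp2"))
  cs <- corruption_spec(miss_prob = 0.3, seg_swap_prob = 0.15, jitter_px = 4,
                        false_positive_rate = 2)
  p1 <- corrupt_perception(r, cs, seed = 8)
  p2 <- corrupt_perception(r, cs, seed = 8)
  expect_identical(p1$segmentation$label_map, p2$segmentation$label_map)
  expect_identical(p1$boxes, p2$boxes)
  expect_true(all(p1$boxes$x1 < p1$boxes$x2 & p1$boxes$y1 < p1$boxes$y2))
  expect_true(all(p1$boxes$x1 >= 0 & p1$boxes$x2 <= 320 &
                  p1$boxes$y1 >= 0 & p1$boxes$y2 <= 240))
})

test_that("geometry dilation keeps the corrupted segmentation a partition", {
  r <- render_scene(occlusion_scene())
  p <- corrupt_perception(r, corruption_spec(morph_px = 2), seed = 1)
  lm <- p$segmentation$label_map
  expect_false(any(is.na(lm)))
  # dilated objects cover at least their original visible area
  expect_gte(sum(lm != match("road", p$segmentation$vocabulary)),
             sum(r$instance_map > 0))
})

test_that("scene YAML specs round-trip into identical renders", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    width = 40, height = 30, background = "road",
    objects = list(
      list(shape = "rect", x1 = 5, y1 = 5, x2 = 25, y2 = 20, depth = 10,
           true_class = "car", det_class = "car"),
      list(shape = "ellipse", cx = 30, cy = 15, rx = 6, ry = 8, depth = 5,
           true_class = "person", det_class = "person"))), path)
  sc <- read_scene_yaml(path)
  r <- render_scene(sc)
  expect_equal(nrow(r$boxes), 2)
  expect_equal(sc$width, 40L)
})
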