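two_region_seg <- function() {
  # two disjoint "car" rectangles on "road"
  lm <- matrix(1L, 20, 30)
  lm[3:8, 3:10] <- 2L    # region A: x 2..9, y 2..7
  lm[12:18, 18:27] <- 2L # region B
  semantic_segmentation(lm, c("road", "car"))
}

test_that("mask_at_point restricts to the fixated component or the whole class", {
  seg <- two_region_seg()
  comp <- mask_at_point(seg, x_px = 4L, y_px = 4L, component_mode = "component")
  expect_equal(attr(comp, "source_label"), "car")
  expect_equal(sum(comp), 6 * 8)            # only region A
  expect_true(comp[5, 5])
  cls <- mask_at_point(seg, 4L, 4L, component_mode = "class")
  expect_equal(sum(cls), 6 * 8 + 7 * 10)    # both regions
  bg <- mask_at_point(seg, 0L, 0L)
  expect_equal(attr(bg, "source_label"), "road")
  expect_error(mask_at_point(seg, 30L, 0L), "outside frame")
})

test_that("4-connectivity does not leak through diagonal touches", {
  lm <- matrix(1L, 5, 5)
  lm[1:2, 1:2] <- 2L
  lm[3:4, 3:4] <- 2L  # touches the first block only at a corner
  seg <- semantic_segmentation(lm, c("bg", "obj"))
  m <- mask_at_point(seg, 0L, 0L, component_mode = "component")
  expect_equal(sum(m), 4)
})

test_that("coverage matches closed forms", {
  m <- matrix(TRUE, 10, 10)
  expect_equal(mask_coverage(m, list(x1 = 0, y1 = 0, x2 = 10, y2 = 10)), 1.0)
  m2 <- matrix(FALSE, 20, 20); m2[6:9, 4:9] <- TRUE  # 4 rows x 6 cols = 24 px
  expect_equal(mask_coverage(m2, list(x1 = 0, y1 = 0, x2 = 10, y2 = 10)), 0.24)
  expect_error(mask_coverage(m, list(x1 = 3, y1 = 3, x2 = 3, y2 = 8)),
               "zero-area")
})

test_that("coverage equals the brute-force per-pixel oracle exactly", {
  withr::with_seed(101, {
    for (i in 1:200) {
      mask <- random_mask(24, 24)
      b <- random_box(24, 24)
      expect_identical(mask_coverage(mask, b),
                       brute_coverage(mask, b$x1, b$y1, b$x2, b$y2))
    }
  })
})

test_that("coverage is translation-invariant and non-increasing under box growth", {
  withr::with_seed(17, {
    for (i in 1:20) {
      m <- matrix(FALSE, 40, 40); m[11:20, 11:20] <- TRUE
      b <- list(x1 = 8, y1 = 8, x2 = 24, y2 = 24)
      c0 <- mask_coverage(m, b)
      # translate mask and box together by (dx, dy)
      dx <- sample(-5:5, 1); dy <- sample(-5:5, 1)
      m2 <- matrix(FALSE, 40, 40); m2[11:20 + dy, 11:20 + dx] <- TRUE
      b2 <- list(x1 = b$x1 + dx, y1 = b$y1 + dy, x2 = b$x2 + dx, y2 = b$y2 + dy)
      expect_identical(mask_coverage(m2, b2), c0)
      # grow the box while the mask stays contained
      g <- sample(1:8, 1)
      bg <- list(x1 = max(0, b$x1 - g), y1 = max(0, b$y1 - g),
                 x2 = min(40, b$x2 + g), y2 = min(40, b$y2 + g))
      expect_lte(mask_coverage(m, bg), c0)
    }
  })
})

test_that("candidate filtering keeps exactly point-containing boxes with C > 0", {
  mask <- matrix(FALSE, 20, 20); mask[6:10, 6:10] <- TRUE
  boxes <- data.frame(
    x1 = c(0, 5, 12, 5), y1 = c(0, 5, 12, 5),
    x2 = c(4, 15, 18, 20), y2 = c(4, 15, 18, 20),
    label = c("a", "b", "c", "d"), confidence = c(0.9, 0.8, 0.7, 0.6))
  cand <- candidate_boxes(boxes, x_px = 7L, y_px = 7L, mask)
  expect_equal(sort(cand$label), c("b", "d"))  # a, c do not contain the point
  expect_true(all(cand$coverage > 0))

  # a box containing the point but no mask pixel is excluded
  empty_mask_box <- data.frame(x1 = 6, y1 = 6, x2 = 9, y2 = 9,
                               label = "e", confidence = 0.9)
  off_mask <- matrix(FALSE, 20, 20); off_mask[16:18, 16:18] <- TRUE
  expect_equal(nrow(candidate_boxes(empty_mask_box, 7L, 7L, off_mask)), 0)

  # no box contains the point -> empty
  expect_equal(nrow(candidate_boxes(boxes, 19L, 0L, mask)), 0)

  # edge inclusivity: the last covered pixel column/row still counts
  edge <- data.frame(x1 = 5, y1 = 5, x2 = 15, y2 = 15, label = "b",
                     confidence = 0.5)
  expect_equal(nrow(candidate_boxes(edge, 14L, 14L, mask)), 1)
  expect_equal(nrow(candidate_boxes(edge, 15L, 14L, mask)), 0)
})

test_that("nested candidate boxes are both retained with distinct coverage", {
  mask <- matrix(FALSE, 120, 120); mask[11:20, 11:20] <- TRUE
  boxes <- data.frame(x1 = c(10, 0), y1 = c(10, 0), x2 = c(20, 100),
                      y2 = c(20, 100), label = c("tight", "loose"),
                      confidence = c(0.5, 0.9))
  cand <- candidate_boxes(boxes, 15L, 15L, mask)
  expect_equal(nrow(cand), 2)
  expect_equal(sort(cand$coverage), c(0.01, 1.0))
})

test_that("the tight box beats a huge containing box (depth-scenario miniature)", {
  mask <- matrix(FALSE, 120, 120); mask[11:20, 11:20] <- TRUE
  boxes <- data.frame(x1 = c(10, 0), y1 = c(10, 0), x2 = c(20, 100),
                      y2 = c(20, 100), label = c("car", "person"),
                      confidence = c(0.5, 0.99))
  sel <- select_box(candidate_boxes(boxes, 15L, 15L, mask))
  expect_equal(sel$label, "car")
  expect_equal(sel$coverage, 1.0)
})

test_that("single candidates are returned as-is and empty sets give NULL", {
  one <- data.frame(x1 = 0, y1 = 0, x2 = 5, y2 = 5, label = "x",
                    confidence = 0.5, coverage = 0.3)
  expect_equal(select_box(one)$label, "x")
  expect_null(select_box(one[0, ]))
  expect_null(select_box(NULL))
})

test_that("selection equals the exhaustive oracle over random candidate sets", {
  withr::with_seed(303, {
    for (i in 1:200) {
      n <- sample(1:8, 1)
      # discrete coverage/confidence grids force frequent ties
      cand <- data.frame(
        x1 = sample(0:20, n, replace = TRUE),
        y1 = sample(0:20, n, replace = TRUE))
      cand$x2 <- cand$x1 + sample(1:20, n, replace = TRUE)
      cand$y2 <- cand$y1 + sample(1:20, n, replace = TRUE)
      cand$label <- sample(letters, n)
      cand$confidence <- sample(c(0.3, 0.5, 0.9), n, replace = TRUE)
      cand$coverage <- sample(c(0.1, 0.5, 1), n, replace = TRUE)
      expect_equal(select_box(cand), brute_select(cand),
                   ignore_attr = "row.names")
    }
  })
})

test_that("annotation is total: every in-frame fixation gets a resolved label", {
  sc <- scene_preset("exp2")
  perc <- synthetic_backend(sc)$perception
  meta <- video_meta(sc$width, sc$height, 30, duration = 10)
  withr::with_seed(55, {
    for (i in 1:40) {
      a <- annotate_fixation(runif(1), runif(1), 0L, perc, meta)
      expect_true(nchar(a$resolved_label) > 0)
      expect_false(is.na(a$mask_label))
      if (!is.na(a$box_label)) {
        expect_gt(a$coverage, 0)
        expect_false(is.na(a$confidence))
      }
      expect_true(a$resolved_label %in% c(a$mask_label, a$box_label))
    }
  })
})

test_that("fusion is deterministic: identical inputs, identical annotations", {
  sc <- scene_preset("exp1")
  perc <- synthetic_backend(sc)$perception
  meta <- video_meta(sc$width, sc$height, 30, duration = 10)
  a1 <- annotate_fixation(0.72, 0.75, 4L, perc, meta)
  a2 <- annotate_fixation(0.72, 0.75, 4L, perc, meta)
  expect_identical(a1, a2)
})

test_that("a fixation on an undetected region resolves to the mask label", {
  sc <- scene_preset("exp1")  # building has no detector class
  perc <- synthetic_backend(sc)$perception
  meta <- video_meta(sc$width, sc$height, 30, duration = 10)
  a <- annotate_fixation(0.5, 0.2, 0L, perc, meta)  # on the building
  expect_equal(a$mask_label, "building")
  expect_true(is.na(a$box_label))
  expect_equal(a$resolved_label, "building")
  expect_equal(a$branch, "no_box")
})

test_that("a priority-listed device label wins over the enclosing person mask", {
  sc <- scene_preset("exp1")
  perc <- synthetic_backend(sc)$perception
  meta <- video_meta(sc$width, sc$height, 30, duration = 10)
  # fixation on the phone held by the person (seg calls the region "person")
  a <- annotate_fixation(236.5 / 320, 188.5 / 240, 0L, perc, meta,
                         cfg = resolution_config(priority = c("cell phone")))
  expect_equal(a$mask_label, "person")
  expect_equal(a$box_label, "cell phone")
  expect_equal(a$resolved_label, "cell phone")
  expect_equal(a$branch, "priority")
})
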