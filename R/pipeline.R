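#' Assemble a pipeline configuration
#'
#' Collects everything the end-to-end run needs. Either construct it
#' directly or load it from YAML with [read_pipeline_config()].
#'
#' @param gaze Path to a gaze CSV, or a [gaze_recording()].
#' @param meta A [video_meta()]; may be `NULL` when `gaze` is a recording
#'   (the recording's own meta is used).
#' @param backend A perception backend (e.g. [synthetic_backend()]) or a
#'   function `(frame_index) -> perception_result`.
#' @param idt An [idt_config()].
#' @param resolution A [resolution_config()].
#' @param merge_map Label merge map (see [default_merge_map()]).
#' @param component_mode Mask mode for fusion (see [mask_at_point()]).
#' @param rate_hz Sampling rate used when `gaze` is a path.
#' @param output_dir Where the annotation CSV (and rendered frames) go.
#' @param render Whether to write annotated frame PNGs.
#' @param seed Seed forwarded to synthetic backends built from config files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(gaze, meta = NULL, backend,
                            idt = idt_config(unit = "normalized",
                                             dispersion_threshold = 0.05),
                            resolution = resolution_config(),
                            merge_map = default_merge_map(),
                            component_mode = "component",
                            rate_hz = 200, output_dir = tempdir(),
                            render = FALSE, seed = 1L) {
  if (inherits(gaze, "gaze_recording") && is.null(meta)) meta <- gaze$meta
  if (is.character(gaze) && is.null(meta))
    stop("usage error: meta is required when gaze is a file path")
  structure(list(gaze = gaze, meta = meta, backend = backend, idt = idt,
                 resolution = resolution, merge_map = merge_map,
                 component_mode = component_mode, rate_hz = rate_hz,
                 output_dir = output_dir, render = render, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys: `gaze` (CSV path), `video` (`width`, `height`, `fps`,
#' `duration`), `rate_hz`, `idt` ([idt_config()] fields), `backend`
#' (`type: synthetic`, `scene`: preset name or scene YAML path, plus
#' optional [corruption_spec()] fields under `corruption`), `resolution`
#' (`priority`, `conf_floor`, `cov_floor`), `merge_map` (mapping),
#' `component_mode`, `output_dir`, `render`, `seed`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("usage error: config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$gaze) || !file.exists(y$gaze))
    stop("usage error: gaze file not found: ", y$gaze)
  meta <- do.call(video_meta, y$video)
  idt <- if (is.null(y$idt)) idt_config(unit = "normalized",
                                        dispersion_threshold = 0.05)
         else do.call(idt_config, y$idt)
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  backend <- {
    b <- y$backend
    if (is.null(b) || identical(b$type, "synthetic")) {
      scene <- if (is.null(b$scene)) "exp1"
               else if (file.exists(b$scene)) read_scene_yaml(b$scene)
               else b$scene
      corr <- if (is.null(b$corruption)) NULL
              else do.call(corruption_spec, b$corruption)
      synthetic_backend(scene, corruption = corr, seed = seed)
    } else {
      stop("usage error: unknown backend type: ", b$type)
    }
  }
  res <- if (is.null(y$resolution)) resolution_config()
         else resolution_config(
           priority = if (is.null(y$resolution$priority)) character(0)
                      else unlist(y$resolution$priority),
           conf_floor = if (is.null(y$resolution$conf_floor)) 0.5
                        else y$resolution$conf_floor,
           cov_floor = if (is.null(y$resolution$cov_floor)) 0.5
                       else y$resolution$cov_floor)
  mm <- if (is.null(y$merge_map)) default_merge_map() else unlist(y$merge_map)
  pipeline_config(
    gaze = y$gaze, meta = meta, backend = backend, idt = idt,
    resolution = res, merge_map = mm,
    component_mode = if (is.null(y$component_mode)) "component"
                     else y$component_mode,
    rate_hz = if (is.null(y$rate_hz)) 200 else y$rate_hz,
    output_dir = if (is.null(y$output_dir)) tempdir() else y$output_dir,
    render = isTRUE(y$render), seed = seed)
}

#' Run the annotation pipeline end to end
#'
#' Load gaze -> IDT fixation detection -> representative-frame assignment ->
#' per-frame perception -> mask-coverage fusion -> label resolution ->
#' annotation CSV (and optional rendered frames). Per-fixation failures are
#' logged and skipped, never fatal; the returned `n_failed` reflects them.
#' Zero detected fixations produce a header-only CSV with a warning, not an
#' error. Results are sorted by `frame_index`, then fixation start time, so
#' any processing order yields identical output.
#'
#' @param cfg A [pipeline_config()] or the path to a YAML config.
#' @return Invisibly, a list: `annotations` (data frame), `fixations`,
#'   `csv` (path written), `rendered` (paths or `NULL`), `n_failed`,
#'   `log` (per-fixation messages).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  rec <- if (inherits(cfg$gaze, "gaze_recording")) cfg$gaze
         else load_gaze_csv(cfg$gaze, meta = cfg$meta, rate_hz = cfg$rate_hz)
  meta <- cfg$meta

  fx <- detect_fixations_idt(rec, cfg$idt)
  fx <- assign_frame(fx, meta)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(cfg$output_dir, "annotations.csv")

  if (!nrow(fx)) {
    warning("no fixations detected; writing header-only annotation file")
    write_annotations(data.frame(), csv_path)
    return(invisible(list(annotations = read_annotations(csv_path),
                          fixations = fx, csv = csv_path, rendered = NULL,
                          n_failed = 0L, log = character(0))))
  }

  rows <- vector("list", nrow(fx))
  log <- character(0)
  for (i in seq_len(nrow(fx))) {
    rows[[i]] <- tryCatch({
      perc <- perceive(cfg$backend, fx$frame_index[i])
      a <- annotate_fixation(fx$x_norm[i], fx$y_norm[i], fx$frame_index[i],
                             perc, meta, cfg = cfg$resolution,
                             merge_map = cfg$merge_map,
                             component_mode = cfg$component_mode)
      a$t_start <- fx$t_start[i]; a$t_end <- fx$t_end[i]
      a
    }, error = function(e) {
      log <<- c(log, sprintf("fixation %d (frame %d) failed: %s",
                             i, fx$frame_index[i], conditionMessage(e)))
      NULL
    })
  }
  n_failed <- sum(vapply(rows, is.null, logical(1)))
  ann <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  ann <- ann[order(ann$frame_index, ann$t_start), , drop = FALSE]
  rownames(ann) <- NULL
  write_annotations(ann, csv_path)

  rendered <- NULL
  if (isTRUE(cfg$render) && inherits(cfg$backend, "synthetic_backend")) {
    rendered <- character(0)
    frame <- cfg$backend$rendered$frame
    perc <- cfg$backend$perception
    for (i in seq_len(nrow(ann))) {
      img <- render_annotation(frame, ann[i, ], seg = perc$segmentation,
                               boxes = perc$boxes)
      p <- file.path(cfg$output_dir,
                     sprintf("frame_%06d.png", ann$frame_index[i]))
      write_frame_png(img, p)
      rendered <- c(rendered, p)
    }
  }
  invisible(list(annotations = ann, fixations = fx, csv = csv_path,
                 rendered = rendered, n_failed = n_failed, log = log))
}

#' Write a complete synthetic fixture set to disk
#'
#' Renders a preset scene and a matching gaze plan, then writes the frame
#' PNG, the gaze CSV and a per-frame ground-truth CSV -- a self-contained
#' input set for exercising the pipeline from files.
#'
#' @param dir Output directory (created if needed).
#' @param preset `"exp1"` or `"exp2"`.
#' @param seed Integer seed for gaze jitter.
#' @param n_targets Number of dwell targets in the gaze plan.
#' @return Invisibly, a list of the paths written plus the objects used.
#' @export
make_fixtures <- function(dir, preset = "exp1", seed = 1L, n_targets = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scene <- scene_preset(preset)
  rendered <- render_scene(scene)
  plan <- preset_gaze_plan(rendered, n_targets = n_targets, seed = seed)
  duration <- sum(plan$targets$duration) +
    (nrow(plan$targets) - 1) * plan$saccade_duration
  meta <- video_meta(scene$width, scene$height, fps = 30, duration = duration)
  rec <- simulate_gaze(plan, seed = seed, meta = meta)

  frame_path <- file.path(dir, "frame_000000.png")
  write_frame_png(rendered$frame, frame_path)
  gaze_path <- file.path(dir, "gaze.csv")
  write_gaze_csv(rec, gaze_path)

  px <- norm_to_pixel(plan$targets$x, plan$targets$y, meta)
  truth <- data.frame(
    target = seq_len(nrow(plan$targets)),
    x_norm = plan$targets$x, y_norm = plan$targets$y,
    label = truth_class_at(rendered, px$x_px, px$y_px))
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE)
  invisible(list(frame = frame_path, gaze = gaze_path, truth = truth_path,
                 scene = scene, rendered = rendered, plan = plan, meta = meta,
                 recording = rec))
}

#' Gaze plan visiting objects of a rendered scene
#'
#' Dwell targets are placed at visible pixels of successive objects
#' (cycling through the object list), with dwell durations drawn uniformly
#' from 120--300 ms -- long enough for a 100 ms IDT duration threshold --
#' and large saccades between targets.
#'
#' @param rendered A [render_scene()] result.
#' @param n_targets Number of dwells.
#' @param seed Integer seed.
#' @param rate_hz,noise_sigma Passed to [gaze_plan()].
#' @return A [gaze_plan()].
#' @export
preset_gaze_plan <- function(rendered, n_targets = 10L, seed = 1L,
                             rate_hz = 200, noise_sigma = 0.002) {
  w <- rendered$spec$width; h <- rendered$spec$height
  inst <- rendered$instance_map
  visible <- rendered$truth$instance[rendered$truth$visible_px > 0]
  withr::with_seed(seed, {
    xs <- numeric(n_targets); ys <- numeric(n_targets)
    for (i in seq_len(n_targets)) {
      k <- visible[((i - 1L) %% length(visible)) + 1L]
      idx <- which(inst == k)
      pick <- idx[sample.int(length(idx), 1)]
      r <- ((pick - 1L) %% h) + 1L
      c <- ((pick - 1L) %/% h) + 1L
      xs[i] <- (c - 0.5) / w
      ys[i] <- (r - 0.5) / h
    }
    dur <- stats::runif(n_targets, 0.12, 0.30)
  })
  gaze_plan(data.frame(x = xs, y = ys, duration = dur),
            rate_hz = rate_hz, noise_sigma = noise_sigma)
}
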