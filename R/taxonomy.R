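#' Default label merge map
#'
#' Related classes split across the two perception vocabularies are merged
#' into broader classes when fine distinctions are irrelevant to the
#' research question: `sidewalk/road`, `person/rider`, `car/truck` and
#' `tablet/cell phone` (the latter because common detector vocabularies have
#' no tablet class, so a tablet consistently named "cell phone" is
#' pragmatically correct). Users extend or replace the map freely -- e.g. a
#' "vehicle" super-class.
#'
#' @return Named character vector: raw class name -> merged class name.
#'   Unmapped names merge to themselves.
#' @export
default_merge_map <- function() {
  c(road = "sidewalk/road", sidewalk = "sidewalk/road",
    person = "person/rider", rider = "person/rider",
    car = "car/truck", truck = "car/truck",
    tablet = "tablet/cell phone", `cell phone` = "tablet/cell phone")
}

#' Merge a class label through a merge map
#'
#' Identity for unmapped names; idempotent by construction (merged names are
#' not themselves keys of the map).
#'
#' @param label Character vector of class names.
#' @param map Named character vector (see [default_merge_map()]); `NULL`
#'   means no merging.
#' @return Character vector of merged names.
#' @examples
#' merge_label(c("rider", "truck", "sky"))  # "person/rider" "car/truck" "sky"
#' @export
merge_label <- function(label, map = default_merge_map()) {
  if (is.null(map) || !length(map)) return(label)
  if (any(unname(map) %in% names(map)))
    stop("merge map must be idempotent: merged names may not be keys")
  hit <- label %in% names(map)
  label[hit] <- unname(map[label[hit]])
  label
}

#' Configuration for label resolution
#'
#' @param priority Ordered character vector of classes of interest (compared
#'   after merging). When the two sources disagree and exactly one side is
#'   on this list, that side wins; when both are, the earlier entry wins.
#' @param conf_floor,cov_floor Confidence and coverage cutoffs in `[0, 1]`
#'   for the final fallback branch.
#' @return An object of class `resolution_config`.
#' @export
resolution_config <- function(priority = character(0),
                              conf_floor = 0.5, cov_floor = 0.5) {
  if (conf_floor < 0 || conf_floor > 1 || cov_floor < 0 || cov_floor > 1)
    stop("floors must lie in [0, 1]")
  structure(list(priority = as.character(priority),
                 conf_floor = conf_floor, cov_floor = cov_floor),
            class = "resolution_config")
}

#' Resolve the segmentation and detection labels into one
#'
#' A deterministic four-branch cascade, first match wins:
#' \enumerate{
#'   \item no box label -> the mask label (the segmentation always predicts;
#'     the detector may not).
#'   \item the two labels agree after merging -> keep that label (the raw
#'     mask-side label is returned, the segmentation being the
#'     boundary-precise source).
#'   \item exactly one of the two merged labels is on the priority list ->
#'     that side's label; if both are listed, the one earlier in the list.
#'   \item otherwise the box label wins only if its confidence and coverage
#'     both reach their floors; else the mask label.
#' }
#'
#' @param mask_label Class name from the segmentation (always present).
#' @param box_label Class name from the selected box, or `NA`.
#' @param coverage,confidence Coverage and confidence of the selected box;
#'   must be present whenever `box_label` is.
#' @param cfg A [resolution_config()].
#' @param map Merge map used for the agreement and priority comparisons
#'   (resolution compares merged labels but returns raw ones).
#' @return The winning raw class name, with attribute `branch` in
#'   `{"no_box", "agreement", "priority", "threshold_box",
#'   "threshold_mask"}` recording which rule fired.
#' @export
resolve_label <- function(mask_label, box_label = NA_character_,
                          coverage = NA_real_, confidence = NA_real_,
                          cfg = resolution_config(),
                          map = default_merge_map()) {
  stopifnot(inherits(cfg, "resolution_config"))
  if (is.na(box_label))
    return(structure(mask_label, branch = "no_box"))
  if (is.na(coverage) || is.na(confidence))
    stop("argument error: box_label present requires coverage and confidence")

  mm <- merge_label(mask_label, map)
  mb <- merge_label(box_label, map)
  if (identical(mm, mb))
    return(structure(mask_label, branch = "agreement"))

  prio <- merge_label(cfg$priority, map)
  pm <- match(mm, prio); pb <- match(mb, prio)
  if (!is.na(pb) && is.na(pm))
    return(structure(box_label, branch = "priority"))
  if (!is.na(pm) && is.na(pb))
    return(structure(mask_label, branch = "priority"))
  if (!is.na(pm) && !is.na(pb))
    return(structure(if (pm <= pb) mask_label else box_label,
                     branch = "priority"))

  if (confidence >= cfg$conf_floor && coverage >= cfg$cov_floor)
    structure(box_label, branch = "threshold_box")
  else
    structure(mask_label, branch = "threshold_mask")
}
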