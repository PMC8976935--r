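# Automated topographic structure-function reference standard.
#
# A visual-field location shows abnormal-structure / abnormal-function
# (aS-aF) agreement when its pattern-deviation p-category is abnormal at
# the 5% level and a topographically corresponding structural region
# (RNFL or GCL+ probability map) is abnormal at the 10% level. An eye is
# likely glaucoma (LG) when both baseline OCT-VF pairs show at least 3
# aS-aF locations. 24-2 and 10-2 locations are counted per test location,
# without deduplicating spatially coincident points.

#' Count aS-aF agreement locations for one eye-visit
#'
#' @param points a [pointwise_maps()] object.
#' @param corr an [sf_correspondence()]; every VF location in `points`
#'   must have an entry.
#' @param vf_alpha p-category cutoff for functional abnormality (default
#'   `"p5"`, i.e. abnormal at the 5% level).
#' @param struct_alpha p-category cutoff for structural abnormality
#'   (default `"p10"`, the 10% level).
#' @param layer_rule `"either"` (default): abnormality in any
#'   corresponding region of either layer suffices; `"both"`: at least one
#'   abnormal corresponding region in each layer; `"RNFL"`/`"GCLPLUS"`:
#'   only regions of that layer are consulted.
#' @param eye_id,visit carried through to the result for bookkeeping.
#' @return a list of class `asaf_result` with `eye_id`, `visit`, `n_asaf`
#'   and the per-location logical map.
#' @export
count_asaf <- function(points, corr, vf_alpha = "p5", struct_alpha = "p10",
                       layer_rule = c("either", "both", "RNFL", "GCLPLUS"),
                       eye_id = NA_character_, visit = NA_integer_) {
  layer_rule <- match.arg(layer_rule)
  stopifnot(inherits(points, "pointwise_maps"),
            inherits(corr, "sf_correspondence"))
  region_p <- c(points$rnfl_regions, points$gclplus_regions)
  struct_abnormal <- function(regions) {
    layers <- corr$region_layer[regions]
    missing <- regions[!regions %in% names(region_p)]
    if (length(missing)) {
      stop("region(s) absent from pointwise maps: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    abn <- pcat_at_least(region_p[regions], struct_alpha)
    switch(layer_rule,
      either = any(abn),
      both = any(abn[layers == "RNFL"]) && any(abn[layers == "GCLPLUS"]),
      RNFL = any(abn[layers == "RNFL"]),
      GCLPLUS = any(abn[layers == "GCLPLUS"]))
  }
  eval_map <- function(pd, location_map) {
    out <- logical(length(pd))
    names(out) <- names(pd)
    fun_abn <- pcat_at_least(pd, vf_alpha)
    for (i in seq_along(pd)) {
      loc <- names(pd)[i]
      regions <- location_map[[loc]]
      if (is.null(regions)) {
        stop("VF location without correspondence entry: ", loc,
             call. = FALSE)
      }
      out[i] <- fun_abn[i] && struct_abnormal(regions)
    }
    out
  }
  per_location <- c(eval_map(points$vf24_pd, corr$map24),
                    eval_map(points$vf10_pd, corr$map10))
  structure(list(eye_id = eye_id, visit = visit,
                 n_asaf = sum(per_location),
                 per_location = per_location),
            class = "asaf_result")
}

#' Classify one eye as likely glaucoma from two baseline aS-aF counts
#'
#' @param visit1,visit2 `asaf_result` objects for the same eye.
#' @param min_locations minimum aS-aF locations required in each OCT-VF
#'   pair (default 3).
#' @return logical: `TRUE` iff both visits reach `min_locations`.
#' @export
classify_lg <- function(visit1, visit2, min_locations = 3L) {
  stopifnot(inherits(visit1, "asaf_result"), inherits(visit2, "asaf_result"))
  if (!is.na(visit1$eye_id) && !is.na(visit2$eye_id) &&
      visit1$eye_id != visit2$eye_id) {
    stop("classify_lg: results belong to different eyes (",
         visit1$eye_id, " vs ", visit2$eye_id, ")", call. = FALSE)
  }
  visit1$n_asaf >= min_locations && visit2$n_asaf >= min_locations
}

#' Label a two-visit cohort as HC / LG / NEITHER
#'
#' Healthy-control eyes keep the label `HC`. Patient eyes are labelled
#' `LG` when both baseline visits show at least `min_locations` aS-aF
#' locations, and `NEITHER` otherwise; `NEITHER` eyes are excluded from
#' sensitivity and specificity denominators downstream.
#'
#' @param records list of `eye_visit` records; each patient eye must have
#'   visits 1 and 2 with pointwise maps.
#' @param corr an [sf_correspondence()].
#' @param min_locations see [classify_lg()].
#' @param ... further arguments passed to [count_asaf()].
#' @return named character vector, eye id -> `"HC"`, `"LG"` or
#'   `"NEITHER"`; names follow first appearance in `records`.
#' @export
label_cohort <- function(records, corr, min_locations = 3L, ...) {
  ids <- vapply(records, `[[`, character(1), "eye_id")
  groups <- vapply(records, `[[`, character(1), "group")
  eye_order <- unique(ids)
  labels <- stats::setNames(character(length(eye_order)), eye_order)
  for (eye in eye_order) {
    recs <- records[ids == eye]
    if (groups[match(eye, ids)] == "HC") {
      labels[eye] <- "HC"
      next
    }
    visits <- vapply(recs, `[[`, integer(1), "visit")
    if (!all(c(1L, 2L) %in% visits)) {
      stop("patient eye ", eye, " is missing a baseline visit",
           call. = FALSE)
    }
    r1 <- recs[[match(1L, visits)]]
    r2 <- recs[[match(2L, visits)]]
    if (is.null(r1$pointwise) || is.null(r2$pointwise)) {
      stop("patient eye ", eye, " has no pointwise maps", call. = FALSE)
    }
    a1 <- count_asaf(r1$pointwise, corr, eye_id = eye, visit = 1L, ...)
    a2 <- count_asaf(r2$pointwise, corr, eye_id = eye, visit = 2L, ...)
    labels[eye] <- if (classify_lg(a1, a2, min_locations)) "LG" else "NEITHER"
  }
  labels
}
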