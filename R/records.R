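# Per-eye, per-visit record structures and their validation.

#' Measures and sector layouts
#'
#' Peripapillary measures (BMO-MRW and the circumpapillary RNFL at the
#' 3.5 mm and 4.7 mm circles) carry a global value and six sectors named
#' after the Garway-Heath regions; macular measures (GCL, IPL, total
#' retina) carry a global value and six posterior-pole sectors.
#' @export
MEASURES <- c("MRW", "RNFL_SMALL", "RNFL_LARGE", "GCL", "IPL", "RETINA")

#' @rdname MEASURES
#' @export
PERIPAPILLARY_SECTORS <- c("G", "T", "TS", "TI", "N", "NS", "NI")

#' @rdname MEASURES
#' @export
MACULAR_SECTORS <- c("G", "S", "TS", "TI", "I", "NS", "NI")

#' Sector labels required for a measure
#' @param measure one of `MEASURES`.
#' @return character vector of sector labels.
#' @export
sectors_for <- function(measure) {
  measure <- match.arg(measure, MEASURES)
  if (measure %in% c("MRW", "RNFL_SMALL", "RNFL_LARGE")) {
    PERIPAPILLARY_SECTORS
  } else {
    MACULAR_SECTORS
  }
}

# Macular measures must carry at least these labels; extra labels are allowed.
MACULAR_MIN_SECTORS <- c("G", "S", "TS", "TI", "I")

#' Build a sector set for one measure
#'
#' @param measure one of `MEASURES`.
#' @param codes named character (or color-code) vector, sector label ->
#'   color code.
#' @return a named ordered color-code factor with a `measure` attribute.
#' @export
sector_set <- function(measure, codes) {
  measure <- match.arg(measure, MEASURES)
  labels <- names(codes)
  required <- if (measure %in% c("MRW", "RNFL_SMALL", "RNFL_LARGE")) {
    PERIPAPILLARY_SECTORS
  } else {
    MACULAR_MIN_SECTORS
  }
  missing <- setdiff(required, labels)
  if (length(missing)) {
    stop(measure, ": missing sector label(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop(measure, ": duplicated sector labels", call. = FALSE)
  }
  out <- color_code(codes)
  if (anyNA(out)) {
    stop(measure, ": invalid color code for sector(s) ",
         paste(labels[is.na(out)], collapse = ", "), call. = FALSE)
  }
  names(out) <- labels
  attr(out, "measure") <- measure
  out
}

#' Build the visual-field metric block for one test
#'
#' @param test "VF24" or "VF10".
#' @param md_p,psd_p p-categories of the mean deviation and pattern standard
#'   deviation.
#' @param ght GHT category; required for VF24, must be absent for VF10.
#' @param fp_rate,fixation_loss_rate reliability indices as fractions in
#'   \[0, 1\].
#' @param md_db,psd_db optional decibel values, needed only by GSS2 staging.
#' @return a list of class `vf_metrics`.
#' @export
vf_metrics <- function(test, md_p, psd_p, ght = NULL,
                       fp_rate = 0, fixation_loss_rate = 0,
                       md_db = NA_real_, psd_db = NA_real_) {
  test <- match.arg(test, c("VF24", "VF10"))
  if (test == "VF24" && is.null(ght)) {
    stop("VF24 requires a GHT category", call. = FALSE)
  }
  if (test == "VF10" && !is.null(ght)) {
    stop("VF10 carries no GHT category", call. = FALSE)
  }
  rates <- c(fp_rate, fixation_loss_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop(test, ": reliability rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    test = test,
    md_p = p_category(md_p),
    psd_p = p_category(psd_p),
    ght = if (is.null(ght)) NULL else ght_category(ght),
    fp_rate = as.numeric(fp_rate),
    fixation_loss_rate = as.numeric(fixation_loss_rate),
    md_db = as.numeric(md_db),
    psd_db = as.numeric(psd_db)
  ), class = "vf_metrics")
}

#' Pointwise probability maps for one eye-visit
#'
#' Pattern-deviation p-categories for the 52 non-blind-spot 24-2 locations
#' and the 68 10-2 locations, plus p-categories of the structural regions
#' (RNFL and GCL+ probability-map regions) they are compared against.
#'
#' @param vf24_pd,vf10_pd named p-category vectors (location id -> category)
#'   with exactly 52 and 68 entries.
#' @param rnfl_regions,gclplus_regions named p-category vectors
#'   (region id -> category).
#' @return a list of class `pointwise_maps`.
#' @export
pointwise_maps <- function(vf24_pd, vf10_pd, rnfl_regions, gclplus_regions) {
  as_map <- function(x, what) {
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      stop(what, ": locations must have unique names", call. = FALSE)
    }
    out <- p_category(x)
    names(out) <- names(x)
    out
  }
  vf24_pd <- as_map(vf24_pd, "vf24_pd")
  vf10_pd <- as_map(vf10_pd, "vf10_pd")
  if (length(vf24_pd) != 52L) {
    stop("vf24_pd must have exactly 52 locations, got ", length(vf24_pd),
         call. = FALSE)
  }
  if (length(vf10_pd) != 68L) {
    stop("vf10_pd must have exactly 68 locations, got ", length(vf10_pd),
         call. = FALSE)
  }
  structure(list(
    vf24_pd = vf24_pd,
    vf10_pd = vf10_pd,
    rnfl_regions = as_map(rnfl_regions, "rnfl_regions"),
    gclplus_regions = as_map(gclplus_regions, "gclplus_regions")
  ), class = "pointwise_maps")
}

#' Assemble one eye-visit record
#'
#' The recruitment `group` ("HC" or "PATIENT") is a label only; whether a
#' patient eye counts as likely glaucoma is computed by the reference
#' standard, never stored as input truth.
#'
#' @param eye_id string.
#' @param visit 1 or 2.
#' @param sectors named list measure -> sector set (see [sector_set()]).
#' @param vf24,vf10 [vf_metrics()] blocks.
#' @param group "HC" or "PATIENT".
#' @param pointwise optional [pointwise_maps()].
#' @return a list of class `eye_visit`.
#' @export
eye_visit_record <- function(eye_id, visit, sectors, vf24, vf10, group,
                             pointwise = NULL) {
  stopifnot(is.character(eye_id), length(eye_id) == 1L, nzchar(eye_id))
  visit <- as.integer(visit)
  if (!visit %in% c(1L, 2L)) stop("visit must be 1 or 2", call. = FALSE)
  group <- match.arg(group, c("HC", "PATIENT"))
  if (!is.list(sectors) || is.null(names(sectors))) {
    stop("sectors must be a named list of sector sets", call. = FALSE)
  }
  bad <- setdiff(names(sectors), MEASURES)
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (m in names(sectors)) {
    if (!identical(attr(sectors[[m]], "measure"), m)) {
      sectors[[m]] <- sector_set(m, sectors[[m]])
    }
  }
  if (!inherits(vf24, "vf_metrics") || vf24$test != "VF24") {
    stop("vf24 must be a VF24 vf_metrics block", call. = FALSE)
  }
  if (!inherits(vf10, "vf_metrics") || vf10$test != "VF10") {
    stop("vf10 must be a VF10 vf_metrics block", call. = FALSE)
  }
  if (!is.null(pointwise) && !inherits(pointwise, "pointwise_maps")) {
    stop("pointwise must be a pointwise_maps object", call. = FALSE)
  }
  structure(list(
    eye_id = eye_id, visit = visit, group = group,
    sectors = sectors, vf24 = vf24, vf10 = vf10,
    pointwise = pointwise
  ), class = "eye_visit")
}

#' @export
print.eye_visit <- function(x, ...) {
  cat(sprintf("<eye_visit> %s visit %d (%s); measures: %s; pointwise: %s\n",
              x$eye_id, x$visit, x$group,
              paste(names(x$sectors), collapse = ", "),
              if (is.null(x$pointwise)) "no" else "yes"))
  invisible(x)
}

#' Look up one sector color code in a record
#'
#' A missing measure or sector label is an error: criteria never treat a
#' missing metric as normal.
#'
#' @param record an `eye_visit`.
#' @param measure one of `MEASURES`.
#' @param sector sector label.
#' @return length-1 ordered color-code factor.
#' @export
sector_code <- function(record, measure, sector) {
  ss <- record$sectors[[measure]]
  if (is.null(ss)) {
    stop("record ", record$eye_id, " visit ", record$visit,
         ": measure ", measure, " not present", call. = FALSE)
  }
  if (!sector %in% names(ss)) {
    stop("record ", record$eye_id, ": measure ", measure,
         " has no sector ", sector, call. = FALSE)
  }
  ss[[sector]]
}

#' Exclude eye-visits with unreliable visual fields
#'
#' A visit is excluded when either VF test had a false-positive response
#' rate above 15% or fixation losses above 33%; values exactly at the
#' limits are kept. Both tests must be reliable for the visit to be kept,
#' since every criterion may consult both.
#'
#' @param records list of `eye_visit` records.
#' @return list with elements `kept` and `excluded`, each preserving input
#'   order; `kept` and `excluded` partition the input.
#' @export
apply_reliability_filter <- function(records) {
  unreliable <- vapply(records, function(r) {
    any(c(r$vf24$fp_rate, r$vf10$fp_rate) > 0.15) ||
      any(c(r$vf24$fixation_loss_rate, r$vf10$fixation_loss_rate) > 1 / 3)
  }, logical(1))
  list(kept = records[!unreliable], excluded = records[unreliable])
}

#' Validate a cohort of records
#'
#' @param records list of `eye_visit` records.
#' @return the records, invisibly; errors on duplicate (eye_id, visit).
#' @export
validate_cohort <- function(records) {
  keys <- vapply(records, function(r) paste(r$eye_id, r$visit), character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (eye_id, visit): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  invisible(records)
}
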