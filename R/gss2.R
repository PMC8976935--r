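# Brusini Glaucoma Staging System 2 (GSS2) staging from 24-2 MD and PSD.
#
# The GSS2 places a field on a nonlinear MD-PSD chart and reads off a
# stage: normal (0), a borderline band, then stages 1 to 5 of increasing
# defect. The chart itself is published as a graphic; the boundary table
# below is this package's own piecewise-constant approximation of it
# (version 1), deliberately simple and validated for monotonicity rather
# than against chart coordinates: holding PSD fixed, a more negative MD
# never lowers the stage, and holding MD fixed, a larger PSD never lowers
# the stage.

# Stage cut-points, version 1. MD in dB (more negative = worse); PSD in dB
# (larger = worse). A field's stage is the worse of its MD-stage and
# PSD-stage; the borderline band surrounds the normal region.
GSS2_MD_CUTS <- c(-2, -4, -8, -14, -20)   # stage >= k iff md <= cut[k]
GSS2_PSD_CUTS <- c(2, 4, 7, 10, 13)       # stage >= k iff psd >= cut[k]
GSS2_BORDERLINE_MD <- -1                  # borderline band: md <= -1 dB
GSS2_BORDERLINE_PSD <- 1.7                # or psd >= 1.7 dB

#' Stage a 24-2 visual field with the GSS2
#'
#' @param md_db 24-2 mean deviation in decibels (finite).
#' @param psd_db 24-2 pattern standard deviation in decibels (finite).
#' @return an object of class `gss2_stage`: a list with integer `stage`
#'   (0-5) and logical `borderline` (only ever `TRUE` at stage 0).
#' @examples
#' gss2_stage(1.0, 1.2)    # clearly normal
#' gss2_stage(-20, 12)     # end-stage
#' @export
gss2_stage <- function(md_db, psd_db) {
  if (!is.finite(md_db) || !is.finite(psd_db)) {
    stop("GSS2 staging needs finite MD and PSD values", call. = FALSE)
  }
  s_md <- sum(md_db <= GSS2_MD_CUTS)
  s_psd <- sum(psd_db >= GSS2_PSD_CUTS)
  stage <- max(s_md, s_psd)
  borderline <- stage == 0L &&
    (md_db <= GSS2_BORDERLINE_MD || psd_db >= GSS2_BORDERLINE_PSD)
  structure(list(stage = as.integer(stage), borderline = borderline),
            class = "gss2_stage")
}

#' @export
print.gss2_stage <- function(x, ...) {
  cat("<gss2_stage>", if (x$borderline) "borderline" else
    paste("stage", x$stage), "\n")
  invisible(x)
}
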