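# Ordinal abnormality scales used on OCT and visual-field reports.

#' Color-code levels, in increasing order of abnormality
#'
#' OCT reports flag each summary metric against a normative database with a
#' traffic-light scheme: green (within normal limits), yellow (borderline,
#' P < 5%) and red (outside normal limits, P < 1%).
#' @export
COLOR_LEVELS <- c("green", "yellow", "red")

#' P-value categories, in increasing order of abnormality
#'
#' The category ladder used by perimetry probability maps: not significant,
#' then P < 10%, < 5%, < 2%, < 1%, < 0.5%. One ordinal type carries all
#' thresholds the package needs (5% for VF abnormality, 10% for structural
#' regions, 1% for the strict criterion mode).
#' @export
P_LEVELS <- c("ns", "p10", "p5", "p2", "p1", "p05")

#' Glaucoma hemifield test categories
#' @export
GHT_LEVELS <- c("wnl", "borderline", "onl", "other")

#' Construct a color-code factor
#'
#' @param x character vector of codes ("green", "yellow", "red"; case
#'   insensitive).
#' @return an ordered factor with levels green < yellow < red.
#' @export
color_code <- function(x) {
  factor(tolower(as.character(x)), levels = COLOR_LEVELS, ordered = TRUE)
}

#' Parse color-code tokens with report synonyms
#'
#' Accepts the literal color names and the within/borderline/outside normal
#' limits synonyms printed on reports. Unknown tokens are an error.
#'
#' @param token character vector of tokens.
#' @param context optional string (e.g. "row 3, column MRW_G") used in the
#'   error message.
#' @return an ordered color-code factor, same length as `token`.
#' @examples
#' parse_color_code("Red")
#' parse_color_code("wnl")
#' @export
parse_color_code <- function(token, context = NULL) {
  stopifnot(length(token) >= 1L)
  tok <- tolower(trimws(as.character(token)))
  syn <- c(green = "green", wnl = "green",
           yellow = "yellow", borderline = "yellow",
           red = "red", onl = "red")
  bad <- !(tok %in% names(syn)) | tok == ""
  if (any(bad)) {
    where <- if (is.null(context)) "" else paste0(" (", context, ")")
    stop("unknown color-code token(s): ",
         paste(unique(token[bad]), collapse = ", "), where, call. = FALSE)
  }
  color_code(unname(syn[tok]))
}

#' Construct a p-category factor
#'
#' @param x character vector among `P_LEVELS` (case insensitive; "<5%",
#'   "p<5", "0.05"-style tokens are not accepted -- categories are named).
#' @return an ordered factor ns < p10 < p5 < p2 < p1 < p05.
#' @export
p_category <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  bad <- !(tok %in% P_LEVELS)
  if (any(bad)) {
    stop("unknown p-category token(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  factor(tok, levels = P_LEVELS, ordered = TRUE)
}

#' Construct a GHT category factor
#'
#' "other" covers messages such as a general reduction of sensitivity that
#' are neither within normal limits, borderline nor outside normal limits.
#' @param x character vector among `GHT_LEVELS` (case insensitive).
#' @return an unordered factor (the GHT scale is only partially ordered).
#' @export
ght_category <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  bad <- !(tok %in% GHT_LEVELS)
  if (any(bad)) {
    stop("unknown GHT token(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(tok, levels = GHT_LEVELS)
}

# p-category threshold queries ------------------------------------------------

#' Is a p-category at least as abnormal as a cutoff?
#'
#' @param p a p-category factor (or character coercible to one).
#' @param cutoff one of `P_LEVELS`; e.g. "p5" asks "abnormal at the 5% level".
#' @return logical vector.
#' @export
pcat_at_least <- function(p, cutoff) {
  p <- p_category(p)
  p >= p_category(cutoff)
}
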