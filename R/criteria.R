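# Composable boolean criterion trees over eye-visit records.
#
# A criterion is a finite tree of nodes: leaves select one metric (an OCT
# sector color code, a VF index, the GHT, or the GSS2 stage); internal
# nodes combine children with AND/OR; two special forms capture the
# paired-sector OCT agreement rule and the quadrant-plus-GHT rule.
# Evaluation is pure: the same record and threshold mode always give the
# same boolean, and child order never changes the result.

new_criterion <- function(kind, ..., name = NULL) {
  structure(c(list(kind = kind), list(...)), name = name, class = "criterion")
}

#' Criterion leaves and combinators
#'
#' * `crit_oct(measure, sector)` -- abnormality of one OCT sector code.
#' * `crit_vf(metric)` -- abnormality of a VF index: one of `"MD24"`,
#'   `"PSD24"`, `"GHT"`, `"MD10"`, `"PSD10"`.
#' * `crit_gss2()` -- abnormality by Brusini GSS2 staging of the 24-2
#'   MD/PSD decibel values.
#' * `crit_and(...)`, `crit_or(...)` -- logical combination of two or more
#'   criteria.
#' * `crit_any_paired(measure_a, measure_b, sectors)` -- true when any one
#'   of the listed sectors is abnormal in both measures.
#' * `crit_quadrant_ght()` -- true when any quadrant sector (TS, NS, TI,
#'   NI) of the small-circle cpRNFL is abnormal and the GHT is abnormal.
#'
#' @param measure,measure_a,measure_b one of `MEASURES`.
#' @param sector,sectors sector label(s); validated at construction.
#' @param metric VF index identifier.
#' @param ... child criteria (at least two).
#' @param name optional human-readable name attached to the node.
#' @return an object of class `criterion`.
#' @export
crit_oct <- function(measure, sector, name = NULL) {
  measure <- match.arg(measure, MEASURES)
  if (!sector %in% sectors_for(measure)) {
    stop("measure ", measure, " has no sector ", sector, call. = FALSE)
  }
  new_criterion("oct", measure = measure, sector = sector,
                name = name %||% paste(measure, sector, sep = "_"))
}

#' @rdname crit_oct
#' @export
crit_vf <- function(metric, name = NULL) {
  metric <- match.arg(metric, c("MD24", "PSD24", "GHT", "MD10", "PSD10"))
  new_criterion("vf", metric = metric, name = name %||% metric)
}

#' @rdname crit_oct
#' @export
crit_gss2 <- function(name = "GSS2") {
  new_criterion("gss2", name = name)
}

#' @rdname crit_oct
#' @export
crit_and <- function(..., name = NULL) {
  children <- list(...)
  stopifnot(length(children) >= 2L,
            all(vapply(children, inherits, logical(1), "criterion")))
  new_criterion("and", children = children, name = name)
}

#' @rdname crit_oct
#' @export
crit_or <- function(..., name = NULL) {
  children <- list(...)
  stopifnot(length(children) >= 2L,
            all(vapply(children, inherits, logical(1), "criterion")))
  new_criterion("or", children = children, name = name)
}

#' @rdname crit_oct
#' @export
crit_any_paired <- function(measure_a, measure_b, sectors, name = NULL) {
  measure_a <- match.arg(measure_a, MEASURES)
  measure_b <- match.arg(measure_b, MEASURES)
  ok <- intersect(sectors_for(measure_a), sectors_for(measure_b))
  bad <- setdiff(sectors, ok)
  if (length(bad)) {
    stop("sector(s) not shared by ", measure_a, " and ", measure_b, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  new_criterion("any_paired", measure_a = measure_a, measure_b = measure_b,
                sectors = sectors, name = name)
}

#' @rdname crit_oct
#' @export
crit_quadrant_ght <- function(name = "IYER_Q_GHT") {
  new_criterion("quadrant_ght", name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.criterion <- function(x, ...) {
  cat("<criterion>", attr(x, "name") %||% x$kind, "\n")
  cat(deparse_criterion(x), "\n")
  invisible(x)
}

#' Render a criterion as a readable boolean expression
#' @param node a `criterion`.
#' @return a single string.
#' @export
deparse_criterion <- function(node) {
  switch(node$kind,
    oct = paste(node$measure, node$sector, sep = "_"),
    vf = node$metric,
    gss2 = "GSS2",
    and = paste0("(", paste(vapply(node$children, deparse_criterion,
                                   character(1)), collapse = " AND "), ")"),
    or = paste0("(", paste(vapply(node$children, deparse_criterion,
                                  character(1)), collapse = " OR "), ")"),
    any_paired = paste0("AnyPaired[", node$measure_a, ",", node$measure_b,
                        "; ", paste(node$sectors, collapse = ","), "]"),
    quadrant_ght = "(Quadrant(RNFL_SMALL) AND GHT)")
}

# Abnormality thresholds ------------------------------------------------------

#' Decide abnormality of a single value under a threshold mode
#'
#' Under the borderline mode a metric is abnormal when it is at least
#' borderline: a yellow or red color code, a p-category of < 5% or worse, a
#' borderline or outside-normal-limits GHT, a borderline-or-worse GSS2
#' stage. Under the strict mode only outside-normal-limits values count:
#' red, p < 1% or worse, GHT outside normal limits, GSS2 stage >= 1.
#' Abnormal under strict always implies abnormal under borderline.
#'
#' @param value a color-code factor, p-category factor, GHT factor, or
#'   `gss2_stage` object.
#' @param threshold `"borderline"` (5% level) or `"strict"` (1% level).
#' @param ght_other_abnormal should the GHT category "other" (e.g. general
#'   reduction of sensitivity) count as abnormal? Default `FALSE`.
#' @return logical.
#' @export
is_abnormal <- function(value, threshold = c("borderline", "strict"),
                        ght_other_abnormal = FALSE) {
  threshold <- match.arg(threshold)
  if (inherits(value, "gss2_stage")) {
    return(if (threshold == "borderline") {
      value$borderline || value$stage >= 1L
    } else {
      value$stage >= 1L
    })
  }
  lev <- levels(value)
  if (identical(lev, COLOR_LEVELS)) {
    cut <- if (threshold == "borderline") "yellow" else "red"
    return(as.logical(value >= color_code(cut)))
  }
  if (identical(lev, P_LEVELS)) {
    cut <- if (threshold == "borderline") "p5" else "p1"
    return(as.logical(value >= p_category(cut)))
  }
  if (identical(lev, GHT_LEVELS)) {
    abn <- if (threshold == "borderline") c("borderline", "onl") else "onl"
    if (ght_other_abnormal) abn <- c(abn, "other")
    return(as.character(value) %in% abn)
  }
  stop("is_abnormal: unrecognised value type", call. = FALSE)
}

vf_value <- function(record, metric) {
  switch(metric,
    MD24 = record$vf24$md_p,
    PSD24 = record$vf24$psd_p,
    GHT = record$vf24$ght %||%
      stop("record ", record$eye_id, ": GHT missing", call. = FALSE),
    MD10 = record$vf10$md_p,
    PSD10 = record$vf10$psd_p)
}

#' Evaluate a criterion on one eye-visit record
#'
#' @param node a `criterion`.
#' @param record an `eye_visit`.
#' @param threshold `"borderline"` or `"strict"` (see [is_abnormal()]).
#' @param ght_other_abnormal passed to [is_abnormal()].
#' @return logical: does the record satisfy the criterion?
#' @export
eval_criterion <- function(node, record,
                           threshold = c("borderline", "strict"),
                           ght_other_abnormal = FALSE) {
  threshold <- match.arg(threshold)
  ev <- function(n) {
    switch(n$kind,
      oct = is_abnormal(sector_code(record, n$measure, n$sector), threshold),
      vf = is_abnormal(vf_value(record, n$metric), threshold,
                       ght_other_abnormal),
      gss2 = {
        if (!is.finite(record$vf24$md_db) || !is.finite(record$vf24$psd_db)) {
          stop("record ", record$eye_id,
               ": GSS2 needs finite 24-2 MD/PSD decibel values",
               call. = FALSE)
        }
        is_abnormal(gss2_stage(record$vf24$md_db, record$vf24$psd_db),
                    threshold)
      },
      and = all(vapply(n$children, ev, logical(1))),
      or = any(vapply(n$children, ev, logical(1))),
      any_paired = any(vapply(n$sectors, function(s) {
        is_abnormal(sector_code(record, n$measure_a, s), threshold) &&
          is_abnormal(sector_code(record, n$measure_b, s), threshold)
      }, logical(1))),
      quadrant_ght = {
        quad <- any(vapply(c("TS", "NS", "TI", "NI"), function(s) {
          is_abnormal(sector_code(record, "RNFL_SMALL", s), threshold)
        }, logical(1)))
        quad && is_abnormal(vf_value(record, "GHT"), threshold,
                            ght_other_abnormal)
      },
      stop("unknown criterion kind: ", n$kind, call. = FALSE))
  }
  ev(node)
}

# Named criteria from the literature ------------------------------------------

#' The structure-structure (S-S) hemifield agreement metric
#'
#' An eye is abnormal when cpRNFL and macular GCL abnormality agree within
#' a hemifield: inferior agreement is an abnormal temporal-inferior
#' small-circle cpRNFL sector together with an abnormal TI or inferior GCL
#' sector; superior agreement is the mirror image. Either hemifield
#' suffices:
#' `(TI_small AND (TI_GCL OR I_GCL)) OR (TS_small AND (TS_GCL OR S_GCL))`.
#'
#' @return a `criterion`.
#' @export
build_ss_metric <- function() {
  crit_or(
    crit_and(crit_oct("RNFL_SMALL", "TI"),
             crit_or(crit_oct("GCL", "TI"), crit_oct("GCL", "I")),
             name = "INFERIOR_SS"),
    crit_and(crit_oct("RNFL_SMALL", "TS"),
             crit_or(crit_oct("GCL", "TS"), crit_oct("GCL", "S")),
             name = "SUPERIOR_SS"),
    name = "SS_METRIC")
}

#' The paired-sector cpRNFL / BMO-MRW agreement criterion
#'
#' Requires the same-named sector to be abnormal in both the small-circle
#' cpRNFL and the BMO-MRW, in any one of the six sectors (Yang et al.
#' style).
#'
#' @return a `criterion`.
#' @export
build_yang <- function() {
  crit_any_paired("RNFL_SMALL", "MRW", c("T", "TS", "TI", "N", "NS", "NI"),
                  name = "YANG_PAIRED")
}

#' The quadrant-plus-GHT structure-function criterion
#'
#' Abnormality of any superior (TS or NS) or inferior (TI or NI) sector of
#' the small-circle cpRNFL together with an abnormal GHT (Iyer et al.,
#' third criterion). Matching is co-occurrence, not hemifield-matched: the
#' GHT is a single categorical outcome with no laterality here.
#'
#' @return a `criterion`.
#' @export
build_iyer_q_ght <- function() {
  crit_quadrant_ght()
}

#' Catalog of all evaluated criteria
#'
#' Every named criterion the package evaluates: all single OCT sector
#' metrics (global + 6 sectors for each of the 6 measures), the five VF
#' indices, structure-structure combinations (including the S-S metric and
#' the paired-sector rule), all pairwise function-function combinations,
#' GSS2, and the structure-function combinations.
#'
#' @return a data frame with columns `name`, `category` (one of
#'   `OCT_SINGLE`, `OCT_COMBO`, `VF_SINGLE`, `FF_COMBO`, `SF_COMBO`) and a
#'   list-column `criterion`.
#' @export
criteria_catalog <- function() {
  entries <- list()
  add <- function(name, category, node) {
    entries[[length(entries) + 1L]] <<-
      list(name = name, category = category, criterion = node)
  }
  for (m in MEASURES) {
    for (s in sectors_for(m)) {
      add(paste(m, s, sep = "_"), "OCT_SINGLE", crit_oct(m, s))
    }
  }
  add("SS_METRIC", "OCT_COMBO", build_ss_metric())
  add("G_SMALL_AND_G_MRW", "OCT_COMBO",
      crit_and(crit_oct("RNFL_SMALL", "G"), crit_oct("MRW", "G")))
  add("TI_SMALL_AND_TI_MRW", "OCT_COMBO",
      crit_and(crit_oct("RNFL_SMALL", "TI"), crit_oct("MRW", "TI")))
  add("YANG_PAIRED", "OCT_COMBO", build_yang())
  add("G_SMALL_AND_G_GCL", "OCT_COMBO",
      crit_and(crit_oct("RNFL_SMALL", "G"), crit_oct("GCL", "G")))
  add("TI_SMALL_AND_TI_GCL", "OCT_COMBO",
      crit_and(crit_oct("RNFL_SMALL", "TI"), crit_oct("GCL", "TI")))
  add("G_SMALL_AND_G_LARGE", "OCT_COMBO",
      crit_and(crit_oct("RNFL_SMALL", "G"), crit_oct("RNFL_LARGE", "G")))
  add("TI_SMALL_AND_TI_LARGE", "OCT_COMBO",
      crit_and(crit_oct("RNFL_SMALL", "TI"), crit_oct("RNFL_LARGE", "TI")))
  vf_ids <- c("MD24", "PSD24", "GHT", "MD10", "PSD10")
  for (v in vf_ids) add(paste0("VF_", v), "VF_SINGLE", crit_vf(v))
  pairs <- utils::combn(vf_ids, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    add(paste0("FF_", a, "_AND_", b), "FF_COMBO",
        crit_and(crit_vf(a), crit_vf(b)))
  }
  add("GSS2", "VF_SINGLE", crit_gss2())
  psd_or <- crit_or(crit_vf("PSD24"), crit_vf("PSD10"))
  md_or <- crit_or(crit_vf("MD24"), crit_vf("MD10"))
  g_or <- crit_or(crit_oct("RNFL_SMALL", "G"), crit_oct("GCL", "G"))
  add("G_OR_AND_PSD_OR", "SF_COMBO", crit_and(g_or, psd_or))
  add("G_OR_AND_MD_OR", "SF_COMBO", crit_and(g_or, md_or))
  for (g in c("RNFL_SMALL", "GCL")) {
    for (v in c("MD24", "PSD24", "MD10", "PSD10")) {
      add(paste0("G_", g, "_AND_", v), "SF_COMBO",
          crit_and(crit_oct(g, "G"), crit_vf(v)))
    }
  }
  ss <- build_ss_metric()
  add("SS_AND_PSD_OR", "SF_COMBO", crit_and(ss, psd_or))
  add("SS_AND_MD_OR", "SF_COMBO", crit_and(ss, md_or))
  add("SS_AND_PSD24", "SF_COMBO", crit_and(ss, crit_vf("PSD24")))
  add("SS_AND_PSD10", "SF_COMBO", crit_and(ss, crit_vf("PSD10")))
  add("SS_AND_MD24", "SF_COMBO", crit_and(ss, crit_vf("MD24")))
  add("SS_AND_MD10", "SF_COMBO", crit_and(ss, crit_vf("MD10")))
  add("IYER_Q_GHT", "SF_COMBO", build_iyer_q_ght())
  df <- data.frame(
    name = vapply(entries, `[[`, character(1), "name"),
    category = vapply(entries, `[[`, character(1), "category"),
    stringsAsFactors = FALSE)
  df$criterion <- lapply(entries, `[[`, "criterion")
  stopifnot(!anyDuplicated(df$name))
  df
}

#' Fetch one catalog criterion by name
#' @param name stable identifier, e.g. `"SS_METRIC"`, `"RNFL_SMALL_TI"`.
#' @param catalog optionally a precomputed [criteria_catalog()].
#' @return a `criterion`.
#' @export
get_criterion <- function(name, catalog = criteria_catalog()) {
  i <- match(name, catalog$name)
  if (is.na(i)) stop("no catalog criterion named ", name, call. = FALSE)
  catalog$criterion[[i]]
}

# YAML expression form --------------------------------------------------------

#' Build a criterion from a nested list / YAML expression
#'
#' Grammar (each node is a mapping with exactly one of these shapes):
#' ```yaml
#' oct: {measure: RNFL_SMALL, sector: TI}
#' vf: PSD24
#' gss2: true
#' and: [<node>, <node>, ...]
#' or:  [<node>, <node>, ...]
#' any_paired: {measure_a: RNFL_SMALL, measure_b: MRW, sectors: [T, TS, TI, N, NS, NI]}
#' quadrant_ght: true
#' catalog: SS_METRIC
#' ```
#'
#' @param x nested list (already parsed) or, for [read_criterion_yaml()], a
#'   YAML file path.
#' @return a `criterion`.
#' @export
criterion_from_list <- function(x) {
  stopifnot(is.list(x), length(x) == 1L)
  key <- names(x)
  val <- x[[1L]]
  switch(key,
    oct = crit_oct(val$measure, val$sector),
    vf = crit_vf(val),
    gss2 = crit_gss2(),
    and = do.call(crit_and, lapply(val, criterion_from_list)),
    or = do.call(crit_or, lapply(val, criterion_from_list)),
    any_paired = crit_any_paired(val$measure_a, val$measure_b,
                                 unlist(val$sectors)),
    quadrant_ght = crit_quadrant_ght(),
    catalog = get_criterion(val),
    stop("unknown criterion expression key: ", key, call. = FALSE))
}

#' @rdname criterion_from_list
#' @export
read_criterion_yaml <- function(x) {
  criterion_from_list(yaml::read_yaml(x))
}
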