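# Flat-file input/output: one CSV row per eye-visit, companion long CSVs
# for pointwise maps and the structure-function correspondence map.

sector_columns <- function() {
  unlist(lapply(MEASURES, function(m) paste(m, sectors_for(m), sep = "_")),
         use.names = FALSE)
}

VF_COLUMNS <- c("vf24_md_p", "vf24_psd_p", "vf24_ght", "vf24_fp", "vf24_fl",
                "vf24_md_db", "vf24_psd_db",
                "vf10_md_p", "vf10_psd_p", "vf10_fp", "vf10_fl")

#' Write a cohort to CSV
#'
#' One row per eye-visit; sector columns are named `<measure>_<sector>`
#' (e.g. `RNFL_SMALL_TI`), visual-field columns `vf24_md_p`, `vf24_ght`,
#' `vf10_psd_p`, ... Pointwise maps, when present, go to a companion
#' long-format CSV keyed by eye id, visit, map and location id.
#'
#' @param records list of `eye_visit` records.
#' @param path output CSV path for the per-visit table.
#' @param pointwise_path optional output path for the pointwise long table.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, pointwise_path = NULL) {
  validate_cohort(records)
  rows <- lapply(records, function(r) {
    row <- list(eye_id = r$eye_id, visit = r$visit, group = r$group)
    for (m in MEASURES) {
      for (s in sectors_for(m)) {
        col <- paste(m, s, sep = "_")
        ss <- r$sectors[[m]]
        row[[col]] <- if (!is.null(ss) && s %in% names(ss)) {
          as.character(ss[[s]])
        } else NA_character_
      }
    }
    row$vf24_md_p <- as.character(r$vf24$md_p)
    row$vf24_psd_p <- as.character(r$vf24$psd_p)
    row$vf24_ght <- as.character(r$vf24$ght)
    row$vf24_fp <- r$vf24$fp_rate
    row$vf24_fl <- r$vf24$fixation_loss_rate
    row$vf24_md_db <- r$vf24$md_db
    row$vf24_psd_db <- r$vf24$psd_db
    row$vf10_md_p <- as.character(r$vf10$md_p)
    row$vf10_psd_p <- as.character(r$vf10$psd_p)
    row$vf10_fp <- r$vf10$fp_rate
    row$vf10_fl <- r$vf10$fixation_loss_rate
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(pointwise_path)) {
    write_pointwise(records, pointwise_path)
  }
  invisible(path)
}

write_pointwise <- function(records, path) {
  rows <- list()
  for (r in records) {
    pw <- r$pointwise
    if (is.null(pw)) next
    for (map in names(pw)) {
      v <- pw[[map]]
      rows[[length(rows) + 1L]] <- data.frame(
        eye_id = r$eye_id, visit = r$visit, map = map,
        location_id = names(v), p = as.character(v),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(eye_id = character(), visit = integer(), map = character(),
               location_id = character(), p = character())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort()]. Row order is preserved; records are fully
#' validated, and a duplicate (eye id, visit) pair or an invalid code is an
#' error naming the offending row.
#'
#' @param path per-visit CSV as written by [write_cohort()].
#' @param pointwise_path optional pointwise long CSV.
#' @return list of `eye_visit` records in file order.
#' @export
read_cohort <- function(path, pointwise_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(eye_id = "character"))
  required <- c("eye_id", "visit", "group",
                paste("RNFL_SMALL", PERIPAPILLARY_SECTORS, sep = "_"),
                "vf24_md_p", "vf24_psd_p", "vf24_ght", "vf24_fp", "vf24_fl",
                "vf10_md_p", "vf10_psd_p", "vf10_fp", "vf10_fl")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort file missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pw_index <- NULL
  if (!is.null(pointwise_path)) {
    pw <- utils::read.csv(pointwise_path, stringsAsFactors = FALSE,
                          colClasses = c(eye_id = "character"))
    pw_index <- split(pw, paste(pw$eye_id, pw$visit))
  }
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    sectors <- list()
    for (m in MEASURES) {
      cols <- paste(m, sectors_for(m), sep = "_")
      present <- intersect(cols, names(df))
      vals <- unlist(row[present], use.names = FALSE)
      keep <- !is.na(vals) & nzchar(vals)
      if (!any(keep)) next
      codes <- tryCatch(
        parse_color_code(vals[keep],
                         context = paste0("row ", i, ", columns ", m)),
        error = function(e) stop("row ", i, ": ", conditionMessage(e),
                                 call. = FALSE))
      names(codes) <- sub(paste0("^", m, "_"), "", present[keep])
      sectors[[m]] <- sector_set(m, codes)
    }
    pwmaps <- NULL
    if (!is.null(pw_index)) {
      chunk <- pw_index[[paste(row$eye_id, row$visit)]]
      if (!is.null(chunk) && nrow(chunk)) {
        get_map <- function(name) {
          sub <- chunk[chunk$map == name, ]
          stats::setNames(sub$p, sub$location_id)
        }
        pwmaps <- pointwise_maps(get_map("vf24_pd"), get_map("vf10_pd"),
                                 get_map("rnfl_regions"),
                                 get_map("gclplus_regions"))
      }
    }
    records[[i]] <- tryCatch(
      eye_visit_record(
        eye_id = row$eye_id, visit = row$visit, group = row$group,
        sectors = sectors,
        vf24 = vf_metrics("VF24", row$vf24_md_p, row$vf24_psd_p,
                          ght = row$vf24_ght,
                          fp_rate = row$vf24_fp,
                          fixation_loss_rate = row$vf24_fl,
                          md_db = if ("vf24_md_db" %in% names(row))
                            row$vf24_md_db else NA_real_,
                          psd_db = if ("vf24_psd_db" %in% names(row))
                            row$vf24_psd_db else NA_real_),
        vf10 = vf_metrics("VF10", row$vf10_md_p, row$vf10_psd_p,
                          fp_rate = row$vf10_fp,
                          fixation_loss_rate = row$vf10_fl),
        pointwise = pwmaps),
      error = function(e) stop("row ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  validate_cohort(records)
  records
}

#' Build a structure-function correspondence map
#'
#' Maps every visual-field location id to the structural region(s) whose
#' probability-map p-category it is compared against, and declares the
#' layer (RNFL or GCL+) of every region.
#'
#' @param map24,map10 named lists, VF location id -> character vector of
#'   region ids (non-empty).
#' @param region_layer named character vector, region id -> "RNFL" or
#'   "GCLPLUS".
#' @return a list of class `sf_correspondence`.
#' @export
sf_correspondence <- function(map24, map10, region_layer) {
  check_map <- function(m, what) {
    if (!is.list(m) || is.null(names(m))) {
      stop(what, " must be a named list", call. = FALSE)
    }
    if (any(!vapply(m, length, integer(1)))) {
      stop(what, ": every location must map to at least one region",
           call. = FALSE)
    }
    m
  }
  map24 <- check_map(map24, "map24")
  map10 <- check_map(map10, "map10")
  referenced <- unique(c(unlist(map24), unlist(map10)))
  undeclared <- setdiff(referenced, names(region_layer))
  if (length(undeclared)) {
    stop("region(s) without a declared layer: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  if (!all(region_layer %in% c("RNFL", "GCLPLUS"))) {
    stop("region_layer values must be RNFL or GCLPLUS", call. = FALSE)
  }
  structure(list(map24 = map24, map10 = map10,
                 region_layer = region_layer),
            class = "sf_correspondence")
}

#' Write / read a correspondence map as a long CSV
#'
#' Columns: vf_test (VF24/VF10), location_id, region_id, layer.
#' @param corr an `sf_correspondence`.
#' @param path CSV path.
#' @return `path` (write) or an `sf_correspondence` (read).
#' @export
write_correspondence <- function(corr, path) {
  rows <- function(m, test) {
    do.call(rbind, lapply(names(m), function(loc) {
      data.frame(vf_test = test, location_id = loc, region_id = m[[loc]],
                 layer = unname(corr$region_layer[m[[loc]]]),
                 stringsAsFactors = FALSE)
    }))
  }
  df <- rbind(rows(corr$map24, "VF24"), rows(corr$map10, "VF10"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correspondence
#' @export
read_correspondence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vf_test", "location_id", "region_id", "layer")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("correspondence file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mk <- function(test) {
    sub <- df[df$vf_test == test, ]
    split(sub$region_id, sub$location_id)
  }
  layer <- df[!duplicated(df$region_id), ]
  sf_correspondence(mk("VF24"), mk("VF10"),
                    stats::setNames(layer$layer, layer$region_id))
}
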