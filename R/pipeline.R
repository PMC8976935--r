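# End-to-end pipeline: simulate (or read) a cohort, label it with the
# reference standard, evaluate the criteria catalog, and write a report
# bundle of plain CSV tables plus a run manifest.

#' Run the full evaluation pipeline
#'
#' Either generates a synthetic cohort from `config` or reads one from
#' `cohort_path` / `pointwise_path` / `correspondence_path`. Visits with
#' unreliable visual fields are excluded, eyes are labelled by the
#' topographic reference standard, and every catalog criterion is scored
#' at visit 1, with a two-baseline repeatability table and optional
#' bootstrap CIs for selected criteria.
#'
#' @param out_dir output directory; created if needed. Existing outputs
#'   are only overwritten with `force = TRUE`.
#' @param config a [generator_config()] (exclusive with `cohort_path`).
#' @param cohort_path,pointwise_path,correspondence_path input CSVs as
#'   written by [write_cohort()] / [write_correspondence()].
#' @param threshold `"borderline"` or `"strict"`.
#' @param criteria subset of catalog names to evaluate (default: all).
#' @param ci_criteria catalog names for which bootstrap CIs are computed
#'   (predictions pooled over both baseline visits, stratified
#'   resampling).
#' @param n_boot,boot_seed bootstrap settings.
#' @param force overwrite existing outputs.
#' @return invisibly, a list with the labels, the evaluation table, the
#'   repeatability table, the CI table and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         config = generator_config(),
                         cohort_path = NULL, pointwise_path = NULL,
                         correspondence_path = NULL,
                         threshold = "borderline",
                         criteria = NULL,
                         ci_criteria = c("SS_METRIC", "RNFL_SMALL_TI",
                                         "G_OR_AND_PSD_OR"),
                         n_boot = 1000L, boot_seed = 1L,
                         force = FALSE) {
  simulate <- is.null(cohort_path)
  if (!simulate && is.null(correspondence_path)) {
    stop("a correspondence map is required with an input cohort",
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- file.path(out_dir, c("cohort.csv", "pointwise.csv",
                                  "correspondence.csv", "labels.csv",
                                  "evaluation.csv", "repeatability.csv",
                                  "bootstrap_ci.csv", "manifest.yaml"))
  exists <- file.exists(outputs)
  if (any(exists) && !force) {
    stop("output file(s) already exist (use force = TRUE): ",
         paste(basename(outputs[exists]), collapse = ", "), call. = FALSE)
  }
  if (simulate) {
    sim <- generate_cohort(config)
    records <- sim$records
    corr <- sim$corr
    write_cohort(records, file.path(out_dir, "cohort.csv"),
                 file.path(out_dir, "pointwise.csv"))
    write_correspondence(corr, file.path(out_dir, "correspondence.csv"))
  } else {
    records <- read_cohort(cohort_path, pointwise_path)
    corr <- read_correspondence(correspondence_path)
  }
  filt <- apply_reliability_filter(records)
  records <- filt$kept
  if (length(filt$excluded)) {
    message(length(filt$excluded), " eye-visit(s) excluded for unreliable VFs")
  }
  labels <- label_cohort(records, corr)
  utils::write.csv(data.frame(eye_id = names(labels), label = labels,
                              row.names = NULL),
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  catalog <- criteria_catalog()
  if (!is.null(criteria)) {
    catalog <- catalog[catalog$name %in% criteria, , drop = FALSE]
  }
  visits <- vapply(records, `[[`, integer(1), "visit")
  v1 <- records[visits == 1L]
  v2 <- records[visits == 2L]
  eval_tab <- evaluate_criteria(v1, labels, catalog, threshold)
  utils::write.csv(eval_tab, file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE)
  rep_tab <- baseline_repeatability(v1, v2, labels, catalog, threshold)
  utils::write.csv(rep_tab, file.path(out_dir, "repeatability.csv"),
                   row.names = FALSE)
  ci_rows <- list()
  for (nm in intersect(ci_criteria, catalog$name)) {
    node <- get_criterion(nm, catalog)
    # pool both baselines as independent units, keyed by eye-visit
    p1 <- predict_criterion(node, v1, threshold)
    p2 <- predict_criterion(node, v2, threshold)
    pred <- c(p1, p2)
    keys <- c(paste0(names(p1), ":1"), paste0(names(p2), ":2"))
    names(pred) <- keys
    lab_pooled <- stats::setNames(labels[sub(":.*", "", keys)], keys)
    st <- bootstrap_ci(pred, lab_pooled, n_iter = n_boot, seed = boot_seed)
    ci_rows[[nm]] <- data.frame(
      name = nm,
      sensitivity = st$sensitivity, sens_lo = st$ci$sensitivity[1],
      sens_hi = st$ci$sensitivity[2],
      specificity = st$specificity, spec_lo = st$ci$specificity[1],
      spec_hi = st$ci$specificity[2],
      accuracy = st$accuracy, acc_lo = st$ci$accuracy[1],
      acc_hi = st$ci$accuracy[2],
      stringsAsFactors = FALSE)
  }
  ci_tab <- if (length(ci_rows)) do.call(rbind, ci_rows) else NULL
  if (!is.null(ci_tab)) {
    utils::write.csv(ci_tab, file.path(out_dir, "bootstrap_ci.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "glaucodx",
    version = as.character(utils::packageVersion("glaucodx")),
    mode = if (simulate) "simulate" else "read",
    seed = if (simulate) config$seed else NA,
    threshold = threshold,
    n_records = length(records),
    n_boot = n_boot, boot_seed = boot_seed,
    r_version = as.character(getRversion()))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(labels = labels, evaluation = eval_tab,
                 repeatability = rep_tab, bootstrap = ci_tab,
                 manifest = manifest))
}
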