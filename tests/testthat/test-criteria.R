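test_that("abnormality thresholds follow the borderline/strict tables", {
  expect_true(is_abnormal(color_code("yellow"), "borderline"))
  expect_false(is_abnormal(color_code("yellow"), "strict"))
  expect_true(is_abnormal(color_code("red"), "strict"))
  expect_false(is_abnormal(color_code("green"), "borderline"))
  expect_false(is_abnormal(color_code("green"), "strict"))
  expect_true(is_abnormal(p_category("p5"), "borderline"))
  expect_false(is_abnormal(p_category("p10"), "borderline"))
  expect_false(is_abnormal(p_category("p2"), "strict"))
  expect_true(is_abnormal(p_category("p1"), "strict"))
  expect_true(is_abnormal(ght_category("borderline"), "borderline"))
  expect_false(is_abnormal(ght_category("borderline"), "strict"))
  expect_true(is_abnormal(ght_category("onl"), "strict"))
  # "other" outcomes do not count as abnormal unless opted in
  expect_false(is_abnormal(ght_category("other"), "borderline"))
  expect_true(is_abnormal(ght_category("other"), "borderline",
                          ght_other_abnormal = TRUE))
  expect_true(is_abnormal(gss2_stage(-1.5, 1.4), "borderline"))  # borderline band
  expect_false(is_abnormal(gss2_stage(-1.5, 1.4), "strict"))
  expect_true(is_abnormal(gss2_stage(-10, 8), "strict"))
})

set_sector <- function(r, measure, sector, code) {
  r$sectors[[measure]][[sector]] <- code
  r
}

test_that("the S-S metric requires hemifield-concordant cpRNFL and GCL defects", {
  node <- build_ss_metric()
  r <- make_normal_record()
  # inferior agreement: TI cpRNFL + inferior GCL
  r1 <- set_sector(set_sector(r, "RNFL_SMALL", "TI", "red"), "GCL", "I",
                   "yellow")
  expect_true(eval_criterion(node, r1))
  # cpRNFL alone is not enough
  r2 <- set_sector(r, "RNFL_SMALL", "TI", "red")
  expect_false(eval_criterion(node, r2))
  # superior agreement: TS cpRNFL + superior GCL
  r3 <- set_sector(set_sector(r, "RNFL_SMALL", "TS", "yellow"), "GCL", "S",
                   "red")
  expect_true(eval_criterion(node, r3))
  # cross-hemifield abnormality does not agree
  r4 <- set_sector(set_sector(r, "RNFL_SMALL", "TI", "red"), "GCL", "S",
                   "red")
  expect_false(eval_criterion(node, r4))
})

test_that("the paired-sector criterion needs the same sector in both measures", {
  node <- build_yang()
  r <- make_normal_record()
  r1 <- set_sector(set_sector(r, "RNFL_SMALL", "NS", "yellow"),
                   "MRW", "NS", "yellow")
  expect_true(eval_criterion(node, r1))
  r2 <- set_sector(set_sector(r, "RNFL_SMALL", "TI", "red"),
                   "MRW", "TS", "red")
  expect_false(eval_criterion(node, r2))
  # the global value is not one of the six paired sectors
  r3 <- set_sector(set_sector(r, "RNFL_SMALL", "G", "red"), "MRW", "G",
                   "red")
  expect_false(eval_criterion(node, r3))
})

test_that("the quadrant-plus-GHT criterion pairs quadrant sectors with the GHT", {
  node <- build_iyer_q_ght()
  r <- make_normal_record()
  r1 <- set_sector(r, "RNFL_SMALL", "NI", "yellow")
  r1$vf24$ght <- ght_category("borderline")
  expect_true(eval_criterion(node, r1))
  # the temporal sector is not a quadrant sector
  r2 <- set_sector(r, "RNFL_SMALL", "T", "red")
  r2$vf24$ght <- ght_category("onl")
  expect_false(eval_criterion(node, r2))
  # abnormal OCT alone never fires the conjunction
  r3 <- set_sector(r, "RNFL_SMALL", "TS", "red")
  expect_false(eval_criterion(node, r3))
})

test_that("the catalog enumerates the full metric grid and is vacuously false", {
  cat <- criteria_catalog()
  expect_gte(sum(cat$category == "OCT_SINGLE"), 42)
  expect_gte(sum(cat$category == "VF_SINGLE"), 5)
  expect_equal(sum(cat$category == "FF_COMBO"), 10)
  expect_identical(deparse_criterion(get_criterion("SS_METRIC", cat)),
                   deparse_criterion(build_ss_metric()))
  normal <- make_normal_record()
  for (i in seq_len(nrow(cat))) {
    expect_false(eval_criterion(cat$criterion[[i]], normal),
                 info = cat$name[i])
    expect_false(eval_criterion(cat$criterion[[i]], normal, "strict"),
                 info = cat$name[i])
  }
})

test_that("a leaf referencing a missing metric errors instead of assuming normal", {
  r <- make_normal_record()
  r$sectors$GCL <- NULL
  expect_error(eval_criterion(build_ss_metric(), r), "GCL")
  expect_error(crit_oct("RNFL_SMALL", "S"), "no sector")
  expect_error(crit_any_paired("RNFL_SMALL", "MRW", c("TI", "S")),
               "not shared")
})

test_that("every catalog criterion matches the independent truth-table oracle", {
  cat <- criteria_catalog()
  for (i in seq_len(nrow(cat))) {
    n <- check_against_oracle(cat$criterion[[i]], max_exhaustive = 6L,
                              n_sample = 300L, seed = 1000L + i)
    expect_gte(n, 3)
  }
})

test_that("evaluation is invariant under child permutation", {
  sim <- small_cohort(seed = 3)
  node <- build_ss_metric()
  flipped <- crit_or(node$children[[2]], node$children[[1]])
  for (r in sim$records[1:12]) {
    expect_identical(eval_criterion(node, r), eval_criterion(flipped, r))
  }
  ff <- crit_and(crit_vf("PSD24"), crit_vf("PSD10"))
  ff_rev <- crit_and(crit_vf("PSD10"), crit_vf("PSD24"))
  for (r in sim$records[1:12]) {
    expect_identical(eval_criterion(ff, r), eval_criterion(ff_rev, r))
  }
})

test_that("criteria can be defined in the YAML expression form", {
  spec <- list(or = list(
    list(and = list(
      list(oct = list(measure = "RNFL_SMALL", sector = "TI")),
      list(or = list(list(oct = list(measure = "GCL", sector = "TI")),
                     list(oct = list(measure = "GCL", sector = "I")))))),
    list(and = list(
      list(oct = list(measure = "RNFL_SMALL", sector = "TS")),
      list(or = list(list(oct = list(measure = "GCL", sector = "TS")),
                     list(oct = list(measure = "GCL", sector = "S"))))))))
  node <- criterion_from_list(spec)
  expect_identical(deparse_criterion(node),
                   deparse_criterion(build_ss_metric()))
  d <- withr::local_tempdir()
  f <- file.path(d, "crit.yaml")
  yaml::write_yaml(list(catalog = "YANG_PAIRED"), f)
  expect_identical(deparse_criterion(read_criterion_yaml(f)),
                   deparse_criterion(build_yang()))
})
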