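test_that("confusion counts match a hand-counted loop on random predictions", {
  labels <- c(stats::setNames(rep("HC", 56), sprintf("H%02d", 1:56)),
              stats::setNames(rep("LG", 40), sprintf("L%02d", 1:40)),
              stats::setNames(rep("NEITHER", 21), sprintf("N%02d", 1:21)))
  perfect <- stats::setNames(names(labels) %in% sprintf("L%02d", 1:40),
                             names(labels))
  cc <- confusion(perfect, labels)
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
               c(tp = 40, fn = 0, fp = 0, tn = 56))
  none <- stats::setNames(rep(FALSE, length(labels)), names(labels))
  cc0 <- confusion(none, labels)
  expect_equal(unlist(cc0[c("tp", "fn", "fp", "tn")]),
               c(tp = 0, fn = 40, fp = 0, tn = 56))
  set.seed(7)
  for (rep in 1:5) {
    pred <- stats::setNames(stats::runif(length(labels)) < 0.4,
                            names(labels))
    cc <- confusion(pred, labels)
    tp <- fn <- fp <- tn <- 0
    for (id in names(labels)) {
      if (labels[id] == "LG") {
        if (pred[id]) tp <- tp + 1 else fn <- fn + 1
      } else if (labels[id] == "HC") {
        if (pred[id]) fp <- fp + 1 else tn <- tn + 1
      }
    }
    expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
                 c(tp = tp, fn = fn, fp = fp, tn = tn))
  }
  expect_error(confusion(perfect[-1], labels), "missing prediction")
})

test_that("percentages use round half up and tolerate empty denominators", {
  expect_equal(round_half_up(c(82.5, 72.5, 47.5, 37.5, 96.43, 58.9)),
               c(83, 73, 48, 38, 96, 59))
  st <- performance(list(tp = 32, fn = 8, fp = 1, tn = 55))
  expect_equal(st$sensitivity, 80)
  expect_equal(unname(st$reported["specificity"]), 98)
  expect_equal(unname(st$reported["accuracy"]), 91)
  st <- performance(list(tp = 28, fn = 12, fp = 5, tn = 51))
  expect_equal(unname(st$reported["sensitivity"]), 70)
  expect_equal(unname(st$reported["specificity"]), 91)
  st <- performance(list(tp = 40, fn = 0, fp = 0, tn = 56))
  expect_equal(c(st$sensitivity, st$specificity, st$accuracy),
               c(100, 100, 100))
  undef <- performance(list(tp = 0, fn = 0, fp = 2, tn = 54))
  expect_true(is.na(undef$sensitivity))
  expect_false(is.na(undef$specificity))
})

test_that("bootstrap CIs are deterministic, degenerate for a perfect predictor", {
  labels <- c(stats::setNames(rep("HC", 30), sprintf("H%02d", 1:30)),
              stats::setNames(rep("LG", 20), sprintf("L%02d", 1:20)))
  perfect <- stats::setNames(grepl("^L", names(labels)), names(labels))
  st <- bootstrap_ci(perfect, labels, n_iter = 200, seed = 4)
  for (s in names(st$ci)) expect_equal(st$ci[[s]], c(100, 100))
  set.seed(31)
  noisy <- stats::setNames(ifelse(grepl("^L", names(labels)),
                                  stats::runif(50) < 0.8,
                                  stats::runif(50) < 0.1), names(labels))
  a <- bootstrap_ci(noisy, labels, n_iter = 300, seed = 9)
  b <- bootstrap_ci(noisy, labels, n_iter = 300, seed = 9)
  expect_identical(a$ci, b$ci)
  expect_lte(a$ci$sensitivity[1], a$sensitivity)
  expect_gte(a$ci$sensitivity[2], a$sensitivity)
  # unstratified resampling still brackets the point estimate
  u <- bootstrap_ci(noisy, labels, n_iter = 300, seed = 9,
                    stratified = FALSE)
  expect_lte(u$ci$specificity[1], u$specificity)
  expect_gte(u$ci$specificity[2], u$specificity)
  expect_error(bootstrap_ci(perfect, stats::setNames(rep("LG", 50),
                                                     names(labels))),
               "each class")
})

test_that("two-baseline repeatability is zero for identical visits", {
  sim <- small_cohort(seed = 13)
  labels <- label_cohort(sim$records, sim$corr)
  visits <- vapply(sim$records, `[[`, integer(1), "visit")
  v1 <- sim$records[visits == 1L]
  cat <- criteria_catalog()
  sub <- cat[cat$name %in% c("SS_METRIC", "RNFL_SMALL_TI", "VF_GHT"), ]
  tab <- baseline_repeatability(v1, v1, labels, sub)
  expect_true(all(tab$sens_diff == 0))
  expect_true(all(tab$spec_diff == 0))
  expect_true(all(tab$acc_diff == 0))
  v2 <- sim$records[visits == 2L]
  expect_error(baseline_repeatability(v1, v2[-1], labels, sub),
               "eye sets differ")
  # with imperfect test-retest agreement, differences stay inside a
  # generous binomial-noise envelope (flip rate bounded by 1 - agreement)
  tab2 <- baseline_repeatability(v1, v2, labels, sub)
  expect_true(all(tab2$sens_diff <= 100 * 6 *
                    sqrt(0.25 / sum(labels == "LG"))))
})
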