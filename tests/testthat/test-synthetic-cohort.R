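test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_hc = 6, n_patient = 8, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$asaf_counts, b$asaf_counts)
  c <- generate_cohort(generator_config(n_hc = 6, n_patient = 8,
                                        seed = 124))
  expect_false(identical(a$records, c$records))
})

test_that("a zero-rate, zero-severity configuration is a null model", {
  cfg <- generator_config(
    n_hc = 5, n_patient = 6, target_lg_fraction = 0,
    suspect_severity_shape = c(1e-9, 10),
    oct_fp_rate = 0, map_noise_rate = 0,
    vf_fp_rates = c(MD24 = 0, PSD24 = 0, GHT = 0, MD10 = 0, PSD10 = 0),
    suspect_high_visit_prob = 0, suspect_asaf_max = 0, seed = 2)
  sim <- generate_cohort(cfg)
  for (r in sim$records) {
    for (m in names(r$sectors)) {
      expect_true(all(r$sectors[[m]] == color_code("green")), info = m)
    }
    expect_equal(as.character(r$vf24$md_p), "ns")
    expect_equal(as.character(r$vf24$psd_p), "ns")
    expect_equal(as.character(r$vf10$md_p), "ns")
    expect_equal(as.character(r$vf10$psd_p), "ns")
    expect_equal(as.character(r$vf24$ght), "wnl")
    expect_true(all(as.character(r$pointwise$vf24_pd) == "ns"))
    expect_true(all(as.character(r$pointwise$vf10_pd) == "ns"))
  }
  expect_false(any(label_cohort(sim$records, sim$corr) == "LG"))
})

test_that("unsatisfiable aS-aF configurations are rejected", {
  expect_error(generator_config(asaf_range = c(1L, 64L)),
               "below min_locations")
  expect_error(generator_config(asaf_range = c(3L, 200L)),
               "exceeds")
  expect_error(generator_config(rho = 1.2), "\\[0, 1\\]")
})

test_that("emitted pointwise maps reproduce the designed aS-aF counts exactly", {
  sim <- generate_cohort(generator_config(n_hc = 2, n_patient = 20,
                                          seed = 17))
  ids <- vapply(sim$records, `[[`, character(1), "eye_id")
  visits <- vapply(sim$records, `[[`, integer(1), "visit")
  for (eye in rownames(sim$asaf_counts)) {
    for (v in 1:2) {
      r <- sim$records[[which(ids == eye & visits == v)]]
      expect_equal(count_asaf(r$pointwise, sim$corr)$n_asaf,
                   unname(sim$asaf_counts[eye, v]),
                   info = paste(eye, "visit", v))
    }
  }
})

test_that("healthy flag rates of single metrics match the configured rate", {
  cfg <- generator_config(n_hc = 250, n_patient = 1, oct_fp_rate = 0.05,
                          seed = 29)
  sim <- generate_cohort(cfg)
  hc1 <- sim$records[vapply(sim$records, function(r)
    r$group == "HC" && r$visit == 1L, logical(1))]
  for (nm in c("RNFL_SMALL_TI", "MRW_G", "GCL_S")) {
    node <- get_criterion(nm)
    rate <- mean(predict_criterion(node, hc1))
    ci <- stats::binom.test(round(rate * 250), 250)$conf.int
    expect_true(cfg$oct_fp_rate >= ci[1] - 1e-9 &&
                  cfg$oct_fp_rate <= ci[2] + 1e-9, info = nm)
  }
})

test_that("printed-count fixtures reproduce their confusion counts exactly", {
  cases <- list(
    list(counts = list(tp = 32, fn = 8, fp = 1, tn = 55),
         node = build_ss_metric()),
    list(counts = list(tp = 29, fn = 11, fp = 4, tn = 52),
         node = build_yang()),
    list(counts = list(tp = 0, fn = 40, fp = 0, tn = 56),
         node = get_criterion("GSS2")),
    list(counts = list(tp = 19, fn = 21, fp = 0, tn = 56),
         node = build_iyer_q_ght()))
  for (cs in cases) {
    fx <- generate_fixture_from_counts(cs$counts, cs$node)
    pred <- predict_criterion(cs$node, fx$records)
    cc <- confusion(pred, fx$labels)
    expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
                 unlist(cs$counts[c("tp", "fn", "fp", "tn")]),
                 ignore_attr = TRUE)
  }
})

test_that("the truncated count model matches its target moments", {
  m <- fit_trunc_nbinom(19, 16, 3, 64)
  expect_equal(m$mean, 19, tolerance = 1e-4)
  expect_equal(m$sd, 16, tolerance = 1e-4)
  expect_equal(sum(m$prob), 1, tolerance = 1e-12)
  expect_true(all(m$k >= 3 & m$k <= 64))
})
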