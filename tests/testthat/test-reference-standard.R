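# helpers to build pointwise maps on the package's synthetic geometry
blank_maps <- function() {
  corr <- default_correspondence()
  regions <- names(corr$region_layer)
  list(corr = corr,
       vf24 = stats::setNames(rep("ns", 52), names(corr$map24)),
       vf10 = stats::setNames(rep("ns", 68), names(corr$map10)),
       regions = stats::setNames(rep("ns", length(regions)), regions))
}

as_pointwise <- function(m) {
  rnfl <- m$regions[grepl("^rnfl", names(m$regions))]
  gcl <- m$regions[grepl("^gcl", names(m$regions))]
  pointwise_maps(m$vf24, m$vf10, rnfl, gcl)
}

test_that("aS-aF counting requires joint functional and structural abnormality", {
  m <- blank_maps()
  expect_equal(count_asaf(as_pointwise(m), m$corr)$n_asaf, 0)

  # three VF locations at p5, each with one corresponding region at p10
  m2 <- blank_maps()
  locs <- names(m2$vf24)[1:3]
  m2$vf24[locs] <- "p5"
  for (loc in locs) m2$regions[m2$corr$map24[[loc]][1]] <- "p10"
  res <- count_asaf(as_pointwise(m2), m2$corr)
  expect_equal(res$n_asaf, 3)
  expect_equal(sum(res$per_location), 3)
  expect_true(all(res$per_location[locs]))

  # deep functional loss over normal structure is not counted
  m3 <- blank_maps()
  m3$vf24[names(m3$vf24)[5]] <- "p1"
  expect_equal(count_asaf(as_pointwise(m3), m3$corr)$n_asaf, 0)

  # structural abnormality at the 10% level suffices when function is at 5%
  m4 <- blank_maps()
  loc <- names(m4$vf10)[10]
  m4$vf10[loc] <- "p5"
  m4$regions[m4$corr$map10[[loc]]] <- "p10"
  expect_equal(count_asaf(as_pointwise(m4), m4$corr)$n_asaf, 1)
  # ... but a p10 VF value is below the 5% functional cutoff
  m4$vf10[loc] <- "p10"
  expect_equal(count_asaf(as_pointwise(m4), m4$corr)$n_asaf, 0)
})

test_that("a VF location without a correspondence entry is an error", {
  m <- blank_maps()
  corr_broken <- m$corr
  corr_broken$map24[["v24_01"]] <- NULL
  expect_error(count_asaf(as_pointwise(m), corr_broken),
               "without correspondence")
})

test_that("counting is monotone in both significance cutoffs", {
  set.seed(21)
  for (rep in 1:5) {
    m <- blank_maps()
    m$vf24[] <- sample(P_LEVELS, 52, replace = TRUE,
                       prob = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1))
    m$vf10[] <- sample(P_LEVELS, 68, replace = TRUE,
                       prob = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1))
    m$regions[] <- sample(P_LEVELS, length(m$regions), replace = TRUE,
                          prob = c(0.6, 0.2, 0.1, 0.05, 0.03, 0.02))
    pw <- as_pointwise(m)
    n_default <- count_asaf(pw, m$corr)$n_asaf
    # relaxing the functional cutoff toward less significant never loses hits
    expect_gte(count_asaf(pw, m$corr, vf_alpha = "p10")$n_asaf, n_default)
    # tightening the structural cutoff never gains hits
    expect_lte(count_asaf(pw, m$corr, struct_alpha = "p5")$n_asaf, n_default)
    # permutation of location order leaves the count unchanged
    perm <- m
    idx <- sample(52)
    perm$vf24 <- perm$vf24[idx]
    expect_equal(count_asaf(as_pointwise(perm), m$corr)$n_asaf, n_default)
    # all-NS structure wipes out every agreement
    wiped <- m
    wiped$regions[] <- "ns"
    expect_equal(count_asaf(as_pointwise(wiped), m$corr)$n_asaf, 0)
  }
})

test_that("likely-glaucoma classification demands replication at both baselines", {
  mk <- function(n) structure(list(eye_id = "E", visit = 1L, n_asaf = n,
                                   per_location = logical(0)),
                              class = "asaf_result")
  expect_true(classify_lg(mk(3), mk(3)))
  expect_false(classify_lg(mk(10), mk(2)))
  expect_true(classify_lg(mk(64), mk(64)))
  expect_false(classify_lg(mk(2), mk(2)))
  # the original two-location rule is laxer: LG(min=3) is a subset of LG(min=2)
  for (n1 in 0:5) for (n2 in 0:5) {
    if (classify_lg(mk(n1), mk(n2), 3)) {
      expect_true(classify_lg(mk(n1), mk(n2), 2))
    }
  }
  bad <- mk(5); bad$eye_id <- "OTHER"
  expect_error(classify_lg(mk(5), bad), "different eyes")
})

test_that("cohort labelling recovers designed labels and flags degenerate inputs", {
  sim <- small_cohort(seed = 5)
  labels <- label_cohort(sim$records, sim$corr)
  expect_identical(unname(labels[names(sim$truth)]),
                   unname(ifelse(sim$truth == "SUSPECT", "NEITHER",
                                 sim$truth)))
  # raising min_locations never grows the LG set
  lab_strict <- label_cohort(sim$records, sim$corr, min_locations = 10L)
  expect_true(all(names(lab_strict)[lab_strict == "LG"] %in%
                    names(labels)[labels == "LG"]))

  # HC-only cohort has no LG eyes
  hc_only <- sim$records[vapply(sim$records, `[[`, character(1),
                                "group") == "HC"]
  expect_false(any(label_cohort(hc_only, sim$corr) == "LG"))

  # a patient eye with all-NS maps at both visits is NEITHER
  m <- blank_maps()
  quiet <- list(
    make_normal_record("P1", 1, "PATIENT", pointwise = as_pointwise(m)),
    make_normal_record("P1", 2, "PATIENT", pointwise = as_pointwise(m)))
  expect_identical(unname(label_cohort(quiet, m$corr)), "NEITHER")

  # a patient eye missing a visit or its maps is an error
  expect_error(label_cohort(quiet[1], m$corr), "missing a baseline visit")
  nomap <- list(make_normal_record("P2", 1, "PATIENT"),
                make_normal_record("P2", 2, "PATIENT"))
  expect_error(label_cohort(nomap, m$corr), "no pointwise maps")
})
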