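# Synthetic cohort generator.
#
# Emulates the data structure the pipeline consumes: two baseline visits
# per eye, hemifield-localised defects whose sector color codes are
# correlated across OCT measures through a shared latent severity, and
# pointwise VF / structural probability maps constructed so that the
# aS-aF count of each designed likely-glaucoma eye-visit equals a draw
# from a truncated negative-binomial count model. Only categorical
# report-level outputs are generated -- no thicknesses or image physics.

# Fixed synthetic geometry: 52 24-2 locations (1-26 in the superior VF
# hemifield), 68 10-2 locations (1-34 superior), and six RNFL plus six
# GCL+ probability-map regions per retinal hemifield. A superior VF
# location projects to inferior retinal regions and vice versa.
VF24_IDS <- sprintf("v24_%02d", 1:52)
VF10_IDS <- sprintf("v10_%02d", 1:68)

synthetic_regions <- function(layer, hemi) {
  paste(tolower(layer), hemi, 1:6, sep = "_")
}

#' Default structure-function correspondence map (synthetic geometry)
#'
#' A Garway-Heath-style sectorization reduced to hemifields: each VF
#' location maps to one RNFL and one GCL+ region of the opposite
#' (retinal) hemifield. This is the map the generator emits alongside its
#' cohorts; it is a synthetic stand-in for an instrument-specific
#' widefield-report mapping, not an anatomical atlas.
#'
#' @return an [sf_correspondence()].
#' @export
default_correspondence <- function() {
  mk <- function(ids, n_sup) {
    m <- vector("list", length(ids))
    names(m) <- ids
    for (j in seq_along(ids)) {
      hemi <- if (j <= n_sup) "inf" else "sup"   # superior VF -> inferior retina
      k <- (j - 1L) %% 6L + 1L
      m[[j]] <- c(paste("rnfl", hemi, k, sep = "_"),
                  paste("gcl", hemi, k, sep = "_"))
    }
    m
  }
  regions <- c(synthetic_regions("rnfl", "inf"), synthetic_regions("rnfl", "sup"),
               synthetic_regions("gcl", "inf"), synthetic_regions("gcl", "sup"))
  layer <- stats::setNames(ifelse(grepl("^rnfl", regions), "RNFL", "GCLPLUS"),
                           regions)
  sf_correspondence(mk(VF24_IDS, 26L), mk(VF10_IDS, 34L), layer)
}

# VF locations whose corresponding structural regions lie in a given
# retinal hemifield.
vf_locations_for_hemifield <- function(hemi) {
  if (hemi == "inferior") c(VF24_IDS[1:26], VF10_IDS[1:34])
  else c(VF24_IDS[27:52], VF10_IDS[35:68])
}

#' Fit a truncated negative-binomial count model by moment matching
#'
#' Finds negative-binomial parameters such that the distribution
#' truncated to `[lo, hi]` has the requested mean and standard deviation
#' (so the configured moments are the moments of what is actually
#' sampled).
#'
#' @param mean,sd target moments of the truncated distribution.
#' @param lo,hi truncation bounds (inclusive).
#' @return list with `k` (support) and `prob` (probabilities), plus the
#'   achieved `mean` and `sd`.
#' @export
fit_trunc_nbinom <- function(mean = 19, sd = 16, lo = 3L, hi = 64L) {
  k <- lo:hi
  moments <- function(par) {
    mu <- exp(par[1]); size <- exp(par[2])
    w <- stats::dnbinom(k, mu = mu, size = size)
    p <- w / sum(w)
    m1 <- sum(k * p)
    v <- sum(k^2 * p) - m1^2
    list(p = p, mean = m1, sd = sqrt(v))
  }
  obj <- function(par) {
    m <- moments(par)
    (m$mean - mean)^2 + (m$sd - sd)^2
  }
  fit <- stats::optim(c(log(mean), log(1.5)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  m <- moments(fit$par)
  list(k = k, prob = m$p, mean = m$mean, sd = m$sd)
}

#' Generator configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for: 56
#' healthy-control eyes and 61 patient eyes of which about 40/61 are
#' designed likely glaucoma; per-eye aS-aF counts with mean 19, SD 16 on
#' support 3-64; per-metric healthy false-positive rates of a few
#' percent.
#'
#' @param n_hc,n_patient cohort sizes.
#' @param target_lg_fraction fraction of patient eyes designed to satisfy
#'   the likely-glaucoma reference standard.
#' @param hemifield_probs probabilities of an inferior, superior or
#'   bilateral defect.
#' @param severity_shape,suspect_severity_shape Beta shape parameters of
#'   the per-eye latent severity for designed-LG and designed-suspect
#'   eyes.
#' @param rho cross-measure correlation of defect detection within the
#'   defect hemifield (Gaussian copula weight on a shared latent).
#' @param kappa structure-function coupling: probability that an abnormal
#'   sector / selected VF location forces a corresponding structural
#'   region abnormal.
#' @param oct_fp_rate healthy per-sector abnormality rate.
#' @param vf_fp_rates healthy abnormality rates of the five VF indices.
#' @param map_noise_rate rate of sub-significant noise on pointwise maps
#'   (healthy maps, and unselected locations of patient maps).
#' @param asaf_mean,asaf_sd,asaf_range truncated count model for aS-aF
#'   locations of designed-LG eye-visits.
#' @param min_locations reference-standard minimum; the aS-aF support
#'   must not fall below it, otherwise designed-LG eyes could not be
#'   recovered.
#' @param test_retest_agreement weight of the eye-level latent shared
#'   between the two baseline visits (1 = identical latents).
#' @param suspect_high_visit_prob probability that a designed-suspect eye
#'   shows a supra-threshold count at one (never both) visit.
#' @param suspect_asaf_max largest sub-threshold aS-aF count drawn for
#'   designed-suspect eye-visits (capped at `min_locations - 1`).
#' @param unreliable_rate probability that a visit draws VF reliability
#'   indices beyond the exclusion limits (default 0: all visits
#'   reliable).
#' @param seed integer RNG seed; a fixed seed gives an identical cohort.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_hc = 56L, n_patient = 61L,
                             target_lg_fraction = 40 / 61,
                             hemifield_probs = c(inferior = 0.5,
                                                 superior = 0.3,
                                                 both = 0.2),
                             severity_shape = c(5, 2),
                             suspect_severity_shape = c(1.5, 4),
                             rho = 0.7, kappa = 0.9,
                             oct_fp_rate = 0.04,
                             vf_fp_rates = c(MD24 = 0.07, PSD24 = 0.09,
                                             GHT = 0.11, MD10 = 0.07,
                                             PSD10 = 0.09),
                             map_noise_rate = 0.04,
                             asaf_mean = 19, asaf_sd = 16,
                             asaf_range = c(3L, 64L),
                             min_locations = 3L,
                             test_retest_agreement = 0.9,
                             suspect_high_visit_prob = 0.2,
                             suspect_asaf_max = 2L,
                             unreliable_rate = 0,
                             seed = 1L) {
  probs <- c(hemifield_probs, rho, kappa, oct_fp_rate, vf_fp_rates,
             map_noise_rate, test_retest_agreement,
             suspect_high_visit_prob, unreliable_rate,
             target_lg_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_hc < 1 || n_patient < 1) stop("counts must be positive",
                                      call. = FALSE)
  if (asaf_range[1] < min_locations) {
    stop("unsatisfiable config: aS-aF support starts below min_locations",
         call. = FALSE)
  }
  n_locations <- length(VF24_IDS) + length(VF10_IDS)
  if (asaf_range[2] > n_locations) {
    stop("unsatisfiable config: aS-aF support exceeds the ", n_locations,
         " VF locations", call. = FALSE)
  }
  structure(list(
    n_hc = as.integer(n_hc), n_patient = as.integer(n_patient),
    target_lg_fraction = target_lg_fraction,
    hemifield_probs = hemifield_probs / sum(hemifield_probs),
    severity_shape = severity_shape,
    suspect_severity_shape = suspect_severity_shape,
    rho = rho, kappa = kappa,
    oct_fp_rate = oct_fp_rate, vf_fp_rates = vf_fp_rates,
    map_noise_rate = map_noise_rate,
    asaf_mean = asaf_mean, asaf_sd = asaf_sd,
    asaf_range = as.integer(asaf_range),
    min_locations = as.integer(min_locations),
    test_retest_agreement = test_retest_agreement,
    suspect_high_visit_prob = suspect_high_visit_prob,
    suspect_asaf_max = min(as.integer(suspect_asaf_max),
                           min_locations - 1L),
    unreliable_rate = unreliable_rate,
    seed = as.integer(seed)
  ), class = "generator_config")
}

draw_code <- function(severity) {
  if (stats::runif(1) < 0.3 + 0.5 * severity) "red" else "yellow"
}

hemifield_sectors <- function(measure, hemi) {
  peri <- measure %in% c("MRW", "RNFL_SMALL", "RNFL_LARGE")
  if (hemi == "inferior") {
    if (peri) list(main = "TI", other = "NI") else
      list(main = "TI", other = c("I", "NI"))
  } else {
    if (peri) list(main = "TS", other = "NS") else
      list(main = "TS", other = c("S", "NS"))
  }
}

#' Generate a synthetic two-visit cohort
#'
#' See [generator_config()] for the knobs. Designed-LG eyes are built so
#' that [count_asaf()] on their emitted pointwise maps reproduces the
#' drawn count exactly at both visits (all counts at or above the
#' reference-standard minimum), so [label_cohort()] recovers the designed
#' LG set by construction; designed-suspect eyes stay sub-threshold on at
#' least one visit.
#'
#' @param config a [generator_config()].
#' @return list with `records` (eye-visit records, both visits),
#'   `truth` (named vector eye id -> `"HC"`, `"LG"`, `"SUSPECT"`),
#'   `asaf_counts` (designed counts per patient eye-visit),
#'   `corr` (the matching [sf_correspondence()]) and `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  corr <- default_correspondence()
  asaf_model <- fit_trunc_nbinom(config$asaf_mean, config$asaf_sd,
                                 config$asaf_range[1], config$asaf_range[2])
  n_lg <- round(config$n_patient * config$target_lg_fraction)
  hc_ids <- sprintf("HC%03d", seq_len(config$n_hc))
  pt_ids <- sprintf("PT%03d", seq_len(config$n_patient))
  lg_set <- sort(sample(pt_ids, n_lg))
  truth <- c(stats::setNames(rep("HC", config$n_hc), hc_ids),
             stats::setNames(ifelse(pt_ids %in% lg_set, "LG", "SUSPECT"),
                             pt_ids))
  records <- list()
  asaf_counts <- list()
  for (eye in names(truth)) {
    role <- truth[[eye]]
    eye_out <- generate_eye(eye, role, config, asaf_model)
    records <- c(records, eye_out$records)
    if (role != "HC") asaf_counts[[eye]] <- eye_out$counts
  }
  list(records = records, truth = truth,
       asaf_counts = do.call(rbind, asaf_counts),
       corr = corr, config = config)
}

generate_eye <- function(eye, role, config, asaf_model) {
  a <- config$test_retest_agreement
  if (role == "HC") {
    severity <- 0
    hemis <- character(0)
  } else {
    shape <- if (role == "LG") config$severity_shape else
      config$suspect_severity_shape
    severity <- stats::rbeta(1, shape[1], shape[2])
    hemi_choice <- sample(names(config$hemifield_probs), 1,
                          prob = config$hemifield_probs)
    hemis <- if (hemi_choice == "both") c("inferior", "superior") else
      hemi_choice
  }
  # eye-level latents shared between visits
  z_h_eye <- stats::setNames(stats::rnorm(2), c("inferior", "superior"))
  z_m_eye <- matrix(stats::rnorm(2 * length(MEASURES)), nrow = 2,
                    dimnames = list(c("inferior", "superior"), MEASURES))
  # designed aS-aF counts
  counts <- if (role == "LG") {
    sample(asaf_model$k, 2, replace = TRUE, prob = asaf_model$prob)
  } else if (role == "SUSPECT") {
    cap <- config$suspect_asaf_max
    cts <- if (cap > 0L) sample(0:cap, 2, replace = TRUE) else c(0L, 0L)
    if (stats::runif(1) < config$suspect_high_visit_prob) {
      cts[sample(2, 1)] <- config$min_locations +
        sample(0:5, 1)  # supra-threshold once: replication still fails
    }
    cts
  } else c(0L, 0L)
  recs <- vector("list", 2L)
  for (v in 1:2) {
    z_h <- sqrt(a) * z_h_eye + sqrt(1 - a) * stats::rnorm(2)
    z_m <- sqrt(a) * z_m_eye +
      sqrt(1 - a) * matrix(stats::rnorm(length(z_m_eye)), nrow = 2)
    sectors <- generate_sectors(role, severity, hemis, z_h, z_m, config)
    pw <- generate_pointwise(role, severity, hemis, counts[v], sectors,
                             config)
    vfb <- generate_vf_blocks(role, severity, config)
    recs[[v]] <- eye_visit_record(
      eye_id = eye, visit = v,
      group = if (role == "HC") "HC" else "PATIENT",
      sectors = sectors, vf24 = vfb$vf24, vf10 = vfb$vf10,
      pointwise = pw)
  }
  list(records = recs, counts = counts)
}

generate_sectors <- function(role, severity, hemis, z_h, z_m, config) {
  sectors <- lapply(stats::setNames(MEASURES, MEASURES), function(m) {
    labs <- sectors_for(m)
    codes <- rep("green", length(labs))
    noisy <- stats::runif(length(labs)) < config$oct_fp_rate
    codes[noisy] <- ifelse(stats::runif(sum(noisy)) < 0.7, "yellow", "red")
    stats::setNames(codes, labs)
  })
  for (h in hemis) {
    for (m in MEASURES) {
      z <- sqrt(config$rho) * z_h[[h]] +
        sqrt(1 - config$rho) * z_m[h, m]
      detected <- stats::pnorm(z) < severity
      if (!detected) next
      hs <- hemifield_sectors(m, h)
      sectors[[m]][[hs$main]] <- draw_code(severity)
      for (s in hs$other) {
        if (stats::runif(1) < 0.5 * severity + 0.2) {
          sectors[[m]][[s]] <- draw_code(severity)
        }
      }
      if (stats::runif(1) < 0.6 * severity) {
        sectors[[m]][["G"]] <- draw_code(severity)
      }
    }
  }
  lapply(stats::setNames(names(sectors), names(sectors)),
         function(m) sector_set(m, sectors[[m]]))
}

generate_pointwise <- function(role, severity, hemis, n_target, sectors,
                               config) {
  all_regions <- c(synthetic_regions("rnfl", "inf"),
                   synthetic_regions("rnfl", "sup"),
                   synthetic_regions("gcl", "inf"),
                   synthetic_regions("gcl", "sup"))
  regions <- stats::setNames(rep("ns", length(all_regions)), all_regions)
  vf24 <- stats::setNames(rep("ns", 52L), VF24_IDS)
  vf10 <- stats::setNames(rep("ns", 68L), VF10_IDS)
  if (role == "HC") {
    # near-NS noise on healthy maps
    for (nm in names(vf24)) if (stats::runif(1) < config$map_noise_rate)
      vf24[[nm]] <- sample(c("p10", "p5"), 1)
    for (nm in names(vf10)) if (stats::runif(1) < config$map_noise_rate)
      vf10[[nm]] <- sample(c("p10", "p5"), 1)
    noisy <- stats::runif(length(regions)) < 0.75 * config$map_noise_rate
    regions[noisy] <- "p10"
    return(pointwise_maps(vf24, vf10, regions[grepl("^rnfl", all_regions)],
                          regions[grepl("^gcl", all_regions)]))
  }
  pool <- unlist(lapply(hemis, vf_locations_for_hemifield), use.names = FALSE)
  complement <- setdiff(c(VF24_IDS, VF10_IDS), pool)
  n_primary <- min(n_target, length(pool))
  selected <- character(0)
  if (n_primary > 0) selected <- sample(pool, n_primary)
  if (n_target > n_primary) {
    # severe defects spill across the horizontal meridian
    selected <- c(selected, sample(complement, n_target - n_primary))
  }
  sel24 <- intersect(selected, VF24_IDS)
  sel10 <- intersect(selected, VF10_IDS)
  abn_cat <- function(n) sample(c("p5", "p2", "p1", "p05"), n,
                                replace = TRUE,
                                prob = c(0.3, 0.3, 0.25, 0.15))
  vf24[sel24] <- abn_cat(length(sel24))
  vf10[sel10] <- abn_cat(length(sel10))
  # sub-significant noise never reaches the 5% level on unselected points
  for (nm in setdiff(names(vf24), sel24))
    if (stats::runif(1) < config$map_noise_rate) vf24[[nm]] <- "p10"
  for (nm in setdiff(names(vf10), sel10))
    if (stats::runif(1) < config$map_noise_rate) vf10[[nm]] <- "p10"
  region_cat <- function() sample(c("p10", "p5", "p1"), 1,
                                  prob = c(0.4, 0.4, 0.2))
  mark_region <- function(reg) {
    if (regions[[reg]] == "ns") regions[[reg]] <<- region_cat()
  }
  corr <- default_correspondence()
  for (loc in selected) {
    regs <- if (loc %in% VF24_IDS) corr$map24[[loc]] else corr$map10[[loc]]
    hit <- stats::runif(2) < config$kappa
    if (!any(hit)) hit[sample(2, 1)] <- TRUE
    for (j in which(hit)) mark_region(regs[j])
  }
  # couple abnormal sector codes to structural regions in their hemifield
  for (h in hemis) {
    tag <- if (h == "inferior") "inf" else "sup"
    for (layer in c("rnfl", "gcl")) {
      measure <- if (layer == "rnfl") "RNFL_SMALL" else "GCL"
      hs <- hemifield_sectors(measure, h)
      abn <- any(sectors[[measure]][c(hs$main, hs$other)] >=
                   color_code("yellow"))
      if (abn && stats::runif(1) < config$kappa) {
        layer_regs <- synthetic_regions(layer, tag)
        if (all(regions[layer_regs] == "ns")) {
          mark_region(sample(layer_regs, 1))
        }
      }
    }
  }
  pointwise_maps(vf24, vf10, regions[grepl("^rnfl", all_regions)],
                 regions[grepl("^gcl", all_regions)])
}

# Monotone severity response in [0, 1] that is exactly 0 at severity 0,
# so a zero-severity, zero-false-positive configuration is a true null
# model.
severity_response <- function(s) {
  base <- stats::plogis(4 * (0 - 0.45))
  pmax(0, (stats::plogis(4 * (s - 0.45)) - base) / (1 - base))
}

generate_vf_blocks <- function(role, severity, config) {
  fp <- config$vf_fp_rates
  resp <- severity_response(severity)
  abn_cat <- function() sample(c("p5", "p2", "p1"), 1,
                               prob = c(0.5, 0.3, 0.2))
  quiet_cat <- function(p_sub) {
    sample(c("ns", "p10"), 1, prob = c(1 - p_sub, p_sub))
  }
  p_index <- function(metric) {
    base <- fp[[metric]]
    p_abn <- if (role == "HC") base else base + (1 - base) * resp
    if (stats::runif(1) < p_abn) abn_cat() else
      quiet_cat(0.5 * base + 0.1 * resp)
  }
  ght <- if (role == "HC") {
    u <- stats::runif(1)
    if (u < fp[["GHT"]] * 0.4) "onl"
    else if (u < fp[["GHT"]]) "borderline"
    else if (u < fp[["GHT"]] + 0.01) "other"
    else "wnl"
  } else {
    u <- stats::runif(1)
    p_onl <- fp[["GHT"]] * 0.4 + resp * 0.7
    if (u < p_onl) "onl"
    else if (u < p_onl + fp[["GHT"]] * 0.6 + 0.4 * resp) "borderline"
    else "wnl"
  }
  if (role == "HC") {
    md_db <- stats::rnorm(1, 0.3, 0.8)
    psd_db <- max(1, stats::rnorm(1, 1.55, 0.35))
  } else {
    md_db <- stats::rnorm(1, 0.5 - 6 * severity, 0.7)
    psd_db <- max(1, stats::rnorm(1, 1.5 + 6.5 * severity, 0.5))
  }
  rel <- function() {
    if (stats::runif(1) < config$unreliable_rate) {
      c(fp = stats::runif(1, 0.16, 0.5), fl = stats::runif(1, 0.34, 0.8))
    } else {
      c(fp = stats::runif(1, 0, 0.12), fl = stats::runif(1, 0, 0.3))
    }
  }
  r24 <- rel(); r10 <- rel()
  list(
    vf24 = vf_metrics("VF24", md_p = p_index("MD24"),
                      psd_p = p_index("PSD24"), ght = ght,
                      fp_rate = r24[["fp"]],
                      fixation_loss_rate = r24[["fl"]],
                      md_db = md_db, psd_db = psd_db),
    vf10 = vf_metrics("VF10", md_p = p_index("MD10"),
                      psd_p = p_index("PSD10"),
                      fp_rate = r10[["fp"]],
                      fixation_loss_rate = r10[["fl"]]))
}

# Worked-example fixtures -----------------------------------------------------

#' A fully normal eye-visit record
#'
#' All sector codes green, all VF indices not significant, GHT within
#' normal limits, MD/PSD decibels in the clearly normal region of the
#' GSS2 chart.
#'
#' @param eye_id,visit,group record identity.
#' @param pointwise optional pointwise maps.
#' @return an `eye_visit`.
#' @export
make_normal_record <- function(eye_id = "EYE1", visit = 1L, group = "HC",
                               pointwise = NULL) {
  sectors <- lapply(stats::setNames(MEASURES, MEASURES), function(m) {
    sector_set(m, stats::setNames(rep("green", length(sectors_for(m))),
                                  sectors_for(m)))
  })
  eye_visit_record(
    eye_id = eye_id, visit = visit, group = group, sectors = sectors,
    vf24 = vf_metrics("VF24", "ns", "ns", ght = "wnl",
                      md_db = 0.5, psd_db = 1.4),
    vf10 = vf_metrics("VF10", "ns", "ns"),
    pointwise = pointwise)
}

# Force a monotone (negation-free) criterion true by setting the metrics
# it needs to clearly abnormal values.
force_true <- function(record, node) {
  switch(node$kind,
    oct = {
      record$sectors[[node$measure]][[node$sector]] <- "red"
      record
    },
    vf = {
      switch(node$metric,
        MD24 = record$vf24$md_p <- p_category("p05"),
        PSD24 = record$vf24$psd_p <- p_category("p05"),
        GHT = record$vf24$ght <- ght_category("onl"),
        MD10 = record$vf10$md_p <- p_category("p05"),
        PSD10 = record$vf10$psd_p <- p_category("p05"))
      record
    },
    gss2 = {
      record$vf24$md_db <- -15
      record$vf24$psd_db <- 11
      record
    },
    and = Reduce(force_true, node$children, record),
    or = force_true(record, node$children[[1L]]),
    any_paired = {
      s <- node$sectors[1L]
      record$sectors[[node$measure_a]][[s]] <- "red"
      record$sectors[[node$measure_b]][[s]] <- "red"
      record
    },
    quadrant_ght = {
      record$sectors[["RNFL_SMALL"]][["TI"]] <- "red"
      record$vf24$ght <- ght_category("onl")
      record
    })
}

#' Build a cohort reproducing given confusion counts for a criterion
#'
#' Constructs `fp + tn` healthy-control eyes and `tp + fn` likely-glaucoma
#' eyes such that exactly `fp` HC eyes and `tp` LG eyes satisfy the
#' criterion: the criterion's own metrics are set clearly abnormal on the
#' flagged eyes and everything else stays normal. Used to turn printed
#' confusion counts into executable worked examples.
#'
#' @param counts a `confusion` (or list with tp/fn/fp/tn).
#' @param criterion a monotone `criterion` (no negations exist in this
#'   engine, so any catalog criterion qualifies).
#' @param threshold threshold mode used for the verification pass.
#' @return list with `records` (one visit per eye) and `labels` (eye id
#'   -> `"HC"`/`"LG"`).
#' @export
generate_fixture_from_counts <- function(counts, criterion,
                                         threshold = "borderline") {
  base <- make_normal_record()
  if (eval_criterion(criterion, base, threshold)) {
    stop("criterion is satisfied by an all-normal record; counts are ",
         "unreachable", call. = FALSE)
  }
  abn <- force_true(make_normal_record(group = "PATIENT"), criterion)
  if (!eval_criterion(criterion, abn, threshold)) {
    stop("failed to construct a record satisfying the criterion",
         call. = FALSE)
  }
  n_hc <- counts$fp + counts$tn
  n_lg <- counts$tp + counts$fn
  records <- list()
  labels <- character(0)
  add <- function(eye, group, flagged) {
    r <- if (flagged) {
      force_true(make_normal_record(eye_id = eye, group = group), criterion)
    } else {
      make_normal_record(eye_id = eye, group = group)
    }
    records[[length(records) + 1L]] <<- r
    labels[[eye]] <<- if (group == "HC") "HC" else "LG"
  }
  for (i in seq_len(n_hc)) {
    add(sprintf("FXHC%03d", i), "HC", i <= counts$fp)
  }
  for (i in seq_len(n_lg)) {
    add(sprintf("FXLG%03d", i), "PATIENT", i <= counts$tp)
  }
  list(records = records, labels = labels)
}
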