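# Independent truth-table oracle for criterion trees.
#
# A criterion is flattened to its leaf "slots" (one per distinct metric it
# consults) and rendered as a plain boolean R expression over a named
# logical vector `abn`. Enumerating abnormality levels per slot
# (0 = normal, 1 = borderline, 2 = outside normal limits), building the
# corresponding record, and comparing eval_criterion() with the evaluated
# expression checks the engine against an independent code path.

oracle_slots <- function(node) {
  switch(node$kind,
    oct = {
      out <- list(list(type = "oct", measure = node$measure,
                       sector = node$sector))
      names(out) <- paste("OCT", node$measure, node$sector, sep = ".")
      out
    },
    vf = {
      out <- list(list(type = if (node$metric == "GHT") "ght" else "p",
                       metric = node$metric))
      names(out) <- paste("VF", node$metric, sep = ".")
      out
    },
    gss2 = list(GSS2 = list(type = "gss2")),
    and = ,
    or = {
      out <- list()
      for (ch in node$children) out <- utils::modifyList(out,
                                                         oracle_slots(ch))
      out
    },
    any_paired = {
      out <- list()
      for (s in node$sectors) {
        for (m in c(node$measure_a, node$measure_b)) {
          out[[paste("OCT", m, s, sep = ".")]] <-
            list(type = "oct", measure = m, sector = s)
        }
      }
      out
    },
    quadrant_ght = {
      out <- list()
      for (s in c("TS", "NS", "TI", "NI")) {
        out[[paste("OCT", "RNFL_SMALL", s, sep = ".")]] <-
          list(type = "oct", measure = "RNFL_SMALL", sector = s)
      }
      out[["VF.GHT"]] <- list(type = "ght", metric = "GHT")
      out
    })
}

oracle_expr <- function(node) {
  switch(node$kind,
    oct = sprintf('abn[["OCT.%s.%s"]]', node$measure, node$sector),
    vf = sprintf('abn[["VF.%s"]]', node$metric),
    gss2 = 'abn[["GSS2"]]',
    and = paste0("(", paste(vapply(node$children, oracle_expr,
                                   character(1)), collapse = " && "), ")"),
    or = paste0("(", paste(vapply(node$children, oracle_expr,
                                  character(1)), collapse = " || "), ")"),
    any_paired = paste0("(", paste(vapply(node$sectors, function(s) {
      sprintf('(abn[["OCT.%s.%s"]] && abn[["OCT.%s.%s"]])',
              node$measure_a, s, node$measure_b, s)
    }, character(1)), collapse = " || "), ")"),
    quadrant_ght = paste0(
      '((abn[["OCT.RNFL_SMALL.TS"]] || abn[["OCT.RNFL_SMALL.NS"]] || ',
      'abn[["OCT.RNFL_SMALL.TI"]] || abn[["OCT.RNFL_SMALL.NI"]]) && ',
      'abn[["VF.GHT"]])'))
}

record_from_levels <- function(slots, levels) {
  r <- make_normal_record()
  for (i in seq_along(slots)) {
    s <- slots[[i]]
    lvl <- levels[i]
    if (s$type == "oct") {
      r$sectors[[s$measure]][[s$sector]] <-
        c("green", "yellow", "red")[lvl + 1]
    } else if (s$type == "p") {
      val <- c("ns", "p5", "p1")[lvl + 1]
      switch(s$metric,
        MD24 = r$vf24$md_p <- p_category(val),
        PSD24 = r$vf24$psd_p <- p_category(val),
        MD10 = r$vf10$md_p <- p_category(val),
        PSD10 = r$vf10$psd_p <- p_category(val))
    } else if (s$type == "ght") {
      r$vf24$ght <- ght_category(c("wnl", "borderline", "onl")[lvl + 1])
    } else {  # gss2: normal / borderline band / stage >= 1
      if (lvl == 0) {
        r$vf24$md_db <- 0.5; r$vf24$psd_db <- 1.4
      } else if (lvl == 1) {
        r$vf24$md_db <- -1.2; r$vf24$psd_db <- 1.4
      } else {
        r$vf24$md_db <- -5; r$vf24$psd_db <- 1.4
      }
    }
  }
  r
}

# Compare eval_criterion against the oracle for every assignment of
# abnormality levels (exhaustive up to `max_exhaustive` slots, sampled
# otherwise). Returns the number of assignments checked.
check_against_oracle <- function(node, max_exhaustive = 6L,
                                 n_sample = 400L, seed = 42L) {
  slots <- oracle_slots(node)
  k <- length(slots)
  expr <- parse(text = oracle_expr(node))[[1]]
  grids <- if (k <= max_exhaustive) {
    as.matrix(expand.grid(rep(list(0:2), k)))
  } else {
    set.seed(seed)
    matrix(sample(0:2, n_sample * k, replace = TRUE), ncol = k)
  }
  for (row in seq_len(nrow(grids))) {
    levels <- grids[row, ]
    rec <- record_from_levels(slots, levels)
    for (mode in c("borderline", "strict")) {
      abn <- if (mode == "borderline") levels >= 1 else levels >= 2
      names(abn) <- names(slots)
      expected <- eval(expr, list(abn = abn))
      got <- eval_criterion(node, rec, mode)
      if (!identical(expected, got)) {
        stop(sprintf("oracle mismatch (%s, %s): levels [%s]",
                     attr(node, "name") %||% node$kind, mode,
                     paste(levels, collapse = ",")))
      }
    }
  }
  nrow(grids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small cohort used by property tests.
small_cohort <- function(seed, n_hc = 8L, n_patient = 10L) {
  generate_cohort(generator_config(n_hc = n_hc, n_patient = n_patient,
                                   seed = seed))
}
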