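test_that("calibration turns count tables into column-conditional models", {
  m <- calibrate_confusion(arf_crosstab("table2_ccus"))
  expect_equal(unname(m$reference_prevalence),
               c(63, 55, 18, 6, 32) / 174, tolerance = 1e-12)
  expect_equal(m$conditional["ALVEOLAR_LUNG", "ALVEOLAR_LUNG"], 54 / 63,
               tolerance = 1e-12)
  expect_equal(unname(colSums(m$conditional)), rep(1, 5), tolerance = 1e-9)
  ident <- crosstab(diag(c(3, 4)), categories = c("a", "b"))
  expect_equal(calibrate_confusion(ident)$conditional, diag(2),
               ignore_attr = TRUE)
  empty_col <- crosstab(matrix(c(2, 1, 0, 0), 2, 2,
                               dimnames = list(c("a", "b"), c("a", "b"))))
  expect_error(calibrate_confusion(empty_col), "empty reference column")
})

test_that("generated findings round-trip through both classifiers", {
  set.seed(111)
  for (ccus in arf_categories())
    for (cxr in arf_categories())
      for (r in 1:20) {
        p <- findings_for_labels(ccus, cxr)
        expect_identical(classify_ccus_abg(p), ccus)
        expect_identical(classify_cxr(p), cxr)
      }
})

test_that("each CCUS template satisfies exactly one rule branch", {
  # if a second branch also matched, some priority rotation would win it
  rotations <- lapply(seq_along(arf_categories()), function(s) {
    cats <- arf_categories()
    triage_config(priority = c(cats[s:length(cats)], cats[seq_len(s - 1)]))
  })
  set.seed(121)
  for (label in arf_categories())
    for (r in 1:10) {
      p <- findings_for_labels(label, "METABOLIC")
      for (config in rotations)
        expect_identical(classify_ccus_abg(p, config), label)
    }
})

test_that("cohorts are reproducible and byte-identical given a seed", {
  m <- calibrate_confusion(arf_crosstab("table2_ccus"))
  m2 <- calibrate_confusion(arf_crosstab("table2_cxr"))
  a <- sample_cohort(60, m, m2, seed = 2024)
  b <- sample_cohort(60, m, m2, seed = 2024)
  expect_identical(a, b)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a, fa)
  write_cohort_csv(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  c <- sample_cohort(60, m, m2, seed = 2025)
  expect_false(identical(a, c))
})

test_that("fixed-margin sampling reproduces the composite margins exactly", {
  m <- calibrate_confusion(arf_crosstab("table2_ccus"))
  cohort <- sample_cohort(174, m, sampling_mode = "fixed_margins",
                          seed = 5)
  counts <- table(factor(cohort$true_category, levels = arf_categories()))
  expect_equal(unname(as.vector(counts)), c(63, 55, 18, 6, 32))
  # margins scale sensibly to other cohort sizes
  small <- sample_cohort(40, m, sampling_mode = "fixed_margins", seed = 5)
  expect_equal(nrow(small), 40)
})

test_that("cohort records survive the CSV schema round trip", {
  m <- calibrate_confusion(arf_crosstab("table2_ccus"))
  cohort <- sample_cohort(25, m, seed = 77)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(back))) {
    p <- patient_findings_from_record(back[i, ])
    expect_identical(classify_ccus_abg(p), cohort$ccus_label[i])
    expect_identical(classify_cxr(p), cohort$cxr_label[i])
  }
})

test_that("record parsing reports missing fields as precondition errors", {
  m <- calibrate_confusion(arf_crosstab("table2_ccus"))
  rec <- as_patient_record(findings_for_labels("METABOLIC", "METABOLIC"))
  rec$lus_profile <- NA
  expect_error(patient_findings_from_record(rec), "lus_profile")
  rec2 <- as_patient_record(findings_for_labels("METABOLIC", "METABOLIC"))
  rec2$pao2 <- NA
  expect_error(patient_findings_from_record(rec2), "pao2")
})

test_that("a calibrated model resamples toward its own proportions", {
  m <- calibrate_confusion(arf_crosstab("table2_ccus"))
  set.seed(131)
  n <- 20000
  true <- sample(m$categories, n, replace = TRUE,
                 prob = m$reference_prevalence)
  idx <- character(n)
  for (j in m$categories) {
    hit <- true == j
    idx[hit] <- sample(m$categories, sum(hit), replace = TRUE,
                       prob = m$conditional[, j])
  }
  ct <- build_crosstab(idx, true)
  back <- calibrate_confusion(ct)
  expect_lt(max(abs(back$reference_prevalence - m$reference_prevalence)),
            0.015)
  expect_lt(max(abs(back$conditional - m$conditional)), 0.05)
})
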