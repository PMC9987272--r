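test_that("Wilson interval matches the score-test inversion oracle", {
  cases <- list(c(54, 63), c(15, 18), c(1, 40), c(20, 40), c(199, 200))
  for (case in cases) {
    got <- wilson_interval(case[1], case[2])
    oracle <- wilson_grid_oracle(case[1], case[2])
    expect_lt(abs(got[["lower"]] - oracle[1]), 2e-5)
    expect_lt(abs(got[["upper"]] - oracle[2]), 2e-5)
  }
})

test_that("Wilson interval handles boundaries and bad input", {
  expect_equal(unname(wilson_interval(0, 10)[["lower"]]), 0)
  expect_equal(unname(wilson_interval(10, 10)[["upper"]]), 1)
  expect_error(wilson_interval(5, 0), "n")
  expect_error(wilson_interval(11, 10), "successes")
  expect_error(wilson_interval(5, 10, level = 1), "level")
})

test_that("Wilson interval contains the point estimate and narrows with n", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(1:500, 1)
    x <- sample(0:n, 1)
    ci <- wilson_interval(x, n)
    expect_true(ci[["lower"]] <= x / n + 1e-12)
    expect_true(ci[["upper"]] >= x / n - 1e-12)
    # same proportion at 4x the sample size gives a narrower interval
    ci4 <- wilson_interval(4 * x, 4 * n)
    expect_lte(ci4[["upper"]] - ci4[["lower"]],
               ci[["upper"]] - ci[["lower"]] + 1e-12)
  }
})

test_that("diagnostic properties reproduce the published accuracy rows", {
  al <- diagnostic_properties(binary_confusion(tp = 54, fp = 15, fn = 9,
                                               tn = 96))
  expect_equal(al$sensitivity, 54 / 63, tolerance = 1e-12)
  expect_equal(round(100 * al$sensitivity, 2), 85.71)
  expect_equal(round(100 * al$specificity, 2), 86.49)
  expect_equal(round(100 * al$ppv, 2), 78.26)
  pe <- diagnostic_properties(binary_confusion(tp = 4, fp = 0, fn = 2,
                                               tn = 168))
  expect_equal(pe$specificity, 1)
  expect_equal(pe$ppv, 1)
  expect_identical(pe$lr_pos, Inf)
  corrected <- diagnostic_properties(
    binary_confusion(tp = 4, fp = 0, fn = 2, tn = 168),
    zero_cell_correction = TRUE)
  expect_true(is.finite(corrected$lr_pos) && corrected$lr_pos > 100)
})

test_that("degenerate denominators yield NA fields, not errors", {
  all_pos <- diagnostic_properties(binary_confusion(tp = 12, fp = 0,
                                                    fn = 0, tn = 0))
  expect_equal(all_pos$sensitivity, 1)
  expect_true(is.na(all_pos$specificity))
  expect_true(is.na(all_pos$npv))
})

test_that("PPV obeys the Bayes identity on random confusion tables", {
  set.seed(41)
  for (i in 1:1000) {
    bc <- random_confusion()
    dp <- diagnostic_properties(bc)
    if (is.na(dp$ppv) || dp$specificity == 1) next
    prev <- dp$prevalence
    bayes <- dp$sensitivity * prev /
      (dp$sensitivity * prev + (1 - dp$specificity) * (1 - prev))
    expect_equal(dp$ppv, bayes, tolerance = 1e-12)
  }
})

test_that("kappa reproduces the published per-category values", {
  expect_equal(cohen_kappa(binary_confusion(54, 15, 9, 96))$kappa,
               0.7074, tolerance = 1e-4)
  expect_equal(cohen_kappa(binary_confusion(52, 8, 3, 111))$kappa,
               0.8573, tolerance = 1e-4)
  perfect <- cohen_kappa(binary_confusion(10, 0, 0, 14))
  expect_equal(perfect$kappa, 1)
  independent <- cohen_kappa(binary_confusion(9, 21, 21, 49))
  expect_equal(independent$kappa, 0, tolerance = 1e-12)
})

test_that("kappa satisfies its structural invariants on random tables", {
  set.seed(51)
  for (i in 1:300) {
    bc <- random_confusion()
    kr <- cohen_kappa(bc)
    if (is.na(kr$kappa)) next
    expect_gte(kr$kappa, -1 - 1e-12)
    expect_lte(kr$kappa, 1 + 1e-12)
    expect_equal(kr$kappa, (kr$po - kr$pe) / (1 - kr$pe), tolerance = 1e-12)
    # kappa = 1 iff the off-diagonal cells vanish
    expect_identical(isTRUE(all.equal(kr$kappa, 1)),
                     bc$fp + bc$fn == 0)
    # swapping the "positive" definition (simultaneous row/col permutation)
    swapped <- cohen_kappa(binary_confusion(tp = bc$tn, fp = bc$fn,
                                            fn = bc$fp, tn = bc$tp))
    expect_equal(swapped$kappa, kr$kappa, tolerance = 1e-12)
  }
})

test_that("kappa and agreement match item-level oracles on random tables", {
  set.seed(61)
  for (i in 1:1000) {
    ct <- random_crosstab(K = 5, n = sample(5:50, 1))
    if (sum(diag(ct$counts)) == ct$n) next  # pe may be 1; kappa undefined
    pairs <- expand_crosstab_to_pairs(ct)
    oracle <- kappa_pairs_oracle(pairs$index, pairs$reference)
    expect_equal(percent_agreement(ct), oracle$po, tolerance = 1e-12)
    kr <- cohen_kappa(ct)
    if (!is.na(kr$kappa))
      expect_equal(kr$kappa, oracle$kappa, tolerance = 1e-10)
  }
})

test_that("multiclass kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(71)
  for (i in 1:25) {
    ct <- random_crosstab(K = sample(2:5, 1), n = sample(20:100, 1))
    ref <- e1071::classAgreement(ct$counts)
    kr <- cohen_kappa(ct)
    if (!is.na(kr$kappa) && is.finite(ref$kappa))
      expect_equal(kr$kappa, ref$kappa, tolerance = 1e-10)
    expect_equal(percent_agreement(ct), ref$diag, tolerance = 1e-12)
  }
})

test_that("both kappa standard-error formulas are available and differ", {
  bc <- binary_confusion(54, 15, 9, 96)
  fce <- cohen_kappa(bc, se_method = "fce")
  agr <- cohen_kappa(bc, se_method = "agreement")
  expect_equal(agr$se,
               sqrt(fce$po * (1 - fce$po) / (bc$n * (1 - fce$pe)^2)),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fce$se, agr$se)))
  expect_true(fce$ci[["lower"]] < fce$kappa &&
                fce$kappa < fce$ci[["upper"]])
})

test_that("McNemar's test handles discordance patterns and edge cases", {
  # symmetric discordance, uncorrected chi-square is exactly zero
  sym <- mcnemar_from_counts(7, 7, continuity = FALSE, exact = FALSE)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  asym <- mcnemar_from_counts(10, 2, continuity = TRUE, exact = FALSE)
  expect_equal(asym$statistic, 49 / 12, tolerance = 1e-12)
  # exact two-sided binomial tail oracle
  exact <- mcnemar_from_counts(10, 2, exact = TRUE)
  expect_equal(exact$p_value, binom.test(2, 12, 0.5)$p.value,
               tolerance = 1e-12)
  none <- mcnemar_from_counts(0, 0)
  expect_equal(none$p_value, 1)
  expect_equal(none$statistic, 0)
  expect_error(mcnemar_test(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("McNemar agrees with the stats implementation on paired flags", {
  set.seed(81)
  a <- runif(300) < 0.8
  b <- runif(300) < 0.6
  got <- mcnemar_test(a, b, continuity = TRUE, exact = FALSE)
  ref <- stats::mcnemar.test(table(a, b), correct = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("evaluate_algorithm assembles per-category rows and attributes", {
  ev <- evaluate_algorithm(arf_crosstab("table2_ccus"))
  expect_s3_class(ev, "algorithm_evaluation")
  expect_equal(nrow(ev), 5)
  expect_equal(attr(ev, "percent_agreement"), 145 / 174, tolerance = 1e-12)
  expect_equal(attr(ev, "n"), 174)
  triv <- crosstab(matrix(6, 1, 1, dimnames = list("only", "only")))
  ev1 <- evaluate_algorithm(triv)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$sensitivity, 1)
})
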