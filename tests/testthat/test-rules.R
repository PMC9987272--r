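test_that("hypoxemia and hypercarbia use the strict study cut-offs", {
  expect_true(as.logical(assess_hypoxemia(abg_panel(pao2 = 55, paco2 = 40))))
  expect_false(as.logical(assess_hypoxemia(abg_panel(pao2 = 60, paco2 = 40))))
  expect_false(as.logical(assess_hypoxemia(abg_panel(pao2 = 95, paco2 = 40))))
  expect_true(assess_hypercarbia(abg_panel(pao2 = 80, paco2 = 60)))
  expect_false(assess_hypercarbia(abg_panel(pao2 = 80, paco2 = 45)))
  expect_false(assess_hypercarbia(abg_panel(pao2 = 80, paco2 = 38)))
  expect_error(abg_panel(pao2 = 0, paco2 = 40), "pao2")
  expect_error(abg_panel(pao2 = 60, paco2 = -3), "paco2")
  expect_error(abg_panel(pao2 = 60, paco2 = 40, ph = 6.2), "ph")
})

test_that("off-room-air panels are scored with a warning annotation", {
  on_air <- assess_hypoxemia(abg_panel(pao2 = 55, paco2 = 40,
                                       on_room_air = TRUE))
  off_air <- assess_hypoxemia(abg_panel(pao2 = 55, paco2 = 40,
                                        on_room_air = FALSE))
  expect_true(as.logical(off_air))
  expect_true(attr(off_air, "off_room_air"))
  expect_null(attr(on_air, "off_room_air"))
})

test_that("the four BLUE-protocol pneumonia patterns are recognized", {
  cases <- list(
    list(lus_exam("C_PROFILE", shred_sign = TRUE), TRUE),
    list(lus_exam("B_FOCAL", focal_interstitial = TRUE), TRUE),
    list(lus_exam("B0_PROFILE"), TRUE),
    list(lus_exam("A_PROFILE", plaps = TRUE), TRUE),
    list(lus_exam("A_PROFILE"), FALSE),
    list(lus_exam("C_PROFILE"), FALSE),
    list(lus_exam("B_PROFILE_BILATERAL"), FALSE))
  for (case in cases)
    expect_identical(match_pneumonia_pattern(case[[1]]), case[[2]])
  expect_error(lus_exam("A_PROFILE", shred_sign = TRUE), "shred")
  expect_error(lus_exam("X_PROFILE"), "profile")
})

test_that("the CCUS+ABG engine reproduces the worked category examples", {
  expect_identical(classify_ccus_abg(example_cardiac()), "ALVEOLAR_CARDIAC")
  expect_identical(classify_ccus_abg(example_metabolic()), "METABOLIC")
  expect_identical(classify_ccus_abg(example_copd()), "VENT_ALVEOLAR")
  pneumonia <- patient_findings(
    "ex-pna", lus = lus_exam("C_PROFILE", shred_sign = TRUE),
    tte = tte_exam("NORMAL"), ivc = "COLLAPSED", dvt = "NEGATIVE",
    abg = abg_panel(pao2 = 48, paco2 = 40))
  expect_identical(classify_ccus_abg(pneumonia), "ALVEOLAR_LUNG")
  pe <- patient_findings(
    "ex-pe", lus = lus_exam("A_PROFILE"),
    tte = tte_exam("NORMAL", rv_dilated = TRUE), ivc = "DISTENDED",
    dvt = "POSITIVE", abg = abg_panel(pao2 = 52, paco2 = 30))
  expect_identical(classify_ccus_abg(pe), "PERFUSION")
  # hypoxemic A-profile with negative DVT matches no branch
  orphan <- patient_findings(
    "ex-none", lus = lus_exam("A_PROFILE"), tte = tte_exam("NORMAL"),
    ivc = "COLLAPSED", dvt = "NEGATIVE",
    abg = abg_panel(pao2 = 50, paco2 = 40))
  expect_identical(classify_ccus_abg(orphan), "UNCLASSIFIED")
  expect_identical(unclassified_reason(orphan, "ccus"),
                   "hypoxemic_findings_match_no_branch")
})

test_that("missing components are precondition errors naming the component", {
  expect_error(patient_findings("p", tte = tte_exam("NORMAL"),
                                ivc = "COLLAPSED", dvt = "NEGATIVE",
                                abg = abg_panel(60, 40)),
               "lung ultrasound")
  expect_error(patient_findings("p", lus = lus_exam("A_PROFILE"),
                                ivc = "COLLAPSED", dvt = "NEGATIVE",
                                abg = abg_panel(60, 40)),
               "echocardiography")
  expect_error(classify_cxr(example_metabolic()), "cxr")
})

test_that("the chest-X-ray engine reproduces the worked category examples", {
  expect_identical(
    classify_cxr(cxr_findings(normal_film = TRUE, spo2_hypoxia = TRUE)),
    "PERFUSION")
  expect_identical(
    classify_cxr(cxr_findings(normal_film = TRUE, spo2_hypoxia = FALSE)),
    "METABOLIC")
  expect_identical(
    classify_cxr(cxr_findings(air_bronchogram_or_opacity = TRUE,
                              spo2_hypoxia = TRUE)),
    "ALVEOLAR_LUNG")
  expect_identical(
    classify_cxr(cxr_findings(bat_wing_or_cardiomegaly_or_hilar = TRUE,
                              spo2_hypoxia = TRUE)),
    "ALVEOLAR_CARDIAC")
  expect_identical(
    classify_cxr(cxr_findings(
      hyperinflation_tubular_heart_flat_diaphragm = TRUE,
      spo2_hypoxia = TRUE)),
    "VENT_ALVEOLAR")
  # abnormal film without hypoxia falls through every branch
  expect_identical(
    classify_cxr(cxr_findings(air_bronchogram_or_opacity = TRUE,
                              spo2_hypoxia = FALSE)),
    "UNCLASSIFIED")
  expect_error(cxr_findings(normal_film = TRUE,
                            air_bronchogram_or_opacity = TRUE),
               "mutually exclusive")
})

test_that("classification is total and deterministic over random records", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_findings()
    a <- classify_ccus_abg(p)
    expect_length(a, 1L)
    expect_true(a %in% arf_categories(with_unclassified = TRUE))
    expect_identical(classify_ccus_abg(p), a)
    b <- classify_cxr(p)
    expect_true(b %in% arf_categories(with_unclassified = TRUE))
    expect_identical(classify_cxr(p), b)
  }
})

test_that("branch priority is configurable and resolves overlap", {
  # record satisfying both the COPD branch and the pneumonia branch
  overlap <- patient_findings(
    "ex-overlap", lus = lus_exam("C_PROFILE", shred_sign = TRUE),
    tte = tte_exam("NORMAL", rv_dilated = TRUE), ivc = "DISTENDED",
    dvt = "NEGATIVE", abg = abg_panel(pao2 = 50, paco2 = 60))
  expect_identical(classify_ccus_abg(overlap), "VENT_ALVEOLAR")
  lung_first <- triage_config(priority = c(
    "ALVEOLAR_LUNG", "ALVEOLAR_CARDIAC", "VENT_ALVEOLAR", "PERFUSION",
    "METABOLIC"))
  expect_identical(classify_ccus_abg(overlap, lung_first), "ALVEOLAR_LUNG")
  expect_error(triage_config(priority = c("ALVEOLAR_LUNG")), "permutation")
})

test_that("the optional hypocarbia requirement gates the perfusion branch", {
  pe_borderline <- patient_findings(
    "ex-pe2", lus = lus_exam("A_PROFILE"),
    tte = tte_exam("NORMAL", rv_dilated = TRUE), ivc = "DISTENDED",
    dvt = "POSITIVE", abg = abg_panel(pao2 = 52, paco2 = 44))
  expect_identical(classify_ccus_abg(pe_borderline), "PERFUSION")
  strict <- triage_config(require_hypocarbia_for_perfusion = TRUE)
  expect_identical(classify_ccus_abg(pe_borderline, strict), "UNCLASSIFIED")
  pe_hypocarbic <- patient_findings(
    "ex-pe3", lus = lus_exam("A_PROFILE"),
    tte = tte_exam("NORMAL", rv_dilated = TRUE), ivc = "DISTENDED",
    dvt = "POSITIVE", abg = abg_panel(pao2 = 52, paco2 = 28))
  expect_identical(classify_ccus_abg(pe_hypocarbic, strict), "PERFUSION")
})
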