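#' Configuration of the triage rule engines
#'
#' Both classifiers evaluate their rule branches in a fixed priority order
#' and return the first branch whose conditions hold, so that records
#' satisfying more than one branch are resolved deterministically. The
#' default order evaluates the cardiac branch before the COPD branch before
#' the pneumonia branch before perfusion before metabolic; clinical
#' overlap (e.g. combined cardiac and pneumonic disease) therefore resolves
#' toward the more specific finding set first. The order can be changed
#' here for sensitivity analyses.
#'
#' @param priority character vector, a permutation of [arf_categories()].
#'   Default: `ALVEOLAR_CARDIAC`, `VENT_ALVEOLAR`, `ALVEOLAR_LUNG`,
#'   `PERFUSION`, `METABOLIC`.
#' @param require_hypocarbia_for_perfusion additionally require PaCO2 below
#'   `hypocarbia_threshold` for the perfusion branch. Off by default: low
#'   CO2 supports pulmonary embolism physiologically but is not part of the
#'   branch definition.
#' @param hypocarbia_threshold PaCO2 (mmHg) below which the patient counts
#'   as hypocarbic, used only when `require_hypocarbia_for_perfusion`.
#' @return An object of class `triage_config`.
#' @export
triage_config <- function(priority = c("ALVEOLAR_CARDIAC", "VENT_ALVEOLAR",
                                       "ALVEOLAR_LUNG", "PERFUSION",
                                       "METABOLIC"),
                          require_hypocarbia_for_perfusion = FALSE,
                          hypocarbia_threshold = 35) {
  if (!setequal(priority, arf_categories()) ||
      length(priority) != length(arf_categories()))
    stop("priority must be a permutation of the five categories",
         call. = FALSE)
  .check_flag(require_hypocarbia_for_perfusion,
              "require_hypocarbia_for_perfusion")
  structure(list(priority = priority,
                 require_hypocarbia_for_perfusion =
                   require_hypocarbia_for_perfusion,
                 hypocarbia_threshold = hypocarbia_threshold),
            class = "triage_config")
}

#' Hypoxemia per the study definition
#'
#' Hypoxemia is PaO2 strictly below 60 mmHg on room air. For samples drawn
#' on supplemental oxygen the same threshold is applied — nearly all
#' critically ill dyspneic patients receive oxygen, so a strict room-air
#' precondition would make the rule inapplicable — and the result carries an
#' `off_room_air` attribute set to `TRUE` as a warning annotation.
#'
#' @param abg an [abg_panel()].
#' @return Logical flag; attribute `off_room_air` is `TRUE` when the panel
#'   was not drawn on room air.
#' @export
#' @examples
#' assess_hypoxemia(abg_panel(pao2 = 55, paco2 = 40))
assess_hypoxemia <- function(abg) {
  if (!inherits(abg, "abg_panel"))
    stop("abg must be an abg_panel", call. = FALSE)
  out <- abg$pao2 < 60
  if (!abg$on_room_air) attr(out, "off_room_air") <- TRUE
  out
}

#' Hypercarbia per the study definition
#'
#' Hypercarbia is PaCO2 strictly above 45 mmHg.
#'
#' @inheritParams assess_hypoxemia
#' @return Logical flag.
#' @export
assess_hypercarbia <- function(abg) {
  if (!inherits(abg, "abg_panel"))
    stop("abg must be an abg_panel", call. = FALSE)
  abg$paco2 > 45
}

#' BLUE-protocol pneumonia patterns
#'
#' True when the lung ultrasound exam shows any of the four sonographic
#' pneumonia patterns: (a) C-profile with shred sign; (b) focal
#' interstitial syndrome; (c) B0-profile; (d) A-profile with PLAPS.
#'
#' @param lus a [lus_exam()].
#' @return Logical flag.
#' @export
#' @examples
#' match_pneumonia_pattern(lus_exam("C_PROFILE", shred_sign = TRUE))
match_pneumonia_pattern <- function(lus) {
  if (!inherits(lus, "lus_exam"))
    stop("lus must be a lus_exam", call. = FALSE)
  (lus$profile == "C_PROFILE" && lus$shred_sign) ||
    lus$focal_interstitial ||
    lus$profile == "B0_PROFILE" ||
    (lus$profile == "A_PROFILE" && lus$plaps)
}

# branch predicates for the CCUS+ABG engine, one per category
.ccus_branch <- function(p, category, config) {
  hypox <- isTRUE(as.logical(assess_hypoxemia(p$abg)))
  switch(category,
    ALVEOLAR_CARDIAC =
      p$lus$profile == "B_PROFILE_BILATERAL" &&
      p$tte$lv_function == "DYSFUNCTION" &&
      p$ivc == "DISTENDED" && hypox,
    VENT_ALVEOLAR =
      p$lus$profile %in% c("B_FOCAL", "C_PROFILE") &&
      p$tte$rv_dilated && p$ivc == "DISTENDED" &&
      hypox && assess_hypercarbia(p$abg),
    ALVEOLAR_LUNG =
      match_pneumonia_pattern(p$lus) &&
      p$tte$lv_function == "NORMAL" && hypox,
    PERFUSION =
      p$lus$profile == "A_PROFILE" && p$dvt == "POSITIVE" &&
      p$tte$rv_dilated && hypox &&
      (!config$require_hypocarbia_for_perfusion ||
         p$abg$paco2 < config$hypocarbia_threshold),
    METABOLIC =
      p$lus$profile == "A_PROFILE" &&
      p$tte$lv_function == "NORMAL" && p$dvt == "NEGATIVE" && !hypox,
    stop("unknown category: ", category, call. = FALSE))
}

#' Classify a patient with the CCUS + ABG algorithm
#'
#' Applies the ultrasound-plus-blood-gas rule set and returns exactly one
#' category. Branches, in default priority order:
#' \describe{
#'   \item{ALVEOLAR_CARDIAC}{bilateral B-lines, LV dysfunction, IVC
#'     distended, hypoxemia (cardiogenic pulmonary oedema).}
#'   \item{VENT_ALVEOLAR}{focal B-lines or C-profile, RV dilated, IVC
#'     distended, hypoxemia and hypercarbia (acute exacerbation of COPD).}
#'   \item{ALVEOLAR_LUNG}{any BLUE-protocol pneumonia pattern with normal
#'     LV and hypoxemia.}
#'   \item{PERFUSION}{A-profile, positive DVT scan, RV dilatation,
#'     hypoxemia (pulmonary embolism).}
#'   \item{METABOLIC}{A-profile, normal LV, negative DVT scan, no
#'     hypoxemia.}
#' }
#' Records matching no branch return `UNCLASSIFIED`.
#'
#' @param p a [patient_findings()] record with all CCUS components present.
#' @param config a [triage_config()].
#' @return A single category code (see [arf_categories()]).
#' @export
#' @examples
#' classify_ccus_abg(patient_findings("pt1",
#'   lus = lus_exam("A_PROFILE"), tte = tte_exam("NORMAL"),
#'   ivc = "COLLAPSED", dvt = "NEGATIVE",
#'   abg = abg_panel(pao2 = 80, paco2 = 40)))
classify_ccus_abg <- function(p, config = triage_config()) {
  if (!inherits(p, "patient_findings"))
    stop("p must be a patient_findings record", call. = FALSE)
  for (category in config$priority)
    if (.ccus_branch(p, category, config)) return(category)
  "UNCLASSIFIED"
}

#' Classify a patient with the chest-X-ray algorithm
#'
#' Applies the radiograph-plus-pulse-oximetry rule set and returns exactly
#' one category: air bronchogram/opacity with hypoxia is alveolar-lung;
#' bat-wing/cardiomegaly/hilar prominence with hypoxia is alveolar-cardiac;
#' hyperinflation/tubular heart/flat diaphragm with hypoxia is
#' ventilation-plus-alveolar; a normal film with hypoxia is perfusion; a
#' normal film without hypoxia is metabolic. Anything else is
#' `UNCLASSIFIED`.
#'
#' @param cxr a [cxr_findings()] object, or a [patient_findings()] record
#'   whose `cxr` component is present.
#' @param config a [triage_config()]; only the branch priority is used.
#' @return A single category code.
#' @export
#' @examples
#' classify_cxr(cxr_findings(normal_film = TRUE, spo2_hypoxia = TRUE))
classify_cxr <- function(cxr, config = triage_config()) {
  if (inherits(cxr, "patient_findings")) {
    if (is.null(cxr$cxr))
      stop("precondition failed: chest X-ray findings (cxr) missing",
           call. = FALSE)
    cxr <- cxr$cxr
  }
  if (!inherits(cxr, "cxr_findings"))
    stop("cxr must be a cxr_findings object", call. = FALSE)
  ok <- function(category) switch(category,
    ALVEOLAR_LUNG    = cxr$air_bronchogram_or_opacity && cxr$spo2_hypoxia,
    ALVEOLAR_CARDIAC = cxr$bat_wing_or_cardiomegaly_or_hilar &&
                       cxr$spo2_hypoxia,
    VENT_ALVEOLAR    = cxr$hyperinflation_tubular_heart_flat_diaphragm &&
                       cxr$spo2_hypoxia,
    PERFUSION        = cxr$normal_film && cxr$spo2_hypoxia,
    METABOLIC        = cxr$normal_film && !cxr$spo2_hypoxia)
  for (category in config$priority) if (ok(category)) return(category)
  "UNCLASSIFIED"
}

#' Reason code for an unclassified record
#'
#' Short diagnostic string explaining why a record fell through every rule
#' branch of the given arm; `NA` when the record does classify.
#'
#' @param p a [patient_findings()] record.
#' @param algorithm `"ccus"` or `"cxr"`.
#' @param config a [triage_config()].
#' @return Character reason code or `NA_character_`.
#' @export
unclassified_reason <- function(p, algorithm = c("ccus", "cxr"),
                                config = triage_config()) {
  algorithm <- match.arg(algorithm)
  label <- if (algorithm == "ccus") classify_ccus_abg(p, config)
           else classify_cxr(p, config)
  if (label != "UNCLASSIFIED") return(NA_character_)
  if (algorithm == "cxr") {
    if (!p$cxr$normal_film && !p$cxr$air_bronchogram_or_opacity &&
        !p$cxr$bat_wing_or_cardiomegaly_or_hilar &&
        !p$cxr$hyperinflation_tubular_heart_flat_diaphragm)
      return("no_radiographic_finding_coded")
    return("abnormal_film_without_hypoxia")
  }
  hypox <- isTRUE(as.logical(assess_hypoxemia(p$abg)))
  if (!hypox) return("no_hypoxemia_outside_metabolic_branch")
  "hypoxemic_findings_match_no_branch"
}
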