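#' Arterial blood gas panel
#'
#' @param pao2 arterial oxygen tension, mmHg (> 0).
#' @param paco2 arterial carbon dioxide tension, mmHg (> 0).
#' @param ph arterial pH; must lie in the physiologic window 6.5--8.0.
#' @param hco3 bicarbonate, mEq/L (> 0).
#' @param on_room_air was the sample drawn on room air? Patients on
#'   supplemental oxygen or ventilatory support are still scored against
#'   the same PaO2 threshold, with a warning annotation (see
#'   [assess_hypoxemia()]).
#' @return An object of class `abg_panel`.
#' @export
#' @examples
#' abg_panel(pao2 = 55, paco2 = 38)
abg_panel <- function(pao2, paco2, ph = 7.40, hco3 = 24, on_room_air = TRUE) {
  if (!is.numeric(pao2) || length(pao2) != 1L || is.na(pao2) || pao2 <= 0)
    stop("pao2 must be a single positive value (mmHg)", call. = FALSE)
  if (!is.numeric(paco2) || length(paco2) != 1L || is.na(paco2) || paco2 <= 0)
    stop("paco2 must be a single positive value (mmHg)", call. = FALSE)
  if (!is.numeric(ph) || length(ph) != 1L || is.na(ph) || ph < 6.5 || ph > 8.0)
    stop("ph outside physiologic bounds [6.5, 8.0]; record rejected",
         call. = FALSE)
  if (!is.numeric(hco3) || length(hco3) != 1L || is.na(hco3) || hco3 <= 0)
    stop("hco3 must be a single positive value (mEq/L)", call. = FALSE)
  .check_flag(on_room_air, "on_room_air")
  structure(list(pao2 = as.numeric(pao2), paco2 = as.numeric(paco2),
                 ph = as.numeric(ph), hco3 = as.numeric(hco3),
                 on_room_air = on_room_air),
            class = "abg_panel")
}

#' Lung ultrasound exam
#'
#' Coded BLUE-protocol lung ultrasound findings. `profile` is the overall
#' sonographic profile; the flags record the ancillary signs used by the
#' pneumonia patterns: the shred sign (irregular pleural-consolidation
#' boundary), PLAPS (posterolateral alveolar and/or pleural syndrome) and
#' focal interstitial syndrome.
#'
#' @param profile one of `A_PROFILE`, `B_PROFILE_BILATERAL`, `B_FOCAL`,
#'   `C_PROFILE`, `B0_PROFILE`.
#' @param shred_sign shred sign present. Only meaningful with a
#'   consolidation (C) or B-type profile; rejected otherwise.
#' @param plaps PLAPS present.
#' @param focal_interstitial focal interstitial syndrome present.
#' @return An object of class `lus_exam`.
#' @export
#' @examples
#' lus_exam("C_PROFILE", shred_sign = TRUE)
lus_exam <- function(profile, shred_sign = FALSE, plaps = FALSE,
                     focal_interstitial = FALSE) {
  .match_enum(profile, .lus_profiles, "lus profile")
  .check_flag(shred_sign, "shred_sign")
  .check_flag(plaps, "plaps")
  .check_flag(focal_interstitial, "focal_interstitial")
  if (shred_sign && !profile %in% c("C_PROFILE", "B_PROFILE_BILATERAL",
                                    "B_FOCAL", "B0_PROFILE"))
    stop("shred_sign requires a C-profile or B-type profile", call. = FALSE)
  structure(list(profile = profile, shred_sign = shred_sign, plaps = plaps,
                 focal_interstitial = focal_interstitial),
            class = "lus_exam")
}

#' Transthoracic echocardiography exam
#'
#' @param lv_function left-ventricular contractility, `NORMAL` or
#'   `DYSFUNCTION`.
#' @param rv_dilated dilated right atrium/ventricle present.
#' @return An object of class `tte_exam`.
#' @export
tte_exam <- function(lv_function, rv_dilated = FALSE) {
  .match_enum(lv_function, .lv_levels, "lv_function")
  .check_flag(rv_dilated, "rv_dilated")
  structure(list(lv_function = lv_function, rv_dilated = rv_dilated),
            class = "tte_exam")
}

#' Chest X-ray findings
#'
#' Coded radiographic findings plus the pulse-oximetry hypoxia flag used by
#' the chest-X-ray triage algorithm. A normal film is mutually exclusive
#' with all three abnormality flags.
#'
#' @param air_bronchogram_or_opacity air bronchogram or air-space opacity.
#' @param bat_wing_or_cardiomegaly_or_hilar bat-wing shadowing, cardiomegaly
#'   or hilar prominence.
#' @param hyperinflation_tubular_heart_flat_diaphragm hyperinflated lungs,
#'   tubular heart or flattened diaphragm.
#' @param normal_film no radiographic abnormality.
#' @param spo2_hypoxia hypoxia on pulse oximetry. Accepted as a pre-coded
#'   flag; see [spo2_is_hypoxic()] for an optional SpO2-percentage helper.
#' @return An object of class `cxr_findings`.
#' @export
#' @examples
#' cxr_findings(normal_film = TRUE, spo2_hypoxia = TRUE)
cxr_findings <- function(air_bronchogram_or_opacity = FALSE,
                         bat_wing_or_cardiomegaly_or_hilar = FALSE,
                         hyperinflation_tubular_heart_flat_diaphragm = FALSE,
                         normal_film = FALSE,
                         spo2_hypoxia = FALSE) {
  .check_flag(air_bronchogram_or_opacity, "air_bronchogram_or_opacity")
  .check_flag(bat_wing_or_cardiomegaly_or_hilar,
              "bat_wing_or_cardiomegaly_or_hilar")
  .check_flag(hyperinflation_tubular_heart_flat_diaphragm,
              "hyperinflation_tubular_heart_flat_diaphragm")
  .check_flag(normal_film, "normal_film")
  .check_flag(spo2_hypoxia, "spo2_hypoxia")
  if (normal_film && (air_bronchogram_or_opacity ||
                      bat_wing_or_cardiomegaly_or_hilar ||
                      hyperinflation_tubular_heart_flat_diaphragm))
    stop("normal_film is mutually exclusive with the abnormality flags",
         call. = FALSE)
  structure(list(
    air_bronchogram_or_opacity = air_bronchogram_or_opacity,
    bat_wing_or_cardiomegaly_or_hilar = bat_wing_or_cardiomegaly_or_hilar,
    hyperinflation_tubular_heart_flat_diaphragm =
      hyperinflation_tubular_heart_flat_diaphragm,
    normal_film = normal_film,
    spo2_hypoxia = spo2_hypoxia), class = "cxr_findings")
}

#' Derive the pulse-oximetry hypoxia flag from an SpO2 percentage
#'
#' The triage rules consume a pre-coded hypoxia flag; when only a raw SpO2
#' reading is available this helper applies a configurable cut-off
#' (default SpO2 < 90\%).
#'
#' @param spo2 oxygen saturation, percent (0--100).
#' @param threshold saturation below which the patient is flagged hypoxic.
#' @return Logical flag.
#' @export
spo2_is_hypoxic <- function(spo2, threshold = 90) {
  if (!is.numeric(spo2) || any(is.na(spo2)) || any(spo2 < 0) || any(spo2 > 100))
    stop("spo2 must be in [0, 100] percent", call. = FALSE)
  spo2 < threshold
}

#' A patient's complete coded findings
#'
#' Bundles one patient's critical-care-ultrasonography components (lung
#' ultrasound, echo, IVC, DVT scan), arterial blood gas panel, and the
#' optional chest-X-ray findings into the record both classifiers consume.
#'
#' @param patient_id opaque identifier.
#' @param lus a [lus_exam()].
#' @param tte a [tte_exam()].
#' @param ivc IVC status: `COLLAPSED`, `DISTENDED` or `NOT_ASSESSED`.
#' @param dvt DVT compression-scan result: `POSITIVE`, `NEGATIVE` or
#'   `NOT_DONE`.
#' @param abg an [abg_panel()].
#' @param cxr an optional [cxr_findings()]; required only for
#'   [classify_cxr()].
#' @return An object of class `patient_findings`.
#' @export
#' @examples
#' p <- patient_findings("pt1",
#'   lus = lus_exam("B_PROFILE_BILATERAL"),
#'   tte = tte_exam("DYSFUNCTION"),
#'   ivc = "DISTENDED", dvt = "NEGATIVE",
#'   abg = abg_panel(pao2 = 50, paco2 = 40))
#' classify_ccus_abg(p)
patient_findings <- function(patient_id, lus, tte, ivc, dvt, abg, cxr = NULL) {
  if (missing(lus) || !inherits(lus, "lus_exam"))
    stop("precondition failed: lung ultrasound exam (lus) missing or invalid",
         call. = FALSE)
  if (missing(tte) || !inherits(tte, "tte_exam"))
    stop("precondition failed: echocardiography exam (tte) missing or invalid",
         call. = FALSE)
  if (missing(abg) || !inherits(abg, "abg_panel"))
    stop("precondition failed: blood gas panel (abg) missing or invalid",
         call. = FALSE)
  .match_enum(ivc, .ivc_levels, "ivc")
  .match_enum(dvt, .dvt_levels, "dvt")
  if (!is.null(cxr) && !inherits(cxr, "cxr_findings"))
    stop("cxr must be NULL or a cxr_findings object", call. = FALSE)
  structure(list(patient_id = as.character(patient_id), lus = lus, tte = tte,
                 ivc = ivc, dvt = dvt, abg = abg, cxr = cxr),
            class = "patient_findings")
}

#' @export
print.patient_findings <- function(x, ...) {
  cat("<patient_findings>", x$patient_id, "\n")
  cat("  LUS:", x$lus$profile,
      if (x$lus$shred_sign) "+shred" else "",
      if (x$lus$plaps) "+PLAPS" else "",
      if (x$lus$focal_interstitial) "+focal-interstitial" else "", "\n")
  cat("  TTE: LV", x$tte$lv_function,
      if (x$tte$rv_dilated) ", RV dilated" else "", "\n")
  cat("  IVC:", x$ivc, " DVT:", x$dvt, "\n")
  cat(sprintf("  ABG: PaO2 %.0f, PaCO2 %.0f, pH %.2f, HCO3 %.0f%s\n",
              x$abg$pao2, x$abg$paco2, x$abg$ph, x$abg$hco3,
              if (x$abg$on_room_air) " (room air)" else " (on O2)"))
  if (!is.null(x$cxr)) {
    on <- names(Filter(isTRUE, x$cxr))
    cat("  CxR:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}
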