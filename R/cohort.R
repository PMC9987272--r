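#' Calibrate a row-conditional confusion model from a count table
#'
#' Turns an observed index-vs-reference cross-tabulation into the sampling
#' model used by the synthetic-cohort generator: the reference-category
#' prevalence vector (column totals over n) and, for each reference
#' category, the conditional distribution of the index-algorithm label
#' (each column normalized by its total).
#'
#' @param ct a [crosstab()] in which every reference column has a positive
#'   total.
#' @return An object of class `confusion_model` with fields `categories`,
#'   `reference_prevalence` and `conditional` (K x K matrix,
#'   `conditional[i, j]` = P(index = i | reference = j); columns sum to 1).
#' @export
#' @examples
#' calibrate_confusion(arf_crosstab("table2_ccus"))
calibrate_confusion <- function(ct) {
  stopifnot(inherits(ct, "crosstab"))
  col_tot <- colSums(ct$counts)
  if (any(col_tot == 0))
    stop("empty reference column(s): ",
         paste(ct$categories[col_tot == 0], collapse = ", "), call. = FALSE)
  conditional <- sweep(ct$counts, 2, col_tot, "/")
  structure(list(categories = ct$categories,
                 reference_prevalence = col_tot / ct$n,
                 conditional = conditional),
            class = "confusion_model")
}

#' @export
print.confusion_model <- function(x, ...) {
  cat("<confusion_model>\n  reference prevalence:\n")
  print(round(x$reference_prevalence, 4))
  cat("  P(index | reference) by column:\n")
  print(round(x$conditional, 4))
  invisible(x)
}

# per-label CCUS finding templates; each satisfies exactly one rule branch
.ccus_template <- function(label) {
  hypox_pao2 <- function() runif(1, 35, 59.5)
  norm_pao2  <- function() runif(1, 60, 95)
  norm_paco2 <- function() runif(1, 30, 45)
  high_paco2 <- function() runif(1, 46, 80)
  low_paco2  <- function() runif(1, 25, 40)
  switch(label,
    ALVEOLAR_LUNG = {
      pattern <- sample(c("c_shred", "focal_interstitial", "b0", "a_plaps"),
                        1L)
      lus <- switch(pattern,
        c_shred = lus_exam("C_PROFILE", shred_sign = TRUE),
        focal_interstitial = lus_exam("B_FOCAL", focal_interstitial = TRUE),
        b0 = lus_exam("B0_PROFILE"),
        a_plaps = lus_exam("A_PROFILE", plaps = TRUE))
      list(lus = lus, tte = tte_exam("NORMAL"),
           ivc = sample(c("COLLAPSED", "DISTENDED"), 1L), dvt = "NEGATIVE",
           pao2 = hypox_pao2(), paco2 = norm_paco2(),
           ph = runif(1, 7.28, 7.46), hco3 = runif(1, 18, 28))
    },
    ALVEOLAR_CARDIAC = list(
      lus = lus_exam("B_PROFILE_BILATERAL"),
      tte = tte_exam("DYSFUNCTION"), ivc = "DISTENDED", dvt = "NEGATIVE",
      pao2 = hypox_pao2(), paco2 = norm_paco2(),
      ph = runif(1, 7.28, 7.46), hco3 = runif(1, 18, 28)),
    VENT_ALVEOLAR = list(
      lus = lus_exam(sample(c("B_FOCAL", "C_PROFILE"), 1L)),
      tte = tte_exam("NORMAL", rv_dilated = TRUE), ivc = "DISTENDED",
      dvt = "NEGATIVE", pao2 = hypox_pao2(), paco2 = high_paco2(),
      ph = runif(1, 7.18, 7.35), hco3 = runif(1, 24, 34)),
    PERFUSION = list(
      lus = lus_exam("A_PROFILE"),
      tte = tte_exam("NORMAL", rv_dilated = TRUE), ivc = "DISTENDED",
      dvt = "POSITIVE", pao2 = hypox_pao2(), paco2 = low_paco2(),
      ph = runif(1, 7.38, 7.52), hco3 = runif(1, 20, 26)),
    METABOLIC = list(
      lus = lus_exam("A_PROFILE"), tte = tte_exam("NORMAL"),
      ivc = "COLLAPSED", dvt = "NEGATIVE",
      pao2 = norm_pao2(), paco2 = low_paco2(),
      ph = runif(1, 7.02, 7.30), hco3 = runif(1, 8, 18)),
    stop("unknown label: ", label, call. = FALSE))
}

.cxr_template <- function(label) {
  switch(label,
    ALVEOLAR_LUNG = cxr_findings(air_bronchogram_or_opacity = TRUE,
                                 spo2_hypoxia = TRUE),
    ALVEOLAR_CARDIAC = cxr_findings(
      bat_wing_or_cardiomegaly_or_hilar = TRUE, spo2_hypoxia = TRUE),
    VENT_ALVEOLAR = cxr_findings(
      hyperinflation_tubular_heart_flat_diaphragm = TRUE,
      spo2_hypoxia = TRUE),
    PERFUSION = cxr_findings(normal_film = TRUE, spo2_hypoxia = TRUE),
    METABOLIC = cxr_findings(normal_film = TRUE, spo2_hypoxia = FALSE),
    stop("unknown label: ", label, call. = FALSE))
}

#' Construct a findings record that classifies to the requested labels
#'
#' Inverse of the rule engines: draws a patient-findings record from
#' per-label templates — with continuous blood-gas values jittered
#' uniformly inside the label's constraint region — such that
#' [classify_ccus_abg()] returns `ccus_label` and [classify_cxr()] returns
#' `cxr_label`. The two arms are filled independently, so all 25 label
#' pairs are realizable; the round trip is asserted before returning.
#'
#' @param ccus_label,cxr_label intended categories (one of
#'   [arf_categories()]).
#' @param patient_id identifier for the generated record.
#' @return A [patient_findings()] record. Uses the current RNG stream.
#' @export
#' @examples
#' set.seed(1)
#' findings_for_labels("METABOLIC", "METABOLIC")
findings_for_labels <- function(ccus_label, cxr_label,
                                patient_id = "synthetic") {
  .match_enum(ccus_label, arf_categories(), "ccus_label")
  .match_enum(cxr_label, arf_categories(), "cxr_label")
  tpl <- .ccus_template(ccus_label)
  p <- patient_findings(
    patient_id, lus = tpl$lus, tte = tpl$tte, ivc = tpl$ivc, dvt = tpl$dvt,
    abg = abg_panel(pao2 = tpl$pao2, paco2 = tpl$paco2, ph = tpl$ph,
                    hco3 = tpl$hco3, on_room_air = runif(1) < 0.06),
    cxr = .cxr_template(cxr_label))
  if (classify_ccus_abg(p) != ccus_label || classify_cxr(p) != cxr_label)
    stop("internal error: template failed the round trip for (",
         ccus_label, ", ", cxr_label, ")", call. = FALSE)
  p
}

# exact per-category counts for fixed-margin sampling (largest remainder)
.fixed_margin_counts <- function(n, prob) {
  raw <- n * prob
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Flatten a findings record to a one-row patient record
#'
#' @param p a [patient_findings()] record.
#' @return One-row data frame in the patient-record CSV schema.
#' @export
as_patient_record <- function(p) {
  stopifnot(inherits(p, "patient_findings"))
  cx <- p$cxr
  data.frame(
    patient_id = p$patient_id,
    lus_profile = p$lus$profile, shred_sign = p$lus$shred_sign,
    plaps = p$lus$plaps, focal_interstitial = p$lus$focal_interstitial,
    lv_function = p$tte$lv_function, rv_dilated = p$tte$rv_dilated,
    ivc_status = p$ivc, dvt_result = p$dvt,
    pao2 = p$abg$pao2, paco2 = p$abg$paco2, ph = p$abg$ph,
    hco3 = p$abg$hco3, on_room_air = p$abg$on_room_air,
    cxr_air_bronchogram_or_opacity =
      if (is.null(cx)) NA else cx$air_bronchogram_or_opacity,
    cxr_bat_wing_or_cardiomegaly_or_hilar =
      if (is.null(cx)) NA else cx$bat_wing_or_cardiomegaly_or_hilar,
    cxr_hyperinflation_tubular_heart_flat_diaphragm =
      if (is.null(cx)) NA else cx$hyperinflation_tubular_heart_flat_diaphragm,
    cxr_normal_film = if (is.null(cx)) NA else cx$normal_film,
    spo2_hypoxia = if (is.null(cx)) NA else cx$spo2_hypoxia,
    stringsAsFactors = FALSE)
}

#' Rebuild a findings record from a one-row patient record
#'
#' Accepts a named list or one-row data frame in the patient-record CSV
#' schema (booleans coded `true`/`false`, missing values as empty cells /
#' `NA`). Chest-X-ray fields may be absent entirely, in which case the
#' record supports only CCUS classification.
#'
#' @param row named list or one-row data frame.
#' @return A [patient_findings()] record.
#' @export
patient_findings_from_record <- function(row) {
  row <- as.list(row)
  need <- function(field) {
    v <- row[[field]]
    if (is.null(v) || (length(v) == 1L && is.na(v)))
      stop("precondition failed: missing field '", field, "'", call. = FALSE)
    v
  }
  flag <- function(v) {
    if (is.logical(v)) return(v)
    v <- tolower(as.character(v))
    if (!v %in% c("true", "false"))
      stop("boolean field must be true/false, got: ", v, call. = FALSE)
    v == "true"
  }
  cxr_fields <- c("cxr_air_bronchogram_or_opacity",
                  "cxr_bat_wing_or_cardiomegaly_or_hilar",
                  "cxr_hyperinflation_tubular_heart_flat_diaphragm",
                  "cxr_normal_film", "spo2_hypoxia")
  have_cxr <- all(vapply(cxr_fields, function(f)
    !is.null(row[[f]]) && !(length(row[[f]]) == 1L && is.na(row[[f]])),
    logical(1)))
  cxr <- if (have_cxr) cxr_findings(
    air_bronchogram_or_opacity = flag(row$cxr_air_bronchogram_or_opacity),
    bat_wing_or_cardiomegaly_or_hilar =
      flag(row$cxr_bat_wing_or_cardiomegaly_or_hilar),
    hyperinflation_tubular_heart_flat_diaphragm =
      flag(row$cxr_hyperinflation_tubular_heart_flat_diaphragm),
    normal_film = flag(row$cxr_normal_film),
    spo2_hypoxia = flag(row$spo2_hypoxia)) else NULL
  patient_findings(
    patient_id = if (is.null(row$patient_id)) "unknown" else row$patient_id,
    lus = lus_exam(need("lus_profile"),
                   shred_sign = flag(need("shred_sign")),
                   plaps = flag(need("plaps")),
                   focal_interstitial = flag(need("focal_interstitial"))),
    tte = tte_exam(need("lv_function"),
                   rv_dilated = flag(need("rv_dilated"))),
    ivc = need("ivc_status"), dvt = need("dvt_result"),
    abg = abg_panel(pao2 = as.numeric(need("pao2")),
                    paco2 = as.numeric(need("paco2")),
                    ph = as.numeric(need("ph")),
                    hco3 = as.numeric(need("hco3")),
                    on_room_air = flag(need("on_room_air"))),
    cxr = cxr)
}

#' Generate a synthetic dyspneic-ICU cohort
#'
#' Draws a cohort with the statistical structure of the validation study:
#' composite (true) diagnoses from the reference prevalence of
#' `model_ccus`, then a CCUS+ABG label and a chest-X-ray label for each
#' patient from the respective reference-conditional misclassification
#' distributions (independently given the true category, since the printed
#' data identify only the two margins, not the three-way table), and
#' finally a findings record realizing both intended labels via
#' [findings_for_labels()]. Demographics (age, sex, SOFA) are sampled from
#' the published cohort margins and carried as passengers; the classifiers
#' never read them.
#'
#' @param n cohort size (>= 1).
#' @param model_ccus a [calibrate_confusion()] model for the CCUS+ABG arm.
#' @param model_cxr confusion model for the chest-X-ray arm; defaults to
#'   `model_ccus`.
#' @param sampling_mode `"multinomial"` (true categories drawn i.i.d.) or
#'   `"fixed_margins"` (exact per-category counts by largest remainder).
#' @param seed optional integer; when given, the RNG is seeded so the
#'   cohort is fully reproducible.
#' @param demographics attach age/sex/SOFA columns.
#' @return A data frame with one row per patient: `true_category`,
#'   `ccus_label`, `cxr_label`, optional demographics, and the full
#'   patient-record schema of [as_patient_record()]. The intended labels
#'   are guaranteed to round-trip through the classifiers.
#' @export
#' @examples
#' m <- calibrate_confusion(arf_crosstab("table2_ccus"))
#' cohort <- sample_cohort(20, m, seed = 1)
#' table(cohort$true_category)
sample_cohort <- function(n, model_ccus, model_cxr = model_ccus,
                          sampling_mode = c("multinomial", "fixed_margins"),
                          seed = NULL, demographics = TRUE) {
  sampling_mode <- match.arg(sampling_mode)
  stopifnot(inherits(model_ccus, "confusion_model"),
            inherits(model_cxr, "confusion_model"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  categories <- model_ccus$categories
  true_category <- if (sampling_mode == "multinomial") {
    sample(categories, n, replace = TRUE,
           prob = model_ccus$reference_prevalence)
  } else {
    counts <- .fixed_margin_counts(n, model_ccus$reference_prevalence)
    sample(rep(categories, counts))
  }
  draw_labels <- function(model) {
    out <- character(n)
    for (j in model$categories) {
      hit <- true_category == j
      if (any(hit))
        out[hit] <- sample(model$categories, sum(hit), replace = TRUE,
                           prob = model$conditional[, j])
    }
    out
  }
  ccus_label <- draw_labels(model_ccus)
  cxr_label <- draw_labels(model_cxr)
  ids <- sprintf("synth-%0*d", nchar(n), seq_len(n))
  plist <- lapply(seq_len(n), function(i)
    findings_for_labels(ccus_label[i], cxr_label[i], patient_id = ids[i]))
  chr <- function(f) vapply(plist, f, character(1))
  num <- function(f) vapply(plist, f, numeric(1))
  lgl <- function(f) vapply(plist, f, logical(1))
  records <- data.frame(
    patient_id = ids,
    lus_profile = chr(function(p) p$lus$profile),
    shred_sign = lgl(function(p) p$lus$shred_sign),
    plaps = lgl(function(p) p$lus$plaps),
    focal_interstitial = lgl(function(p) p$lus$focal_interstitial),
    lv_function = chr(function(p) p$tte$lv_function),
    rv_dilated = lgl(function(p) p$tte$rv_dilated),
    ivc_status = chr(function(p) p$ivc),
    dvt_result = chr(function(p) p$dvt),
    pao2 = num(function(p) p$abg$pao2),
    paco2 = num(function(p) p$abg$paco2),
    ph = num(function(p) p$abg$ph),
    hco3 = num(function(p) p$abg$hco3),
    on_room_air = lgl(function(p) p$abg$on_room_air),
    cxr_air_bronchogram_or_opacity =
      lgl(function(p) p$cxr$air_bronchogram_or_opacity),
    cxr_bat_wing_or_cardiomegaly_or_hilar =
      lgl(function(p) p$cxr$bat_wing_or_cardiomegaly_or_hilar),
    cxr_hyperinflation_tubular_heart_flat_diaphragm =
      lgl(function(p) p$cxr$hyperinflation_tubular_heart_flat_diaphragm),
    cxr_normal_film = lgl(function(p) p$cxr$normal_film),
    spo2_hypoxia = lgl(function(p) p$cxr$spo2_hypoxia),
    stringsAsFactors = FALSE)
  meta <- data.frame(true_category = true_category,
                     ccus_label = ccus_label, cxr_label = cxr_label,
                     stringsAsFactors = FALSE)
  if (demographics) {
    meta$age <- pmin(pmax(round(rnorm(n, 51, 17)), 18), 95)
    meta$sex <- sample(c("M", "F"), n, replace = TRUE,
                       prob = c(0.615, 0.385))
    meta$sofa <- pmin(pmax(round(rlnorm(n, log(6), 0.66)), 0), 24)
  }
  cbind(records[, "patient_id", drop = FALSE], meta,
        records[, setdiff(names(records), "patient_id")])
}

#' Write a cohort (or any patient-record table) as CSV
#'
#' Booleans are written as lowercase `true`/`false` and missing values as
#' empty cells, matching the record schema read by [run_classify()].
#'
#' @param cohort data frame from [sample_cohort()] or compatible.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (nm in names(out))
    if (is.logical(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), "",
                          ifelse(out[[nm]], "true", "false"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
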