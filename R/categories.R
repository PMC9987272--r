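#' Pathophysiological diagnostic categories
#'
#' The five-category scheme used by both triage algorithms: pneumonia
#' (`ALVEOLAR_LUNG`), cardiogenic pulmonary oedema (`ALVEOLAR_CARDIAC`),
#' acute exacerbation of COPD (`VENT_ALVEOLAR`), pulmonary embolism
#' (`PERFUSION`) and metabolic causes of dyspnoea (`METABOLIC`).
#' `UNCLASSIFIED` is emitted when a record matches no rule branch; it is
#' never an intended label.
#'
#' @param with_unclassified include the `UNCLASSIFIED` sentinel.
#' @return Character vector of category codes, in fixed display order.
#' @export
#' @examples
#' arf_categories()
arf_categories <- function(with_unclassified = FALSE) {
  base <- c("ALVEOLAR_LUNG", "ALVEOLAR_CARDIAC", "VENT_ALVEOLAR",
            "PERFUSION", "METABOLIC")
  if (with_unclassified) c(base, "UNCLASSIFIED") else base
}

#' Human-readable labels for the diagnostic categories
#'
#' @return Named character vector mapping category codes to display labels.
#' @export
arf_category_labels <- function() {
  c(ALVEOLAR_LUNG    = "Alveolar (lung) defect",
    ALVEOLAR_CARDIAC = "Alveolar (cardiac) defect",
    VENT_ALVEOLAR    = "Ventilation plus alveolar defect",
    PERFUSION        = "Perfusion defect",
    METABOLIC        = "Metabolic defect",
    UNCLASSIFIED     = "Unclassified")
}

# enumerations shared by the finding constructors
.lus_profiles <- c("A_PROFILE", "B_PROFILE_BILATERAL", "B_FOCAL",
                   "C_PROFILE", "B0_PROFILE")
.ivc_levels <- c("COLLAPSED", "DISTENDED", "NOT_ASSESSED")
.dvt_levels <- c("POSITIVE", "NEGATIVE", "NOT_DONE")
.lv_levels  <- c("NORMAL", "DYSFUNCTION")

.match_enum <- function(value, levels, what) {
  if (length(value) != 1L || is.na(value) || !value %in% levels)
    stop(sprintf("%s must be one of %s (got %s)", what,
                 paste(levels, collapse = ", "),
                 if (length(value) == 1L) as.character(value) else
                   sprintf("a length-%d vector", length(value))),
         call. = FALSE)
  value
}

.check_flag <- function(value, what) {
  if (length(value) != 1L || is.na(value) || !is.logical(value))
    stop(sprintf("%s must be a single TRUE/FALSE", what), call. = FALSE)
  value
}
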