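#' Batch-classify a patient-record table
#'
#' Runs one or both triage rule engines over a table of coded patient
#' records (a data frame or a CSV path in the schema of
#' [as_patient_record()]) and appends the predicted category column(s).
#' Rows that fail schema validation are reported, not silently dropped:
#' their predictions are `NA` and the offending message is kept in an
#' error column.
#'
#' @param input data frame or CSV file path.
#' @param algorithm `"both"`, `"ccus"` or `"cxr"`.
#' @param config a [triage_config()].
#' @param output optional CSV path for the labeled table.
#' @return The input table with appended columns `ccus_class` /
#'   `cxr_class`, matching `*_reason` columns (reason codes for
#'   `UNCLASSIFIED` rows) and a `row_error` column (`NA` when the row is
#'   valid). Attribute `n_errors` counts invalid rows.
#' @export
#' @examples
#' m <- calibrate_confusion(arf_crosstab("table2_ccus"))
#' run_classify(sample_cohort(5, m, seed = 1))[, c("ccus_class", "cxr_class")]
run_classify <- function(input, algorithm = c("both", "ccus", "cxr"),
                         config = triage_config(), output = NULL) {
  algorithm <- match.arg(algorithm)
  df <- if (is.character(input))
    utils::read.csv(input, stringsAsFactors = FALSE) else input
  if (!is.data.frame(df)) stop("input must be a data frame or CSV path",
                               call. = FALSE)
  n <- nrow(df)
  if (n == 0L) warning("empty input: no rows to classify")
  want_ccus <- algorithm %in% c("both", "ccus")
  want_cxr <- algorithm %in% c("both", "cxr")
  ccus_class <- ccus_reason <- cxr_class <- cxr_reason <-
    row_error <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- tryCatch(patient_findings_from_record(df[i, , drop = FALSE]),
                  error = function(e) e)
    if (inherits(p, "error")) { row_error[i] <- conditionMessage(p); next }
    if (want_ccus) {
      ccus_class[i] <- classify_ccus_abg(p, config)
      ccus_reason[i] <- unclassified_reason(p, "ccus", config)
    }
    if (want_cxr) {
      res <- tryCatch({
        cl <- classify_cxr(p, config)
        c(cl, unclassified_reason(p, "cxr", config))
      }, error = function(e) c(NA_character_, conditionMessage(e)))
      cxr_class[i] <- res[1]; cxr_reason[i] <- res[2]
    }
  }
  if (want_ccus) { df$ccus_class <- ccus_class; df$ccus_reason <- ccus_reason }
  if (want_cxr) { df$cxr_class <- cxr_class; df$cxr_reason <- cxr_reason }
  df$row_error <- row_error
  attr(df, "n_errors") <- sum(!is.na(row_error))
  if (!is.null(output)) write_cohort_csv(df, output)
  df
}

#' Full agreement / diagnostic-accuracy report for a labeled table
#'
#' Builds, from a table carrying a reference column and one or two
#' prediction columns, the complete validation report: the
#' cross-tabulation(s), per-category diagnostic properties and kappa for
#' each prediction column against the reference, the head-to-head
#' cross-tabulation and kappa between the two prediction columns, and
#' McNemar's test on paired per-patient correctness when both predictions
#' are present.
#'
#' @param labeled data frame (e.g. output of [run_classify()] on a cohort
#'   with ground truth, or a generated cohort).
#' @param reference name of the reference (composite-diagnosis) column.
#' @param predictions named character vector of prediction columns, e.g.
#'   `c(ccus = "ccus_class", cxr = "cxr_class")`. Names label the report.
#' @param level confidence level.
#' @param categories category set; rows with labels outside it (e.g.
#'   `UNCLASSIFIED`) raise an error so exclusions are always explicit.
#' @return An object of class `study_report`: list with `n`,
#'   `comparisons` (per prediction: `crosstab` + `evaluation`),
#'   `head_to_head` (when two predictions) and `mcnemar`.
#' @export
#' @examples
#' m <- calibrate_confusion(arf_crosstab("table2_ccus"))
#' cohort <- sample_cohort(120, m, seed = 7)
#' run_evaluate(cohort, reference = "true_category",
#'              predictions = c(ccus = "ccus_label", cxr = "cxr_label"))
run_evaluate <- function(labeled, reference = "true_category",
                         predictions = c(ccus = "ccus_class",
                                         cxr = "cxr_class"),
                         level = 0.95, categories = arf_categories()) {
  if (!reference %in% names(labeled))
    stop("reference column '", reference, "' not found", call. = FALSE)
  predictions <- predictions[predictions %in% names(labeled)]
  if (!length(predictions))
    stop("no prediction column found", call. = FALSE)
  comparisons <- lapply(predictions, function(col) {
    ct <- build_crosstab(labeled[[col]], labeled[[reference]], categories)
    list(crosstab = ct, evaluation = evaluate_algorithm(ct, level = level))
  })
  head_to_head <- NULL
  mcnemar <- NULL
  if (length(predictions) >= 2) {
    a <- predictions[[1]]; b <- predictions[[2]]
    ct_hh <- build_crosstab(labeled[[b]], labeled[[a]], categories)
    head_to_head <- list(
      index = names(predictions)[2], reference_algorithm =
        names(predictions)[1],
      crosstab = ct_hh, evaluation = evaluate_algorithm(ct_hh, level = level))
    mcnemar <- mcnemar_test(labeled[[a]] == labeled[[reference]],
                            labeled[[b]] == labeled[[reference]])
  }
  structure(list(n = nrow(labeled), level = level,
                 comparisons = comparisons, head_to_head = head_to_head,
                 mcnemar = mcnemar),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> n = %d, level = %.0f%%\n",
              x$n, 100 * x$level))
  for (nm in names(x$comparisons)) {
    cat("\n==", nm, "vs reference ==\n")
    print(x$comparisons[[nm]]$evaluation)
  }
  if (!is.null(x$head_to_head)) {
    cat(sprintf("\n== %s vs %s (head to head) ==\n",
                x$head_to_head$index, x$head_to_head$reference_algorithm))
    print(x$head_to_head$evaluation)
  }
  if (!is.null(x$mcnemar)) {
    cat("\n== McNemar (paired correctness) ==\n")
    print(x$mcnemar)
  }
  invisible(x)
}

.evaluation_as_list <- function(ev) {
  list(n = attr(ev, "n"),
       percent_agreement = attr(ev, "percent_agreement"),
       overall_kappa = attr(ev, "overall_kappa")$kappa,
       per_category = as.data.frame(ev))
}

#' Serialize a study report
#'
#' Writes the report as JSON (full precision) and/or a tab-separated table
#' (percentages to 2 decimal places, kappa to 4, the convention of the
#' published tables).
#'
#' @param report a `study_report` from [run_evaluate()].
#' @param json optional JSON output path.
#' @param tsv optional TSV output path.
#' @return Invisibly, the report.
#' @export
write_report <- function(report, json = NULL, tsv = NULL) {
  stopifnot(inherits(report, "study_report"))
  if (!is.null(json)) {
    payload <- list(
      n = report$n, level = report$level,
      comparisons = lapply(report$comparisons, function(cmp)
        .evaluation_as_list(cmp$evaluation)))
    if (!is.null(report$head_to_head))
      payload$head_to_head <- .evaluation_as_list(
        report$head_to_head$evaluation)
    if (!is.null(report$mcnemar))
      payload$mcnemar <- report$mcnemar[c("b", "c", "statistic", "p_value",
                                          "continuity_corrected", "exact")]
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  if (!is.null(tsv)) {
    fmt_pct <- function(p, lo, hi)
      ifelse(is.na(p), "",
             sprintf("%.2f%% (%.2f-%.2f)", 100 * p, 100 * lo, 100 * hi))
    rows <- do.call(rbind, lapply(names(report$comparisons), function(nm) {
      ev <- report$comparisons[[nm]]$evaluation
      data.frame(comparison = nm, category = ev$category,
                 sensitivity = fmt_pct(ev$sensitivity, ev$sens_lower,
                                       ev$sens_upper),
                 specificity = fmt_pct(ev$specificity, ev$spec_lower,
                                       ev$spec_upper),
                 ppv = fmt_pct(ev$ppv, ev$ppv_lower, ev$ppv_upper),
                 kappa = sprintf("%.4f (%.4f-%.4f)", ev$kappa,
                                 ev$kappa_lower, ev$kappa_upper),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(report)
}

#' Rebuild the published validation tables from the packaged fixtures
#'
#' Expands the three packaged count tables ([arf_crosstab()]) to item-level
#' label pairs, re-tabulates them, and computes every per-category accuracy
#' and agreement statistic — the end-to-end golden path for the published
#' validation of the two triage algorithms in 174 dyspneic ICU patients.
#'
#' @param level confidence level.
#' @return A list of three [evaluate_algorithm()] tables:
#'   `ccus_vs_composite`, `cxr_vs_composite`, `cxr_vs_ccus`.
#' @export
#' @examples
#' rep <- reproduce_study()
#' rep$ccus_vs_composite
reproduce_study <- function(level = 0.95) {
  rebuild <- function(name) {
    pairs <- expand_crosstab_to_pairs(arf_crosstab(name))
    build_crosstab(pairs$index, pairs$reference)
  }
  list(ccus_vs_composite = evaluate_algorithm(rebuild("table2_ccus"),
                                              level = level),
       cxr_vs_composite = evaluate_algorithm(rebuild("table2_cxr"),
                                             level = level),
       cxr_vs_ccus = evaluate_algorithm(rebuild("table3_cxr_vs_ccus"),
                                        level = level))
}
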