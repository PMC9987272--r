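#' Wilson score interval for a binomial proportion
#'
#' Confidence interval obtained by inverting the normal-approximation score
#' test, without continuity correction. Unlike the Wald interval it is
#' well-behaved at proportions near 0 or 1 and never escapes \[0, 1\],
#' which matters here because several one-vs-rest confusion tables have
#' empty off-diagonal cells.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param level confidence level in (0, 1).
#' @return Named numeric vector `c(lower, upper)` with attribute `level`.
#' @export
#' @examples
#' wilson_interval(54, 63)   # sensitivity 85.71%, CI approx (0.750, 0.923)
wilson_interval <- function(successes, n, level = 0.95) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive count", call. = FALSE)
  if (length(successes) != 1L || is.na(successes) ||
      successes < 0 || successes > n)
    stop("successes must lie in [0, n]", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  out <- c(lower = max(0, centre - half), upper = min(1, centre + half))
  attr(out, "level") <- level
  out
}

.undef <- function() c(lower = NA_real_, upper = NA_real_)

#' Diagnostic test properties of a binary confusion table
#'
#' Sensitivity, specificity, predictive values and likelihood ratios, each
#' proportion accompanied by a Wilson score interval. Fields whose
#' denominator is zero are returned as `NA` rather than raising an error,
#' so degenerate one-vs-rest tables (e.g. a category never called by the
#' index test) still produce a report row.
#'
#' @param bc a [binary_confusion()].
#' @param level confidence level for the Wilson intervals.
#' @param zero_cell_correction apply the Haldane--Anscombe 0.5 continuity
#'   correction to the likelihood-ratio cells when a zero cell would make
#'   the ratio infinite. Off by default: a specificity of exactly 1 then
#'   reports `lr_pos = Inf`.
#' @return An object of class `diagnostic_properties`: a list with point
#'   estimates, intervals (`*_ci`), `lr_pos`, `lr_neg`, `prevalence` and
#'   the input cells.
#' @export
#' @examples
#' diagnostic_properties(binary_confusion(tp = 54, fp = 15, fn = 9, tn = 96))
diagnostic_properties <- function(bc, level = 0.95,
                                  zero_cell_correction = FALSE) {
  stopifnot(inherits(bc, "binary_confusion"))
  prop <- function(x, m) if (m >= 1) x / m else NA_real_
  ci <- function(x, m) if (m >= 1) wilson_interval(x, m, level) else .undef()
  sens <- prop(bc$tp, bc$tp + bc$fn)
  spec <- prop(bc$tn, bc$tn + bc$fp)
  lr <- function(num, den, cells) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) {
      if (!zero_cell_correction) return(Inf)
      # Haldane-Anscombe: add 0.5 to every cell and recompute
      tp <- bc$tp + 0.5; fp <- bc$fp + 0.5
      fn <- bc$fn + 0.5; tn <- bc$tn + 0.5
      s1 <- tp / (tp + fn); s2 <- tn / (tn + fp)
      return(if (cells == "pos") s1 / (1 - s2) else (1 - s1) / s2)
    }
    num / den
  }
  structure(list(
    sensitivity = sens, sensitivity_ci = ci(bc$tp, bc$tp + bc$fn),
    specificity = spec, specificity_ci = ci(bc$tn, bc$tn + bc$fp),
    ppv = prop(bc$tp, bc$tp + bc$fp),
    ppv_ci = ci(bc$tp, bc$tp + bc$fp),
    npv = prop(bc$tn, bc$tn + bc$fn),
    npv_ci = ci(bc$tn, bc$tn + bc$fn),
    lr_pos = lr(sens, 1 - spec, "pos"),
    lr_neg = lr(1 - sens, spec, "neg"),
    prevalence = (bc$tp + bc$fn) / bc$n,
    level = level, cells = bc), class = "diagnostic_properties")
}

#' @export
print.diagnostic_properties <- function(x, digits = 2, ...) {
  pct <- function(p, ci) {
    if (is.na(p)) return("  --")
    sprintf("%.*f%% (%.*f-%.*f)", digits, 100 * p,
            digits, 100 * ci[["lower"]], digits, 100 * ci[["upper"]])
  }
  cat("<diagnostic_properties>",
      if (!is.null(x$cells$category)) paste0("(", x$cells$category, ")"), "\n")
  cat("  sensitivity:", pct(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  specificity:", pct(x$specificity, x$specificity_ci), "\n")
  cat("  PPV:        ", pct(x$ppv, x$ppv_ci), "\n")
  cat("  NPV:        ", pct(x$npv, x$npv_ci), "\n")
  cat(sprintf("  LR+: %.3f  LR-: %.3f  prevalence: %.3f\n",
              x$lr_pos, x$lr_neg, x$prevalence))
  invisible(x)
}

# Fleiss-Cohen-Everitt large-sample variance factor of Cohen's kappa:
# Q such that var(kappa-hat) ~= Q / n, from a matrix of cell proportions.
.fce_Q <- function(P) {
  pr <- rowSums(P); pc <- colSums(P)
  po <- sum(diag(P)); pe <- sum(pr * pc)
  if (1 - pe < .Machine$double.eps^0.5) return(NA_real_)
  A <- sum(diag(P) * ((1 - pe) - (pr + pc) * (1 - po))^2)
  B <- 0
  K <- nrow(P)
  for (i in seq_len(K)) for (j in seq_len(K))
    if (i != j) B <- B + P[i, j] * (pc[i] + pr[j])^2
  B <- (1 - po)^2 * B
  C <- (po * pe - 2 * pe + po)^2
  (A + B - C) / (1 - pe)^4
}

.kappa_from_probs <- function(P, n, level, se_method) {
  pr <- rowSums(P); pc <- colSums(P)
  po <- sum(diag(P)); pe <- sum(pr * pc)
  if (1 - pe < .Machine$double.eps^0.5)
    return(structure(list(kappa = NA_real_, po = po, pe = pe,
                          se = NA_real_, ci = .undef(), n = n,
                          level = level, se_method = se_method),
                     class = "kappa_result"))
  kappa <- (po - pe) / (1 - pe)
  se <- switch(se_method,
    fce = { q <- .fce_Q(P); if (is.na(q) || q < 0) NA_real_
            else sqrt(q / n) },
    agreement = sqrt(po * (1 - po) / (n * (1 - pe)^2)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- if (is.na(se)) .undef() else
    c(lower = kappa - z * se, upper = kappa + z * se)  # untruncated
  structure(list(kappa = kappa, po = po, pe = pe, se = se, ci = ci,
                 n = n, level = level, se_method = se_method),
            class = "kappa_result")
}

#' Cohen's kappa with an asymptotic confidence interval
#'
#' Chance-corrected agreement, `(po - pe) / (1 - pe)`, for a 2x2
#' [binary_confusion()] (one-vs-rest agreement on a single category) or a
#' K x K [crosstab()] (overall agreement beyond chance). Two standard-error
#' formulas are available: the Fleiss--Cohen--Everitt large-sample variance
#' (default) and the simpler agreement-variance formula
#' `sqrt(po (1 - po) / (n (1 - pe)^2))`. Interval endpoints are reported
#' untruncated, so an upper limit may exceed 1 for strong agreement on a
#' small sample.
#'
#' @param x a [binary_confusion()], [crosstab()] or square count matrix.
#' @param level confidence level.
#' @param se_method `"fce"` (Fleiss--Cohen--Everitt) or `"agreement"`.
#' @param ... passed between methods.
#' @return An object of class `kappa_result` with fields `kappa`, `po`,
#'   `pe`, `se`, `ci`, `n`.
#' @export
#' @examples
#' cohen_kappa(binary_confusion(tp = 54, fp = 15, fn = 9, tn = 96))
cohen_kappa <- function(x, level = 0.95, se_method = c("fce", "agreement"),
                        ...) {
  UseMethod("cohen_kappa")
}

#' @rdname cohen_kappa
#' @export
cohen_kappa.binary_confusion <- function(x, level = 0.95,
                                         se_method = c("fce", "agreement"),
                                         ...) {
  se_method <- match.arg(se_method)
  if (x$n < 2) stop("kappa requires n >= 2", call. = FALSE)
  P <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2) / x$n
  out <- .kappa_from_probs(P, x$n, level, se_method)
  out$category <- x$category
  out
}

#' @rdname cohen_kappa
#' @export
cohen_kappa.crosstab <- function(x, level = 0.95,
                                 se_method = c("fce", "agreement"), ...) {
  se_method <- match.arg(se_method)
  if (x$n < 2) stop("kappa requires n >= 2", call. = FALSE)
  .kappa_from_probs(x$counts / x$n, x$n, level, se_method)
}

#' @rdname cohen_kappa
#' @export
cohen_kappa.matrix <- function(x, level = 0.95,
                               se_method = c("fce", "agreement"), ...) {
  cohen_kappa(crosstab(x, categories = rownames(x) %||% as.character(
    seq_len(nrow(x)))), level = level, se_method = se_method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "<kappa_result>%s kappa = %.4f (%.4f-%.4f), po = %.4f, pe = %.4f, n = %d\n",
    if (!is.null(x$category)) paste0(" (", x$category, ")") else "",
    x$kappa, x$ci[["lower"]], x$ci[["upper"]], x$po, x$pe, x$n))
  invisible(x)
}

#' McNemar's test for paired classifier accuracy
#'
#' Compares the per-patient correctness of two algorithms applied to the
#' same patients, using only the discordant pairs: `b` patients correct
#' under the first but not the second, `c` the reverse. The chi-square
#' statistic is `(|b - c| - 1)^2 / (b + c)` with continuity correction
#' (default) or `(b - c)^2 / (b + c)` without, on 1 df. For few discordant
#' pairs an exact two-sided binomial test is available and is chosen
#' automatically when `exact = NULL` and `b + c < 25`.
#'
#' @param correct_a,correct_b logical vectors of equal length: was each
#'   patient correctly classified by algorithm A / algorithm B?
#' @param continuity apply the continuity correction.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   binomial p-value.
#' @return An object of class `mcnemar_result` with fields `b`, `c`,
#'   `statistic`, `p_value`, `continuity_corrected`, `exact`.
#' @export
#' @examples
#' mcnemar_test(c(TRUE, TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE, TRUE))
mcnemar_test <- function(correct_a, correct_b, continuity = TRUE,
                         exact = NULL) {
  if (length(correct_a) != length(correct_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(correct_a) < 1L)
    stop("need at least one pair", call. = FALSE)
  b <- sum(correct_a & !correct_b)
  c_ <- sum(!correct_a & correct_b)
  mcnemar_from_counts(b, c_, continuity = continuity, exact = exact)
}

#' @rdname mcnemar_test
#' @param b,c discordant-pair counts.
#' @export
mcnemar_from_counts <- function(b, c, continuity = TRUE, exact = NULL) {
  if (b < 0 || c < 0) stop("counts must be non-negative", call. = FALSE)
  nd <- b + c
  use_exact <- if (is.null(exact)) nd > 0 && nd < 25 else isTRUE(exact)
  if (nd == 0) {
    statistic <- 0; p <- 1
  } else if (use_exact) {
    statistic <- NA_real_
    p <- min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
  } else {
    statistic <- if (continuity) (abs(b - c) - 1)^2 / nd else (b - c)^2 / nd
    if (continuity && abs(b - c) < 1) statistic <- 0
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  }
  structure(list(b = b, c = c, statistic = statistic, p_value = p,
                 continuity_corrected = continuity && !use_exact && nd > 0,
                 exact = use_exact), class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat("<mcnemar_result> b =", x$b, ", c =", x$c)
  if (x$exact) cat(", exact binomial")
  else cat(sprintf(", chi-square = %.4f%s", x$statistic,
                   if (x$continuity_corrected) " (continuity-corrected)"
                   else ""))
  cat(sprintf(", p = %.4g\n", x$p_value))
  invisible(x)
}

#' Per-category diagnostic accuracy of a classification algorithm
#'
#' For each category of a cross-tabulation, reduces to the one-vs-rest
#' confusion table and computes [diagnostic_properties()] and
#' [cohen_kappa()]; also records the overall percent agreement and
#' overall (multi-category) kappa.
#'
#' @param ct a [crosstab()] of index-test vs reference labels.
#' @param level confidence level.
#' @param se_method kappa standard-error method, see [cohen_kappa()].
#' @return An object of class `algorithm_evaluation`: a data frame with one
#'   row per category (cells, sensitivity/specificity/PPV/NPV with interval
#'   bounds, likelihood ratios, prevalence, kappa with interval bounds),
#'   with attributes `percent_agreement`, `overall_kappa`, `n` and `level`.
#' @export
#' @examples
#' evaluate_algorithm(arf_crosstab("table2_ccus"))
evaluate_algorithm <- function(ct, level = 0.95,
                               se_method = c("fce", "agreement")) {
  stopifnot(inherits(ct, "crosstab"))
  se_method <- match.arg(se_method)
  rows <- lapply(ct$categories, function(category) {
    bc <- dichotomize(ct, category)
    dp <- diagnostic_properties(bc, level = level)
    kp <- cohen_kappa(bc, level = level, se_method = se_method)
    data.frame(
      category = category, tp = bc$tp, fp = bc$fp, fn = bc$fn, tn = bc$tn,
      sensitivity = dp$sensitivity,
      sens_lower = dp$sensitivity_ci[["lower"]],
      sens_upper = dp$sensitivity_ci[["upper"]],
      specificity = dp$specificity,
      spec_lower = dp$specificity_ci[["lower"]],
      spec_upper = dp$specificity_ci[["upper"]],
      ppv = dp$ppv, ppv_lower = dp$ppv_ci[["lower"]],
      ppv_upper = dp$ppv_ci[["upper"]],
      npv = dp$npv, npv_lower = dp$npv_ci[["lower"]],
      npv_upper = dp$npv_ci[["upper"]],
      lr_pos = dp$lr_pos, lr_neg = dp$lr_neg,
      prevalence = dp$prevalence,
      kappa = kp$kappa, kappa_se = kp$se,
      kappa_lower = kp$ci[["lower"]], kappa_upper = kp$ci[["upper"]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "percent_agreement") <- percent_agreement(ct)
  attr(out, "overall_kappa") <- cohen_kappa(ct, level = level,
                                            se_method = se_method)
  attr(out, "n") <- ct$n
  attr(out, "level") <- level
  class(out) <- c("algorithm_evaluation", "data.frame")
  out
}

#' @export
print.algorithm_evaluation <- function(x, ...) {
  cat(sprintf("<algorithm_evaluation> n = %d, agreement = %.2f%%, overall kappa = %.4f\n\n",
              attr(x, "n"), 100 * attr(x, "percent_agreement"),
              attr(x, "overall_kappa")$kappa))
  fmt <- function(p, lo, hi)
    ifelse(is.na(p), "--",
           sprintf("%.2f%% (%.2f-%.2f)", 100 * p, 100 * lo, 100 * hi))
  disp <- data.frame(
    category = x$category,
    sensitivity = fmt(x$sensitivity, x$sens_lower, x$sens_upper),
    specificity = fmt(x$specificity, x$spec_lower, x$spec_upper),
    ppv = fmt(x$ppv, x$ppv_lower, x$ppv_upper),
    kappa = sprintf("%.4f (%.4f-%.4f)", x$kappa, x$kappa_lower,
                    x$kappa_upper),
    stringsAsFactors = FALSE)
  print(disp, row.names = FALSE, right = FALSE)
  invisible(x)
}
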