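# 2x2 agreement cell probabilities for two raters sharing marginal
# prevalence p of the positive trait, at a given kappa.
.kappa_cell_probs <- function(kappa, prevalence) {
  p <- prevalence; q <- 1 - p
  if (p <= 0 || p >= 1)
    stop("prevalence must lie strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) ||
      kappa <= -1 || kappa > 1)
    stop("kappa must lie in (-1, 1]", call. = FALSE)
  disc <- (1 - kappa) * p * q
  P <- matrix(c(p^2 + kappa * p * q, disc,
                disc, q^2 + kappa * p * q), 2, 2)
  if (any(P < -1e-12))
    stop("kappa incompatible with the marginal prevalence", call. = FALSE)
  pmax(P, 0)
}

#' Asymptotic variance factor Q of Cohen's kappa for a binary trait
#'
#' For two raters who share a common marginal prevalence of the positive
#' trait, the large-sample variance of the kappa estimate is `Q / N`. Q is
#' obtained by evaluating the Fleiss--Cohen--Everitt asymptotic variance at
#' the 2x2 cell probabilities implied by (`kappa`, `prevalence`). At
#' `kappa = 0` the factor reduces to exactly 1 for any prevalence.
#'
#' @param kappa agreement in (-1, 1), compatible with the prevalence.
#' @param prevalence marginal probability of the positive trait, in (0, 1),
#'   assumed common to both raters.
#' @return Non-negative scalar Q.
#' @export
#' @examples
#' kappa_variance_factor(0, 0.3)     # exactly 1
#' kappa_variance_factor(0.6, 0.3)
kappa_variance_factor <- function(kappa, prevalence) {
  P <- .kappa_cell_probs(kappa, prevalence)
  q <- .fce_Q(P)
  if (is.na(q)) stop("degenerate marginals: variance undefined",
                     call. = FALSE)
  max(q, 0)
}

#' Sample size for testing an observed kappa against a null value
#'
#' Number of paired ratings needed so that a test of the null agreement
#' `kappa0` attains the requested power when the true agreement is
#' `kappa1`, for a dichotomous trait with common marginal prevalence:
#' \deqn{N = \left(\frac{z_\alpha\sqrt{Q_0} + z_\beta\sqrt{Q_A}}
#'   {\kappa_1 - \kappa_0}\right)^2}
#' with `Q` the asymptotic variance factor of [kappa_variance_factor()]
#' evaluated under the null and the alternative. With
#' `design = "two_sample"` the same construction sizes a comparison of two
#' independent kappas, each estimated from its own sample of size N, and
#' the variance terms double.
#'
#' @param kappa0 null-hypothesis agreement.
#' @param kappa1 anticipated (alternative) agreement; must differ from
#'   `kappa0`.
#' @param prevalence marginal positive-trait probability in (0, 1). There
#'   is no default: it must be stated for the study at hand.
#' @param alpha significance level (two-sided unless `one_sided`).
#' @param power target power in (0, 1).
#' @param design `"one_sample"` (one kappa against a null value, default)
#'   or `"two_sample"` (two independent kappas).
#' @param one_sided use a one-sided critical value.
#' @return An object of class `kappa_sample_size`: list with `N` (smallest
#'   sufficient integer), `Q0`, `QA`, and the inputs.
#' @export
#' @examples
#' kappa_sample_size(kappa0 = 0.5, kappa1 = 0.8, prevalence = 0.35)
kappa_sample_size <- function(kappa0, kappa1, prevalence, alpha = 0.05,
                              power = 0.80,
                              design = c("one_sample", "two_sample"),
                              one_sided = FALSE) {
  design <- match.arg(design)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  if (identical(kappa0, kappa1))
    stop("kappa1 must differ from kappa0 (sample size is infinite)",
         call. = FALSE)
  Q0 <- kappa_variance_factor(kappa0, prevalence)
  QA <- kappa_variance_factor(kappa1, prevalence)
  mult <- if (design == "two_sample") 2 else 1
  za <- stats::qnorm(1 - if (one_sided) alpha else alpha / 2)
  zb <- stats::qnorm(power)
  n_real <- ((za * sqrt(mult * Q0) + zb * sqrt(mult * QA)) /
               (kappa1 - kappa0))^2
  structure(list(N = as.integer(ceiling(n_real)), n_real = n_real,
                 Q0 = Q0, QA = QA, kappa0 = kappa0, kappa1 = kappa1,
                 prevalence = prevalence, alpha = alpha, power = power,
                 design = design, one_sided = one_sided),
            class = "kappa_sample_size")
}

#' @export
print.kappa_sample_size <- function(x, ...) {
  cat(sprintf(
    "<kappa_sample_size> N = %d (%s)\n  kappa0 = %.3f (Q0 = %.4f), kappa1 = %.3f (QA = %.4f)\n  prevalence = %.3f, alpha = %.3g%s, power = %.2f\n",
    x$N, gsub("_", "-", x$design), x$kappa0, x$Q0, x$kappa1, x$QA,
    x$prevalence, x$alpha, if (x$one_sided) " (one-sided)" else "",
    x$power))
  invisible(x)
}

#' Monte-Carlo power of the kappa test at a given sample size
#'
#' Simulates paired binary ratings at the alternative agreement `kappa1`
#' and performs, on each replicate, a two-sided Wald test of
#' `H0: kappa = kappa0` whose standard error is evaluated under the null
#' (the variance factor at `kappa0` with the empirically pooled marginal
#' prevalence), matching the construction of the sample-size formula.
#'
#' @inheritParams kappa_sample_size
#' @param N number of paired ratings per replicate.
#' @param reps number of Monte-Carlo replicates.
#' @return Estimated power (rejection proportion). Uses the current RNG
#'   stream; set a seed for reproducibility.
#' @export
simulate_kappa_power <- function(N, kappa0, kappa1, prevalence,
                                 alpha = 0.05, reps = 2000) {
  P <- .kappa_cell_probs(kappa1, prevalence)
  za <- stats::qnorm(1 - alpha / 2)
  draws <- stats::rmultinom(reps, N, as.vector(P))
  reject <- vapply(seq_len(reps), function(r) {
    M <- matrix(draws[, r], 2, 2) / N
    pr <- rowSums(M); pc <- colSums(M)
    po <- sum(diag(M)); pe <- sum(pr * pc)
    if (1 - pe < 1e-12) return(FALSE)
    kh <- (po - pe) / (1 - pe)
    phat <- (pr[1] + pc[1]) / 2
    if (phat <= 0 || phat >= 1) return(FALSE)
    se0 <- sqrt(kappa_variance_factor(kappa0, phat) / N)
    is.finite(se0) && se0 > 0 && abs(kh - kappa0) / se0 > za
  }, logical(1))
  mean(reject)
}
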