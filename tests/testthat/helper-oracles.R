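# Independent oracles and random-instance generators used across the suite.

# Wilson interval by brute-force inversion of the score test over a fine
# grid of candidate proportions (independent of the closed form).
wilson_grid_oracle <- function(successes, n, level = 0.95,
                               grid = seq(0, 1, by = 1e-5)) {
  z <- qnorm(1 - (1 - level) / 2)
  phat <- successes / n
  keep <- abs(phat - grid) <= z * sqrt(grid * (1 - grid) / n) + 1e-12
  range(grid[keep])
}

# kappa and percent agreement recomputed from expanded per-item label
# lists, using only counting over the item vectors.
kappa_pairs_oracle <- function(index, reference) {
  categories <- sort(unique(c(index, reference)))
  po <- mean(index == reference)
  pe <- sum(vapply(categories, function(cl)
    mean(index == cl) * mean(reference == cl), numeric(1)))
  list(po = po, pe = pe, kappa = (po - pe) / (1 - pe))
}

# random K x K count table with n items (possibly sparse)
random_crosstab <- function(K = 5, n = 50, categories = NULL) {
  if (is.null(categories)) categories <- paste0("cat", seq_len(K))
  probs <- runif(K * K)
  m <- matrix(as.vector(rmultinom(1, n, probs / sum(probs))), K, K,
              dimnames = list(categories, categories))
  crosstab(m)
}

# random non-degenerate binary confusion table
random_confusion <- function(nmax = 200) {
  repeat {
    cells <- as.vector(rmultinom(1, sample(4:nmax, 1), runif(4, 0.05, 1)))
    if ((cells[1] + cells[3]) > 0 && (cells[2] + cells[4]) > 0) break
  }
  binary_confusion(tp = cells[1], fp = cells[2], fn = cells[3],
                   tn = cells[4])
}

# one valid patient_findings record drawn uniformly over the coded enums
random_findings <- function() {
  profile <- sample(c("A_PROFILE", "B_PROFILE_BILATERAL", "B_FOCAL",
                      "C_PROFILE", "B0_PROFILE"), 1)
  shred_ok <- profile != "A_PROFILE"
  patient_findings(
    patient_id = "rand",
    lus = lus_exam(profile,
                   shred_sign = shred_ok && runif(1) < 0.3,
                   plaps = runif(1) < 0.3,
                   focal_interstitial = runif(1) < 0.3),
    tte = tte_exam(sample(c("NORMAL", "DYSFUNCTION"), 1),
                   rv_dilated = runif(1) < 0.3),
    ivc = sample(c("COLLAPSED", "DISTENDED", "NOT_ASSESSED"), 1),
    dvt = sample(c("POSITIVE", "NEGATIVE", "NOT_DONE"), 1),
    abg = abg_panel(pao2 = runif(1, 30, 110), paco2 = runif(1, 20, 90),
                    ph = runif(1, 6.9, 7.7), hco3 = runif(1, 5, 40),
                    on_room_air = runif(1) < 0.5),
    cxr = {
      normal <- runif(1) < 0.4
      cxr_findings(
        air_bronchogram_or_opacity = !normal && runif(1) < 0.4,
        bat_wing_or_cardiomegaly_or_hilar = !normal && runif(1) < 0.4,
        hyperinflation_tubular_heart_flat_diaphragm =
          !normal && runif(1) < 0.4,
        normal_film = normal,
        spo2_hypoxia = runif(1) < 0.5)
    })
}

# canonical worked examples for the CCUS+ABG engine
example_cardiac <- function() patient_findings(
  "ex-cardiac", lus = lus_exam("B_PROFILE_BILATERAL"),
  tte = tte_exam("DYSFUNCTION"), ivc = "DISTENDED", dvt = "NEGATIVE",
  abg = abg_panel(pao2 = 50, paco2 = 40))

example_metabolic <- function() patient_findings(
  "ex-metabolic", lus = lus_exam("A_PROFILE"), tte = tte_exam("NORMAL"),
  ivc = "COLLAPSED", dvt = "NEGATIVE",
  abg = abg_panel(pao2 = 80, paco2 = 38))

example_copd <- function() patient_findings(
  "ex-copd", lus = lus_exam("C_PROFILE"),
  tte = tte_exam("NORMAL", rv_dilated = TRUE), ivc = "DISTENDED",
  dvt = "NEGATIVE", abg = abg_panel(pao2 = 52, paco2 = 65))
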