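#' Index-test vs reference cross-tabulation
#'
#' A K-by-K count table with rows indexed by the test-under-evaluation
#' (index) label and columns by the reference label, both over the same
#' ordered category set.
#'
#' @param counts K x K matrix of non-negative integer counts (rows = index
#'   label, columns = reference label).
#' @param categories ordered category labels; defaults to the dimnames of
#'   `counts`.
#' @return An object of class `crosstab` with fields `counts`,
#'   `categories` and `n`.
#' @export
#' @examples
#' m <- diag(c(5, 3, 2))
#' dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
#' crosstab(m)
crosstab <- function(counts, categories = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("counts must be square with one row/column per category",
         call. = FALSE)
  if (is.null(categories))
    stop("categories must be supplied or present as dimnames", call. = FALSE)
  categories <- as.character(categories)
  if (nrow(counts) != length(categories))
    stop("counts must be square with one row/column per category",
         call. = FALSE)
  if (anyDuplicated(categories))
    stop("categories must be distinct", call. = FALSE)
  storage.mode(counts) <- "double"
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers", call. = FALSE)
  counts <- round(counts)
  dimnames(counts) <- list(index = categories, reference = categories)
  structure(list(counts = counts, categories = categories,
                 n = sum(counts)), class = "crosstab")
}

#' Build a cross-tabulation from per-patient label pairs
#'
#' @param index character vector of index-test labels.
#' @param reference character vector of reference labels, same length.
#' @param categories ordered category labels; every label in `index` and
#'   `reference` must appear here.
#' @return A [crosstab()].
#' @export
#' @examples
#' build_crosstab(c("a", "a"), c("a", "b"), categories = c("a", "b"))
build_crosstab <- function(index, reference, categories = arf_categories()) {
  if (length(index) != length(reference))
    stop("index and reference must have equal length", call. = FALSE)
  if (length(index) == 0L)
    stop("cannot build a cross-tabulation from zero pairs", call. = FALSE)
  bad <- setdiff(unique(c(index, reference)), categories)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  tab <- table(factor(index, levels = categories),
               factor(reference, levels = categories))
  crosstab(unclass(as.matrix(tab)), categories)
}

#' Expand a cross-tabulation back into per-patient label pairs
#'
#' Inverse of [build_crosstab()]: emits one `(index, reference)` pair per
#' counted unit, in deterministic row-major order, so that packaged count
#' fixtures can feed item-level statistics.
#'
#' @param ct a [crosstab()].
#' @return A data frame with columns `index` and `reference`, `ct$n` rows.
#' @export
expand_crosstab_to_pairs <- function(ct) {
  stopifnot(inherits(ct, "crosstab"))
  idx <- which(ct$counts > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(index = character(), reference = character(),
                      stringsAsFactors = FALSE))
  reps <- ct$counts[idx]
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]; reps <- reps[ord]
  data.frame(
    index = rep(ct$categories[idx[, 1L]], reps),
    reference = rep(ct$categories[idx[, 2L]], reps),
    stringsAsFactors = FALSE)
}

#' Observed percent agreement
#'
#' Diagonal mass of the cross-tabulation: the proportion of units on which
#' index and reference labels agree.
#'
#' @param ct a [crosstab()].
#' @return Proportion in \[0, 1\].
#' @export
percent_agreement <- function(ct) {
  stopifnot(inherits(ct, "crosstab"))
  if (ct$n < 1) stop("empty cross-tabulation", call. = FALSE)
  sum(diag(ct$counts)) / ct$n
}

#' One-vs-rest reduction of a cross-tabulation
#'
#' Collapses a K-category cross-tabulation to the 2x2 confusion table for
#' one category: that category's diagonal cell is the true positives, the
#' rest of its reference column the false negatives, the rest of its index
#' row the false positives.
#'
#' @param ct a [crosstab()].
#' @param category the category treated as "positive".
#' @return An object of class `binary_confusion` with fields `tp`, `fp`,
#'   `fn`, `tn`, `n` and `category`.
#' @export
#' @examples
#' ct <- arf_crosstab("table2_ccus")
#' dichotomize(ct, "ALVEOLAR_LUNG")
dichotomize <- function(ct, category) {
  stopifnot(inherits(ct, "crosstab"))
  if (!category %in% ct$categories)
    stop("unknown category: ", category, call. = FALSE)
  tp <- ct$counts[category, category]
  fn <- sum(ct$counts[, category]) - tp
  fp <- sum(ct$counts[category, ]) - tp
  tn <- ct$n - tp - fn - fp
  binary_confusion(tp, fp, fn, tn, category = category)
}

#' Binary confusion table
#'
#' @param tp,fp,fn,tn non-negative cell counts (true positives, false
#'   positives, false negatives, true negatives).
#' @param category optional label of the "positive" category.
#' @return An object of class `binary_confusion`.
#' @export
binary_confusion <- function(tp, fp, fn, tn, category = NULL) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) ||
      any(abs(cells - round(cells)) > 1e-8))
    stop("confusion cells must be non-negative integers", call. = FALSE)
  n <- sum(cells)
  if (n < 1) stop("confusion table is empty", call. = FALSE)
  structure(list(tp = round(tp), fp = round(fp), fn = round(fn),
                 tn = round(tn), n = n, category = category),
            class = "binary_confusion")
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("<crosstab> %d categories, n = %d\n",
              length(x$categories), x$n))
  print(x$counts)
  invisible(x)
}

#' @export
print.binary_confusion <- function(x, ...) {
  cat("<binary_confusion>",
      if (!is.null(x$category)) paste0("(", x$category, ")"), "\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(index = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Read / write a cross-tabulation as a labelled CSV count table
#'
#' The on-disk format is a plain CSV with the category labels as both the
#' header row and the first column; rows are index-test labels, columns
#' reference labels.
#'
#' @param path file path.
#' @return `read_crosstab` returns a [crosstab()]; `write_crosstab`
#'   invisibly returns `path`.
#' @export
read_crosstab <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels must be identical and ordered", call. = FALSE)
  crosstab(m)
}

#' @rdname read_crosstab
#' @param ct a [crosstab()].
#' @export
write_crosstab <- function(ct, path) {
  stopifnot(inherits(ct, "crosstab"))
  df <- data.frame(category = ct$categories, ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged validation-study count tables
#'
#' The three cross-tabulations from the published validation study of the
#' two triage algorithms in 174 dyspneic ICU patients, shipped as plain CSV
#' fixtures: the CCUS+ABG arm against the composite reference diagnosis,
#' the chest-X-ray arm against the composite diagnosis, and the chest-X-ray
#' arm against the CCUS+ABG arm.
#'
#' @param name one of `"table2_ccus"` (CCUS+ABG vs composite),
#'   `"table2_cxr"` (CxR vs composite), `"table3_cxr_vs_ccus"` (CxR as
#'   index vs CCUS+ABG as reference).
#' @return A [crosstab()] over the five categories, n = 174.
#' @export
#' @examples
#' arf_crosstab("table2_ccus")
arf_crosstab <- function(name = c("table2_ccus", "table2_cxr",
                                  "table3_cxr_vs_ccus")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "arftriage", mustWork = TRUE)
  read_crosstab(path)
}
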