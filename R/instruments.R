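#' Score the Insomnia Severity Index
#'
#' Sums the seven 0-4 items and assigns the standard severity band. The
#' bands are exposed as an argument because band definitions are a clinical
#' convention, not part of the scoring arithmetic; defaults are the widely
#' used cutoffs 0-7 (no insomnia), 8-14 (sub-threshold), 15-21 (moderate
#' severity), 22-28 (severe), inclusive on the left edge.
#'
#' @param items Numeric vector of 7 item scores in 0..4, or a data frame /
#'   matrix with 7 item columns (one respondent per row).
#' @param cutoffs Increasing integer vector of lower band edges (first must
#'   be 0).
#' @param labels Band labels, one per cutoff.
#' @return A tibble with columns `total` (0-28) and `category`.
#' @examples
#' score_isi(c(3, 2, 3, 2, 3, 2, 2))
#' @export
score_isi <- function(items,
                      cutoffs = c(0, 8, 15, 22),
                      labels = c("no insomnia", "sub-threshold",
                                 "moderate severity", "severe")) {
  m <- as_item_matrix(items, k = 7, lo = 0, hi = 4, name = "ISI")
  stopifnot(length(cutoffs) == length(labels), cutoffs[1] == 0,
            !is.unsorted(cutoffs, strictly = TRUE))
  total <- rowSums(m)
  category <- labels[findInterval(total, cutoffs)]
  tibble(total = total,
         category = factor(category, levels = labels))
}

as_item_matrix <- function(items, k, lo, hi, name) {
  m <- if (is.data.frame(items) || is.matrix(items)) {
    as.matrix(items)
  } else {
    matrix(items, nrow = 1)
  }
  if (ncol(m) != k) {
    abort(sprintf("%s responses need exactly %d items (got %d).",
                  name, k, ncol(m)))
  }
  if (anyNA(m)) {
    abort(sprintf("%s responses contain missing items; no imputation is done.",
                  name))
  }
  if (any(m < lo | m > hi)) {
    abort(sprintf("%s items must lie in %d..%d.", name, lo, hi))
  }
  m
}

#' Centre a 7-point Likert response at its neutral midpoint
#'
#' Maps raw scores 1..7 to centred scores -3..3 (`raw - 4`) so deviation
#' from the neutral point 0 can be tested directly. The map is a bijection
#' between the raw and centred scales.
#'
#' @param raw Numeric vector of raw scores in 1..7.
#' @return Centred scores in -3..3.
#' @examples
#' center_likert(c(1, 4, 7))
#' @export
center_likert <- function(raw) {
  if (anyNA(raw) || any(raw < 1 | raw > 7)) {
    abort("Raw Likert scores must lie in 1..7 with no missing values.")
  }
  raw - 4
}

#' Score the feeling-of-being-heard scale
#'
#' Seven 7-point items (two adapted from the patient satisfaction
#' questionnaire, two from the trust-in-physician scale, three new) are
#' centred at the neutral midpoint and averaged into a single score in
#' \[-3, 3\]. Scoring is item-content agnostic; the item texts ship as a
#' data file (see `system.file("extdata/fbh_items.json", package =
#' "mhtriage")`).
#'
#' @param items Numeric vector of 7 raw item scores in 1..7, or a data
#'   frame / matrix with 7 item columns.
#' @return Numeric scale score(s), one per respondent row.
#' @examples
#' score_fbh(c(4, 4, 4, 4, 4, 4, 4))  # all neutral -> 0
#' @export
score_fbh <- function(items) {
  m <- as_item_matrix(items, k = 7, lo = 1, hi = 7, name = "FBH")
  rowMeans(center_likert(m))
}

#' Cronbach's alpha scale reliability
#'
#' `alpha = k/(k-1) * (1 - sum(var(item_i)) / var(total))` with sample
#' variances (n-1 denominator). Defined for at least two items, two
#' respondents and nonzero total-score variance; alpha is invariant under
#' adding a constant to any item column and equals 1 for perfectly
#' consistent (duplicated) items.
#'
#' @param x Numeric matrix or data frame, respondents in rows, items in
#'   columns.
#' @return A one-row tibble with `alpha`, `k` (items), `n` (respondents).
#' @examples
#' set.seed(1)
#' latent <- rnorm(50)
#' items <- sapply(1:4, function(i) latent + rnorm(50, sd = 0.4))
#' cronbach_alpha(items)
#' @export
cronbach_alpha <- function(x) {
  m <- as.matrix(x)
  if (anyNA(m)) abort("Reliability requires complete responses.")
  k <- ncol(m); n <- nrow(m)
  if (k < 2L || n < 2L) {
    abort("Cronbach's alpha needs at least 2 items and 2 respondents.")
  }
  total_var <- var(rowSums(m))
  if (total_var <= .Machine$double.eps) {
    abort("Total-score variance is zero; reliability is undefined.")
  }
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
  tibble(alpha = alpha, k = k, n = n)
}
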