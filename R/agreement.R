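# Inter-rater agreement: percent agreement and Cohen's kappa.

#' Cross-tabulate two raters
#'
#' @param r1,r2 Vectors of categorical ratings of equal length (character
#'   or factor).  Missing values are not allowed.
#' @return A square contingency table over the union of observed
#'   categories, rater 1 in rows.
#' @export
rating_table <- function(r1, r2) {
  if (length(r1) != length(r2) || !length(r1))
    stopf("`r1` and `r2` must be non-empty vectors of equal length")
  if (anyNA(r1) || anyNA(r2)) stopf("ratings must not contain missing values")
  lev <- sort(unique(c(as.character(r1), as.character(r2))))
  table(factor(as.character(r1), levels = lev),
        factor(as.character(r2), levels = lev),
        dnn = c("rater1", "rater2"))
}

#' Percent agreement between two raters
#'
#' `100 * (number of identical ratings) / (number of items)`.
#'
#' @inheritParams rating_table
#' @return Percentage in `[0, 100]`.
#' @export
percent_agreement <- function(r1, r2) {
  tab <- rating_table(r1, r2)
  100 * sum(diag(tab)) / sum(tab)
}

#' Cohen's kappa
#'
#' Unweighted Cohen's kappa `(p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e` from the marginal distributions.  When both raters use
#' a single identical category for every item, `p_e = 1` and kappa is
#' undefined; by convention this returns 1 with a warning when observed
#' agreement is perfect, and `NaN` otherwise.
#'
#' @inheritParams rating_table
#' @return A single number in `[-1, 1]` (or `NaN` in the degenerate case).
#' @export
cohen_kappa <- function(r1, r2) {
  tab <- rating_table(r1, r2)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1 - 1e-12) {
    warnf("kappa undefined: expected agreement is 1 (constant ratings)")
    return(if (p_o >= 1 - 1e-12) 1 else NaN)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Agreement summary for two raters
#'
#' @inheritParams rating_table
#' @return List with `n`, `n_agree`, `percent_agreement`, `kappa` and the
#'   contingency `table`.
#' @export
agreement_stats <- function(r1, r2) {
  tab <- rating_table(r1, r2)
  list(n = sum(tab),
       n_agree = sum(diag(tab)),
       percent_agreement = 100 * sum(diag(tab)) / sum(tab),
       kappa = cohen_kappa(r1, r2),
       table = tab)
}

#' Read paired ratings from CSV
#'
#' Expects a header and columns `item_id`, `rater_a`, `rater_b` (named
#' rater columns are matched case-insensitively); otherwise the first two
#' non-`item_id` columns are taken as the two raters.
#'
#' @param path Path to a CSV file.
#' @return Data frame with character columns `rater1` and `rater2`.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stopf("ratings file does not exist: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  df <- df[, nm != "item_id", drop = FALSE]
  nm <- tolower(names(df))
  ia <- match("rater_a", nm)
  ib <- match("rater_b", nm)
  if (is.na(ia) || is.na(ib)) { ia <- 1L; ib <- 2L }
  if (ncol(df) < 2L || !nrow(df))
    stopf("'%s' must have a header and at least two columns of ratings", path)
  out <- data.frame(rater1 = as.character(df[[ia]]),
                    rater2 = as.character(df[[ib]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$rater1) || anyNA(out$rater2))
    stopf("ratings must not contain missing values")
  out
}
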