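#' Adjusted Rand index between two label vectors
#'
#' Chance-corrected agreement between two partitions, used to quantify
#' recovery of planted subtype labels.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A number in \[-1, 1\]; 1 means identical partitions, 0 is the
#'   expectation under independent random labellings.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Macro-averaged F1 score
#'
#' @param truth,pred Factors or character vectors of class labels.
#' @return List with `per_class` F1 values and `macro_f1` (their unweighted
#'   mean; classes absent from both truth and prediction are skipped).
#' @export
macro_f1 <- function(truth, pred) {
  classes <- union(unique(as.character(truth)), unique(as.character(pred)))
  per <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp + fp + fn == 0) return(NA_real_)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, 0)
  list(per_class = per, macro_f1 = mean(per, na.rm = TRUE))
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Mean absolute deviation about the mean
#'
#' Feature-variability measure used to select clustering input rows.
#'
#' @param x Numeric vector (NAs removed).
#' @return `mean(|x - mean(x)|)`.
#' @export
mean_abs_deviation <- function(x) {
  x <- x[!is.na(x)]
  mean(abs(x - mean(x)))
}
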