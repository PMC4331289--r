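# Confusion matrices and the accuracy statistics UA / PA / OA.
#
# Convention used throughout (deliberately documented, because it is the
# REVERSE of the common remote-sensing textbook convention): UA for a
# class is computed on the OBSERVED row (correct / row total) and PA on
# the PREDICTED column (correct / column total).  Every published
# confusion table this package reproduces computes its statistics this
# way, so the package follows suit.

#' Confusion matrix from label vectors
#'
#' @param observed,predicted equal-length label vectors.
#' @param classes class ordering for rows/columns; default: sorted union
#'   of both vectors.
#' @return square integer matrix of class `crop_confusion` with
#'   `dimnames` `observed` x `predicted`.
#' @export
confusion <- function(observed, predicted, classes = NULL) {
  observed <- as.character(observed); predicted <- as.character(predicted)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted differ in length")
  }
  if (is.null(classes)) classes <- sort(unique(c(observed, predicted)))
  extra <- setdiff(unique(c(observed, predicted)), classes)
  if (length(extra)) {
    stop("label(s) outside the class list: ", paste(extra, collapse = ", "))
  }
  m <- table(factor(observed, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(observed = classes, predicted = classes))
  structure(m, class = c("crop_confusion", class(m)))
}

#' Build a confusion matrix from counts
#'
#' @param counts square numeric matrix (observed rows x predicted
#'   columns) with identical row/column names.
#' @return a `crop_confusion`.
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) ||
      !identical(rownames(counts), colnames(counts))) {
    stop("counts must be square with identical row and column names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  m <- matrix(as.integer(counts), nrow = nrow(counts),
              dimnames = list(observed = rownames(counts),
                              predicted = colnames(counts)))
  structure(m, class = c("crop_confusion", class(m)))
}

#' Read a confusion matrix from a TSV file
#'
#' Expects a header `observed<TAB>class1<TAB>class2...` and one row per
#' observed class starting with its name.
#'
#' @param path tab-delimited file.
#' @return a `crop_confusion`.
#' @export
read_confusion <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as_confusion(as.matrix(tab))
}

#' Accuracy statistics from a confusion matrix
#'
#' User's accuracy `UA_c = 100 * m[c, c] / rowSum(c)` (observed-row
#' basis), producer's accuracy `PA_c = 100 * m[c, c] / colSum(c)`
#' (predicted-column basis) and overall accuracy
#' `OA = 100 * trace / total`.  A class with zero denominator gets `NA`.
#'
#' @param matrix a `crop_confusion` with positive total.
#' @return list with named numeric vectors `UA`, `PA` (percent, per
#'   class) and scalar `OA` (percent).
#' @export
accuracy_stats <- function(matrix) {
  m <- unclass(matrix)
  total <- sum(m)
  if (!length(m) || total <= 0) stop("empty confusion matrix")
  d <- diag(m)
  rs <- rowSums(m); cs <- colSums(m)
  ua <- ifelse(rs > 0, 100 * d / rs, NA_real_)
  pa <- ifelse(cs > 0, 100 * d / cs, NA_real_)
  list(UA = stats::setNames(ua, rownames(m)),
       PA = stats::setNames(pa, colnames(m)),
       OA = 100 * sum(d) / total)
}

#' Risk estimate from a confusion matrix
#'
#' `risk = 1 - OA/100` with binomial standard error
#' `sqrt(risk (1 - risk) / N)`; the resubstitution counterpart of the
#' cross-validated tree risk.
#'
#' @param matrix a `crop_confusion` with positive total.
#' @return a `risk_estimate`.
#' @export
risk_from_matrix <- function(matrix) {
  st <- accuracy_stats(matrix)
  risk_estimate(1 - st$OA / 100, sum(unclass(matrix)), "resubstitution")
}

#' Human-readable accuracy report
#'
#' @param matrix a `crop_confusion`.
#' @return character vector of report lines (also printed).
#' @export
accuracy_report <- function(matrix) {
  st <- accuracy_stats(matrix)
  rk <- risk_from_matrix(matrix)
  lines <- c(
    sprintf("Parcels evaluated: %d", sum(unclass(matrix))),
    sprintf("Overall accuracy (OA): %.1f%%", st$OA),
    sprintf("Risk: %.3f +/- %.3f", rk$risk, rk$se),
    "Per-class accuracy (UA on observed row, PA on predicted column):",
    sprintf("  %-8s UA %6.1f%%  PA %6.1f%%", names(st$UA), st$UA, st$PA))
  cat(lines, sep = "\n")
  invisible(lines)
}
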