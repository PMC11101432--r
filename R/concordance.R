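#' Cross-tabulate classifier calls against molecular truth
#'
#' Builds the 5 (molecular truth: LAR, IM, BL1, M, UNC) x 4 (classified:
#' LAR, LP, LI, LD) confusion table. Unclassified (UNC) cases are retained
#' as a truth row here; the agreement metrics decide separately whether to
#' exclude them.
#'
#' @param calls character vector of classified labels (LAR/LP/LI/LD).
#' @param truths character vector of molecular labels (LAR/IM/BL1/M/UNC).
#' @return object of class `confusion_table`: the count matrix with truth
#'   rows and classified columns.
#' @export
crosstab <- function(calls, truths) {
  stopifnot(length(calls) == length(truths))
  calls <- as.character(calls)
  truths <- as.character(truths)
  if (!all(calls %in% SUBTYPE_LEVELS)) {
    stop("classified labels outside {", paste(SUBTYPE_LEVELS, collapse = ","),
         "}", call. = FALSE)
  }
  if (!all(truths %in% MOLECULAR_LEVELS)) {
    stop("molecular labels outside {", paste(MOLECULAR_LEVELS, collapse = ","),
         "}", call. = FALSE)
  }
  tab <- table(factor(truths, MOLECULAR_LEVELS), factor(calls, SUBTYPE_LEVELS))
  m <- matrix(as.integer(tab), nrow = length(MOLECULAR_LEVELS),
              dimnames = list(truth = MOLECULAR_LEVELS,
                              classified = SUBTYPE_LEVELS))
  class(m) <- c("confusion_table", class(m))
  m
}

round_half_up <- function(x, digits = 1) {
  # report-parity rounding: 0.05 at the last digit always rounds up
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Column percentages of a confusion table
#'
#' Each cell as a percentage of its classified-column total, rounded
#' half-up to one decimal (report parity with published cross-tabulations,
#' whose column denominators include the UNC row). Columns with zero total
#' are reported as NA.
#'
#' @param ct a `confusion_table` from [crosstab()].
#' @param digits decimals to keep (default 1).
#' @return numeric matrix of percentages with the same dimnames.
#' @export
column_percentages <- function(ct, digits = 1) {
  stopifnot(inherits(ct, "confusion_table"))
  totals <- colSums(ct)
  pct <- sweep(unclass(ct), 2L, totals, "/") * 100
  pct[, totals == 0] <- NA_real_
  round_half_up(pct, digits)
}

## collapse the 5x4 table to the matched 4x4 table (truth rows reordered to
## the classified correspondence LAR/IM/BL1/M; UNC dropped). A plain square
## count matrix is passed through, so the agreement metrics also work on toy
## agreement tables.
matched_table <- function(ct, exclude_unc = TRUE) {
  if (inherits(ct, "confusion_table")) {
    if (!exclude_unc) {
      stop("agreement metrics are defined on the matched 4x4 table; ",
           "UNC truth cases have no corresponding classified label",
           call. = FALSE)
    }
    m <- unclass(ct)[SUBTYPE_CORRESPONDENCE, SUBTYPE_LEVELS, drop = FALSE]
    rownames(m) <- SUBTYPE_LEVELS  # truth rows relabelled by correspondence
    return(m)
  }
  m <- as.matrix(ct)
  stopifnot(is.numeric(m), nrow(m) == ncol(m))
  m
}

#' Wilson score interval for a binomial proportion
#'
#' @param x successes; @param n trials; @param conf confidence level.
#' @return c(lower, upper).
#' @keywords internal
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Overall accuracy of the subtype classification
#'
#' Accuracy is the fraction of cases whose classified label matches the
#' molecular truth under the correspondence LAR<->LAR, LP<->IM, LI<->BL1,
#' LD<->M, computed after excluding UNC truth cases (which cannot match any
#' classified label). The 95% CI uses the Wilson score interval by default;
#' `ci_method = "clopper-pearson"` gives the exact interval.
#'
#' @param ct a `confusion_table`.
#' @param exclude_unc must be TRUE (kept as an explicit argument to document
#'   the exclusion).
#' @param conf confidence level (default 0.95).
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @return list with `accuracy`, `lower`, `upper`, `n` (non-UNC total),
#'   `matched` (agreeing count).
#' @export
overall_accuracy <- function(ct, exclude_unc = TRUE, conf = 0.95,
                             ci_method = c("wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  m <- matched_table(ct, exclude_unc)
  n <- sum(m)
  if (n == 0L) stop("no cases left after UNC exclusion", call. = FALSE)
  x <- sum(diag(m))
  ci <- if (ci_method == "wilson") {
    wilson_ci(x, n, conf)
  } else {
    as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
  }
  list(accuracy = x / n, lower = ci[[1]], upper = ci[[2]], n = n, matched = x)
}

#' Cohen's kappa for the subtype classification
#'
#' Unweighted Cohen's kappa on the matched 4x4 table (UNC truth excluded).
#' Returns NA when the expected agreement is 1 (degenerate marginals).
#'
#' @inheritParams overall_accuracy
#' @return numeric kappa (or NA).
#' @export
cohen_kappa <- function(ct, exclude_unc = TRUE) {
  m <- matched_table(ct, exclude_unc)
  n <- sum(m)
  if (n == 0L) stop("no cases left after UNC exclusion", call. = FALSE)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Per-subtype precision, recall, F1 and balanced accuracy
#'
#' One-vs-rest metrics per subtype on the matched 4x4 table (UNC truth
#' excluded): precision = TP/(TP+FP), recall (sensitivity) = TP/(TP+FN),
#' F1 = harmonic mean of the two, balanced accuracy =
#' (sensitivity + specificity)/2. Zero denominators yield NA.
#'
#' @inheritParams overall_accuracy
#' @return data.frame with one row per subtype.
#' @export
per_class_metrics <- function(ct, exclude_unc = TRUE) {
  m <- matched_table(ct, exclude_unc)
  n <- sum(m)
  if (is.null(rownames(m))) {
    dimnames(m) <- list(seq_len(nrow(m)), seq_len(ncol(m)))
  }
  classes <- rownames(m)
  out <- lapply(classes, function(cl) {
    tp <- m[cl, cl]
    fp <- sum(m[, cl]) - tp
    fn <- sum(m[cl, ]) - tp
    tn <- n - tp - fp - fn
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    bal <- if (!is.na(recall) && !is.na(specificity)) {
      (recall + specificity) / 2
    } else NA_real_
    data.frame(subtype = cl, precision = precision, recall = recall,
               f1 = f1, balanced_accuracy = bal, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
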