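#' Normalize an expression matrix
#'
#' Preprocessing for the centroid-correlation molecular caller: quantile
#' normalization across samples (columns), log2 transformation of raw
#' intensities, and per-gene median centering, in that order. Already-logged
#' input is accepted via `pre_logged = TRUE`, in which case only quantile
#' normalization and median centering are applied.
#'
#' Quantile normalization is delegated to [limma::normalizeQuantiles()]
#' (rank-mean algorithm). After centering every gene's median is 0 by
#' construction, so the operation is idempotent up to centering.
#'
#' @param raw numeric genes x samples matrix with rownames (gene ids) and
#'   colnames (sample ids).
#' @param pre_logged logical; set TRUE if `raw` is already on the log2
#'   scale. If FALSE, all values must be strictly positive.
#' @return the normalized matrix with attribute `normalized = TRUE`.
#' @export
normalize_expression <- function(raw, pre_logged = FALSE) {
  raw <- as.matrix(raw)
  stopifnot(is.numeric(raw), nrow(raw) >= 1L, ncol(raw) >= 1L)
  if (anyNA(raw)) stop("missing values in expression matrix", call. = FALSE)
  if (!pre_logged && any(raw <= 0)) {
    stop("nonpositive intensities; log2 needs strictly positive values ",
         "(use pre_logged = TRUE for logged data)", call. = FALSE)
  }
  x <- limma::normalizeQuantiles(raw)
  if (!pre_logged) x <- log2(x)
  x <- x - apply(x, 1L, stats::median)
  dimnames(x) <- dimnames(raw)
  attr(x, "normalized") <- TRUE
  x
}

cor_with_p <- function(x, y, method = "pearson") {
  # two-sided p via the t transform of r (df = n - 2)
  ok <- stats::sd(x) > 0 && stats::sd(y) > 0
  if (!ok) return(c(r = NA_real_, p = NA_real_))
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(c(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Call the molecular subtype of one expression profile
#'
#' Correlates the profile with the four subtype centroids (LAR, IM, BL1, M)
#' and assigns the subtype with the highest correlation, provided that
#' correlation's two-sided p-value is below `alpha`; if no centroid reaches
#' significance the case is unclassified (`UNC`). Ties in the maximum
#' correlation are broken by the fixed order LAR > IM > BL1 > M.
#'
#' The p-value uses the t-distribution transform of r. A zero-variance
#' profile (or centroid) yields NA correlations and an `UNC` call with a
#' warning.
#'
#' @param profile named numeric vector (gene ids as names).
#' @param centroids genes x 4 numeric matrix with rownames (gene ids) and
#'   colnames LAR, IM, BL1, M (any order; matched by name).
#' @param alpha significance level for a confident call (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `label`, `scores` (named correlations) and `p_values`.
#' @export
call_molecular_subtype <- function(profile, centroids, alpha = 0.05,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  centroids <- as.matrix(centroids)
  stopifnot(!is.null(names(profile)), !is.null(rownames(centroids)))
  if (!all(MOLECULAR_CORE %in% colnames(centroids))) {
    stop("centroids must have columns ", paste(MOLECULAR_CORE, collapse = ", "),
         call. = FALSE)
  }
  centroids <- centroids[, MOLECULAR_CORE, drop = FALSE]
  shared <- intersect(names(profile), rownames(centroids))
  if (length(shared) < 10L) {
    stop("need >= 10 genes shared between profile and centroids; got ",
         length(shared), call. = FALSE)
  }
  prof <- profile[shared]
  res <- vapply(MOLECULAR_CORE,
                function(s) cor_with_p(prof, centroids[shared, s], method),
                numeric(2))
  scores <- res["r", ]
  p_values <- res["p", ]
  if (all(is.na(scores))) {
    warning("zero-variance profile; returning UNC", call. = FALSE)
    label <- "UNC"
  } else {
    sig <- !is.na(p_values) & p_values < alpha
    if (!any(sig)) {
      label <- "UNC"
    } else {
      # argmax correlation among all four; tie-break by fixed subtype order
      best <- which.max(scores)
      label <- if (!is.na(p_values[best]) && p_values[best] < alpha) {
        MOLECULAR_CORE[best]
      } else "UNC"
    }
  }
  list(label = label, scores = scores, p_values = p_values)
}

#' Call molecular subtypes for a whole cohort
#'
#' Applies [call_molecular_subtype()] to every column of a normalized
#' expression matrix and reports the unclassified fraction.
#'
#' @param mat normalized genes x samples matrix.
#' @inheritParams call_molecular_subtype
#' @return data.frame with one row per sample: `sample_id`, `label`, the
#'   four correlation scores (`cor_LAR`, ...) and p-values (`p_LAR`, ...).
#' @export
call_cohort <- function(mat, centroids, alpha = 0.05,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  ids <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  rows <- lapply(seq_len(ncol(mat)), function(i) {
    call <- call_molecular_subtype(stats::setNames(mat[, i], rownames(mat)),
                                   centroids, alpha, method)
    data.frame(sample_id = ids[i], label = call$label,
               t(stats::setNames(call$scores, paste0("cor_", MOLECULAR_CORE))),
               t(stats::setNames(call$p_values, paste0("p_", MOLECULAR_CORE))),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sample_id = character(0), label = character(0))
  }
  if (nrow(out)) {
    message(sprintf("UNC fraction: %.3f", mean(out$label == "UNC")))
  }
  rownames(out) <- NULL
  out
}
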