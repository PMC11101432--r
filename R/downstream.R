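#' Per-sample signature scores
#'
#' Scores each sample against each gene set, either by a single-sample
#' rank-based enrichment statistic (`method = "ssgsea"`) or by the mean of
#' per-gene z-scores (`method = "mean_z"`).
#'
#' The ssGSEA-style statistic ranks the genes of a sample (decreasing
#' expression), walks the ranked list accumulating a rank-weighted ECDF for
#' set genes (weights |rank value|^0.25) against the uniform ECDF of the
#' complement, and takes the difference of the two weighted sums; scores are
#' normalized by the range of attainable values so they are comparable
#' across sets. Being rank-based, scores are invariant to monotone
#' transforms of the expression values.
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param genesets named list of character vectors of gene ids (e.g. read
#'   with [read_gmt()]).
#' @param method `"ssgsea"` (default) or `"mean_z"`.
#' @param exponent rank weighting exponent for ssgsea (default 0.25).
#' @return signatures x samples matrix with attribute `method`; sets with
#'   no overlapping genes give an NA row with a warning.
#' @export
signature_scores <- function(expr, genesets, method = c("ssgsea", "mean_z"),
                             exponent = 0.25) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  stopifnot(is.numeric(expr), !is.null(rownames(expr)), length(genesets) >= 1L,
            !is.null(names(genesets)))
  usable <- vapply(genesets, function(g) sum(g %in% rownames(expr)) >= 2L,
                   logical(1))
  if (!any(usable)) {
    stop("no gene set with >= 2 genes present in the matrix", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow = length(genesets), ncol = ncol(expr),
                dimnames = list(names(genesets), colnames(expr)))
  if (method == "mean_z") {
    # z-score each sample across its genes, so the all-genes score is 0
    mu <- colMeans(expr)
    sdv <- apply(expr, 2L, stats::sd)
    z <- sweep(sweep(expr, 2L, mu), 2L, ifelse(sdv == 0, 1, sdv), "/")
    for (s in names(genesets)) {
      idx <- intersect(genesets[[s]], rownames(expr))
      if (length(idx) < 2L) next
      out[s, ] <- colMeans(z[idx, , drop = FALSE])
    }
  } else {
    n_genes <- nrow(expr)
    for (j in seq_len(ncol(expr))) {
      # ranks: largest expression gets the largest rank value
      r <- rank(expr[, j], ties.method = "average")
      ord <- order(r, decreasing = TRUE)
      r_sorted <- r[ord]
      gene_sorted <- rownames(expr)[ord]
      for (s in names(genesets)) {
        set <- intersect(genesets[[s]], rownames(expr))
        if (length(set) < 2L) next
        inset <- gene_sorted %in% set
        w <- abs(r_sorted)^exponent * inset
        p_hit <- cumsum(w) / sum(w)
        p_miss <- cumsum(!inset) / (n_genes - sum(inset))
        es <- sum(p_hit - p_miss)
        out[s, j] <- es / (n_genes - 1)  # range normalization
      }
    }
  }
  empty <- names(genesets)[!usable]
  if (length(empty)) {
    warning("gene set(s) with empty overlap: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  attr(out, "method") <- method
  out
}

#' One-way ANOVA per signature with FDR adjustment
#'
#' Tests each signature's scores for a mean difference across groups with a
#' one-way ANOVA (equal-variance F test) and adjusts the p-values across
#' signatures with the Benjamini-Hochberg step-up procedure.
#'
#' @param scores signatures x samples matrix (from [signature_scores()]).
#' @param groups grouping vector, one entry per sample.
#' @param q significance level on the adjusted p (default 0.05).
#' @return data.frame: `signature`, `p`, `p_adj`, `significant`. Constant
#'   (or all-NA) signatures get NA p-values.
#' @export
group_anova_fdr <- function(scores, groups, q = 0.05) {
  scores <- as.matrix(scores)
  g <- droplevels(factor(groups))
  stopifnot(ncol(scores) == length(g))
  if (nlevels(g) < 2L || min(table(g)) < 2L) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  p <- apply(scores, 1L, function(y) {
    if (anyNA(y) || stats::sd(y) == 0) return(NA_real_)
    stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1L]
  })
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(signature = rownames(scores) %||% seq_len(nrow(scores)),
             p = unname(p), p_adj = unname(p_adj),
             significant = !is.na(p_adj) & p_adj < q,
             stringsAsFactors = FALSE)
}

#' Pairwise Student's t-tests per signature
#'
#' Post-hoc two-sided equal-variance t-tests for every pair of groups.
#' Pairs with a group of fewer than two samples are skipped with a warning.
#'
#' @inheritParams group_anova_fdr
#' @return data.frame: `signature`, `group1`, `group2`, `p`.
#' @export
posthoc_pairwise_t <- function(scores, groups) {
  scores <- as.matrix(scores)
  g <- droplevels(factor(groups))
  stopifnot(ncol(scores) == length(g))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    if (sum(g == a) < 2L || sum(g == b) < 2L) {
      warning("pair ", a, "-", b, " skipped: group with < 2 samples",
              call. = FALSE)
      next
    }
    p <- apply(scores, 1L, function(y) {
      ya <- y[g == a]; yb <- y[g == b]
      if (anyNA(c(ya, yb)) || stats::sd(c(ya, yb)) == 0) return(NA_real_)
      stats::t.test(ya, yb, var.equal = TRUE)$p.value
    })
    rows[[k]] <- data.frame(
      signature = rownames(scores) %||% seq_len(nrow(scores)),
      group1 = a, group2 = b, p = unname(p), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Per-event alteration frequency tests across subtypes
#'
#' For every alteration event (gene + event type) tests whether the altered
#' fraction differs across groups with Fisher's exact test on the
#' group x altered contingency table (the Freeman-Halton extension for more
#' than two groups), then adjusts across events with Benjamini-Hochberg.
#' Events absent from every sample are skipped.
#'
#' @param alts events x samples binary matrix (rownames like
#'   `"PIK3CA:mutation"`).
#' @param groups grouping vector, one entry per sample.
#' @return data.frame: `event`, per-group frequency columns (`freq_<group>`),
#'   `p`, `p_adj`.
#' @export
alteration_tests <- function(alts, groups) {
  alts <- as.matrix(alts)
  g <- droplevels(factor(groups))
  stopifnot(ncol(alts) == length(g), all(alts %in% c(0, 1)))
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  keep <- rowSums(alts) > 0
  if (!all(keep)) {
    message(sum(!keep), " event(s) absent from all samples skipped")
  }
  alts <- alts[keep, , drop = FALSE]
  if (nrow(alts) == 0L) {
    return(data.frame(event = character(0), p = numeric(0),
                      p_adj = numeric(0)))
  }
  lv <- levels(g)
  res <- lapply(rownames(alts), function(ev) {
    x <- alts[ev, ]
    tab <- rbind(altered = tapply(x, g, sum),
                 wild = tapply(1 - x, g, sum))
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    freqs <- tab["altered", ] / colSums(tab)
    out <- data.frame(event = ev, p = p, stringsAsFactors = FALSE)
    out[paste0("freq_", lv)] <- as.list(freqs[lv])
    out
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Compare HRD-like scores across subtypes
#'
#' Kruskal-Wallis test across groups followed by pairwise two-sample
#' Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment. The rank-sum
#' test is the operative post-hoc for independent groups; the signed-rank
#' test is only available for explicitly paired input of equal length
#' (`paired = TRUE` with exactly two groups).
#'
#' @param scores numeric vector of HRD (genomic scar) scores.
#' @param groups grouping vector.
#' @param paired logical; use the signed-rank test (two equal-size groups
#'   only).
#' @return list with `kw` (`statistic`, `df`, `p`) and `pairwise`
#'   (data.frame `group1`, `group2`, `p`, `p_adj`).
#' @export
hrd_compare <- function(scores, groups, paired = FALSE) {
  g <- droplevels(factor(groups))
  stopifnot(length(scores) == length(g))
  if (nlevels(g) < 2L || min(table(g)) < 2L) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  kw <- if (length(unique(scores)) == 1L) {
    list(statistic = NA_real_, df = nlevels(g) - 1L, p = NA_real_)
  } else {
    k <- stats::kruskal.test(scores, g)
    list(statistic = unname(k$statistic), df = unname(k$parameter),
         p = k$p.value)
  }
  pairs <- utils::combn(levels(g), 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    xa <- scores[g == a]; xb <- scores[g == b]
    p <- if (paired) {
      if (length(xa) != length(xb)) {
        stop("signed-rank test needs equal-size paired groups", call. = FALSE)
      }
      stats::wilcox.test(xa, xb, paired = TRUE, exact = FALSE)$p.value
    } else {
      stats::wilcox.test(xa, xb, exact = FALSE)$p.value
    }
    data.frame(group1 = a, group2 = b, p = p, stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  list(kw = kw, pairwise = pw)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path path to a .gmt file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  sets
}
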