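#' Fit a classification tree by greedy binary recursive partitioning
#'
#' In-house CART trainer used to re-derive the subtype decision thresholds.
#' At each node every midpoint between consecutive observed values of each
#' numeric feature is evaluated and the split with the largest Gini impurity
#' decrease is taken. Ties in Gini decrease are broken by feature name
#' (ascending) and then by the lower threshold, so fits are deterministic.
#' Growth stops at `max_depth`, at pure nodes, or when the best split's
#' improvement in resubstitution misclassification count falls below
#' `cp` times the root misclassification count (the complexity rule).
#'
#' The trainer is implemented in the package (not delegated to a tree
#' library) so that the threshold-reporting convention of
#' [report_thresholds()] is under control: a split whose midpoint lies
#' between observed values 5 and 6 is reported as the cut-off "6", i.e. the
#' smallest observed value on the right (>=) side, matching how integer
#' cut-offs on the Allred and TIL scales are reported.
#'
#' @param features data.frame (or matrix) of numeric predictor columns,
#'   e.g. `allred_total` and `til_percent`.
#' @param labels vector of class labels (coerced to factor; factor level
#'   order is the prediction tie-break order).
#' @param max_depth maximum tree depth (root = depth 0); default 5.
#' @param cp complexity parameter; default 0.0001.
#' @return an object of class `cart_tree`: a recursive node structure with
#'   per-node class counts, predicted class and split description, plus the
#'   root resubstitution error.
#' @seealso [cart_predict()], [report_thresholds()]
#' @export
cart_fit <- function(features, labels, max_depth = 5, cp = 0.0001) {
  features <- as.data.frame(features)
  if (!all(vapply(features, is.numeric, logical(1)))) {
    stop("all features must be numeric", call. = FALSE)
  }
  labels <- factor(labels)
  n <- nrow(features)
  stopifnot(n == length(labels), n >= 1L, max_depth >= 0, cp >= 0)
  if (anyNA(features) || anyNA(labels)) {
    stop("missing values in features or labels", call. = FALSE)
  }
  classes <- levels(labels)
  feat_order <- order(names(features))  # tie-break: feature name ascending
  y <- as.integer(labels)

  node_counts <- function(idx) {
    cnt <- tabulate(y[idx], nbins = length(classes))
    names(cnt) <- classes
    cnt
  }
  root_counts <- node_counts(seq_len(n))
  root_error <- n - max(root_counts)
  min_improve <- cp * root_error

  ## children's summed count-squared-over-n; maximizing this maximizes the
  ## Gini decrease (the parent term is constant within a node)
  best_split <- function(idx) {
    best <- NULL
    best_g <- -Inf
    for (j in feat_order) {
      x <- features[idx, j]
      o <- order(x)
      xs <- x[o]
      ys <- y[idx][o]
      # boundaries between distinct consecutive values
      bnd <- which(xs[-1] != xs[-length(xs)])
      if (length(bnd) == 0L) next
      cum <- apply(outer(ys, seq_along(classes), "=="), 2, cumsum)
      tot <- cum[length(ys), ]
      for (b in bnd) {
        nl <- b
        nr <- length(ys) - b
        cl <- cum[b, ]
        cr <- tot - cl
        g <- sum(cl^2) / nl + sum(cr^2) / nr
        if (g > best_g) {
          best_g <- g
          best <- list(
            feature = names(features)[j],
            threshold = (as.numeric(xs[b]) + as.numeric(xs[b + 1L])) / 2,
            threshold_report = as.numeric(xs[b + 1L]),
            err_children = (nl - max(cl)) + (nr - max(cr))
          )
        }
      }
    }
    best
  }

  grow <- function(idx, depth) {
    cnt <- node_counts(idx)
    pred <- classes[which.max(cnt)]
    err <- length(idx) - max(cnt)
    node <- list(n = length(idx), counts = cnt, prediction = pred,
                 error = err, depth = depth, leaf = TRUE)
    if (err == 0L || depth >= max_depth) return(node)
    sp <- best_split(idx)
    if (is.null(sp)) return(node)
    improvement <- err - sp$err_children
    if (improvement < min_improve || (cp > 0 && improvement <= 0)) return(node)
    go_left <- features[idx, sp$feature] < sp$threshold
    node$leaf <- FALSE
    node$feature <- sp$feature
    node$threshold <- sp$threshold
    node$threshold_report <- sp$threshold_report
    node$left <- grow(idx[go_left], depth + 1L)
    node$right <- grow(idx[!go_left], depth + 1L)
    node
  }

  tree <- list(
    root = grow(seq_len(n), 0L),
    classes = classes,
    features = names(features),
    n = n,
    root_error = root_error,
    max_depth = max_depth,
    cp = cp
  )
  class(tree) <- "cart_tree"
  tree
}

#' Predict classes from a fitted classification tree
#'
#' Routes each row down the tree: rows with feature value strictly below a
#' node's threshold go left, others right.
#'
#' @param tree a `cart_tree` from [cart_fit()].
#' @param newdata data.frame containing the tree's feature columns.
#' @return character vector of predicted class labels.
#' @export
cart_predict <- function(tree, newdata) {
  stopifnot(inherits(tree, "cart_tree"))
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(tree$features, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  one <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[[node$feature]] < node$threshold) node$left else node$right
    }
    node$prediction
  }
  vapply(seq_len(nrow(newdata)), function(i) one(tree$root, newdata[i, , drop = FALSE]),
         character(1))
}

#' Resubstitution error of a fitted tree
#'
#' Total misclassified training count summed over the leaves.
#'
#' @inheritParams cart_predict
#' @return integer misclassification count.
#' @export
cart_resub_error <- function(tree) {
  stopifnot(inherits(tree, "cart_tree"))
  walk <- function(node) {
    if (node$leaf) return(node$error)
    walk(node$left) + walk(node$right)
  }
  walk(tree$root)
}

#' Report the cut-offs of a fitted tree
#'
#' Collects every internal split as a cut-off under the
#' smallest-right-side-value convention: the reported number is the smallest
#' observed value of the split feature on the `>=` branch of the training
#' data at that node (a split whose midpoint lies between TIL 50 and 60
#' reports 60). Cut-offs are deduplicated and sorted per feature.
#'
#' @inheritParams cart_predict
#' @return named list, one sorted numeric vector of cut-offs per feature
#'   that is actually used by a split; an empty list for a depth-0 tree.
#' @export
report_thresholds <- function(tree) {
  if (!inherits(tree, "cart_tree")) {
    stop("report_thresholds() needs a fitted cart_tree", call. = FALSE)
  }
  acc <- list()
  walk <- function(node) {
    if (node$leaf) return(invisible())
    acc[[node$feature]] <<- c(acc[[node$feature]], node$threshold_report)
    walk(node$left)
    walk(node$right)
  }
  walk(tree$root)
  if (!length(acc)) return(structure(list(), names = character(0)))
  lapply(acc[order(names(acc))], function(v) sort(unique(v)))
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("CART tree: n=%d, classes=%s, root error=%d, cp=%g\n",
              x$n, paste(x$classes, collapse = "/"), x$root_error, x$cp))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%s* predict %s (n=%d, err=%d)\n",
                  pad, node$prediction, node$n, node$error))
    } else {
      cat(sprintf("%s%s < %g ? (report cut-off %g)\n",
                  pad, node$feature, node$threshold, node$threshold_report))
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  show(x$root, 0L)
  invisible(x)
}
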