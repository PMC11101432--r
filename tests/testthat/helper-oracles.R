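# Independent oracles used by the tests. These are deliberately naive
# (enumeration / textbook formulas) and share no code with the package
# implementation they check.

## exhaustive search over all axis-aligned binary partitions up to `depth`;
## returns the minimum attainable resubstitution misclassification count
brute_force_tree_error <- function(X, y, depth) {
  y <- as.character(y)
  node_err <- function(idx) length(idx) - max(table(y[idx]))
  rec <- function(idx, d) {
    best <- node_err(idx)
    if (d == 0L || best == 0L) return(best)
    for (j in seq_len(ncol(X))) {
      v <- sort(unique(X[idx, j]))
      if (length(v) < 2L) next
      for (k in seq_len(length(v) - 1L)) {
        thr <- (v[k] + v[k + 1L]) / 2
        left <- idx[X[idx, j] < thr]
        right <- idx[X[idx, j] >= thr]
        best <- min(best, rec(left, d - 1L) + rec(right, d - 1L))
      }
    }
    best
  }
  rec(seq_len(nrow(X)), depth)
}

## textbook K=2 log-rank: sum over event times of (O - E) in group 1 and the
## hypergeometric variance
hand_logrank_2g <- function(time, event, group) {
  g1 <- sort(unique(group))[1L]
  ts <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    o1 <- sum(event == 1 & time == t & group == g1)
    U <- U + o1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- U^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

## hand product-limit estimator at the observed event times
hand_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

## two-sided Fisher p for a 2x2 table by hypergeometric enumeration
hand_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## simple deterministic rule-labeled toy dataset with optional label flips
toy_rule_data <- function(n, seed, flips = 0L) {
  set.seed(seed)
  allred <- sample(0:8, n, replace = TRUE)
  til <- sample(seq(0, 100, 10), n, replace = TRUE)
  lab <- classify_subtype(allred, til)
  if (flips > 0L) {
    idx <- sample.int(n, flips)
    for (i in idx) {
      lab[i] <- sample(setdiff(c("LAR", "LP", "LI", "LD"), lab[i]), 1L)
    }
  }
  list(X = data.frame(allred_total = allred, til_percent = til), y = lab)
}

## flip a fraction of labels uniformly to a different class
flip_labels <- function(lab, frac) {
  n <- length(lab)
  idx <- sample.int(n, round(frac * n))
  for (i in idx) {
    lab[i] <- sample(setdiff(c("LAR", "LP", "LI", "LD"), lab[i]), 1L)
  }
  lab
}
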