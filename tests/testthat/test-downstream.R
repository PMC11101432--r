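toy_expr <- function(n_genes = 50, n_samples = 24, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", 1:n_genes),
                         sprintf("s%03d", 1:n_samples)))
}

test_that("mean_z scoring matches hand z-score arithmetic", {
  # frozen from an independent implementation: per-sample z across genes,
  # then the mean over set genes {g1, g2}
  M <- matrix(c(1, 4, 0, 5, 2, 2, 2, 6, 0, 1, 3, 8, 3, 5, 0), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  sc <- signature_scores(M, list(set12 = c("g1", "g2")), method = "mean_z")
  expect_equal(unname(sc["set12", ]),
               c(0.04822428, -0.08770580, 0.57635398), tolerance = 1e-7)
  # set = all genes -> 0 for every sample (a sample's z-scores sum to 0)
  sc_all <- signature_scores(M, list(all = paste0("g", 1:5)),
                             method = "mean_z")
  expect_equal(unname(sc_all["all", ]), c(0, 0, 0))
})

test_that("ssgsea scoring is rank-based and monotone in set placement", {
  expr <- toy_expr(seed = 5)
  top_set <- names(sort(expr[, 1], decreasing = TRUE))[1:5]
  bottom_set <- names(sort(expr[, 1]))[1:5]
  sc <- signature_scores(expr, list(top = top_set, bottom = bottom_set))
  expect_gt(sc["top", 1], sc["bottom", 1])
  # invariant to monotone transforms
  sc2 <- signature_scores(exp(expr), list(top = top_set, bottom = bottom_set))
  expect_equal(sc, sc2, ignore_attr = TRUE)
  expect_equal(attr(sc, "method"), "ssgsea")
  # empty overlap warns and yields NA
  expect_warning(
    sc3 <- signature_scores(expr, list(top = top_set, none = c("zz1", "zz2"))),
    "empty overlap")
  expect_true(all(is.na(sc3["none", ])))
})

test_that("ANOVA + BH behaves under null and shifted alternatives", {
  set.seed(9)
  groups <- rep(c("LAR", "LP", "LI", "LD"), each = 30)
  null_scores <- matrix(rnorm(40 * 120), 40, 120,
                        dimnames = list(paste0("sig", 1:40), NULL))
  res <- group_anova_fdr(null_scores, groups)
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
  expect_lte(mean(res$significant), 0.15)  # BH controls FDR under the null
  # one signature shifted by 3 SD in one group
  shifted <- null_scores
  shifted[1, groups == "LD"] <- shifted[1, groups == "LD"] + 3
  res2 <- group_anova_fdr(shifted, groups)
  expect_true(res2$significant[1])
  # single signature: adjusted p equals raw p
  res3 <- group_anova_fdr(null_scores[1, , drop = FALSE], groups)
  expect_equal(res3$p_adj, res3$p)
  # constant scores -> NA
  const <- matrix(1, 1, 120, dimnames = list("flat", NULL))
  expect_true(is.na(group_anova_fdr(const, groups)$p))
})

test_that("pairwise t-tests match the hand formula and are symmetric", {
  scores <- matrix(c(1, 2, 3, 2, 4, 6), 1,
                   dimnames = list("sig", NULL))
  groups <- rep(c("A", "B"), each = 3)
  res <- posthoc_pairwise_t(scores, groups)
  # frozen from scipy.stats.ttest_ind(equal_var=True)
  expect_equal(res$p, 0.19626117814926966, tolerance = 1e-10)
  res_swap <- posthoc_pairwise_t(scores, rep(c("B", "A"), each = 3))
  expect_equal(res_swap$p, res$p)
  expect_equal(nrow(posthoc_pairwise_t(
    matrix(rnorm(24), 2, 12), rep(c("a", "b", "c", "d"), 3))), 12L)
  expect_warning(
    posthoc_pairwise_t(scores, c("A", "A", "A", "A", "A", "B")),
    "skipped")
})

test_that("Fisher alteration tests agree with hypergeometric hand values", {
  # 5/5 altered in one group vs 0/15 elsewhere
  alts <- matrix(c(rep(1L, 5), rep(0L, 15)), 1,
                 dimnames = list("GENEX:mutation", paste0("s", 1:20)))
  groups <- rep(c("g1", "g2"), c(5, 15))
  res <- alteration_tests(alts, groups)
  hand <- hand_fisher_2x2(matrix(c(5, 0, 0, 15), 2, byrow = TRUE))
  expect_equal(res$p, hand, tolerance = 1e-10)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-10)
  expect_equal(res$freq_g1, 1)
  expect_equal(res$freq_g2, 0)
  # identical frequency in all groups with equal margins -> p = 1
  bal <- matrix(rep(c(1L, 0L), 10), 1, dimnames = list("G:del", NULL))
  res_bal <- alteration_tests(bal, rep(c("a", "b"), each = 10))
  expect_equal(res_bal$p, 1)
  # all-zero matrix -> empty result
  zero <- matrix(0L, 2, 10,
                 dimnames = list(c("A:mutation", "B:deletion"), NULL))
  expect_message(res0 <- alteration_tests(zero, rep(c("a", "b"), 5)),
                 "skipped")
  expect_equal(nrow(res0), 0L)
  # BH monotonicity across events
  set.seed(13)
  many <- matrix(rbinom(30 * 40, 1, 0.3), 30, 40,
                 dimnames = list(paste0("G", 1:30, ":mutation"), NULL))
  resm <- alteration_tests(many, rep(c("a", "b", "c", "d"), 10))
  expect_true(all(resm$p_adj >= resm$p))
  o <- order(resm$p)
  expect_true(all(diff(resm$p_adj[o]) >= -1e-12))
})

test_that("HRD comparison: null calibration, power and pairing contract", {
  set.seed(31)
  # null: KW rejection rate near alpha (200 replicates, 4 groups of 25)
  rej <- vapply(1:200, function(i) {
    hrd_compare(rnorm(100), rep(c("LAR", "LP", "LI", "LD"), 25))$kw$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.1)
  # LD shifted by 2 SD: LD-vs-LAR pairwise significant at n=30/group
  g <- rep(c("LAR", "LP", "LI", "LD"), each = 30)
  x <- rnorm(120) + ifelse(g == "LD", 2, 0)
  res <- hrd_compare(x, g)
  expect_lt(res$kw$p, 0.05)
  pw <- res$pairwise
  expect_lt(pw$p_adj[(pw$group1 == "LAR" & pw$group2 == "LD") |
                       (pw$group1 == "LD" & pw$group2 == "LAR")], 0.05)
  # two groups: KW p approximately equals the rank-sum p at large n
  g2 <- rep(c("a", "b"), each = 150)
  x2 <- rnorm(300) + ifelse(g2 == "b", 0.3, 0)
  res2 <- hrd_compare(x2, g2)
  expect_equal(res2$kw$p, res2$pairwise$p, tolerance = 0.05)
  # all-tied scores -> KW NA
  expect_true(is.na(hrd_compare(rep(1, 40),
                                rep(c("a", "b"), 20))$kw$p))
  # paired signed-rank needs equal sizes
  expect_error(hrd_compare(rnorm(30), rep(c("a", "b"), c(10, 20)),
                           paired = TRUE), "equal-size")
})

test_that("GMT round-trip", {
  tf <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg4\tg5"), tf)
  sets <- read_gmt(tf)
  expect_equal(sets, list(setA = c("g1", "g2", "g3"), setB = c("g4", "g5")))
})
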