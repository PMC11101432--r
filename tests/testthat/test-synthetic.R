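test_that("the fixture is deterministic and reproduces the cross-tabulation", {
  f1 <- build_table1_fixture()
  f2 <- build_table1_fixture()
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 317L)
  # 34 cases classified LAR with molecular truth LAR
  cls <- classify_table(f1)
  expect_equal(sum(cls$classified == "LAR" & cls$molecular_truth == "LAR"),
               34L)
  # invariants on the record fields
  expect_true(all(f1$ar_percent >= 0 & f1$ar_percent <= 100))
  expect_true(all(f1$til_percent >= 0 & f1$til_percent <= 100))
  expect_true(all(f1$event_os %in% 0:1 & f1$time_os >= 0))
})

test_that("cohort config validation rejects bad inputs", {
  expect_error(cohort_config(-5), "nonnegative")
  bad_priors <- setNames(c(0.3, 0.3, 0.3, 0.3, 0.3),
                         c("LAR", "IM", "BL1", "M", "UNC"))
  expect_error(cohort_config(10, subtype_priors = bad_priors), "sum to 1")
  expect_error(cohort_config(10, baseline_hazard = 0), "rates must be > 0")
  cal <- default_calibration()
  hr_bad <- cal$hr_map
  hr_bad$os$LD <- -1
  expect_error(cohort_config(10, hr_map = hr_bad), "> 0")
})

test_that("generators are seed-deterministic and honor degenerate priors", {
  cfg <- cohort_config(150, seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(generate_cohort(cohort_config(0))), 0L)
  # LAR prior 1 with AR concentrated high -> everything classified LAR
  priors <- setNames(c(1, 0, 0, 0, 0), c("LAR", "IM", "BL1", "M", "UNC"))
  cond <- matrix(0, 5, 4, dimnames = list(c("LAR", "IM", "BL1", "M", "UNC"),
                                          c("LAR", "LP", "LI", "LD")))
  cond[, "LAR"] <- 1
  cc <- cohort_config(50, seed = 9, subtype_priors = priors,
                      conditionals = cond)
  cohort <- classify_table(generate_cohort(cc))
  expect_true(all(cohort$classified == "LAR"))
  expect_true(all(cohort$molecular_truth == "LAR"))
  # TIL snapped to multiples of 10 by default
  expect_true(all(c1$til_percent %% 10 == 0))
  # expression / alteration determinism
  e1 <- generate_expression(c1, seed = 3)
  e2 <- generate_expression(c1, seed = 3)
  expect_identical(e1, e2)
  cls <- classify_table(c1)
  a1 <- generate_alterations(cls, seed = 3)
  a2 <- generate_alterations(cls, seed = 3)
  expect_identical(a1, a2)
})

test_that("a simulated cohort matches the calibrated column percentages", {
  cfg <- cohort_config(2000, seed = 11)
  cohort <- classify_table(generate_cohort(cfg))
  emp <- column_percentages(crosstab(cohort$classified,
                                     cohort$molecular_truth))
  fix <- classify_table(build_table1_fixture())
  ref <- column_percentages(crosstab(fix$classified, fix$molecular_truth))
  expect_lte(max(abs(emp - ref)), 5)
})

test_that("P(classified | truth) converges to the configured conditionals", {
  cfg <- cohort_config(5000, seed = 101)
  cohort <- classify_table(generate_cohort(cfg))
  tab <- table(factor(cohort$molecular_truth, rownames(cfg$conditionals)),
               factor(cohort$classified, colnames(cfg$conditionals)))
  emp <- prop.table(tab, 1)
  expect_lte(max(abs(emp - cfg$conditionals) * 100), 3)
})

test_that("expression generator: exact self-correlation at zero noise", {
  cases <- data.frame(
    case_id = paste0("c", 1:8),
    molecular_truth = c("LAR", "IM", "BL1", "M", "LAR", "IM", "UNC", "UNC"))
  ge <- generate_expression(cases, n_genes = 40, noise_sd = 0, seed = 2)
  for (j in 1:6) {
    r <- cor(ge$expr[, j], ge$centroids[, cases$molecular_truth[j]])
    expect_equal(r, 1, tolerance = 1e-12)
  }
  # UNC samples carry no centroid signal: expected correlation ~ 0
  set.seed(1)
  unc <- data.frame(case_id = paste0("u", 1:200),
                    molecular_truth = rep("UNC", 200))
  geu <- generate_expression(unc, n_genes = 50, noise_sd = 1, seed = 4)
  calls <- suppressMessages(call_cohort(geu$expr, geu$centroids))
  expect_gte(mean(apply(
    as.matrix(calls[, paste0("p_", c("LAR", "IM", "BL1", "M"))]), 1,
    function(p) all(p >= 0.05))), 0.5)
  expect_error(generate_expression(cases, n_genes = 5), ">= 10")
})

test_that("alteration generator respects frequencies and powers the KW test", {
  cohort <- classify_table(generate_cohort(cohort_config(400, seed = 15)))
  cal <- default_calibration()
  # frequency 0 everywhere -> empty (all-zero) matrix
  f0 <- cal$alteration_frequencies
  f0[c("LAR", "LP", "LI", "LD")] <- 0
  a0 <- generate_alterations(cohort, freq_table = f0, seed = 1)
  expect_true(all(a0$alterations == 0L))
  # frequency 1 for PIK3CA mutation in LAR -> every LAR case mutated
  f1 <- cal$alteration_frequencies
  f1$LAR[f1$gene == "PIK3CA"] <- 1
  a1 <- generate_alterations(cohort, freq_table = f1, seed = 1)
  lar_cols <- cohort$classified == "LAR"
  expect_true(all(a1$alterations["PIK3CA:mutation", lar_cols] == 1L))
  # defaults: HRD scores differ across subtypes (Kruskal-Wallis rejects)
  ad <- generate_alterations(cohort, seed = 2)
  kw <- hrd_compare(ad$hrd_scores, cohort$classified)
  expect_lt(kw$kw$p, 0.05)
  # unknown subtype key rejected
  bad <- cohort
  bad$classified[1] <- "XX"
  expect_error(generate_alterations(bad), "unknown subtype")
  # out-of-range frequency rejected
  f2 <- cal$alteration_frequencies
  f2$LD[1] <- 1.5
  expect_error(generate_alterations(cohort, freq_table = f2), "\\[0, 1\\]")
})
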