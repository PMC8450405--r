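test_that("median fold change follows the pseudocounted-median definition", {
  expect_equal(median_fold_change(c(0, 0), c(0, 0, 0))$fc, 1)
  expect_equal(median_fold_change(c(5, 5, 5), c(1, 1, 1))$fc, 3)
  # medians 2 and 4 -> (2+1)/(4+1)
  r <- median_fold_change(c(0, 2, 4), c(4, 4, 10))
  expect_equal(r$median_tumor, 2)
  expect_equal(r$median_normal, 4)
  expect_equal(r$fc, 0.6)
  expect_equal(r$fc_raw, 0.5)
  expect_error(median_fold_change(numeric(0), 1), "empty")
  # configurable pseudocount
  expect_equal(median_fold_change(c(5, 5, 5), c(1, 1, 1),
                                  pseudocount = 0.5)$fc, 5.5 / 1.5)
})

test_that("direction classification uses strict thresholds", {
  expect_identical(classify_direction(c(0.5, 0.667, 1, 1.5, 3)),
                   c("DOWN", "UNCHANGED", "UNCHANGED", "UNCHANGED", "UP"))
  expect_error(classify_direction(-1), "positive")
})

test_that("classification is antisymmetric under cohort swap", {
  set.seed(15)
  fc <- exp(rnorm(200))
  flip <- classify_direction(1 / fc)
  orig <- classify_direction(fc)
  expect_identical(flip[orig == "UP"],
                   rep("DOWN", sum(orig == "UP")))
  expect_identical(flip[orig == "DOWN"],
                   rep("UP", sum(orig == "DOWN")))
  expect_identical(flip[orig == "UNCHANGED"],
                   rep("UNCHANGED", sum(orig == "UNCHANGED")))
})

test_that("rank-sum p-values match enumeration and stats::wilcox.test", {
  r <- rank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)

  set.seed(55)
  for (i in 1:15) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    a <- round(rnorm(m), 2); b <- round(rnorm(n), 2)
    expect_equal(rank_test(a, b)$p_value, enumerate_ranksum_p(a, b),
                 tolerance = 1e-12)
    # tie-free cases also agree with the standard exact implementation
    if (!anyDuplicated(c(a, b))) {
      expect_equal(rank_test(a, b)$p_value,
                   wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
    # heavily tied layouts
    at <- sample(0:2, m, replace = TRUE); bt <- sample(0:2, n, replace = TRUE)
    expect_equal(rank_test(at, bt)$p_value, enumerate_ranksum_p(at, bt),
                 tolerance = 1e-12)
  }
  expect_error(rank_test(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("identical samples sit at the null center", {
  r <- rank_test(1:5, 1:5)
  expect_equal(r$statistic, 12.5)
  expect_equal(r$p_value, 1)
})

test_that("a large planted shift is overwhelmingly significant", {
  set.seed(99)
  a <- 8 * exp(rnorm(200, 0, 0.5))
  b <- exp(rnorm(200, 0, 0.5))
  expect_lt(rank_test(a, b)$p_value, 1e-4)
})

test_that("paired signed-rank test agrees with the standard implementation", {
  set.seed(60)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    a <- round(rnorm(n), 3); b <- round(rnorm(n), 3)
    if (anyDuplicated(abs(a - b)) || any(a == b)) next
    expect_equal(rank_test_paired(a, b)$p_value,
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # all-zero differences degenerate to p = 1
  expect_equal(rank_test_paired(1:4, 1:4)$p_value, 1)
})

test_that("cohort comparison covers genes and reactions with coherent records", {
  kb <- load_kb()
  set.seed(23)
  m <- random_kb_tpm(kb, n_samples = 6)
  same <- compare_cohorts(kb, m, m)
  expect_s3_class(same, "gag_comparison")
  expect_true(all(same$fc == 1))
  expect_true(all(same$direction == "UNCHANGED"))
  # every KB reaction has exactly one reaction-level record
  rx <- same[same$level == "reaction", ]
  expect_identical(sort(rx$target_id), sort(kb_reaction_ids(kb)))
  # gene-level records for all KB genes
  expect_setequal(same$target_id[same$level == "gene"], kb_genes(kb))
})

test_that("swapping cohorts inverts fold changes and directions", {
  kb <- load_kb()
  sim <- simulate_cohorts(cohort_sim_config(
    n_tumor = 12, n_normal = 15,
    planted_fc = c(CHST3 = 4, DSE = 0.25), seed = 31), kb)
  fwd <- compare_cohorts(kb, sim$tumor, sim$normal)
  rev <- compare_cohorts(kb, sim$normal, sim$tumor)
  ord <- order(fwd$target_id); ord2 <- order(rev$target_id)
  expect_equal(fwd$fc[ord] * rev$fc[ord2], rep(1, nrow(fwd)),
               tolerance = 1e-12)
  up_fwd <- fwd$target_id[fwd$direction == "UP"]
  down_rev <- rev$target_id[rev$direction == "DOWN"]
  expect_setequal(up_fwd, down_rev)
})

test_that("planted gene changes propagate to genes and their reactions", {
  kb <- load_kb()
  sim <- simulate_cohorts(cohort_sim_config(
    planted_fc = c(CHST3 = 4.0, DSE = 0.4), seed = 17), kb)
  cmp <- compare_cohorts(kb, sim$tumor, sim$normal)
  gene <- function(g) cmp[cmp$level == "gene" & cmp$target_id == g, ]
  expect_identical(gene("CHST3")$direction, "UP")
  expect_identical(gene("DSE")$direction, "DOWN")
  expect_lt(gene("CHST3")$p_value, 1e-4)
  # CHST3 alone carries CS 6-O-sulfation, so the reaction moves with it
  rx <- cmp[cmp$level == "reaction" &
              cmp$target_id == "csds.04.galnac_6o_sulfation", ]
  expect_identical(rx$direction, "UP")
})

test_that("disjoint gene sets and unknown extras are rejected", {
  kb <- load_kb()
  vals <- matrix(1:4, 2, dimnames = list(c("NOTAGENE1", "NOTAGENE2"),
                                         c("s1", "s2")))
  other <- expression_matrix(vals)
  set.seed(2)
  m <- random_kb_tpm(kb, 4)
  expect_error(compare_cohorts(kb, other, m), "no KB gene")
  expect_error(compare_cohorts(kb, m, m, extra_genes = "VCAN"),
               "extra genes absent")
})

test_that("median-then-aggregate ordering is available for sensitivity checks", {
  kb <- load_kb()
  set.seed(71)
  sim <- simulate_cohorts(cohort_sim_config(
    n_tumor = 10, n_normal = 10, planted_fc = c(CHST3 = 6), seed = 71), kb)
  alt <- compare_cohorts(kb, sim$tumor, sim$normal,
                         reaction_order = "median_then_aggregate")
  rx <- alt[alt$level == "reaction", ]
  expect_true(all(is.na(rx$p_value)))
  expect_identical(
    rx$direction[rx$target_id == "csds.04.galnac_6o_sulfation"], "UP")
})

test_that("optional BH adjustment adds a within-level adjusted column", {
  kb <- load_kb()
  sim <- simulate_cohorts(cohort_sim_config(
    n_tumor = 8, n_normal = 8, planted_fc = c(CHST3 = 5), seed = 13), kb)
  cmp <- compare_cohorts(kb, sim$tumor, sim$normal, bh = TRUE)
  expect_true("p_adj" %in% colnames(cmp))
  g <- cmp[cmp$level == "gene", ]
  expect_equal(g$p_adj, p.adjust(g$p_value, method = "BH"))
})
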