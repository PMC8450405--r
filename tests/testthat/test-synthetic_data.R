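test_that("simulation configs are validated", {
  expect_error(tissue_sim_config(noise_sd = -1), "noise_sd")
  expect_error(tissue_sim_config(archetypes = c(liver = "MEDIUM")),
               "HIGH_GAG")
  expect_error(cohort_sim_config(planted_fc = c(CHST3 = -2)), "> 0")
  expect_error(cohort_sim_config(planted_fc = setNames(2, "")), "named")
  expect_error(cohort_sim_config(planted_fc = c(NOSUCHGENE123 = 2)),
               "baseline")
  expect_error(cohort_sim_config(n_tumor = 0), ">= 1")
  expect_error(simulate_tissues(cohort_sim_config()), "not a tissue")
})

test_that("the default tissue panel has 37 tissues in two archetypes", {
  arch <- default_tissue_archetypes()
  expect_length(arch, 37)
  expect_identical(sum(arch == "HIGH_GAG"), 20L)
  expect_identical(sum(arch == "LOW_GAG"), 17L)
  expect_identical(unname(arch[["cerebral cortex"]]), "HIGH_GAG")
  expect_identical(unname(arch[["pancreas"]]), "LOW_GAG")
})

test_that("simulation is deterministic per seed and leaves the RNG alone", {
  kb <- load_kb()
  cfg <- tissue_sim_config(seed = 6)
  s1 <- simulate_tissues(cfg, kb)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  s2 <- simulate_tissues(cfg, kb)
  after <- runif(1)
  expect_identical(unclass(s1$matrix), unclass(s2$matrix))
  expect_identical(before, after)  # caller RNG stream unaffected

  c1 <- simulate_cohorts(cohort_sim_config(n_tumor = 5, n_normal = 5,
                                           seed = 8), kb)
  c2 <- simulate_cohorts(cohort_sim_config(n_tumor = 5, n_normal = 5,
                                           seed = 8), kb)
  expect_identical(unclass(c1$tumor), unclass(c2$tumor))
})

test_that("zero noise reproduces the deterministic means exactly", {
  kb <- load_kb()
  sim <- simulate_tissues(tissue_sim_config(noise_sd = 0, seed = 1), kb)
  base <- default_baseline()
  reaction_genes <- kb_genes(kb, include_auxiliary = FALSE)
  vals <- unclass(sim$matrix)
  expect_equal(vals["SLC35B2", "liver"],
               2^base[["SLC35B2"]], tolerance = 1e-12)
  expect_equal(vals["XYLT1", "liver"], 2^base[["XYLT1"]], tolerance = 1e-12)
  expect_equal(vals["XYLT1", "cerebral cortex"],
               2^(base[["XYLT1"]] + 3), tolerance = 1e-12)
  # auxiliary genes get no archetype offset
  expect_equal(vals["GOLPH3", "cerebral cortex"], vals["GOLPH3", "liver"],
               tolerance = 1e-12)
})

test_that("cohort simulation plants fold changes on the tumor TPM scale", {
  kb <- load_kb()
  fc <- c(CHST3 = 4, DSE = 0.4, VCAN = 4.8)
  sim <- simulate_cohorts(cohort_sim_config(n_tumor = 4, n_normal = 4,
                                            planted_fc = fc, noise_sd = 0,
                                            seed = 2), kb)
  base <- default_baseline()
  expect_equal(unname(unclass(sim$tumor)["CHST3", 1]) /
                 unname(unclass(sim$normal)["CHST3", 1]), 4,
               tolerance = 1e-12)
  expect_equal(unname(unclass(sim$tumor)["VCAN", 1]),
               2^base[["VCAN"]] * 4.8, tolerance = 1e-9)
  expect_identical(unname(sim$truth$expected_direction[c("CHST3", "DSE")]),
                   c("UP", "DOWN"))
  expect_identical(unname(sim$truth$expected_direction[["XYLT1"]]),
                   "UNCHANGED")
  # DCN-style threshold-sitting changes are not classified as UP
  sim15 <- simulate_cohorts(cohort_sim_config(n_tumor = 3, n_normal = 3,
                                              planted_fc = c(DCN = 1.5),
                                              noise_sd = 0, seed = 3), kb)
  expect_identical(unname(sim15$truth$expected_direction[["DCN"]]),
                   "UNCHANGED")
})

test_that("sample groups label tumor and normal arms", {
  sim <- simulate_cohorts(cohort_sim_config(n_tumor = 3, n_normal = 2,
                                            seed = 4))
  expect_identical(unname(table(sample_groups(sim$tumor))[["tumor"]]), 3L)
  expect_identical(unname(table(sample_groups(sim$normal))[["normal"]]), 2L)
  expect_identical(ncol(sim$tumor), 3L)
  expect_identical(ncol(sim$normal), 2L)
})

test_that("under the null almost no gene is classified as changed", {
  kb <- load_kb()
  frac_changed <- vapply(1:5, function(s) {
    sim <- simulate_cohorts(cohort_sim_config(seed = s), kb)
    cmp <- compare_cohorts(kb, sim$tumor, sim$normal)
    g <- cmp[cmp$level == "gene", ]
    mean(g$direction != "UNCHANGED")
  }, numeric(1))
  expect_lte(mean(frac_changed), 0.05)
})
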