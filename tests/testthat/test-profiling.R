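test_that("row z-scores use the sample sd and flag flat rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_identical(attr(z, "zero_variance_rows"), "b")

  z2 <- zscore_rows(rbind(c = c(0, 10)))
  expect_equal(unname(z2["c", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  expect_error(zscore_rows(m[, 1, drop = FALSE]), "2 columns")
})

test_that("nonzero-variance rows have mean 0 and sd 1 after z-scoring", {
  set.seed(12)
  m <- matrix(rnorm(300), nrow = 20)
  z <- zscore_rows(m)
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-9))
  # idempotence
  expect_equal(zscore_rows(z)[, ], z[, ], tolerance = 1e-9)
  # population-sd option
  zp <- zscore_rows(m, population_sd = TRUE)
  expect_true(all(abs(apply(zp, 1, function(r)
    sqrt(mean((r - mean(r))^2))) - 1) < 1e-9))
})

test_that("pearson correlation matches the closed-form oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 2, 4)
  m <- rbind(gx = x, gy = y, gneg = -x)
  colnames(m) <- paste0("t", 1:4)
  r <- pearson_matrix(m)
  expect_equal(r["gx", "gx"], 1)
  expect_equal(r["gx", "gneg"], -1)
  expect_equal(r["gx", "gy"], closed_form_pearson(x, y), tolerance = 1e-12)
  expect_equal(r["gx", "gy"], 18 / sqrt(380), tolerance = 1e-12)

  set.seed(77)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    mm <- rbind(a = a, b = b)
    colnames(mm) <- paste0("s", 1:10)
    r2 <- pearson_matrix(mm)
    expect_equal(r2["a", "b"], closed_form_pearson(a, b), tolerance = 1e-12)
  }
})

test_that("pearson matrix is symmetric, unit-diagonal and bounded", {
  kb <- load_kb()
  set.seed(3)
  m <- random_kb_tpm(kb, n_samples = 12)
  r <- pearson_matrix(m, genes = kb_genes(kb)[1:30])
  expect_equal(unclass(r)[, ], t(unclass(r)[, ]), tolerance = 1e-12)
  expect_equal(unname(diag(r)), rep(1, 30))
  expect_true(all(abs(r) <= 1 + 1e-12))
})

test_that("pearson is invariant under positive-scale affine transforms", {
  set.seed(8)
  m <- matrix(rnorm(50), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  r1 <- pearson_matrix(m)
  scaled <- m * runif(5, 0.5, 4) + rnorm(5)
  r2 <- pearson_matrix(scaled)
  expect_equal(unclass(r2)[, ], unclass(r1)[, ], tolerance = 1e-9)
})

test_that("degenerate correlation inputs are dropped or rejected", {
  m <- rbind(flat = rep(3, 5), g1 = 1:5, g2 = c(2, 1, 4, 3, 5))
  colnames(m) <- paste0("s", 1:5)
  r <- pearson_matrix(m)
  expect_identical(attr(r, "dropped_genes"), "flat")
  expect_identical(rownames(r), c("g1", "g2"))
  expect_error(pearson_matrix(m[, 1:2]), "3 samples")
  expect_error(pearson_matrix(rbind(flat = rep(1, 5), g = 1:5,
                                    deparse.level = 1)), "nonzero variance")
})

test_that("identical columns merge first and small trees are label-sorted", {
  m <- cbind(t1 = c(1, 2, 3), t2 = c(10, 11, 12), t3 = c(1, 2, 3))
  rownames(m) <- paste0("g", 1:3)
  cl <- hierarchical_cluster(m, axis = "cols")
  hc <- cl$hclust
  first_merge <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first_merge, c("t1", "t3"))

  two <- hierarchical_cluster(m[, c("t2", "t1")], axis = "cols")
  expect_identical(two$labels, c("t1", "t2"))
  expect_identical(sort(two$order), c("t1", "t2"))
  expect_error(hierarchical_cluster(m[, 1, drop = FALSE], axis = "cols"),
               "at least 2")
})

test_that("leaf order is a permutation of the input labels", {
  kb <- load_kb()
  set.seed(21)
  m <- random_kb_tpm(kb, n_samples = 8)
  act <- reaction_activity(kb, m)
  cl <- hierarchical_cluster(zscore_rows(unclass(act)), axis = "cols")
  expect_setequal(cl$order, colnames(act))
  k <- cut_clusters(cl, 3)
  expect_identical(sort(unique(unname(k))), 1:3)
})

test_that("clustering separates the two planted tissue archetypes", {
  skip_if_not_installed("mclust")
  kb <- load_kb()
  sim <- simulate_tissues(tissue_sim_config(seed = 4), kb)
  act <- reaction_activity(kb, harmonize_symbols(sim$matrix, kb)$matrix)
  cl <- hierarchical_cluster(zscore_rows(unclass(act)), axis = "cols")
  k2 <- cut_clusters(cl, 2)
  truth <- sim$truth$archetype_assignment[names(k2)]
  ari <- mclust::adjustedRandIndex(k2, truth)
  expect_gte(ari, 0.9)
})
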