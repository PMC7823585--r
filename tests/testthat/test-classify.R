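test_that("centroid_correlations matches closed-form cases", {
  cen <- toy_centroids(block = 5, subtypes = c("LumA", "LumB"))
  prof <- cen[, "LumA"]
  co <- centroid_correlations(prof, cen, method = "pearson")
  expect_equal(unname(co["LumA"]), 1)
  expect_equal(unname(centroid_correlations(-prof, cen,
                                            method = "pearson")["LumA"]), -1)

  # 4-gene toy profile against 2 centroids: spearman by hand-rank arithmetic
  cen4 <- cbind(A = c(1, 2, 3, 4), B = c(4, 1, 2, 3))
  rownames(cen4) <- paste0("g", 1:4)
  prof4 <- c(g1 = 10, g2 = 30, g3 = 20, g4 = 40)    # ranks 1, 3, 2, 4
  got <- centroid_correlations(prof4, cen4, method = "spearman")
  hand <- c(A = cor(c(1, 3, 2, 4), c(1, 2, 3, 4)),
            B = cor(c(1, 3, 2, 4), c(4, 1, 2, 3)))
  expect_equal(got, hand)

  const <- setNames(rep(2, 10), rownames(cen))
  expect_true(all(is.nan(centroid_correlations(const, cen))))
  expect_error(centroid_correlations(prof4[1:2], cen4), "fewer than 3")
})

test_that("exhaustive permutation p-values equal exact enumeration", {
  cen4 <- cbind(A = c(0.3, 1.2, -0.5, 2.0), B = c(1.4, -0.8, 0.9, 0.1))
  rownames(cen4) <- paste0("g", 1:4)
  set.seed(5)
  for (i in 1:5) {
    prof <- setNames(rnorm(4), paste0("g", 1:4))
    call <- permutation_confidence(prof, cen4, alpha = 0.05,
                                   exhaustive = TRUE)
    expect_equal(call$p, oracle_perm_pvalues(prof, cen4))
  }
})

test_that("a perfect centroid match is confidently assigned", {
  cen <- toy_centroids(block = 6, subtypes = c("LumA", "LumB", "Her2e"))
  prof <- cen[, "LumB"]
  call <- permutation_confidence(prof, cen, B = 1000, alpha = 0.01, seed = 9)
  expect_equal(unname(call$p["LumB"]), 1 / 1001)  # beats every permutation
  expect_identical(call$status, "assigned")
  expect_identical(call$subtype, "LumB")
  expect_error(permutation_confidence(prof, cen, B = 50), "at least 100")
  const <- setNames(rep(1, nrow(cen)), rownames(cen))
  expect_identical(permutation_confidence(const, cen, B = 200,
                                          seed = 1)$status, "unassigned")
})

test_that("calls are reproducible under a fixed seed", {
  cen <- generate_centroids(30, 1.5, seed = 2)
  set.seed(3)
  prof <- setNames(cen[, "Basal"] + rnorm(30, sd = 0.8), rownames(cen))
  c1 <- permutation_confidence(prof, cen, B = 500, seed = 77)
  c2 <- permutation_confidence(prof, cen, B = 500, seed = 77)
  expect_identical(c1, c2)

  ds <- generate_dataset(sim_config(n_cohorts = 1, samples_per_cohort = 12,
                                    n_genes = 80, n_core_genes = 5,
                                    seed = 13))
  lc <- log_cpm(ds$counts[[1]])
  r1 <- classify_samples(lc, ds$centroids, B = 300, seed = 5)
  r2 <- classify_samples(lc, ds$centroids, B = 300, seed = 5)
  expect_identical(r1, r2)
})

test_that("assign_classes maps confident subtypes to C1/C2 and none", {
  calls <- data.frame(
    sample = paste0("s", 1:6), cohort = c(rep("A", 4), "B", "B"),
    status = c("assigned", "assigned", "assigned", "ambiguous",
               "unassigned", "assigned"),
    subtype = c("LumA", "Basal", "Her2e", "LumB", NA, "Normal"),
    stringsAsFactors = FALSE)
  out <- assign_classes(calls)
  expect_identical(out$class,
                   c("C1", "C2", "C2", "none", "none", "none"))
  expect_equal(as.numeric(attr(out, "unassigned_prop")[c("A", "B")]),
               c(0.25, 0.5))
  calls$subtype[1] <- "Claudin"
  expect_error(assign_classes(calls), "unknown subtype")
})

test_that("unassigned fraction grows with noise", {
  unas <- sapply(c(0.05, 0.5, 3), function(disp) {
    mean(sapply(1:3, function(seed) {
      cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 40,
                        n_genes = 120, n_core_genes = 10,
                        nb_dispersion = disp, paired_normal_fraction = 0,
                        seed = 500 + seed)
      ds <- generate_dataset(cfg)
      lc <- log_cpm(ds$counts[[1]])
      calls <- classify_samples(lc, ds$centroids, B = 300, alpha = 0.01,
                                seed = seed)
      mean(calls$status != "assigned")
    }))
  })
  expect_true(all(diff(unas) >= 0))
})

test_that("subtype recovery is near-perfect in the easy regime", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 60, n_genes = 150,
                    n_core_genes = 10, centroid_separation = 3,
                    nb_dispersion = 0.05, paired_normal_fraction = 0,
                    seed = 61)
  ds <- generate_dataset(cfg)
  calls <- classify_samples(log_cpm(ds$counts[[1]]), ds$centroids,
                            B = 500, alpha = 0.01, seed = 62)
  tr <- ds$truth[match(calls$sample, ds$truth$sample), ]
  ok <- calls$status == "assigned"
  expect_gt(mean(ok), 0.8)
  expect_gte(mean(calls$subtype[ok] == tr$subtype[ok]), 0.95)
  expect_identical(calls$class[ok], paste0("C", tr$class[ok]))
})
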