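test_that("cox_class_model reports HR for C2 vs C1 and eligibility", {
  rec <- sim_surv_records(300, log_hr = 0.7, seed = 2)
  fit <- cox_class_model(rec)
  expect_gt(fit$hr, 1)
  expect_true(fit$eligible)
  expect_lt(fit$ci[1], fit$hr); expect_gt(fit$ci[2], fit$hr)

  small <- sim_surv_records(12, 0, censor = 0.8, seed = 3)
  w <- capture_warnings(cox_class_model(small))
  expect_true(any(grepl("ineligible", w)))
  expect_error(cox_class_model(rec[rec$class == "C1", ]), "both classes")
})

test_that("null class labels give uniform Cox p-values", {
  ps <- sapply(1:80, function(s)
    suppressWarnings(cox_class_model(sim_surv_records(120, 0,
                                                      seed = 900 + s)))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("complete separation is flagged", {
  rec <- data.frame(sample = paste0("s", 1:12),
                    time = c(1:6, 101:106),
                    event = rep(1L, 12),
                    class = rep(c("C2", "C1"), each = 6))
  expect_warning(fit <- cox_class_model(rec), "monotone|ineligible")
  expect_true(fit$separation || abs(fit$log_hr) > 3)
})

test_that("random_gene_classification: median split, determinism, geometry", {
  set.seed(5)
  m <- matrix(rnorm(80 * 40), 80, 40,
              dimnames = list(paste0("g", 1:80), paste0("s", 1:40)))
  lab <- random_gene_classification(m, n_genes = 20, seed = 7)
  expect_equal(sum(lab == 1), 20)              # even n: exact halves
  expect_identical(lab, random_gene_classification(m, n_genes = 20,
                                                   seed = 7))
  sub <- random_gene_classification(m, n_genes = 20, n_target = 30,
                                    seed = 7)
  expect_length(sub, 30)
  expect_error(random_gene_classification(m, n_genes = 200), "fewer than")

  # two planted clusters separated along every gene: PC1 recovers them
  m2 <- matrix(rnorm(60 * 50, sd = 0.3), 60, 50) +
    matrix(rep(rep(c(0, 3), each = 25), each = 60), 60, 50)
  dimnames(m2) <- list(paste0("g", 1:60), paste0("s", 1:50))
  lab2 <- random_gene_classification(m2, n_genes = 30, seed = 11)
  truth <- rep(0:1, each = 25)
  expect_gte(max(mean(lab2 == truth), mean(lab2 != truth)), 0.95)
})

test_that("v_score equals the independent oracle replicate-for-replicate", {
  set.seed(21)
  m <- matrix(rnorm(120 * 60), 120, 60,
              dimnames = list(paste0("g", 1:120), paste0("s", 1:60)))
  rec <- sim_surv_records(60, 0.4, seed = 22)
  rec$sample <- colnames(m)
  obs <- list(log_hr = 0.3, p = 0.2, n = 60)
  vs <- v_score(m, rec, obs, R = 50, n_genes = 25, seed = 23)
  expect_equal(vs$v_score,
               oracle_vscore(m, rec, 0.3, 0.2, R = 50, n_genes = 25,
                             n_target = 60, seed = 23))
  # subsampled replicates must also replay exactly
  vs2 <- v_score(m, rec, obs, R = 30, n_genes = 25, n_target = 45,
                 seed = 24)
  expect_equal(vs2$v_score,
               oracle_vscore(m, rec, 0.3, 0.2, R = 30, n_genes = 25,
                             n_target = 45, seed = 24))
})

test_that("v_score limiting cases and monotonicity in the observed fit", {
  set.seed(31)
  m <- matrix(rnorm(100 * 50), 100, 50,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:50)))
  rec <- sim_surv_records(50, 0, seed = 32)
  rec$sample <- colnames(m)
  null_obs <- list(log_hr = 0, p = 1, n = 50)
  vs_hi <- v_score(m, rec, null_obs, R = 60, seed = 33)
  expect_gt(vs_hi$v_score, 0.95)               # anything beats a null fit
  strong <- list(log_hr = 50, p = 1e-300, n = 50)
  expect_equal(v_score(m, rec, strong, R = 60, seed = 33)$v_score, 0)

  mid <- v_score(m, rec, list(log_hr = 0.5, p = 0.05, n = 50),
                 R = 60, seed = 33)$v_score
  worse_p <- v_score(m, rec, list(log_hr = 0.5, p = 0.5, n = 50),
                     R = 60, seed = 33)$v_score
  expect_gte(worse_p, mid)                     # larger observed p, larger V
})

test_that("infiltrate interaction model detects and quantifies class-dependent effects", {
  simrec <- function(n, b1, b2, seed) {
    set.seed(seed)
    cl <- rep(c("C1", "C2"), length.out = n)
    cd8 <- rbeta(n, 2, 8)
    hi <- as.integer(cd8 > median(cd8))
    rate <- 0.15 * exp(ifelse(cl == "C1", b1, b2) * hi)
    tt <- rexp(n, rate)
    ct <- runif(n, 0, quantile(tt, 0.7) * 3)
    data.frame(time = pmin(tt, ct), event = as.integer(tt <= ct),
               class = cl, CD8_T = cd8)
  }
  out <- infiltrate_interaction(simrec(400, -0.7, 0.7, 41), "CD8_T")
  expect_lt(out$interaction_p, 0.05)
  expect_lt(out$per_class_hr[["C1"]], 1)
  expect_gt(out$per_class_hr[["C2"]], 1)
  expect_gte(out$deviance_stat, 0)             # nested models
  expect_lt(out$deviance_p, 0.05)

  # no interaction planted: p behaves like a null p-value (not degenerate)
  ps <- sapply(1:25, function(s)
    infiltrate_interaction(simrec(150, 0.3, 0.3, 600 + s),
                           "CD8_T")$interaction_p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(infiltrate_interaction(simrec(50, 0, 0, 1)[0, ], "CD8_T"))
})
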