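test_that("mean-of-z signature values match hand arithmetic", {
  z <- rbind(a = c(s1 = 1, s2 = 0.5), b = c(-1, 1.5),
             c = c(0, 2.5), d = c(5, 3.5))
  expect_equal(unname(signature_value(z, c("a", "b", "c"))["s1"]), 0)
  expect_equal(unname(signature_value(z, letters[1:4])["s2"]), 2.0)
  expect_equal(signature_value(z, "d"), z["d", ])   # single feature identity
  expect_warning(v <- signature_value(z, c("a", "b", "zz")), "missing")
  expect_equal(unname(v["s1"]), 0)
  expect_error(signature_value(z, c("q1", "q2")), "no signature feature")
})

test_that("cohort-standardized sum score matches hand arithmetic", {
  # cohort matrix engineered so median = 5 and sd = 2 over all values
  base <- c(7, 9, 5)
  filler <- c(5 - sqrt(29 / 8), rep(5, 2), 5 + sqrt(29 / 8), 3, 5)
  m <- matrix(c(base, filler), ncol = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  stopifnot(abs(median(m) - 5) < 1e-12)
  sdev <- sd(as.vector(m))
  v <- ca20_value(m, c("g1", "g2", "g3"))
  expect_equal(unname(v["s1"]), sum((base - 5) / sdev))
  # the printed toy case: m = 5, sigma = 2, values (7, 9, 5) -> V = 3
  expect_equal(sum((c(7, 9, 5) - 5) / 2), 3)
  # consistency identity: sum score = k x mean of standardized values
  expect_equal(unname(v["s1"]),
               3 * mean((m[c("g1", "g2", "g3"), "s1"] - 5) / sdev))
  expect_error(ca20_value(matrix(1, 3, 3,
                                 dimnames = list(paste0("g", 1:3),
                                                 paste0("s", 1:3))),
                          "g1"), "zero")
})

test_that("sum score is linear in duplicated signature genes", {
  m <- toy_counts(genes = 12, samples = 4, seed = 6) + 0
  m2 <- rbind(m, m[1:6, ] + 0)
  rownames(m2) <- c(rownames(m), paste0("dup_", rownames(m)[1:6]))
  sig <- rownames(m)[1:6]
  # same cohort statistics: doubling the signature via duplicate values
  # doubles V when the cohort matrix is held fixed
  v1 <- ca20_value(m2, sig)
  v2 <- ca20_value(m2, c(sig, paste0("dup_", sig)))
  expect_equal(v2, 2 * v1)
})

test_that("paired differences follow D = V_tumor - V_normal", {
  scores <- c(t1 = 3, n1 = 1, t2 = 2, n2 = 2, t3 = 9)
  meta <- data.frame(sample = names(scores),
                     participant = c("p1", "p1", "p2", "p2", "p3"),
                     tissue = c("tumor", "normal", "tumor", "normal",
                                "tumor"),
                     stringsAsFactors = FALSE)
  expect_warning(d <- paired_difference(scores, meta), "skipped")
  expect_equal(d$d[d$participant == "p1"], 2)
  expect_equal(d$d[d$participant == "p2"], 0)
  expect_false("p3" %in% d$participant)
})

test_that("exact small-sample rank tests", {
  x <- c(1:8); y <- c(11:18)
  out <- class_signature_test(c(x, y),
                              rep(c("C1", "C2"), each = 8))
  expect_equal(out$p, 2 / 12870)
  expect_equal(out$adj_p, out$p)

  sr <- signed_rank_test(c(0.5, 1.2, 0.3, 2.2, 0.9, 1.1))
  expect_equal(sr$p, 0.03125)     # all-positive n = 6, two-sided 2/2^6

  set.seed(12)
  nulls <- replicate(20, class_signature_test(rnorm(20),
                                              rep(c("C1", "C2"), 10))$p)
  expect_lt(mean(nulls < 0.05), 0.3)
  expect_error(class_signature_test(1:4, c("C1", "C1", "C1", "C2")),
               "undersized")
})

test_that("BH families follow the grouping label", {
  set.seed(3)
  v <- c(rnorm(16), rnorm(16, sd = 2))
  cl <- rep(rep(c("C1", "C2"), each = 8), 2)
  grp <- rep(c("dbA", "dbB"), each = 16)
  out <- class_signature_test(v, cl, group = grp)
  expect_equal(nrow(out), 2)
  expect_setequal(out$group, c("dbA", "dbB"))
  expect_true(all(out$adj_p >= out$p))
})

test_that("expr -> zscore -> mean-z pipeline is gene-wise location/scale invariant", {
  m <- toy_counts(genes = 15, samples = 6, seed = 8) + 0
  sig <- rownames(m)[2:6]
  v1 <- signature_value(zscore_within_cohort(m), sig)
  m2 <- m
  m2[3, ] <- 10 * m2[3, ] + 100    # rescale one signature gene
  v2 <- signature_value(zscore_within_cohort(m2), sig)
  expect_equal(v1, v2)
})

test_that("bundled signature files parse", {
  tp53 <- read_signature(system.file("extdata", "tp53_signature.txt",
                                     package = "panclass"))
  expect_identical(tp53$genes, c("CDC20", "CENPA", "KIF2C", "PLK1"))
  expect_identical(tp53$mode, "mean_z")
  ca20 <- read_signature(system.file("extdata",
                                     "ca20_signature_synthetic.txt",
                                     package = "panclass"))
  expect_identical(ca20$mode, "ca20")
  expect_length(ca20$genes, 20)
  esc <- read_signature(system.file("extdata", "esc_signature.txt",
                                    package = "panclass"))
  expect_length(esc$genes, 9)
})
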