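# Cross-sample kernel-CDF statistic for one gene.  gaussian: smoothed ECDF
# with per-gene bandwidth sd/4 (zero-bandwidth guard falls back to the
# mid-rank ECDF); poisson: discrete kernel for raw counts.
kcdf_stat <- function(x, kernel = "gaussian") {
  n <- length(x)
  if (kernel == "gaussian") {
    h <- stats::sd(x) / 4
    if (!is.finite(h) || h == 0) {
      return(vapply(x, function(v)
        (sum(x < v) + 0.5 * sum(x == v)) / n, numeric(1)))
    }
    vapply(x, function(v) mean(stats::pnorm((v - x) / h)), numeric(1))
  } else {
    vapply(x, function(v) mean(stats::ppois(v, lambda = x + 0.5)),
           numeric(1))
  }
}

# Weighted KS-like random walk for one sample.  r: average ranks of the
# per-sample statistic (higher = more expressed); order: strict walk order
# from most to least expressed; inset: logical membership vector.
es_walk <- function(r, ord, inset, tau, es_mode) {
  G <- length(r)
  w <- abs(r - (G + 1) / 2)^tau
  denom <- sum(w[inset])
  k <- sum(inset)
  steps <- numeric(G)
  steps[ord] <- ifelse(inset[ord],
                       if (denom > 0) w[ord] / denom else 1 / k,
                       -1 / (G - k))
  walk <- cumsum(steps[ord])
  if (es_mode == "max_diff") {
    max(c(0, walk)) + min(c(0, walk))
  } else {
    walk[which.max(abs(walk))]
  }
}

#' Single-sample gene-set enrichment scores
#'
#' Rank-based random-walk enrichment in the GSVA style.  Per gene, a
#' cross-sample kernel-CDF statistic expresses how high the gene sits in each
#' sample relative to its own cross-sample distribution (gaussian kernel with
#' bandwidth `sd/4` on log-scale data; a poisson kernel is available for raw
#' counts).  Per sample, genes are ranked by that statistic (ties get average
#' ranks) and ranks are symmetrized about the midpoint; per set, a weighted
#' Kolmogorov-Smirnov-like walk runs from the most to the least expressed
#' gene with in-set increments proportional to `|symmetrized rank|^tau` and
#' constant out-of-set decrements.  The enrichment score is the sum of the
#' maximum positive and maximum negative deviations (`max_diff`, default) or
#' the single largest-magnitude deviation (`max_abs`).
#'
#' @param x `expr_matrix` (logCPM recommended for the gaussian kernel) or
#'   bare matrix.
#' @param sets named list of gene-id vectors; sets with no gene in `x` are
#'   dropped with a warning.  Use [filter_gene_sets()] beforehand to apply
#'   the production 15-500 size window.
#' @param kernel `"gaussian"` or `"poisson"`.
#' @param tau rank weight exponent (default 1).
#' @param es_mode `"max_diff"` or `"max_abs"`.
#' @return Matrix of class `enrichment_matrix`, sets x samples, with the
#'   parameter record in attribute `"params"` and cohort in `"cohort"`.
#' @export
gsva_scores <- function(x, sets, kernel = c("gaussian", "poisson"),
                        tau = 1, es_mode = c("max_diff", "max_abs")) {
  kernel <- match.arg(kernel)
  es_mode <- match.arg(es_mode)
  m <- expr_values(x)
  if (ncol(m) < 3L) stop("kernel CDF estimation needs at least 3 samples")
  sets <- lapply(sets, intersect, y = rownames(m))
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) with no gene in the matrix dropped")
    sets <- sets[!empty]
  }
  if (length(sets) == 0L) stop("no usable gene sets")
  z <- t(apply(m, 1L, kcdf_stat, kernel = kernel))
  G <- nrow(m)
  es <- matrix(NA_real_, length(sets), ncol(m),
               dimnames = list(names(sets), colnames(m)))
  member <- lapply(sets, function(s) rownames(m) %in% s)
  for (j in seq_len(ncol(m))) {
    r <- rank(z[, j])
    ord <- order(z[, j], decreasing = TRUE)
    for (i in seq_along(sets)) {
      es[i, j] <- es_walk(r, ord, member[[i]], tau, es_mode)
    }
  }
  structure(es,
            params = list(kernel = kernel, tau = tau, es_mode = es_mode),
            cohort = if (inherits(x, "expr_matrix")) x$cohort else "cohort1",
            class = c("enrichment_matrix", class(es)))
}

#' Per-set rank test of enrichment scores between the C1 and C2 classes
#'
#' Two-sided Wilcoxon rank-sum test per gene set, BH-adjusted within the
#' cohort; the direction is the sign of `median(C2) - median(C1)`.
#'
#' @param scores sets x samples matrix ([gsva_scores()] output) or any
#'   feature x sample matrix.
#' @param classes character vector of `"C1"`/`"C2"` labels, either named by
#'   sample or aligned with the columns of `scores`; samples with any other
#'   label are ignored.
#' @param min_per_class minimum samples per class (production consistency
#'   runs use 8; relax for toy data).
#' @return Data frame: `feature`, `statistic` (rank-sum W), `p`, `adj_p`,
#'   `direction` (+1 when C2 > C1), `median_diff`.
#' @export
enrichment_class_test <- function(scores, classes, min_per_class = 2) {
  scores <- as.matrix(scores)
  if (!is.null(names(classes))) {
    classes <- classes[colnames(scores)]
  } else if (length(classes) != ncol(scores)) {
    stop("classes must be named by sample or aligned with columns")
  }
  i1 <- which(classes == "C1")
  i2 <- which(classes == "C2")
  if (length(i1) < min_per_class || length(i2) < min_per_class) {
    stop(sprintf("need at least %d samples per class (got %d C1, %d C2)",
                 min_per_class, length(i1), length(i2)))
  }
  res <- t(apply(scores, 1L, function(v) {
    wt <- suppressWarnings(stats::wilcox.test(v[i2], v[i1],
                                              alternative = "two.sided"))
    md <- stats::median(v[i2]) - stats::median(v[i1])
    c(statistic = unname(wt$statistic), p = wt$p.value,
      median_diff = md)
  }))
  out <- data.frame(feature = rownames(scores),
                    statistic = res[, "statistic"],
                    p = res[, "p"],
                    adj_p = stats::p.adjust(res[, "p"], method = "BH"),
                    direction = sign(res[, "median_diff"]),
                    median_diff = res[, "median_diff"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
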