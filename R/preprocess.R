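#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scaling factors for count data, following the published TMM
#' procedure: the reference sample is the one whose 75th-percentile count
#' fraction is closest to the mean of those fractions; for every sample,
#' M-values (log2 ratios of count fractions against the reference) and
#' A-values (average log2 abundances) are computed over genes positive in both
#' the sample and the reference, the 30 percent most extreme M-values and the
#' 5 percent most extreme A-values are trimmed on each side, and the factor is
#' 2 to the precision-weighted mean of the surviving M-values.  Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param x `expr_matrix` of raw counts (or bare count matrix).
#' @param logratio_trim,abundance_trim two-sided trim fractions for M and A.
#' @return Object of class `tmm_factors`: a named numeric vector of per-sample
#'   factors with the reference sample id in attribute `"reference"`.
#' @export
tmm_factors <- function(x, logratio_trim = 0.30, abundance_trim = 0.05) {
  m <- expr_values(x, unit = "counts")
  lib <- colSums(m)
  zero <- lib == 0
  if (any(zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  n <- ncol(m)
  if (n < 2L) {
    warning("single sample: identity TMM factor")
    out <- stats::setNames(1, colnames(m))
    return(structure(out, reference = colnames(m)[1L], class = "tmm_factors"))
  }
  f75 <- apply(m, 2L, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- m[, ref]
  nr <- lib[ref]
  f <- vapply(seq_len(n), function(j) {
    if (j == ref) return(1)
    ys <- m[, j]
    ns <- lib[j]
    ok <- ys > 0 & yr > 0
    ys <- ys[ok]; yrk <- yr[ok]
    M <- log2((ys / ns) / (yrk / nr))
    A <- 0.5 * log2((ys / ns) * (yrk / nr))
    # asymptotic delta-method variance of M (binomial sampling in both samples)
    w <- (ns - ys) / (ns * ys) + (nr - yrk) / (nr * yrk)
    ng <- length(M)
    loM <- floor(ng * logratio_trim) + 1
    hiM <- ng + 1 - loM
    loA <- floor(ng * abundance_trim) + 1
    hiA <- ng + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(stats::setNames(f, colnames(m)), reference = colnames(m)[ref],
            class = "tmm_factors")
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat(sprintf("<tmm_factors> %d samples, reference '%s'\n",
              length(x), attr(x, "reference")))
  print(unclass(x)[seq_len(min(6L, length(x)))])
  invisible(x)
}

#' Log2 counts-per-million transform
#'
#' `CPM = counts / (library size x TMM factor) * 1e6`; the returned values are
#' `log2(CPM + 0.5)` so zero counts map to `log2(0.5) = -1` and stay finite.
#'
#' @param x `expr_matrix` of raw counts.
#' @param factors optional [tmm_factors()] result aligned to the samples of
#'   `x`; computed on the fly when `NULL`.  Use `factors = 1` for raw
#'   library-size CPM.
#' @param log take log2 of `CPM + 0.5` (default) or return plain CPM.
#' @return `expr_matrix` with unit `"logCPM"` (or `"CPM"`).
#' @export
log_cpm <- function(x, factors = NULL, log = TRUE) {
  m <- expr_values(x, unit = "counts")
  if (is.null(factors)) factors <- tmm_factors(m)
  if (length(factors) == 1L && is.null(names(factors))) {
    factors <- stats::setNames(rep(factors, ncol(m)), colnames(m))
  }
  if (!all(colnames(m) %in% names(factors))) {
    stop("normalization factors do not cover all samples")
  }
  f <- unclass(factors)[colnames(m)]
  cpm <- sweep(m, 2L, colSums(m) * f, "/") * 1e6
  cohort <- if (inherits(x, "expr_matrix")) x$cohort else "cohort1"
  if (log) {
    expr_matrix(log2(cpm + 0.5), cohort = cohort, unit = "logCPM")
  } else {
    expr_matrix(cpm, cohort = cohort, unit = "CPM")
  }
}

#' Low-expression gene filter
#'
#' A gene is discarded when its CPM (raw library sizes, no TMM rescaling) is
#' below `cpm_threshold` in more than half of the cohort's samples; "more than
#' half" is strict, so a gene above threshold in exactly half of an even-sized
#' cohort is kept.
#'
#' @param x `expr_matrix` of raw counts for one cohort.
#' @param cpm_threshold CPM cutoff (default 1).
#' @return Named logical vector, `TRUE` for genes to keep.
#' @export
filter_low_expression <- function(x, cpm_threshold = 1) {
  m <- expr_values(x, unit = "counts")
  if (ncol(m) == 0L) stop("empty cohort")
  cpm <- sweep(m, 2L, colSums(m), "/") * 1e6
  low <- rowSums(cpm < cpm_threshold)
  stats::setNames(!(low > ncol(m) / 2), rownames(m))
}

# Row-wise z-scoring of a bare matrix (n-1 denominator); constant rows -> 0.
zscore_rows <- function(m) {
  if (ncol(m) < 2L) stop("z-scoring needs at least 2 samples per cohort")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  flat <- sd == 0 | !is.finite(sd)
  if (any(flat)) {
    warning(sum(flat), " constant feature(s) mapped to z = 0")
    sd[flat] <- 1
  }
  z <- (m - mu) / sd
  z[flat, ] <- 0
  z
}

#' Within-cohort z-scoring
#'
#' Standardizes each gene (row) to mean 0 and unit sample standard deviation
#' (n-1 denominator) within the cohort.  Constant genes map to 0 with a
#' warning.
#'
#' @param x `expr_matrix` (any real-valued unit) or bare matrix.
#' @return `expr_matrix` with unit `"zscore"` (or a bare matrix when the input
#'   was one).
#' @export
zscore_within_cohort <- function(x) {
  m <- expr_values(x)
  z <- zscore_rows(m)
  if (inherits(x, "expr_matrix")) {
    expr_matrix(z, cohort = x$cohort, unit = "zscore")
  } else {
    z
  }
}
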