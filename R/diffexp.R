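# Moment-based fit of the scaled inverse-chi-square prior for gene-wise
# variances: log s^2 is a shifted log-F; matching its mean and variance gives
# the prior df d0 and prior variance s0^2.  Genes with s^2 = 0 are excluded
# from the fit.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s02 = mean(s2[ok], na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of trigamma on (0, Inf) (monotone decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Moderated two-group differential expression on logCPM
#'
#' Per gene, a two-group comparison of C2 against C1 on logCPM values with
#' empirical-Bayes variance moderation: the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)` with the prior `(d0, s0^2)` fitted by
#' moments on the log sample variances, and the moderated t statistic is
#' referred to a t distribution with `d0 + d` degrees of freedom.  P-values
#' are BH-adjusted within the cohort.
#'
#' @param x `expr_matrix` of logCPM values (or bare matrix), already filtered
#'   for low expression.
#' @param classes `"C1"`/`"C2"` labels, named by sample or aligned with the
#'   columns; other labels are dropped.
#' @param min_per_class cohort eligibility gate (default 8 samples per
#'   class).
#' @param prior_df override the fitted prior df `d0` (0 gives ordinary
#'   two-sample t statistics; `NULL` fits by moments).
#' @return Data frame of class `de_result`: `feature`, `lfc`
#'   (mean C2 - mean C1), `t`, `p`, `adj_p`, `direction`; the fitted prior
#'   and per-class sizes are attached as attributes.
#' @export
moderated_de <- function(x, classes, min_per_class = 8, prior_df = NULL) {
  m <- expr_values(x)
  if (!is.null(names(classes))) {
    classes <- classes[colnames(m)]
  } else if (length(classes) != ncol(m)) {
    stop("classes must be named by sample or aligned with columns")
  }
  i1 <- which(classes == "C1")
  i2 <- which(classes == "C2")
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < min_per_class || n2 < min_per_class) {
    stop(sprintf("cohort not eligible: %d C1 / %d C2 (need >= %d each)",
                 n1, n2, min_per_class))
  }
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  ss <- function(idx, mu) rowSums((m[, idx, drop = FALSE] - mu)^2)
  df <- n1 + n2 - 2
  s2 <- (ss(i1, m1) + ss(i2, m2)) / df
  if (all(s2 == 0)) stop("zero within-group variance for every gene")
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, df)
  } else {
    prior <- list(d0 = prior_df,
                  s02 = if (prior_df > 0) fit_variance_prior(s2, df)$s02
                        else NA_real_)
  }
  d0 <- prior$d0
  post <- if (is.infinite(d0)) rep(prior$s02, length(s2))
          else if (d0 == 0) s2
          else (d0 * prior$s02 + df * s2) / (d0 + df)
  lfc <- m2 - m1
  tstat <- lfc / sqrt(post * (1 / n1 + 1 / n2))
  tdf <- min(d0 + df, .Machine$double.xmax)
  p <- 2 * stats::pt(-abs(tstat), df = tdf)
  p[!is.finite(tstat)] <- NA_real_
  tstat[s2 == 0 & lfc == 0] <- 0
  p[s2 == 0 & lfc == 0] <- 1
  out <- data.frame(feature = rownames(m), lfc = lfc, t = tstat, p = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    direction = sign(lfc),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior") <- prior
  attr(out, "n_per_class") <- c(C1 = n1, C2 = n2)
  attr(out, "cohort") <- if (inherits(x, "expr_matrix")) x$cohort else NA
  class(out) <- c("de_result", class(out))
  out
}

#' Cross-cohort consistency counting of differential features
#'
#' Counts, per feature, the cohorts in which it is significant (BH-adjusted
#' p below `alpha`) and, when `require_direction = TRUE`, up-regulated in C2
#' (`direction > 0`).  Features reaching `min_cohorts` significant cohorts
#' form the core list; features significant in more than half of the
#' eligible cohorts form the broad list.
#'
#' @param results named list of per-cohort result tables, each with columns
#'   `feature`, `adj_p` and `direction` ([moderated_de()] or
#'   [enrichment_class_test()] output).  All tables must share one feature
#'   universe.
#' @param min_cohorts core threshold (e.g. 30 of 33 cohorts).
#' @param require_direction demand C2 > C1 concordance on top of
#'   significance.
#' @param alpha adjusted-p significance gate within each cohort.
#' @return Data frame of class `consistency_table`: `feature`, `n_cohorts`,
#'   `n_significant`, `direction` (sign of the summed significant
#'   directions), `is_core`, `in_broad`.
#' @export
cross_cohort_consistency <- function(results, min_cohorts,
                                     require_direction = TRUE,
                                     alpha = 0.05) {
  stopifnot(length(results) >= 1L)
  universe <- results[[1L]]$feature
  bad <- names(results)[!vapply(results, function(r)
    setequal(r$feature, universe), logical(1))]
  if (length(bad)) {
    stop("inconsistent feature universes in cohort(s): ",
         paste(bad, collapse = ", "))
  }
  nC <- length(results)
  hits <- sapply(results, function(r) {
    r <- r[match(universe, r$feature), ]
    sig <- !is.na(r$adj_p) & r$adj_p < alpha
    if (require_direction) sig & r$direction > 0 else sig
  })
  dirs <- sapply(results, function(r) {
    r <- r[match(universe, r$feature), ]
    ifelse(!is.na(r$adj_p) & r$adj_p < alpha, r$direction, 0)
  })
  nsig <- rowSums(hits)
  out <- data.frame(feature = universe,
                    n_cohorts = nC,
                    n_significant = nsig,
                    direction = sign(rowSums(dirs)),
                    is_core = nsig >= min_cohorts,
                    in_broad = nsig > nC / 2,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "thresholds") <- list(min_cohorts = min_cohorts, alpha = alpha,
                                  require_direction = require_direction)
  class(out) <- c("consistency_table", class(out))
  out
}
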