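#' Levene / Brown-Forsythe test of variance homogeneity
#'
#' One-way Levene test on the absolute deviations from the group center
#' (median by default, the robust Brown-Forsythe variant; switchable to the
#' mean-centered original).
#'
#' @param values numeric response vector.
#' @param groups group labels.
#' @param center `"median"` (Brown-Forsythe) or `"mean"`.
#' @return List with `statistic` (F), `df`, and `p`.
#' @export
levene_test <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  ctr <- tapply(values, groups,
                if (center == "median") stats::median else mean)
  dev <- abs(values - ctr[groups])
  fit <- stats::anova(stats::lm(dev ~ groups))
  list(statistic = fit$`F value`[1L],
       df = fit$Df,
       p = fit$`Pr(>F)`[1L])
}

#' Per-drug linear models of lnIC50 on the C1/C2 class
#'
#' For each drug within each cohort with at least `min_per_class` cell lines
#' per class, fits the two-group linear model `lnIC50 ~ class` (whose p-value
#' equals the equal-variance two-sample t-test), checks residual normality
#' (Shapiro-Wilk) and variance homogeneity (Levene, median-centered), and
#' BH-adjusts the model p-values within each cohort.  A drug is flagged
#' significant only when adjusted p < `alpha` AND Shapiro-Wilk p > 0.05 AND
#' Levene p > 0.05 (`nominal = TRUE` gates on the raw model p instead, the
#' looser reported rule).
#'
#' @param responses data frame with columns `cell_line`, `cohort`, `drug`,
#'   `lnIC50` (one record per cell line and drug).
#' @param classes `"C1"`/`"C2"` labels named by cell line.
#' @param alpha model p-value gate (default 0.01).
#' @param nominal gate on the raw rather than BH-adjusted model p.
#' @param min_per_class cell lines required per class (default 2).
#' @param levene_center passed to [levene_test()].
#' @return Data frame of class `drug_scan`: per cohort x drug, `effect`
#'   (mean lnIC50 C2 - C1), `p`, `adj_p`, `shapiro_p`, `levene_p`,
#'   `significant`, `n_C1`, `n_C2`, `skipped_reason`; per-cohort signed
#'   counts of significant drugs favoring each class are in attribute
#'   `"class_balance"`.
#' @export
drug_class_scan <- function(responses, classes, alpha = 0.01,
                            nominal = FALSE, min_per_class = 2,
                            levene_center = "median") {
  stopifnot(all(c("cell_line", "cohort", "drug", "lnIC50")
                %in% names(responses)))
  if (anyDuplicated(responses[, c("cell_line", "drug")])) {
    stop("more than one record per (cell line, drug)")
  }
  responses$class <- classes[responses$cell_line]
  responses <- responses[responses$class %in% c("C1", "C2"), ]
  res <- lapply(split(responses, responses$cohort), function(coh) {
    rows <- lapply(split(coh, coh$drug), function(d) {
      n1 <- sum(d$class == "C1"); n2 <- sum(d$class == "C2")
      out <- data.frame(cohort = d$cohort[1L], drug = d$drug[1L],
                        effect = NA_real_, p = NA_real_,
                        shapiro_p = NA_real_, levene_p = NA_real_,
                        n_C1 = n1, n_C2 = n2,
                        skipped_reason = NA_character_,
                        stringsAsFactors = FALSE)
      if (n1 < min_per_class || n2 < min_per_class) {
        out$skipped_reason <- "fewer than 2 cell lines in a class"
        return(out)
      }
      fit <- stats::lm(lnIC50 ~ class, data = d)
      an <- stats::anova(fit)
      out$effect <- mean(d$lnIC50[d$class == "C2"]) -
        mean(d$lnIC50[d$class == "C1"])
      out$p <- an$`Pr(>F)`[1L]
      rs <- stats::residuals(fit)
      out$shapiro_p <- if (length(rs) >= 3 && length(rs) <= 5000 &&
                           stats::sd(rs) > 0)
        stats::shapiro.test(rs)$p.value else NA_real_
      out$levene_p <- levene_test(d$lnIC50, d$class,
                                  center = levene_center)$p
      out
    })
    tab <- do.call(rbind, c(rows, make.row.names = FALSE))
    tab$adj_p <- stats::p.adjust(tab$p, method = "BH")
    tab
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  gate_p <- if (nominal) out$p else out$adj_p
  out$significant <- !is.na(gate_p) & gate_p < alpha &
    !is.na(out$shapiro_p) & out$shapiro_p > 0.05 &
    !is.na(out$levene_p) & out$levene_p > 0.05
  cols <- c("cohort", "drug", "effect", "p", "adj_p", "shapiro_p",
            "levene_p", "significant", "n_C1", "n_C2", "skipped_reason")
  out <- out[, cols]
  sig <- out[out$significant, ]
  balance <- do.call(rbind, lapply(split(sig, sig$cohort), function(s)
    data.frame(cohort = s$cohort[1L],
               favor_C2 = sum(s$effect < 0),   # C2 more sensitive
               favor_C1 = sum(s$effect > 0),
               stringsAsFactors = FALSE)))
  attr(out, "class_balance") <- balance
  attr(out, "gate") <- list(alpha = alpha, nominal = nominal)
  class(out) <- c("drug_scan", class(out))
  out
}
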