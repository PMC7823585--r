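#' Univariate Cox model of survival on the C1/C2 class
#'
#' Fits `Surv(time, event) ~ class` and reports the hazard ratio of C2
#' against C1 with its Wald confidence interval and p-value.  Cohorts with
#' fewer than `min_events` death events are flagged ineligible with a
#' warning (the pipeline's gate is 10 events); monotone likelihood
#' (complete separation) is reported with a warning and flagged.
#'
#' @param records data frame with columns `time` (> 0), `event` (0/1) and
#'   `class` (`"C1"`/`"C2"`; other rows dropped).
#' @param min_events eligibility gate on the number of events.
#' @return List of class `cox_class_fit`: `log_hr`, `hr`, `se`, `ci`
#'   (95 percent), `p`, `n`, `n_events`, `eligible`, `separation`.
#' @export
cox_class_model <- function(records, min_events = 10) {
  stopifnot(all(c("time", "event", "class") %in% names(records)))
  records <- records[records$class %in% c("C1", "C2"), ]
  if (length(unique(records$class)) < 2L) {
    stop("both classes must be present")
  }
  if (any(records$time <= 0)) stop("survival times must be positive")
  nev <- sum(records$event)
  eligible <- nev >= min_events
  if (!eligible) {
    warning(sprintf("only %d events (< %d): cohort flagged ineligible",
                    nev, min_events))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ I(class == "C2"),
                    data = records),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep) warning("monotone likelihood: hazard ratio estimate unstable")
  beta <- unname(stats::coef(fit)[1L])
  se <- sqrt(unname(fit$var[1L, 1L]))
  structure(list(log_hr = beta, hr = exp(beta), se = se,
                 ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 n = nrow(records), n_events = nev,
                 eligible = eligible, separation = sep),
            class = "cox_class_fit")
}

#' @export
print.cox_class_fit <- function(x, ...) {
  cat(sprintf("<cox_class_fit> HR(C2 vs C1) = %.3f [%.3f, %.3f], p = %.3g (%d events)\n",
              x$hr, x$ci[1], x$ci[2], x$p, x$n_events))
  invisible(x)
}

#' Random-gene PCA-median-split classification
#'
#' The building block of the V-score null: draw `n_genes` genes at random,
#' z-score them across samples, take the first principal component of the
#' samples, split at its median (samples exactly at the median go to the
#' low side), and subsample without replacement to `n_target` samples so the
#' replicate matches the size of the classification under study.  The PC1
#' sign is made deterministic by forcing the largest-magnitude gene loading
#' positive.
#'
#' @param x gene x sample matrix (`expr_matrix` on any real scale or bare
#'   matrix).
#' @param n_genes genes per random signature (default 50).
#' @param n_target replicate sample size; `NULL` keeps all samples (no
#'   subsampling draw is consumed in that case).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @param max_retries redraws allowed when PC1 is constant.
#' @return Named integer vector (1 = above-median PC1, 0 = at-or-below) on
#'   the retained samples.
#' @export
random_gene_classification <- function(x, n_genes = 50, n_target = NULL,
                                       seed = NULL, max_retries = 10) {
  m <- expr_values(x)
  if (nrow(m) < n_genes) stop("matrix has fewer than n_genes genes")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_target)) n_target <- ncol(m)
  if (n_target > ncol(m)) stop("n_target exceeds the number of samples")
  for (try in seq_len(max_retries)) {
    genes <- sample.int(nrow(m), n_genes)
    z <- zscore_rows_quiet(m[genes, , drop = FALSE])
    sv <- svd(t(z) - colMeans(t(z)), nu = 1, nv = 1)
    load <- sv$v[, 1L]
    if (load[which.max(abs(load))] < 0) load <- -load
    pc1 <- drop((t(z) - colMeans(t(z))) %*% load)
    if (stats::sd(pc1) > 0) {
      lab <- as.integer(pc1 > stats::median(pc1))
      names(lab) <- colnames(m)
      if (n_target < length(lab)) {
        lab <- lab[sort(sample.int(length(lab), n_target))]
      }
      return(lab)
    }
  }
  stop("PC1 constant after ", max_retries, " gene redraws")
}

zscore_rows_quiet <- function(m) suppressWarnings(zscore_rows(m))

#' V-score: benchmarking a classification against random-gene nulls
#'
#' Repeats [random_gene_classification()] `R` times, refits the Cox class
#' model on each replicate, and reports the proportion of replicates that
#' outperform the observed fit: a larger `|log HR|` *and* a smaller p-value
#' ("more prominent hazard ratio and smaller p-value").  Replicates whose
#' Cox fit fails count as non-outperforming and are tallied.
#'
#' @param x gene x sample expression matrix covering the cohort's samples.
#' @param records survival data frame (`sample`, `time`, `event`); replicate
#'   class labels are joined by sample id.
#' @param observed list with elements `log_hr` (or `hr`) and `p` of the
#'   classification under study, e.g. a [cox_class_model()] fit.
#' @param R replicate count (published analyses use 5000).
#' @param n_genes genes per random signature.
#' @param n_target replicate size; defaults to the number of samples used by
#'   the observed classification (`observed$n`) when available.
#' @param seed integer seed for the whole replicate stream.
#' @return List of class `v_score_result`: `v_score`, `n_outperform`, `R`,
#'   `n_failed`, `observed`, `seed`.
#' @export
v_score <- function(x, records, observed, R = 5000, n_genes = 50,
                    n_target = NULL, seed = 1) {
  stopifnot(R >= 1)
  m <- expr_values(x)
  stopifnot(all(c("sample", "time", "event") %in% names(records)))
  records <- records[records$sample %in% colnames(m), ]
  m <- m[, colnames(m) %in% records$sample, drop = FALSE]
  if (ncol(m) < 2L) stop("fewer than 2 samples shared between matrix and records")
  obs_loghr <- if (!is.null(observed$log_hr)) observed$log_hr
               else log(observed$hr)
  obs_p <- observed$p
  if (is.null(n_target)) {
    n_target <- if (!is.null(observed$n)) min(observed$n, ncol(m))
                else ncol(m)
  }
  set.seed(seed)
  wins <- 0L
  fails <- 0L
  for (r in seq_len(R)) {
    lab <- random_gene_classification(m, n_genes = n_genes,
                                      n_target = n_target, seed = NULL)
    rec <- records[match(names(lab), records$sample), ]
    rec$class <- ifelse(lab == 1L, "C2", "C1")
    fit <- tryCatch(
      suppressWarnings(cox_class_model(rec, min_events = 0)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$log_hr) || !is.finite(fit$p)) {
      fails <- fails + 1L
    } else if (abs(fit$log_hr) > abs(obs_loghr) && fit$p < obs_p) {
      wins <- wins + 1L
    }
  }
  structure(list(v_score = wins / R, n_outperform = wins, R = R,
                 n_failed = fails,
                 observed = list(log_hr = obs_loghr, p = obs_p),
                 seed = seed),
            class = "v_score_result")
}

#' @export
print.v_score_result <- function(x, ...) {
  cat(sprintf("<v_score_result> V = %.4f (%d / %d replicates outperform, %d failed)\n",
              x$v_score, x$n_outperform, x$R, x$n_failed))
  invisible(x)
}

#' Class-by-immune-infiltrate Cox interaction model
#'
#' Dichotomizes one cell type's infiltrate fraction at the within-cohort
#' median (ties to the low side), fits the complete Cox model
#' `Surv ~ class * high_infiltrate`, and reports the interaction Wald
#' p-value, the likelihood-ratio (analysis of deviance) comparison of the
#' complete model against the infiltrate-only model, and per-class hazard
#' ratios of the high-infiltrate effect.
#'
#' @param records data frame with `time`, `event`, `class` and the
#'   infiltrate fraction column named by `fraction_col`.
#' @param fraction_col name of the cell-type fraction column.
#' @param min_events_warn warn when a class has fewer events than this.
#' @return List of class `infiltrate_interaction`: `interaction_p`,
#'   `deviance_p`, `deviance_stat`, `per_class_hr`, `fits`.
#' @export
infiltrate_interaction <- function(records, fraction_col,
                                   min_events_warn = 10) {
  stopifnot(all(c("time", "event", "class", fraction_col)
                %in% names(records)))
  records <- records[records$class %in% c("C1", "C2"), ]
  frac <- records[[fraction_col]]
  if (anyNA(frac)) stop("missing infiltrate fractions")
  records$high <- as.integer(frac > stats::median(frac))
  for (cl in c("C1", "C2")) {
    strat <- records[records$class == cl, ]
    if (nrow(strat) == 0L) stop("empty stratum: class ", cl)
    if (sum(strat$event) < min_events_warn) {
      warning(sprintf("class %s has only %d events", cl, sum(strat$event)))
    }
  }
  full <- survival::coxph(survival::Surv(time, event) ~ class * high,
                          data = records)
  uni <- survival::coxph(survival::Surv(time, event) ~ high,
                         data = records)
  co <- summary(full)$coefficients
  irow <- grep(":", rownames(co))
  dev <- 2 * (full$loglik[2L] - uni$loglik[2L])
  ddf <- length(stats::coef(full)) - length(stats::coef(uni))
  per_class <- vapply(c("C1", "C2"), function(cl) {
    f <- survival::coxph(survival::Surv(time, event) ~ high,
                         data = records[records$class == cl, ])
    exp(unname(stats::coef(f)[1L]))
  }, numeric(1))
  structure(list(interaction_p = unname(co[irow, "Pr(>|z|)"]),
                 deviance_stat = dev,
                 deviance_p = stats::pchisq(dev, df = ddf,
                                            lower.tail = FALSE),
                 per_class_hr = per_class,
                 fits = list(full = full, infiltrate_only = uni)),
            class = "infiltrate_interaction")
}
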