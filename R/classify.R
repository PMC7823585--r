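#' Correlations between a sample profile and subtype centroids
#'
#' @param profile named numeric vector of a sample's expression over the
#'   panel genes.
#' @param centroids matrix of reference values, panel genes x subtypes.
#' @param method `"spearman"` (default; ties get average ranks) or
#'   `"pearson"`.
#' @return Named numeric vector, one correlation per subtype.  A constant
#'   profile yields `NaN` for every subtype (the sample cannot be assigned).
#' @export
centroid_correlations <- function(profile, centroids,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  centroids <- as.matrix(centroids)
  if (ncol(centroids) < 2L) stop("need at least 2 subtype centroids")
  if (anyDuplicated(rownames(centroids))) stop("duplicate panel genes")
  common <- intersect(names(profile), rownames(centroids))
  if (length(common) < 3L) {
    stop("fewer than 3 panel genes shared between profile and centroids")
  }
  if (length(common) < 0.8 * nrow(centroids)) {
    warning("more than 20% of panel genes missing from the profile")
  }
  x <- profile[common]
  cen <- centroids[common, , drop = FALSE]
  if (stats::sd(x) == 0) {
    return(stats::setNames(rep(NaN, ncol(cen)), colnames(cen)))
  }
  if (method == "spearman") {
    x <- rank(x)
    cen <- apply(cen, 2L, rank)
  }
  drop(stats::cor(x, cen))
}

# Standardize columns to mean 0 / unit norm so correlations become
# crossproducts; used by the vectorized permutation machinery.
std_cols <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  nrm <- sqrt(colSums(m^2))
  nrm[nrm == 0] <- Inf
  sweep(m, 2L, nrm, "/")
}

# All permutations of 1..n (n <= 8), one per row.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  if (n > 8L) stop("exhaustive enumeration limited to 8 elements")
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Permutation-based classification confidence for one sample
#'
#' Builds a null by permuting the sample's panel-gene values `B` times and
#' recomputing every subtype correlation; the raw p-value for subtype *k* is
#' `(1 + #permutations with correlation >= observed_k) / (B + 1)`.  P-values
#' are BH-adjusted across subtypes, and the sample is `assigned` when the
#' argmax-correlation subtype is the unique subtype with adjusted p below
#' `alpha`; `ambiguous` when two or more subtypes are significant; otherwise
#' `unassigned`.  With `exhaustive = TRUE` all `n!` permutations of the panel
#' are enumerated and p-values are exact proportions.
#'
#' @inheritParams centroid_correlations
#' @param B number of permutations (>= 100).
#' @param alpha significance level for the adjusted p-values.
#' @param seed optional integer seed; leave `NULL` to use the current RNG
#'   stream.
#' @param exhaustive enumerate all permutations (small panels only).
#' @return List of class `subtype_call`: `correlation`, `p`, `adj_p`,
#'   `status`, `subtype`.
#' @export
permutation_confidence <- function(profile, centroids, B = 10000,
                                   alpha = 0.01,
                                   method = c("spearman", "pearson"),
                                   seed = NULL, exhaustive = FALSE) {
  method <- match.arg(method)
  if (!exhaustive && B < 100) stop("B must be at least 100")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  centroids <- as.matrix(centroids)
  obs <- centroid_correlations(profile, centroids, method = method)
  out <- list(correlation = obs,
              p = stats::setNames(rep(NA_real_, length(obs)), names(obs)),
              adj_p = stats::setNames(rep(NA_real_, length(obs)), names(obs)),
              status = "unassigned", subtype = NA_character_)
  class(out) <- "subtype_call"
  if (anyNA(obs) || any(is.nan(obs))) return(out)   # constant profile

  common <- intersect(names(profile), rownames(centroids))
  x <- profile[common]
  cen <- centroids[common, , drop = FALSE]
  if (method == "spearman") {
    x <- rank(x)
    cen <- apply(cen, 2L, rank)
  }
  n <- length(x)
  cs <- std_cols(cen)
  if (exhaustive) {
    perm <- all_permutations(n)
  } else {
    perm <- t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
  }
  xs <- drop(std_cols(matrix(x, ncol = 1)))
  pc <- matrix(xs[perm], nrow(perm), n) %*% cs      # permuted correlations
  ge <- colSums(pc >= matrix(obs, nrow(perm), ncol(cs), byrow = TRUE) - 1e-12)
  p <- if (exhaustive) ge / nrow(perm) else (1 + ge) / (nrow(perm) + 1)
  names(p) <- names(obs)
  adj <- stats::p.adjust(p, method = "BH")
  sig <- which(adj < alpha)
  top <- which(obs == max(obs))
  if (length(top) > 1L) {
    warning("tied maximal correlations; keeping the first subtype in order")
    top <- top[1L]
  }
  out$p <- p
  out$adj_p <- adj
  if (length(sig) == 1L && sig == top) {
    out$status <- "assigned"
    out$subtype <- names(obs)[top]
  } else if (length(sig) >= 2L) {
    out$status <- "ambiguous"
  }
  out
}

#' Classify every sample of a cohort against subtype centroids
#'
#' Applies per-cohort gene-wise median-centering of the panel genes (standard
#' practice for cross-platform centroid classification; disable with
#' `median_center = FALSE`), then runs [permutation_confidence()] per sample
#' and [assign_classes()] on the calls.
#'
#' @param x `expr_matrix` (logCPM or comparable per-cohort scale).
#' @param centroids panel-gene x subtype matrix.
#' @param B,alpha,method,seed see [permutation_confidence()].
#' @param median_center median-center panel genes across the cohort first.
#' @return Data frame with one row per sample: correlations (`cor_<subtype>`),
#'   raw and adjusted p-values, `status`, `subtype` and `class`; the
#'   per-cohort unassigned proportion is in attribute `"unassigned_prop"`.
#' @export
classify_samples <- function(x, centroids, B = 10000, alpha = 0.01,
                             method = c("spearman", "pearson"), seed = 1,
                             median_center = TRUE) {
  method <- match.arg(method)
  m <- expr_values(x)
  centroids <- as.matrix(centroids)
  panel <- intersect(rownames(centroids), rownames(m))
  if (length(panel) < 3L) stop("expression matrix lacks the panel genes")
  pm <- m[panel, , drop = FALSE]
  if (median_center) pm <- pm - apply(pm, 1L, stats::median)
  if (!is.null(seed)) set.seed(seed)
  calls <- lapply(colnames(pm), function(s) {
    permutation_confidence(pm[, s], centroids, B = B, alpha = alpha,
                           method = method, seed = NULL)
  })
  sub <- vapply(calls, function(cl) cl$subtype, character(1))
  df <- data.frame(
    sample = colnames(pm),
    cohort = if (inherits(x, "expr_matrix")) x$cohort else "cohort1",
    t(vapply(calls, function(cl) cl$correlation,
             numeric(ncol(centroids)))),
    t(vapply(calls, function(cl) cl$adj_p, numeric(ncol(centroids)))),
    status = vapply(calls, function(cl) cl$status, character(1)),
    subtype = sub, stringsAsFactors = FALSE)
  names(df)[3:(2 + ncol(centroids))] <- paste0("cor_", colnames(centroids))
  names(df)[(3 + ncol(centroids)):(2 + 2 * ncol(centroids))] <-
    paste0("adj_p_", colnames(centroids))
  assign_classes(df)
}

#' Collapse confident subtype calls into the C1/C2 classes
#'
#' Confidently assigned LumA samples form C1; assigned LumB, Her2e or Basal
#' samples form C2; everything else (ambiguous, unassigned, or an assigned
#' Normal-like call when a five-centroid panel is used) gets class `none` and
#' is excluded downstream.
#'
#' @param calls data frame with columns `status` and `subtype` (as produced
#'   by [classify_samples()]).
#' @return `calls` with a `class` column filled; per-cohort unassigned
#'   proportions (status != "assigned") in attribute `"unassigned_prop"`.
#' @export
assign_classes <- function(calls) {
  stopifnot(all(c("status", "subtype") %in% names(calls)))
  map <- c(LumA = "C1", LumB = "C2", Her2e = "C2", Basal = "C2",
           Normal = "none", `Normal-like` = "none")
  sub <- calls$subtype[calls$status == "assigned"]
  unknown <- setdiff(stats::na.omit(unique(sub)), names(map))
  if (length(unknown)) {
    stop("unknown subtype name(s): ", paste(unknown, collapse = ", "))
  }
  cls <- rep("none", nrow(calls))
  ok <- calls$status == "assigned"
  cls[ok] <- unname(map[calls$subtype[ok]])
  calls$class <- cls
  grp <- if ("cohort" %in% names(calls)) calls$cohort else
    rep("cohort1", nrow(calls))
  attr(calls, "unassigned_prop") <-
    tapply(calls$status != "assigned", grp, mean)
  calls
}
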