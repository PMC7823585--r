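#' Mean-of-z signature score
#'
#' The signature value of a sample is the average of its z-scored features
#' (genes or gene-set enrichment scores) over the signature:
#' `V_s = (1/k) sum_i e_si`.  Inputs must already be standardized within the
#' cohort (see [zscore_within_cohort()]).
#'
#' @param z feature x sample matrix in z-score units (`expr_matrix` with
#'   unit `"zscore"`, a z-scored [gsva_scores()] matrix, or a bare matrix).
#' @param genes character vector of signature feature ids; features missing
#'   from `z` are dropped with a warning.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_value <- function(z, genes) {
  m <- if (inherits(z, "expr_matrix")) expr_values(z, unit = "zscore")
       else as.matrix(z)
  found <- intersect(genes, rownames(m))
  if (length(found) == 0L) stop("no signature feature found in the matrix")
  if (length(found) < length(genes)) {
    warning(length(genes) - length(found),
            " signature feature(s) missing; k updated to ", length(found))
  }
  colMeans(m[found, , drop = FALSE])
}

#' Cohort-standardized sum score (centrosome-amplification style)
#'
#' `V_s = sum_g (e_sg - m) / sigma` over the signature genes, where `m` is
#' the median and `sigma` the standard deviation of *all* expression values
#' of the cohort matrix.  A sum, not an average, so the score grows with the
#' signature size.
#'
#' @param x feature x sample expression matrix on any real-valued scale
#'   (`expr_matrix` or bare matrix); the cohort statistics are taken over
#'   this whole matrix.
#' @param genes signature gene ids (missing genes dropped with a warning).
#' @return Named numeric vector of per-sample scores.
#' @export
ca20_value <- function(x, genes) {
  m <- expr_values(x)
  ctr <- stats::median(m)
  sdev <- stats::sd(as.vector(m))
  if (!is.finite(sdev) || sdev == 0) {
    stop("cohort-wide standard deviation is zero")
  }
  found <- intersect(genes, rownames(m))
  if (length(found) == 0L) stop("no signature gene found in the matrix")
  if (length(found) < length(genes)) {
    warning(length(genes) - length(found), " signature gene(s) missing")
  }
  colSums((m[found, , drop = FALSE] - ctr) / sdev)
}

#' Paired tumor-normal signature differences
#'
#' `D_p = V_tumor - V_normal` for every participant contributing both a
#' tumor and a normal sample; participants missing either member are skipped
#' with a warning.
#'
#' @param scores named numeric vector of per-sample signature values.
#' @param meta data frame with columns `sample`, `participant` and `tissue`
#'   (`"tumor"`/`"normal"`).
#' @return Data frame with columns `participant` and `d`.
#' @export
paired_difference <- function(scores, meta) {
  stopifnot(all(c("sample", "participant", "tissue") %in% names(meta)))
  meta <- meta[meta$sample %in% names(scores), ]
  out <- lapply(split(meta, meta$participant), function(g) {
    tu <- g$sample[g$tissue == "tumor"]
    no <- g$sample[g$tissue == "normal"]
    if (length(tu) == 1L && length(no) == 1L) {
      data.frame(participant = g$participant[1L],
                 d = unname(scores[tu] - scores[no]),
                 stringsAsFactors = FALSE)
    } else NULL
  })
  skipped <- sum(vapply(out, is.null, logical(1)))
  pairs <- sum(!vapply(out, is.null, logical(1)))
  if (skipped > 0 && pairs > 0) {
    warning(skipped, " participant(s) without a complete tumor/normal pair",
            " skipped")
  }
  if (pairs == 0L) {
    return(data.frame(participant = character(0), d = numeric(0)))
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   make.row.names = FALSE))
}

#' Rank test of signature scores (or paired differences) between classes
#'
#' C1 and C2 are independent groups, so the class comparison uses the
#' two-sided Wilcoxon rank-sum test (exact when sample sizes permit); the
#' companion [signed_rank_test()] covers paired tumor-normal differences.
#' BH adjustment is applied within each level of `group` (e.g. the gene-set
#' database a signature came from).
#'
#' @param values numeric vector of scores or differences, named by sample or
#'   aligned with `classes`.
#' @param classes `"C1"`/`"C2"` labels.
#' @param group optional grouping labels for the BH families; a single test
#'   per call is the common case, in which `adj_p = p`.
#' @param min_per_class eligibility gate (default 2 per class).
#' @return Data frame: `group`, `statistic`, `p`, `adj_p`, `median_diff`
#'   (C2 - C1).
#' @export
class_signature_test <- function(values, classes, group = NULL,
                                 min_per_class = 2) {
  if (!is.null(names(values)) && !is.null(names(classes))) {
    classes <- classes[names(values)]
  }
  if (length(values) != length(classes)) {
    stop("values and classes must align")
  }
  if (is.null(group)) group <- rep("all", length(values))
  keep <- classes %in% c("C1", "C2")
  values <- values[keep]; classes <- classes[keep]; group <- group[keep]
  res <- lapply(split(seq_along(values), group), function(idx) {
    v <- values[idx]; cl <- classes[idx]
    x1 <- v[cl == "C1"]; x2 <- v[cl == "C2"]
    if (length(x1) < min_per_class || length(x2) < min_per_class) {
      stop("empty or undersized class in group '", group[idx][1L], "'")
    }
    wt <- suppressWarnings(stats::wilcox.test(x2, x1))
    data.frame(group = group[idx][1L], statistic = unname(wt$statistic),
               p = wt$p.value,
               median_diff = stats::median(x2) - stats::median(x1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out[, c("group", "statistic", "p", "adj_p", "median_diff")]
}

#' One-sample Wilcoxon signed-rank test
#'
#' Exact two-sided signed-rank test of paired differences against zero
#' (exact p-values whenever there are no ties/zeros and n < 50).
#'
#' @param d numeric vector of paired differences.
#' @param mu null location (default 0).
#' @return List with `statistic` (V) and `p`.
#' @export
signed_rank_test <- function(d, mu = 0) {
  wt <- suppressWarnings(stats::wilcox.test(d, mu = mu))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
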