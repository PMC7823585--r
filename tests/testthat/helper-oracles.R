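# Independent reference implementations used as oracles.  These are written
# from the method definitions directly (plain loops, no shared code with the
# package internals) so agreement is evidence, not tautology.

# --- TMM oracle -------------------------------------------------------------
# Published trimmed-mean-of-M-values: reference = sample whose 75th-percentile
# count fraction is closest to the mean of those; M/A over genes positive in
# both; two-sided trims (30% on M, 5% on A) by average rank; factor =
# 2^(inverse-variance weighted mean of surviving M); geometric mean rescaled
# to 1.
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  q75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    q75[j] <- quantile(counts[, j], 0.75) / lib[j]
  }
  ref <- which.min(abs(q75 - mean(q75)))
  avg_rank <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      out[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    out
  }
  fac <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) { fac[j] <- 1; next }
    M <- c(); A <- c(); w <- c()
    for (g in seq_len(nrow(counts))) {
      ys <- counts[g, j]; yr <- counts[g, ref]
      if (ys > 0 && yr > 0) {
        ps <- ys / lib[j]; pr <- yr / lib[ref]
        M <- c(M, log2(ps / pr))
        A <- c(A, 0.5 * log2(ps * pr))
        w <- c(w, (lib[j] - ys) / (lib[j] * ys) +
                 (lib[ref] - yr) / (lib[ref] * yr))
      }
    }
    n <- length(M)
    loM <- floor(n * 0.30) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    rM <- avg_rank(M); rA <- avg_rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    fac[j] <- if (any(keep)) {
      2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    } else 1
  }
  fac / exp(mean(log(fac)))
}

# --- enrichment-score oracle ------------------------------------------------
# Step-by-step single-sample enrichment: gaussian kernel CDF statistic,
# midpoint-symmetrized average ranks, weighted KS walk.
oracle_gsva <- function(m, sets, tau = 1, es_mode = "max_diff") {
  n <- ncol(m); G <- nrow(m)
  z <- matrix(0, G, n)
  for (g in seq_len(G)) {
    h <- sd(m[g, ]) / 4
    for (s in seq_len(n)) {
      if (h == 0) {
        z[g, s] <- (sum(m[g, ] < m[g, s]) +
                      0.5 * sum(m[g, ] == m[g, s])) / n
      } else {
        z[g, s] <- mean(pnorm((m[g, s] - m[g, ]) / h))
      }
    }
  }
  es <- matrix(0, length(sets), n,
               dimnames = list(names(sets), colnames(m)))
  for (s in seq_len(n)) {
    r <- rank(z[, s])
    ord <- order(-z[, s])
    for (i in seq_along(sets)) {
      inset <- rownames(m) %in% sets[[i]]
      k <- sum(inset)
      wsum <- sum(abs(r[inset] - (G + 1) / 2)^tau)
      walk <- 0; path <- numeric(G)
      for (pos in seq_len(G)) {
        g <- ord[pos]
        if (inset[g]) {
          step <- if (wsum > 0) abs(r[g] - (G + 1) / 2)^tau / wsum else 1 / k
        } else {
          step <- -1 / (G - k)
        }
        walk <- walk + step
        path[pos] <- walk
      }
      es[i, s] <- if (es_mode == "max_diff") {
        max(c(0, path)) + min(c(0, path))
      } else {
        path[which.max(abs(path))]
      }
    }
  }
  es
}

# --- exhaustive permutation oracle -----------------------------------------
# All permutations of 1..n via recursive insertion (independent of the
# package's enumerator).
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  shorter <- oracle_perms(n - 1)
  out <- list()
  for (p in shorter) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Exact permutation p-values for one profile against centroids (spearman).
oracle_perm_pvalues <- function(profile, centroids) {
  obs <- sapply(colnames(centroids), function(s)
    cor(rank(profile), rank(centroids[, s])))
  perms <- oracle_perms(length(profile))
  count <- setNames(numeric(ncol(centroids)), colnames(centroids))
  for (p in perms) {
    for (s in colnames(centroids)) {
      r <- cor(rank(profile[p]), rank(centroids[, s]))
      if (r >= obs[s] - 1e-12) count[s] <- count[s] + 1
    }
  }
  count / length(perms)
}

# --- V-score oracle ---------------------------------------------------------
# Replays the exact replicate stream (same RNG consumption order as
# v_score: gene draw, then subsample draw when n_target < n) but computes
# PCA, median split and the Cox comparison with its own code.
oracle_vscore <- function(m, records, obs_loghr, obs_p, R, n_genes,
                          n_target, seed) {
  set.seed(seed)
  wins <- 0
  for (r in seq_len(R)) {
    gi <- sample.int(nrow(m), n_genes)
    sub <- m[gi, , drop = FALSE]
    for (g in seq_len(nrow(sub))) {
      sub[g, ] <- (sub[g, ] - mean(sub[g, ])) / sd(sub[g, ])
    }
    pc <- prcomp(t(sub), center = TRUE, scale. = FALSE)
    load <- pc$rotation[, 1]
    if (load[which.max(abs(load))] < 0) load <- -load
    score <- drop(scale(t(sub), center = TRUE, scale = FALSE) %*% load)
    lab <- as.integer(score > median(score))
    names(lab) <- colnames(m)
    if (n_target < length(lab)) {
      lab <- lab[sort(sample.int(length(lab), n_target))]
    }
    rec <- records[match(names(lab), records$sample), ]
    rec$grp <- lab
    fit <- tryCatch(
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ grp,
                                       data = rec)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      b <- coef(fit)[1]
      se <- sqrt(fit$var[1, 1])
      p <- 2 * pnorm(-abs(b / se))
      if (is.finite(b) && is.finite(p) &&
          abs(b) > abs(obs_loghr) && p < obs_p) {
        wins <- wins + 1
      }
    }
  }
  wins / R
}
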