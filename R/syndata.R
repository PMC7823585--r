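#' Simulation configuration for the multi-cohort synthetic generator
#'
#' Bundles and validates every knob of [generate_dataset()].  Defaults encode
#' a bulk RNA-seq world that is realistic for tumor cohorts: negative-binomial
#' counts with dispersion 0.15 (biological CV about 0.39), log-normal library
#' sizes (CV about 0.3), gene-wise log-normal cohort effects, subtype centroid
#' contrasts of 1.5 log2 units (about 3-fold) on a 50-gene panel, a core
#' module up-regulated 2-fold in the latent class-2 group, exponential
#' survival with a class-2 log-hazard of 0.7 and 40 percent uniform censoring,
#' and a 1 natural-log unit class shift in drug lnIC50.
#'
#' @param n_cohorts number of cohorts.
#' @param samples_per_cohort tumor samples per cohort.
#' @param n_genes total genes (panel + core + background).
#' @param n_panel_genes size of the classifier panel (default 50).
#' @param n_core_genes size of the planted class-2 core module.
#' @param subtype_proportions probability vector over
#'   `LumA, LumB, Her2e, Basal` (must sum to 1).
#' @param centroid_separation non-negative effect size (log2 units) of the
#'   subtype structure on panel genes.
#' @param core_effect log2 fold change of core genes in class-2 tumors.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (`Var = mu + phi mu^2`), shared across genes.
#' @param paired_normal_fraction fraction of participants that also contribute
#'   a paired normal sample.
#' @param survival_log_hr class-2 log hazard ratio for overall survival.
#' @param censoring_rate target fraction of censored samples, in `[0, 1)`.
#' @param drug_effect shift of mean lnIC50 in class-2 lines (natural-log
#'   units; negative = class 2 more sensitive).
#' @param infiltrate_log_hr length-2 numeric `c(C1, C2)`: log hazard ratio of
#'   a high (above-median) CD8-T infiltrate within each class; both 0 by
#'   default (no interaction).
#' @param n_drugs drugs screened per cohort.
#' @param drug_sigma within-class standard deviation of lnIC50.
#' @param seed integer seed; every draw of the generator flows from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 3,
                       samples_per_cohort = 60,
                       n_genes = 1000,
                       n_panel_genes = 50,
                       n_core_genes = 95,
                       subtype_proportions = c(LumA = 0.40, LumB = 0.20,
                                               Her2e = 0.15, Basal = 0.25),
                       centroid_separation = 1.5,
                       core_effect = 1,
                       nb_dispersion = 0.15,
                       paired_normal_fraction = 0.1,
                       survival_log_hr = 0.7,
                       censoring_rate = 0.4,
                       drug_effect = -1,
                       infiltrate_log_hr = c(0, 0),
                       n_drugs = 10,
                       drug_sigma = 1,
                       seed = 1) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = as.integer(samples_per_cohort),
              n_genes = as.integer(n_genes),
              n_panel_genes = as.integer(n_panel_genes),
              n_core_genes = as.integer(n_core_genes),
              subtype_proportions = subtype_proportions,
              centroid_separation = centroid_separation,
              core_effect = core_effect,
              nb_dispersion = nb_dispersion,
              paired_normal_fraction = paired_normal_fraction,
              survival_log_hr = survival_log_hr,
              censoring_rate = censoring_rate,
              drug_effect = drug_effect,
              infiltrate_log_hr = as.numeric(infiltrate_log_hr),
              n_drugs = as.integer(n_drugs),
              drug_sigma = drug_sigma,
              seed = as.integer(seed))
  stopifnot(cfg$n_cohorts >= 1, cfg$samples_per_cohort >= 1,
            cfg$n_genes >= 1, cfg$n_panel_genes >= 2, cfg$n_core_genes >= 0,
            length(cfg$subtype_proportions) == 4,
            all(cfg$subtype_proportions >= 0),
            cfg$centroid_separation >= 0,
            is.finite(cfg$core_effect),
            cfg$nb_dispersion > 0, is.finite(cfg$nb_dispersion),
            cfg$paired_normal_fraction >= 0, cfg$paired_normal_fraction <= 1,
            is.finite(cfg$survival_log_hr),
            cfg$censoring_rate >= 0, cfg$censoring_rate < 1,
            length(cfg$infiltrate_log_hr) == 2,
            cfg$n_drugs >= 0, cfg$drug_sigma > 0)
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-8) {
    stop("subtype_proportions must sum to 1")
  }
  if (cfg$n_panel_genes + cfg$n_core_genes > cfg$n_genes) {
    stop("n_panel_genes + n_core_genes exceeds n_genes")
  }
  if (is.null(names(cfg$subtype_proportions))) {
    names(cfg$subtype_proportions) <- pam_subtypes()
  }
  class(cfg) <- "sim_config"
  cfg
}

pam_subtypes <- function() c("LumA", "LumB", "Her2e", "Basal")

#' Generate synthetic subtype centroids
#'
#' Builds a panel-gene-by-4 matrix of log2-scale reference contrasts.  A
#' "proliferation block" (the first 30 percent of panel genes) is elevated by
#' `separation` in LumB, Her2e and Basal and depressed in LumA, so the LumA
#' column is anticorrelated with the other three and the C1/C2 contrast is
#' realizable; the remaining genes carry independent subtype-specific offsets
#' of the same scale, keeping the three class-2 centroids mutually
#' distinguishable (pairwise correlation about 0.3).  With `separation = 0`
#' all columns are identically zero.
#'
#' @param n_panel_genes number of panel genes (>= 2).
#' @param separation non-negative log2 effect size.
#' @param seed integer seed.
#' @return Matrix of class `centroid_profile` (genes x subtypes) with
#'   rownames `panel_01, ...` and columns `LumA, LumB, Her2e, Basal`.
#' @export
generate_centroids <- function(n_panel_genes = 50, separation = 1.5,
                               seed = 1) {
  if (n_panel_genes < 2) stop("need at least 2 panel genes")
  if (separation < 0) stop("separation must be non-negative")
  set.seed(seed)
  g <- n_panel_genes
  ids <- sprintf("panel_%02d", seq_len(g))
  n_prolif <- max(1L, round(0.3 * g))
  prolif <- seq_len(n_prolif)
  cen <- matrix(0, g, 4, dimnames = list(ids, pam_subtypes()))
  mag <- stats::runif(n_prolif, 0.5, 1.5)
  cen[prolif, "LumA"] <- -separation * mag
  for (s in c("LumB", "Her2e", "Basal")) cen[prolif, s] <- separation * mag
  spec <- matrix(stats::rnorm(4 * (g - n_prolif), sd = separation),
                 g - n_prolif, 4)
  cen[-prolif, ] <- cen[-prolif, ] + spec
  class(cen) <- c("centroid_profile", class(cen))
  cen
}

# tmax for uniform censoring C ~ U(0, tmax) giving the target censored
# fraction under an exponential mixture of class hazards.
censoring_tmax <- function(rates, weights, censoring_rate) {
  if (censoring_rate <= 0) return(Inf)
  pevent <- function(tmax) {
    sum(weights * (1 - (1 - exp(-rates * tmax)) / (rates * tmax)))
  }
  stats::uniroot(function(t) pevent(t) - (1 - censoring_rate),
                 lower = 1e-6, upper = 1e6, tol = 1e-10)$root
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Generate a full multi-cohort synthetic dataset
#'
#' Produces everything the pipeline consumes: per-cohort raw count matrices,
#' a truth table (subtype, latent class, pairing), a clinical table (survival
#' and immune-infiltrate fractions for tumor samples), a drug lnIC50 table,
#' and the centroid profile used to plant the subtype structure.
#'
#' Counts are negative-binomial (`Var = mu + phi mu^2`) around gene baselines
#' (log-normal, median 100) times gene-wise log-normal cohort multipliers and
#' log-normal per-sample library factors.  Panel genes follow the centroid of
#' the sample's true subtype; core genes gain `core_effect` log2 units in
#' class-2 tumors; paired normals carry neither effect.  Survival is
#' exponential with class-2 log hazard `survival_log_hr` (plus any configured
#' infiltrate-by-class effect), censored by an independent uniform time
#' calibrated to `censoring_rate`.  Infiltrate fractions are Dirichlet over
#' five cell types.  Each tumor sample doubles as a screened cell line with
#' normal lnIC50 shifted by `drug_effect` in class 2.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_dataset` with elements `counts` (named list of
#'   `expr_matrix`), `truth`, `clinical`, `drugs` (data frames), `centroids`,
#'   `gene_roles`, `mu` (list of expected-mean matrices, for diagnostics) and
#'   `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cen <- generate_centroids(cfg$n_panel_genes, cfg$centroid_separation,
                            seed = cfg$seed)
  set.seed(cfg$seed)
  G <- cfg$n_genes
  gene_ids <- c(rownames(cen),
                if (cfg$n_core_genes > 0)
                  sprintf("core_%03d", seq_len(cfg$n_core_genes)),
                sprintf("gene_%04d",
                        seq_len(G - cfg$n_panel_genes - cfg$n_core_genes)))
  role <- rep(c("panel", "core", "background"),
              c(cfg$n_panel_genes, cfg$n_core_genes,
                G - cfg$n_panel_genes - cfg$n_core_genes))
  baseline <- exp(stats::rnorm(G, log(100), 1))
  names(baseline) <- gene_ids

  rate0 <- log(2) / 5                      # median survival 5 time units in C1
  rates <- rate0 * exp(c(0, cfg$survival_log_hr))
  p1 <- cfg$subtype_proportions[["LumA"]]
  tmax <- censoring_tmax(rates, c(p1, 1 - p1), cfg$censoring_rate)
  infil_alpha <- c(CD8_T = 2, CD4_T = 2, NK = 1, B = 1, Macrophage = 4)
  cd8_median <- stats::qbeta(0.5, infil_alpha[1], sum(infil_alpha[-1]))

  counts <- list()
  mu_list <- list()
  truth <- list()
  clinical <- list()
  drugs <- list()
  for (k in seq_len(cfg$n_cohorts)) {
    cid <- sprintf("COH%02d", k)
    n <- cfg$samples_per_cohort
    cohort_mult <- exp(stats::rnorm(G, 0, 0.3))
    subtype <- sample(pam_subtypes(), n, replace = TRUE,
                      prob = cfg$subtype_proportions)
    klass <- ifelse(subtype == "LumA", 1L, 2L)
    participant <- sprintf("%s_P%03d", cid, seq_len(n))
    tumor_ids <- sprintf("%s_T%03d", cid, seq_len(n))
    n_norm <- round(cfg$paired_normal_fraction * n)
    norm_of <- if (n_norm > 0) sort(sample.int(n, n_norm)) else integer(0)
    normal_ids <- sprintf("%s_N%03d", cid, norm_of)

    sdlog <- sqrt(log(1 + 0.3^2))          # library-size CV ~ 0.3
    lib <- exp(stats::rnorm(n + n_norm, 0, sdlog))

    lfc <- matrix(0, G, n + n_norm)        # log2 offsets from baseline
    for (i in seq_len(n)) {
      lfc[role == "panel", i] <- cen[, subtype[i]]
      if (klass[i] == 2L) lfc[role == "core", i] <- cfg$core_effect
    }
    mu <- baseline * cohort_mult * 2^lfc
    mu <- sweep(mu, 2L, lib, "*")
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / cfg$nb_dispersion),
                  G, n + n_norm)
    dimnames(cnt) <- dimnames(mu) <- list(gene_ids,
                                          c(tumor_ids, normal_ids))
    counts[[cid]] <- expr_matrix(cnt, cohort = cid, unit = "counts")
    mu_list[[cid]] <- mu

    truth[[cid]] <- data.frame(
      sample = c(tumor_ids, normal_ids),
      cohort = cid,
      participant = c(participant, participant[norm_of]),
      tissue = rep(c("tumor", "normal"), c(n, n_norm)),
      subtype = c(subtype, rep(NA_character_, n_norm)),
      class = c(klass, rep(NA_integer_, n_norm)),
      stringsAsFactors = FALSE)

    infil <- t(vapply(seq_len(n), function(i) rdirichlet1(infil_alpha),
                      numeric(length(infil_alpha))))
    colnames(infil) <- names(infil_alpha)
    hi_cd8 <- infil[, "CD8_T"] > cd8_median
    loghaz <- log(rate0) + cfg$survival_log_hr * (klass == 2L) +
      ifelse(klass == 1L, cfg$infiltrate_log_hr[1],
             cfg$infiltrate_log_hr[2]) * hi_cd8
    tt <- stats::rexp(n, rate = exp(loghaz))
    ct <- if (is.finite(tmax)) stats::runif(n, 0, tmax) else rep(Inf, n)
    clinical[[cid]] <- data.frame(
      sample = tumor_ids, cohort = cid,
      time = pmin(tt, ct), event = as.integer(tt <= ct),
      infil, stringsAsFactors = FALSE)

    if (cfg$n_drugs > 0) {
      drug_ids <- sprintf("drug_%02d", seq_len(cfg$n_drugs))
      dd <- expand.grid(cell_line = tumor_ids, drug = drug_ids,
                        stringsAsFactors = FALSE)
      dd$cohort <- cid
      base_ic50 <- stats::setNames(stats::rnorm(cfg$n_drugs, 3, 1), drug_ids)
      kl <- klass[match(dd$cell_line, tumor_ids)]
      dd$lnIC50 <- base_ic50[dd$drug] + cfg$drug_effect * (kl == 2L) +
        stats::rnorm(nrow(dd), 0, cfg$drug_sigma)
      drugs[[cid]] <- dd[, c("cell_line", "cohort", "drug", "lnIC50")]
    }
  }
  structure(list(counts = counts,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 clinical = do.call(rbind, c(clinical,
                                             make.row.names = FALSE)),
                 drugs = if (length(drugs))
                   do.call(rbind, c(drugs, make.row.names = FALSE)) else NULL,
                 centroids = cen,
                 gene_roles = data.frame(gene = gene_ids, role = role,
                                         stringsAsFactors = FALSE),
                 mu = mu_list,
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d cohorts x %d genes, %d samples total\n",
              length(x$counts), x$config$n_genes, nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic dataset to a directory of TSV/JSON files
#'
#' One `counts_<cohort>.tsv` per cohort (genes x samples), plus `truth.tsv`,
#' `clinical.tsv`, `drugs.tsv`, `centroids.tsv` and `config.json`.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cid in names(ds$counts)) {
    write_expression_tsv(ds$counts[[cid]],
                         file.path(dir, paste0("counts_", cid, ".tsv")))
  }
  wt <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(ds$truth, "truth.tsv")
  wt(ds$clinical, "clinical.tsv")
  if (!is.null(ds$drugs)) wt(ds$drugs, "drugs.tsv")
  write_expression_tsv(unclass(ds$centroids), file.path(dir, "centroids.tsv"))
  jsonlite::write_json(unclass(ds$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
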