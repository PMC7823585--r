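# Small fixture builders shared across test files.

toy_counts <- function(genes = 20, samples = 5, seed = 1, lambda = 60) {
  set.seed(seed)
  m <- matrix(rpois(genes * samples, lambda) + 1L, genes, samples,
              dimnames = list(sprintf("g%03d", seq_len(genes)),
                              sprintf("s%02d", seq_len(samples))))
  m
}

# Orthogonal toy centroids on 2k genes: subtype i elevated on its own block.
toy_centroids <- function(block = 5, subtypes = c("LumA", "LumB")) {
  k <- length(subtypes)
  cen <- matrix(0, block * k, k,
                dimnames = list(sprintf("p%02d", seq_len(block * k)),
                                subtypes))
  for (i in seq_len(k)) cen[(i - 1) * block + seq_len(block), i] <- 1
  cen + 1e-3 * matrix(seq_len(block * k * k), block * k, k)  # break rank ties
}

# Survival records with exponential times and a class effect.
sim_surv_records <- function(n, log_hr, censor = 0.4, p2 = 0.5, seed = 1) {
  set.seed(seed)
  cl <- ifelse(runif(n) < p2, "C2", "C1")
  rate <- 0.2 * exp(log_hr * (cl == "C2"))
  tt <- rexp(n, rate)
  ct <- if (censor > 0) runif(n, 0, quantile(tt, 1 - censor) * 2.5) else Inf
  data.frame(sample = sprintf("s%04d", seq_len(n)),
             time = pmin(tt, ct), event = as.integer(tt <= ct),
             class = cl, stringsAsFactors = FALSE)
}

# Drug-response fixture: lnIC50 table with optional planted class-2 shifts.
make_responses <- function(n_drugs, n1 = 15, n2 = 15, shift_drugs = integer(0),
                           shift = 0, sigma = 1, seed = 1,
                           cohort = "COH01") {
  set.seed(seed)
  lines <- sprintf("cl%03d", 1:(n1 + n2))
  classes <- setNames(rep(c("C1", "C2"), c(n1, n2)), lines)
  resp <- expand.grid(cell_line = lines,
                      drug = sprintf("d%03d", 1:n_drugs),
                      stringsAsFactors = FALSE)
  resp$cohort <- cohort
  resp$lnIC50 <- rnorm(nrow(resp), 3, sigma)
  didx <- match(resp$drug, sprintf("d%03d", 1:n_drugs))
  hit <- didx %in% shift_drugs & classes[resp$cell_line] == "C2"
  resp$lnIC50[hit] <- resp$lnIC50[hit] + shift
  list(responses = resp[, c("cell_line", "cohort", "drug", "lnIC50")],
       classes = classes)
}
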