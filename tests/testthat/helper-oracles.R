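# Independent reference implementations used as oracles. These transcribe
# the model equations directly with explicit loops and plain arithmetic,
# deliberately sharing no code with the package internals.

# Antiparallel pair of codon position k: anticodon position 4 - k.
oracle_pairs <- function(codon, anticodon) {
  cn <- strsplit(codon, "")[[1]]
  an <- strsplit(anticodon, "")[[1]]
  rbind(c(cn[1], an[3]), c(cn[2], an[2]), c(cn[3], an[1]))
}

# Direct evaluation of the incorporation probabilities for one codon:
# binding softmax, arrival race, repeated-attempt product, total
# probability, then normalization.
oracle_incorporation <- function(codon, pool, model, geometry) {
  n_sites <- geometry$volume / geometry$trna_length^3
  tau <- geometry$trna_length^2 / (6 * geometry$diffusion_coeff)
  lambda <- (pool$abundance / n_sites) / tau
  m <- nrow(pool)
  dA <- numeric(m)
  for (j in seq_len(m)) {
    prs <- oracle_pairs(codon, pool$anticodon[j])
    s <- c(model$s[["s1"]], model$s[["s2"]], 1)
    for (k in 1:3) {
      dA[j] <- dA[j] + model$a[prs[k, 1], prs[k, 2]] * s[k]
    }
  }
  pb <- exp(-dA) / sum(exp(-dA))
  pfirst <- lambda / sum(lambda)
  pi_raw <- numeric(m)
  for (i in seq_len(m)) {
    prod_nf <- 1
    for (k in seq_len(m)) {
      if (k != i) prod_nf <- prod_nf * (1 - pb[k])^(lambda[k] / lambda[i])
    }
    pi_raw[i] <- pb[i] * pfirst[i] + pb[i] * prod_nf * (1 - pfirst[i])
  }
  list(pb = pb, raw = pi_raw, norm = pi_raw / sum(pi_raw))
}

# Multinomial log-pmf by direct factorial arithmetic (counts <= 20).
oracle_multinom_logpmf <- function(counts, probs) {
  stopifnot(all(counts <= 20))
  log(factorial(sum(counts))) - sum(log(factorial(counts))) +
    sum(counts[counts > 0] * log(probs[counts > 0]))
}

# Monte-Carlo exponential race: probability that species 1 arrives first.
oracle_race_first <- function(rates, draws = 1e5) {
  winners <- vapply(seq_len(draws), function(i) {
    which.min(stats::rexp(length(rates), rates))
  }, integer(1))
  mean(winners == 1L)
}

# Monte-Carlo protein translation: fraction of error-free translations
# given per-site error probabilities.
oracle_translate_error_free <- function(p_err_sites, reps = 1e4) {
  hits <- vapply(seq_len(reps), function(r) {
    !any(stats::runif(length(p_err_sites)) < p_err_sites)
  }, logical(1))
  mean(hits)
}

# Small standard pool/model/geometry for quick tests.
tiny_truth <- function(seed = 1, n_species = 20) {
  synthetic_truth(seed, n_species = n_species)
}
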