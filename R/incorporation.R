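# tRNA incorporation probabilities: the arrived-first branch and the
# repeated-binding-attempt branch, combined by total probability, then
# normalized per codon into multinomial category probabilities.

# Precomputed structures shared by every likelihood evaluation: aligned
# pair indices into the affinity matrix for all codons x species, arrival
# rates, and species -> amino-acid aggregation maps.
.landscape_engine <- function(pool, geometry, lysidine = TRUE,
                              codons = SENSE_CODONS) {
  if (nrow(pool) == 0L) stop("empty tRNA pool")
  .check_codon(codons, sense_only = TRUE)
  .check_anticodon(pool$anticodon)
  if (!lysidine && any(grepl("L", pool$anticodon, fixed = TRUE))) {
    stop("pool contains lysidine anticodons but the model excludes L")
  }
  n <- length(codons)
  m <- nrow(pool)
  cm <- matrix(unlist(strsplit(codons, "")), nrow = n, byrow = TRUE)
  am <- matrix(unlist(strsplit(pool$anticodon, "")), nrow = m, byrow = TRUE)
  # idx[[k]][i, j]: affinity-vector index of codon i position k against
  # anticodon j position 4-k (antiparallel alignment)
  idx <- lapply(1:3, function(k) {
    ci <- match(cm[, k], .CODON_NT)
    ai <- match(am[, 4L - k], if (lysidine) .ANTI_NT else .CODON_NT)
    matrix(rep(ci, m), n, m) + 4L * (rep(ai, each = n) - 1L)
  })
  lambda <- arrival_rate(pool$abundance, geometry)
  codon_aa <- translate_codons(codons)
  species_aa <- pool$amino_acid
  # aggregation: species -> 20 amino acids, species -> 19 merged categories
  agg20 <- outer(species_aa, .AA_CANONICAL, "==") * 1
  colnames(agg20) <- .AA_CANONICAL
  agg19 <- outer(.merge_il(species_aa), .AA_MERGED, "==") * 1
  colnames(agg19) <- .AA_MERGED
  syn <- outer(codon_aa, species_aa, "==") # strict synonymy codon x species
  list(
    codons = codons, ids = pool$id, n = n, m = m, idx = idx,
    lambda = lambda, pfirst = lambda / sum(lambda),
    codon_aa = codon_aa, species_aa = species_aa,
    agg20 = agg20, agg19 = agg19, syn = syn, lysidine = lysidine
  )
}

# Core forward computation for one parameter setting. Returns per-codon
# binding probabilities, raw incorporation probabilities and their
# normalized (multinomial simplex) version, all codons x species.
.engine_probs <- function(engine, avec, s1, s2) {
  x <- -(s1 * avec[engine$idx[[1L]]] +
           s2 * avec[engine$idx[[2L]]] +
           avec[engine$idx[[3L]]])
  dim(x) <- c(engine$n, engine$m)
  xmax <- x[cbind(seq_len(engine$n), max.col(x, ties.method = "first"))]
  lse <- xmax + log(rowSums(exp(x - xmax)))
  log_pb <- x - lse
  pb <- exp(log_pb)
  # log(1 - Pb), stable near Pb = 1; floor -Inf (complete saturation) at
  # the smallest representable log so self-exclusion stays finite
  l1m <- ifelse(log_pb > -0.6931472, log(-expm1(log_pb)), log1p(-pb))
  l1m[l1m == -Inf] <- -745
  lam <- engine$lambda
  tot <- drop(l1m %*% lam) # sum_j lambda_j log(1 - Pb_j), per codon
  # exclude the focal species, divide by its rate: log prod_{k != i}
  # (1 - Pb_k)^(lambda_k / lambda_i)
  nt <- sweep(tot - sweep(l1m, 2L, lam, "*"), 2L, lam, "/")
  pf <- engine$pfirst
  pi_raw <- sweep(pb, 2L, pf, "*") +
    sweep(pb * exp(nt), 2L, 1 - pf, "*")
  pi_norm <- pi_raw / rowSums(pi_raw)
  list(pb = pb, pi_raw = pi_raw, pi = pi_norm)
}

.model_avec <- function(model, engine) {
  if (model$lysidine != engine$lysidine) {
    stop("model and pool disagree on the lysidine alphabet")
  }
  as.vector(model$a)
}

#' Incorporation probabilities of all tRNAs at a codon
#'
#' Combines the arrived-first branch (incorporation probability equals the
#' binding probability) with the not-first branch, in which every competitor
#' is expected to arrive `lambda_k / lambda_i` times beforehand and must
#' fail to bind each time. The raw per-species probabilities are then
#' renormalized across species to give the multinomial category
#' probabilities of the error landscape.
#'
#' @param codon A sense codon.
#' @param pool A `trna_pool`.
#' @param model An [affinity_model()].
#' @param geometry A [cell_geometry()].
#' @return Named vector of normalized incorporation probabilities (sums to
#'   1) with attributes `raw` (unnormalized probabilities) and `pb`
#'   (binding probabilities).
#' @export
incorporation_probabilities <- function(codon, pool, model, geometry) {
  engine <- .landscape_engine(pool, geometry, model$lysidine, codons = codon)
  pr <- .engine_probs(engine, .model_avec(model, engine),
                      model$s[["s1"]], model$s[["s2"]])
  out <- stats::setNames(drop(pr$pi), pool$id)
  attr(out, "raw") <- stats::setNames(drop(pr$pi_raw), pool$id)
  attr(out, "pb") <- stats::setNames(drop(pr$pb), pool$id)
  out
}

#' Probability of non-synonymous incorporation at a codon
#'
#' Sum of the normalized incorporation probabilities over all tRNA species
#' carrying an amino acid different from the codon's translation.
#'
#' @inheritParams incorporation_probabilities
#' @return A single probability; warns when the pool contains no synonymous
#'   species for the codon.
#' @export
codon_error_probability <- function(codon, pool, model, geometry) {
  .check_codon(codon, sense_only = TRUE)
  syn <- pool$amino_acid == translate_codons(codon)
  if (!any(syn)) {
    warning("no synonymous tRNA for codon ", codon,
            " in the pool; error probability may be large")
  }
  pi <- incorporation_probabilities(codon, pool, model, geometry)
  sum(pi[!syn])
}

#' Build the codon x amino-acid error landscape
#'
#' For every sense codon, the normalized incorporation probabilities are
#' aggregated by the amino acid each tRNA species carries. Two views are
#' kept: the mechanistic 61 x 20 matrix over true amino acids (used by the
#' fitness layer) and the observable 61 x 19 matrix with leucine and
#' isoleucine merged into one `I/L` category (used by the likelihood, since
#' mass spectrometry cannot separate them).
#'
#' @inheritParams incorporation_probabilities
#' @return An object of class `error_landscape` with elements `P`
#'   (61 x 20, rows sum to 1), `P_obs` (61 x 19, merged), `p_error`
#'   (per-codon probability of non-synonymous incorporation) and
#'   `p_correct_obs` (per-codon probability of the codon's own merged
#'   category).
#' @export
build_landscape <- function(pool, model, geometry) {
  engine <- .landscape_engine(pool, geometry, model$lysidine)
  pr <- .engine_probs(engine, .model_avec(model, engine),
                      model$s[["s1"]], model$s[["s2"]])
  .landscape_from_probs(engine, pr$pi)
}

.landscape_from_probs <- function(engine, pi_norm) {
  P <- pi_norm %*% engine$agg20
  P_obs <- pi_norm %*% engine$agg19
  rownames(P) <- rownames(P_obs) <- engine$codons
  p_error <- 1 - rowSums(pi_norm * engine$syn)
  correct_cat <- match(.merge_il(engine$codon_aa), .AA_MERGED)
  p_correct_obs <- P_obs[cbind(seq_len(engine$n), correct_cat)]
  structure(
    list(
      P = P, P_obs = P_obs,
      p_error = stats::setNames(p_error, engine$codons),
      p_correct_obs = stats::setNames(p_correct_obs, engine$codons),
      codons = engine$codons
    ),
    class = "error_landscape"
  )
}

#' @export
print.error_landscape <- function(x, ...) {
  cat("translation error landscape:", length(x$codons), "codons x",
      ncol(x$P_obs), "observable amino-acid categories\n")
  cat(sprintf("per-codon error probability: median %.3g, range [%.3g, %.3g]\n",
              stats::median(x$p_error), min(x$p_error), max(x$p_error)))
  invisible(x)
}

#' Probability of error-free protein translation
#'
#' Under site independence, the product over codon sites of the per-site
#' probability of correct (synonymous) incorporation. An empty sequence
#' gives 1.
#'
#' @param codon_sequence Character vector of sense codons (the protein's
#'   coding sequence, one codon per site).
#' @param landscape An [build_landscape()] result.
#' @return Probability that no site misincorporates.
#' @export
protein_error_free_probability <- function(codon_sequence, landscape) {
  stopifnot(inherits(landscape, "error_landscape"))
  if (length(codon_sequence) == 0L) return(1)
  unknown <- setdiff(codon_sequence, landscape$codons)
  if (length(unknown)) {
    stop("codon(s) not in landscape: ", paste(unknown, collapse = ", "))
  }
  prod(1 - landscape$p_error[codon_sequence])
}

#' Export a landscape as a TSV matrix
#'
#' Writes the observable codon x amino-acid-category matrix (rows = codons,
#' columns = destination categories, leucine/isoleucine merged as `I/L`).
#'
#' @param landscape An `error_landscape`.
#' @param path Output path.
#' @export
write_landscape <- function(landscape, path) {
  m <- landscape$P_obs
  colnames(m) <- .aa_category_label(colnames(m))
  df <- data.frame(codon = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
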