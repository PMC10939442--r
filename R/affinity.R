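# Effective codon/anticodon binding affinities: a positionally additive
# model with per-nucleotide-pair affinities and site importance weights.

#' Construct an effective binding affinity model
#'
#' The effective binding affinity of a codon/anticodon pair is the sum over
#' the three aligned positions of a per-nucleotide-pair affinity, weighted
#' by a site importance term (`s3 = 1` fixed, so `s1` and `s2` are relative
#' to the wobble position). Lower affinity values mean stronger effective
#' binding: the binding probability is proportional to `exp(-affinity)`.
#' Because the binding softmax is evaluated per codon, adding a constant to
#' a whole codon-nucleotide row cancels for every anticodon: each of the
#' four rows carries one free gauge direction. Fits anchor the Watson-Crick
#' entry of every row at 0, so mismatch entries read as binding penalties
#' relative to the row's Watson-Crick pair.
#'
#' @param nucleotide_affinity 4 x 5 numeric matrix (rows: codon nucleotides
#'   A,C,G,U; columns: anticodon nucleotides A,C,G,U,L) or 4 x 4 when
#'   lysidine is disabled. Unit-less; lower = stronger binding.
#' @param s1,s2 Site importance weights for codon positions 1 and 2
#'   (position 3, the wobble position, has weight 1).
#' @param lysidine Logical; whether the anticodon alphabet includes
#'   lysidine (`L`).
#' @return An object of class `affinity_model`.
#' @export
affinity_model <- function(nucleotide_affinity = NULL, s1 = 1, s2 = 1,
                           lysidine = TRUE) {
  anti <- if (lysidine) .ANTI_NT else .CODON_NT
  if (is.null(nucleotide_affinity)) {
    nucleotide_affinity <- matrix(0, 4L, length(anti),
                                  dimnames = list(.CODON_NT, anti))
  }
  a <- as.matrix(nucleotide_affinity)
  if (!all(dim(a) == c(4L, length(anti)))) {
    stop("nucleotide_affinity must be 4 x ", length(anti),
         if (lysidine) " (anticodon alphabet A,C,G,U,L)" else
           " (anticodon alphabet A,C,G,U)")
  }
  if (is.null(dimnames(a))) dimnames(a) <- list(.CODON_NT, anti)
  if (!identical(rownames(a), .CODON_NT) || !identical(colnames(a), anti)) {
    a <- a[.CODON_NT, anti]
  }
  if (any(!is.finite(a))) stop("affinity entries must be finite")
  if (!is.finite(s1) || !is.finite(s2)) stop("site weights must be finite")
  structure(
    list(a = a, s = c(s1 = s1, s2 = s2, s3 = 1), lysidine = lysidine),
    class = "affinity_model"
  )
}

#' @export
print.affinity_model <- function(x, digits = 3, ...) {
  cat("effective binding affinity model",
      if (x$lysidine) "(with lysidine)" else "(no lysidine)", "\n")
  cat(sprintf("site weights: s1 = %.*g, s2 = %.*g, s3 = 1 (wobble)\n",
              digits, x$s[["s1"]], digits, x$s[["s2"]]))
  cat("nucleotide affinities (codon rows x anticodon columns):\n")
  print(round(x$a, digits))
  invisible(x)
}

# Integer index of an aligned pair into as.vector(model$a):
# codon nt index + 4 * (anticodon nt index - 1).
.pair_index <- function(codon_nt, anticodon_nt, lysidine = TRUE) {
  anti <- if (lysidine) .ANTI_NT else .CODON_NT
  ci <- match(codon_nt, .CODON_NT)
  ai <- match(anticodon_nt, anti)
  if (anyNA(ci) || anyNA(ai)) stop("invalid nucleotide in pairing")
  ci + 4L * (ai - 1L)
}

#' Effective binding affinity of codon/anticodon pairs
#'
#' Computes `sum_k a[codon_k, anticodon_(4-k)] * s_k` over the three
#' antiparallel-aligned positions. Lower values mean stronger effective
#' binding.
#'
#' @param codon,anticodon Character vectors (recycled to common length).
#' @param model An [affinity_model()].
#' @return Numeric vector of affinities.
#' @examples
#' m <- affinity_model()
#' effective_affinity("AAA", "UUU", m) # all-zero model: 0
#' @export
effective_affinity <- function(codon, anticodon, model) {
  stopifnot(inherits(model, "affinity_model"))
  n <- max(length(codon), length(anticodon))
  codon <- rep_len(codon, n)
  anticodon <- rep_len(anticodon, n)
  .check_codon(codon)
  .check_anticodon(anticodon)
  cm <- matrix(unlist(strsplit(codon, "")), nrow = n, byrow = TRUE)
  am <- matrix(unlist(strsplit(anticodon, "")), nrow = n, byrow = TRUE)
  avec <- as.vector(model$a)
  s <- model$s
  # codon position k pairs with anticodon position 4 - k
  avec[.pair_index(cm[, 1L], am[, 3L], model$lysidine)] * s[[1L]] +
    avec[.pair_index(cm[, 2L], am[, 2L], model$lysidine)] * s[[2L]] +
    avec[.pair_index(cm[, 3L], am[, 1L], model$lysidine)] * s[[3L]]
}

#' Affinity matrix over codons and anticodons
#'
#' Evaluates the effective binding affinity for every combination of the
#' given codons and anticodons, by default all 61 sense codons. Anticodons
#' need not correspond to existing tRNAs, which supports in-silico
#' experiments with hypothetical (missing) anticodons.
#'
#' @param model An [affinity_model()].
#' @param codons Codons (rows); default all sense codons.
#' @param anticodons Anticodons (columns).
#' @return Numeric matrix `length(codons) x length(anticodons)`.
#' @export
affinity_matrix <- function(model, anticodons, codons = SENSE_CODONS) {
  out <- vapply(
    anticodons,
    function(ac) effective_affinity(codons, ac, model),
    numeric(length(codons))
  )
  out <- matrix(out, nrow = length(codons),
                dimnames = list(codons, anticodons))
  out
}

#' Per-codon tRNA binding probabilities
#'
#' Softmax of minus the effective affinity over all tRNA species in the
#' pool (a partition function over binding states): species with lower
#' affinity values bind with higher probability; probabilities sum to 1 per
#' codon. Computed with max-subtraction so the result equals exact
#' arithmetic.
#'
#' @param codon A sense codon.
#' @param pool A `trna_pool`.
#' @param model An [affinity_model()].
#' @return Named probability vector over pool species.
#' @export
binding_probabilities <- function(codon, pool, model) {
  if (nrow(pool) == 0L) stop("empty tRNA pool")
  dA <- effective_affinity(rep(codon, nrow(pool)), pool$anticodon, model)
  x <- -dA
  x <- x - max(x)
  p <- exp(x)
  stats::setNames(p / sum(p), pool$id)
}

#' Relative affinity profile of an anticodon
#'
#' For one anticodon (existing or hypothetical), the effective binding
#' affinity of each codon relative to the lowest (strongest) affinity among
#' the codons synonymous with the anticodon's amino acid. The
#' strongest-bound synonymous codon maps to 0; negative values indicate
#' binding stronger than that reference, positive values weaker.
#'
#' @param anticodon The anticodon to profile.
#' @param amino_acid Amino acid carried by the (possibly hypothetical) tRNA;
#'   defines which codons count as synonymous.
#' @param model An [affinity_model()].
#' @param codons Codon set to profile; default all sense codons.
#' @return Data.frame with columns `codon`, `synonymous`, `affinity`,
#'   `relative_affinity`.
#' @export
relative_affinity_profile <- function(anticodon, amino_acid, model,
                                      codons = SENSE_CODONS) {
  .check_codon(codons, sense_only = TRUE)
  syn <- translate_codons(codons) == amino_acid
  if (!any(syn)) stop("no synonymous codon for ", amino_acid, " in codon set")
  dA <- effective_affinity(codons, anticodon, model)
  ref <- min(dA[syn])
  data.frame(
    codon = codons,
    synonymous = syn,
    affinity = dA,
    relative_affinity = dA - ref,
    stringsAsFactors = FALSE
  )
}

#' Serialize an affinity model to JSON
#'
#' @param model An [affinity_model()].
#' @param path Output path.
#' @export
write_affinity_model <- function(model, path) {
  obj <- list(
    nucleotide_affinity = apply(model$a, 1L, as.list, simplify = FALSE),
    site_weights = list(s1 = model$s[["s1"]], s2 = model$s[["s2"]]),
    lysidine = model$lysidine,
    gauge = "WC-anchored: aAU=aCG=aGC=aUA=0"
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an affinity model from JSON
#'
#' @param path Path written by [write_affinity_model()].
#' @return An [affinity_model()].
#' @export
read_affinity_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- do.call(rbind, lapply(obj$nucleotide_affinity, unlist))
  affinity_model(a, s1 = obj$site_weights$s1, s2 = obj$site_weights$s2,
                 lysidine = isTRUE(obj$lysidine))
}
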