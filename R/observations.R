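# Per-codon misincorporation count containers and the multinomial
# likelihood evaluated on the observable (Leu/Ile-merged) landscape.

#' Construct per-codon misincorporation observations
#'
#' Counts are held in long format: one row per (codon, destination
#' amino-acid category) with the codon's total PSM-level observation count
#' repeated per row. Destinations are merged over leucine/isoleucine. Rows
#' with destination equal to the codon's own (merged) amino acid are
#' rejected: correct incorporations are the complement of the error counts.
#'
#' @param codon Sense codons (may repeat across destinations).
#' @param total_count Total observations of the codon (PSM-level), one
#'   value per codon.
#' @param dest_aa Destination amino acid of the error (one-letter; `"I"`
#'   and `"L"` are merged).
#' @param error_count Number of observations showing that destination.
#' @return A data.frame of class `codon_obs`.
#' @export
codon_observations <- function(codon, total_count, dest_aa, error_count) {
  .check_codon(codon, sense_only = TRUE)
  stopifnot(length(codon) == length(dest_aa),
            length(dest_aa) == length(error_count))
  if (any(error_count < 0) || any(error_count != round(error_count))) {
    stop("error counts must be non-negative integers")
  }
  dest <- .merge_il(dest_aa)
  bad <- setdiff(unique(dest), .AA_MERGED)
  if (length(bad)) stop("unknown destination amino acid(s): ",
                        paste(.aa_category_label(bad), collapse = ", "))
  own <- .merge_il(translate_codons(codon))
  if (any(dest == own)) {
    stop("destination equals the codon's own amino acid for: ",
         paste(unique(codon[dest == own]), collapse = ", "))
  }
  obs <- data.frame(codon = codon, total_count = as.numeric(total_count),
                    dest_aa = .aa_category_label(dest),
                    error_count = as.numeric(error_count),
                    stringsAsFactors = FALSE)
  tot <- tapply(obs$total_count, obs$codon, function(x) {
    if (length(unique(x)) > 1L) stop("inconsistent total_count for a codon")
    x[1L]
  })
  err <- tapply(obs$error_count, obs$codon, sum)
  over <- names(err)[err > tot[names(err)]]
  if (length(over)) {
    stop("error counts exceed total count for codon(s): ",
         paste(over, collapse = ", "))
  }
  class(obs) <- c("codon_obs", "data.frame")
  obs
}

#' Read observations from a long-format TSV
#'
#' Columns: `codon`, `total_count`, `dest_aa`, `error_count`.
#'
#' @param path Path to a tab-separated file.
#' @return A `codon_obs` data.frame.
#' @export
read_codon_observations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "total_count", "dest_aa", "error_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("observations file is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  codon_observations(tab$codon, tab$total_count, tab$dest_aa,
                     tab$error_count)
}

#' Write observations to TSV
#' @param obs A `codon_obs`.
#' @param path Output path.
#' @export
write_codon_observations <- function(obs, path) {
  utils::write.table(as.data.frame(obs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pool observations from several datasets
#'
#' Sums totals and error counts codon-by-codon and
#' destination-by-destination before fitting.
#'
#' @param ... `codon_obs` objects (or a single list of them).
#' @return A pooled `codon_obs`.
#' @export
pool_observations <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1L]], "codon_obs")) {
    parts <- parts[[1L]]
  }
  long <- do.call(rbind, lapply(parts, as.data.frame))
  totals <- lapply(parts, function(p) {
    u <- p[!duplicated(p$codon), c("codon", "total_count")]
    u
  })
  tot <- stats::aggregate(total_count ~ codon, do.call(rbind, totals), sum)
  err <- stats::aggregate(error_count ~ codon + dest_aa, long, sum)
  err$total_count <- tot$total_count[match(err$codon, tot$codon)]
  codon_observations(err$codon, err$total_count, err$dest_aa,
                     err$error_count)
}

# Dense count representation aligned with an engine's codon rows and the
# 19 merged categories; correct counts sit in the codon's own category.
# keep[i, j] = FALSE marks a masked (codon, category) cell, excluded from
# the multinomial with renormalization of the remaining categories.
.loglik_env <- function(obs, engine, mask = NULL,
                        on_impossible = c("error", "drop")) {
  on_impossible <- match.arg(on_impossible)
  codons <- engine$codons
  k <- length(.AA_MERGED)
  C <- matrix(0, length(codons), k, dimnames = list(codons, .AA_MERGED))
  ci <- match(obs$codon, codons)
  if (anyNA(ci)) {
    stop("observed codon(s) missing from the engine codon set: ",
         paste(unique(obs$codon[is.na(ci)]), collapse = ", "))
  }
  di <- match(.merge_il(obs$dest_aa), .AA_MERGED)
  # destinations no tRNA in the pool can produce have probability zero
  # under every parameter setting
  producible <- .AA_MERGED %in% .merge_il(engine$species_aa)
  if (any(obs$error_count > 0 & !producible[di])) {
    offending <- unique(obs$dest_aa[obs$error_count > 0 & !producible[di]])
    msg <- paste("destination(s) not producible by any pooled tRNA:",
                 paste(.aa_category_label(offending), collapse = ", "))
    if (on_impossible == "error") stop(msg)
    warning(msg, "; dropping those counts")
    obs <- obs[producible[di] | obs$error_count == 0, , drop = FALSE]
    ci <- match(obs$codon, codons)
    di <- match(.merge_il(obs$dest_aa), .AA_MERGED)
  }
  for (r in seq_len(nrow(obs))) C[ci[r], di[r]] <- C[ci[r], di[r]] + obs$error_count[r]
  tot_by_codon <- tapply(obs$total_count, obs$codon, `[`, 1L)
  own <- match(.merge_il(engine$codon_aa), .AA_MERGED)
  idx <- match(names(tot_by_codon), codons)
  C[cbind(idx, own[idx])] <- tot_by_codon - rowSums(C[idx, , drop = FALSE])
  keep <- matrix(TRUE, nrow(C), k, dimnames = dimnames(C))
  if (!is.null(mask)) {
    mi <- match(mask$codon, codons)
    mj <- match(.merge_il(mask$dest_aa), .AA_MERGED)
    ok <- !is.na(mi) & !is.na(mj)
    keep[cbind(mi[ok], mj[ok])] <- FALSE
    if (any(C[!keep] > 0)) {
      stop("masked categories carry observed counts; masking is only ",
           "valid for categories the detection stage cannot see")
    }
  }
  C[!keep] <- 0
  totals <- rowSums(C)
  const <- sum(lgamma(totals + 1)) - sum(lgamma(C + 1))
  list(C = C, keep = keep, const = const, masked = !is.null(mask))
}

.loglik_eval <- function(env, engine, avec, s1, s2, floor_prob = 0) {
  pr <- .engine_probs(engine, avec, s1, s2)
  P <- pr$pi %*% engine$agg19
  if (env$masked) {
    P[!env$keep] <- 0
    P <- P / rowSums(P)
  }
  pos <- env$C > 0
  if (floor_prob > 0) {
    # smooth finite surrogate for optimizers: probabilities floored away
    # from zero so line searches never meet -Inf
    return(env$const + sum(env$C[pos] * log(pmax(P[pos], floor_prob))))
  }
  if (any(P[pos] <= 0)) return(-Inf)
  env$const + sum(env$C[pos] * log(P[pos]))
}

#' Multinomial log-likelihood of misincorporation counts
#'
#' For each observed codon, the counts over `{correct} + destination
#' categories` follow a multinomial with probabilities given by the
#' observable (Leu/Ile-merged) landscape implied by the affinity model,
#' tRNA pool and cell geometry. The multinomial coefficient is included, so
#' an empty observation set gives exactly 0. Categories listed in `mask`
#' (substitutions indistinguishable from PTMs) are excluded and the
#' remaining categories renormalized at likelihood time only.
#'
#' @param model An [affinity_model()].
#' @param observations A `codon_obs` object.
#' @param pool A `trna_pool`.
#' @param geometry A [cell_geometry()].
#' @param mask Optional data.frame with columns `codon`, `dest_aa` of
#'   categories to exclude.
#' @param on_impossible What to do when an observed destination cannot be
#'   produced by any tRNA in the pool: `"error"` (default) or `"drop"`
#'   with a warning.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(model, observations, pool, geometry,
                           mask = NULL, on_impossible = c("error", "drop")) {
  if (nrow(observations) == 0L) return(0)
  engine <- .landscape_engine(pool, geometry, model$lysidine,
                              codons = unique(observations$codon))
  env <- .loglik_env(observations, engine, mask, on_impossible)
  .loglik_eval(env, engine, .model_avec(model, engine),
               model$s[["s1"]], model$s[["s2"]])
}
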