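# Population-genetics layer: expected site costs of misincorporation,
# abundance-weighted protein burdens, Sella-Hirsh relative fixation
# probabilities and the nearly-neutral classification band.

#' Population-genetic constants
#'
#' @param Ne Effective population size (>= 1).
#' @param q Protein-production cost scaling constant (> 0); the selection
#'   coefficient of a fitness difference `dx` is `S = q * Ne * dx`.
#' @return A list of class `popgen_params`.
#' @export
popgen_params <- function(Ne, q = 4.19e-7) {
  stopifnot(Ne >= 1, q > 0)
  structure(list(Ne = Ne, q = q), class = "popgen_params")
}

#' Species presets for population-genetic constants
#'
#' `Ne = 1e8` for E. coli, `Ne = 8.6e6` for S. cerevisiae, shared
#' `q = 4.19e-7`.
#'
#' @param species `"ecoli"` or `"scerevisiae"`.
#' @return A [popgen_params()].
#' @export
popgen_preset <- function(species = c("ecoli", "scerevisiae")) {
  species <- match.arg(species)
  popgen_params(Ne = switch(species, ecoli = 1e8, scerevisiae = 8.6e6))
}

#' Expected fitness cost of misincorporation at one site
#'
#' The probability-weighted sum, over all amino acids, of the
#' variant-effect score of replacing the encoded residue: the encoded amino
#' acid scores 0 by definition, so the sum effectively runs over
#' misincorporations. Lower (more negative) values are more severe.
#'
#' @param codon The sense codon at the site.
#' @param site_scores Named numeric vector of variant-effect scores by
#'   amino acid (the encoded residue's entry is forced to 0; missing
#'   entries are handled per `on_missing`).
#' @param landscape An [build_landscape()] result (its mechanistic,
#'   unmerged probabilities are used).
#' @param on_missing What to do when an amino acid with nonzero
#'   incorporation probability has no score: `"error"` (default) or
#'   `"renormalize"` (drop it and rescale the remaining misincorporation
#'   probabilities to the same total error mass).
#' @return The expected cost (scalar).
#' @export
site_cost <- function(codon, site_scores, landscape,
                      on_missing = c("error", "renormalize")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(landscape, "error_landscape"))
  .check_codon(codon, sense_only = TRUE)
  p <- landscape$P[codon, ]
  enc <- translate_codons(codon)
  scores <- site_scores[colnames(landscape$P)]
  names(scores) <- colnames(landscape$P)
  scores[enc] <- 0
  missing <- is.na(scores) & p > 0
  if (any(missing)) {
    if (on_missing == "error") {
      stop("no variant-effect score for amino acid(s) ",
           paste(names(scores)[missing], collapse = ", "),
           " with nonzero incorporation probability at codon ", codon)
    }
    err_mask <- names(p) != enc
    total_err <- sum(p[err_mask])
    p[missing] <- 0
    kept_err <- sum(p[err_mask])
    if (kept_err > 0) p[err_mask] <- p[err_mask] * total_err / kept_err
  }
  scores[is.na(scores)] <- 0
  sum(p * scores)
}

#' Abundance-weighted misincorporation burden of a protein
#'
#' The protein's relative abundance (proteome fraction) times the sum of
#' its per-site expected costs.
#'
#' @param phi Relative protein abundance (dimensionless proteome fraction).
#' @param site_costs Numeric vector of per-site costs (see [site_cost()]).
#' @return The protein burden (scalar).
#' @export
protein_burden <- function(phi, site_costs) {
  stopifnot(phi >= 0)
  phi * sum(site_costs)
}

#' Relative fixation probability of a fitness difference
#'
#' Sella-Hirsh fixation probability of a genotype with fitness difference
#' `dx` relative to the reference, `Theta = 2S / (1 - exp(-2S))` with
#' `S = q * Ne * dx`. `Theta(0) = 1` by the limit; the evaluation is
#' numerically stable for large `|S|` (`Theta -> 2S` for strongly
#' advantageous, `Theta -> -2S * exp(2S)` for strongly deleterious
#' differences).
#'
#' @param dx Fitness difference(s); vectorized.
#' @param popgen A [popgen_params()].
#' @return Relative fixation probability `Theta >= 0`.
#' @export
fixation_ratio <- function(dx, popgen) {
  stopifnot(inherits(popgen, "popgen_params"))
  if (any(!is.finite(dx))) stop("fitness differences must be finite")
  S <- popgen$q * popgen$Ne * dx
  theta <- numeric(length(S))
  big_neg <- S < -350 # 1 - exp(-2S) overflows; use Theta = -2S exp(2S)
  zero <- S == 0
  rest <- !big_neg & !zero
  theta[zero] <- 1
  theta[big_neg] <- -2 * S[big_neg] * exp(2 * S[big_neg])
  theta[rest] <- 2 * S[rest] / (-expm1(-2 * S[rest]))
  theta
}

#' Classify a relative fixation probability
#'
#' Fitness effects changing the fixation probability by at most 5% are
#' treated as (nearly) neutral: `|Theta - 1| <= 0.05`; `Theta < 0.95` is
#' deleterious and `Theta > 1.05` advantageous. The three classes
#' partition `[0, Inf)` exactly.
#'
#' @param theta Relative fixation probabilities (vectorized, `>= 0`).
#' @param band Half-width of the neutral band (default 0.05).
#' @return Character vector in `{"deleterious", "neutral", "advantageous"}`.
#' @export
classify_effect <- function(theta, band = 0.05) {
  if (any(theta < 0)) stop("relative fixation probabilities must be >= 0")
  # tiny slack so exact band edges (e.g. 1.05) are neutral despite
  # floating-point representation
  neutral <- abs(theta - 1) <= band + 1e-12
  ifelse(neutral, "neutral", ifelse(theta < 1, "deleterious",
                                    "advantageous"))
}

#' Read a variant-effect score table
#'
#' TSV with columns `protein_id`, `site` (1-based), `amino_acid`,
#' `deltaE` (lower = more severe).
#'
#' @param path Path to the table.
#' @return Data.frame of class `fitness_scores`.
#' @export
read_fitness_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "site", "amino_acid", "deltaE")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("score table missing column(s): ",
                         paste(miss, collapse = ", "))
  class(tab) <- c("fitness_scores", "data.frame")
  tab
}

#' Write a variant-effect score table
#' @param scores A `fitness_scores` data.frame.
#' @param path Output path.
#' @export
write_fitness_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Site costs, burdens and fixation classes for a proteome
#'
#' Convenience wrapper: computes per-site expected costs for every scored
#' site of every protein, the per-protein abundance-weighted burden, and
#' the neutral/deleterious/advantageous classification of each site's
#' fixation ratio.
#'
#' @param proteome Data.frame with columns `protein_id`, `phi` and a list
#'   column `codons` (character vector of sense codons per protein).
#' @param scores A `fitness_scores` table.
#' @param landscape An [build_landscape()] result.
#' @param popgen A [popgen_params()].
#' @param on_missing Passed to [site_cost()].
#' @return A list with `sites` (protein, site, codon, cost, theta, class)
#'   and `proteins` (protein, phi, burden, theta, class).
#' @export
fitness_landscape <- function(proteome, scores, landscape, popgen,
                              on_missing = c("error", "renormalize")) {
  on_missing <- match.arg(on_missing)
  score_split <- split(scores, scores$protein_id)
  site_rows <- list()
  prot_rows <- list()
  for (i in seq_len(nrow(proteome))) {
    pid <- proteome$protein_id[i]
    codons <- proteome$codons[[i]]
    sc <- score_split[[pid]]
    if (is.null(sc)) next
    by_site <- split(sc, sc$site)
    sites <- as.integer(names(by_site))
    costs <- vapply(seq_along(sites), function(k) {
      s <- sites[k]
      if (s > length(codons)) stop("scored site ", s,
                                   " beyond protein length for ", pid)
      site_cost(codons[s],
                stats::setNames(by_site[[k]]$deltaE,
                                by_site[[k]]$amino_acid),
                landscape, on_missing = on_missing)
    }, numeric(1L))
    site_rows[[pid]] <- data.frame(
      protein_id = pid, site = sites, codon = codons[sites],
      cost = costs, stringsAsFactors = FALSE
    )
    prot_rows[[pid]] <- data.frame(
      protein_id = pid, phi = proteome$phi[i],
      burden = protein_burden(proteome$phi[i], costs),
      stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, site_rows)
  proteins <- do.call(rbind, prot_rows)
  rownames(sites) <- rownames(proteins) <- NULL
  sites$theta <- fixation_ratio(sites$cost, popgen)
  sites$class <- classify_effect(sites$theta)
  proteins$theta <- fixation_ratio(proteins$burden, popgen)
  proteins$class <- classify_effect(proteins$theta)
  list(sites = sites, proteins = proteins)
}

#' Compare site-cost distributions across synonymous codons
#'
#' Groups per-site expected costs by codon within each amino-acid family
#' (families with a single codon are excluded) and runs pairwise Wilcoxon
#' rank-sum tests between synonymous codons. Raw p-values are reported
#' alongside Benjamini-Hochberg-adjusted ones (adjusted across all pairs).
#' When RSCU values are supplied, each codon is annotated as preferred
#' (RSCU > 1) or not.
#'
#' @param site_costs Data.frame with columns `codon` and `cost` (e.g. the
#'   `sites` element of [fitness_landscape()]).
#' @param rscu_values Optional named RSCU vector (see [rscu()]).
#' @return A list with `groups` (per-codon n, median cost, RSCU,
#'   preferred) and `tests` (pairwise comparisons with `p_value` and
#'   `p_adjusted`).
#' @export
synonymous_cost_comparison <- function(site_costs, rscu_values = NULL) {
  stopifnot(all(c("codon", "cost") %in% names(site_costs)))
  .check_codon(unique(site_costs$codon), sense_only = TRUE)
  site_costs$amino_acid <- translate_codons(site_costs$codon)
  fam_size <- stats::ave(seq_len(61), translate_codons(SENSE_CODONS),
                         FUN = length)
  multi <- SENSE_CODONS[fam_size > 1]
  site_costs <- site_costs[site_costs$codon %in% multi, , drop = FALSE]
  if (nrow(site_costs) == 0L) stop("no sites at multi-codon amino acids")
  groups <- do.call(rbind, lapply(
    split(site_costs, site_costs$codon), function(g) {
      data.frame(codon = g$codon[1L], amino_acid = g$amino_acid[1L],
                 n = nrow(g), median_cost = stats::median(g$cost),
                 stringsAsFactors = FALSE)
    }))
  rownames(groups) <- NULL
  if (!is.null(rscu_values)) {
    groups$rscu <- unname(rscu_values[groups$codon])
    groups$preferred <- groups$rscu > 1
  }
  tests <- list()
  for (aa in unique(site_costs$amino_acid)) {
    sub <- site_costs[site_costs$amino_acid == aa, ]
    cods <- sort(unique(sub$codon))
    if (length(cods) < 2L) next
    for (i in seq_len(length(cods) - 1L)) {
      for (j in (i + 1L):length(cods)) {
        x <- sub$cost[sub$codon == cods[i]]
        y <- sub$cost[sub$codon == cods[j]]
        if (!length(x) || !length(y)) next
        p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
        tests[[length(tests) + 1L]] <- data.frame(
          amino_acid = aa, codon_a = cods[i], codon_b = cods[j],
          n_a = length(x), n_b = length(y), p_value = p,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tests <- do.call(rbind, tests)
  if (!is.null(tests)) {
    tests$p_adjusted <- stats::p.adjust(tests$p_value, method = "BH")
  }
  list(groups = groups, tests = tests)
}
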