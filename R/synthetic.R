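# Synthetic generators: tRNA pools, ground-truth affinity models,
# multinomial misincorporation counts, PSM fixtures with decoys, random
# proteomes and DFE-like variant-effect score tables. Every generator is
# deterministic under its seed.

#' Generate a synthetic tRNA pool
#'
#' Anticodons are drawn from the Watson-Crick anticodons of the sense
#' codons so that every one of the 20 amino acids has at least one species;
#' abundances are log-uniform over `abundance_range` (molecules per cell).
#' With `lysidine = TRUE` the isoleucine codon AUA is served by a
#' lysidine-modified anticodon (`LAU`) rather than the unmodified
#' Watson-Crick one, as in bacteria.
#'
#' @param seed Integer seed.
#' @param n_species Number of tRNA species (20 to 61).
#' @param abundance_range Abundance range, molecules per cell.
#' @param lysidine Include a lysidine wobble species for AUA.
#' @return A `trna_pool`.
#' @export
gen_trna_pool <- function(seed, n_species = 42L,
                          abundance_range = c(1e3, 1e5), lysidine = TRUE) {
  candidates <- data.frame(
    anticodon = vapply(SENSE_CODONS, .wc_anticodon, character(1L)),
    amino_acid = translate_codons(SENSE_CODONS),
    stringsAsFactors = FALSE
  )
  if (lysidine) {
    candidates$anticodon[rownames(candidates) == "AUA"] <- "LAU"
  }
  if (n_species < length(unique(candidates$amino_acid)) ||
      n_species > nrow(candidates)) {
    stop("infeasible coverage request: n_species must be between 20 and ",
         nrow(candidates))
  }
  set.seed(seed)
  # one anticodon per amino acid first, then fill at random
  first <- vapply(split(seq_len(nrow(candidates)), candidates$amino_acid),
                  function(ix) ix[sample.int(length(ix), 1L)], integer(1L))
  rest <- setdiff(seq_len(nrow(candidates)), first)
  extra <- sample(rest, n_species - length(first))
  pick <- sort(c(unname(first), extra))
  ab <- exp(stats::runif(length(pick), log(abundance_range[1L]),
                         log(abundance_range[2L])))
  pool <- trna_pool(
    id = paste0(candidates$amino_acid[pick], "-", candidates$anticodon[pick]),
    anticodon = candidates$anticodon[pick],
    amino_acid = candidates$amino_acid[pick],
    abundance = ab
  )
  attr(pool, "seed") <- seed
  pool
}

#' Generate a ground-truth affinity model
#'
#' Watson-Crick pairs receive strong (low) affinities around
#' `-wc_strength`, mismatches weak (high) ones; the lysidine column is
#' mildly favorable toward every codon nucleotide and strongly favorable
#' toward A (its canonical partner). The result is expressed in the
#' canonical gauge (the Watson-Crick entry of every codon-nucleotide row
#' anchored at 0, matching the fit's parameterization) and the site
#' weights are drawn uniformly in `[0.5, 3]`.
#'
#' @param seed Integer seed.
#' @param wc_strength Positive scalar: affinity advantage of Watson-Crick
#'   pairs.
#' @param lysidine Include the lysidine anticodon column.
#' @return An [affinity_model()] whose Watson-Crick entries are strictly
#'   below all mismatch entries.
#' @export
gen_true_model <- function(seed, wc_strength = 6, lysidine = TRUE) {
  stopifnot(wc_strength > 0)
  set.seed(seed)
  anti <- if (lysidine) .ANTI_NT else .CODON_NT
  a <- matrix(stats::runif(4L * length(anti), 0, wc_strength / 2),
              4L, length(anti), dimnames = list(.CODON_NT, anti))
  for (cn in .CODON_NT) {
    a[cn, .WC_PARTNER[[cn]]] <- -wc_strength * stats::runif(1L, 0.8, 1.2)
  }
  if (lysidine) {
    a["A", "L"] <- -wc_strength * stats::runif(1L, 0.8, 1.2)
    a[c("C", "G", "U"), "L"] <- -wc_strength *
      stats::runif(3L, 0.1, 0.5)
  }
  for (cn in .CODON_NT) { # canonical gauge: row-wise Watson-Crick anchor
    a[cn, ] <- a[cn, ] - a[cn, .WC_PARTNER[[cn]]]
  }
  s <- stats::runif(2L, 0.5, 3)
  model <- affinity_model(a, s1 = s[1L], s2 = s[2L], lysidine = lysidine)
  attr(model, "seed") <- seed
  model
}

#' Bundle a complete synthetic ground truth
#'
#' Pool, true affinity model, cell geometry and the implied error
#' landscape, all reproducible from one seed.
#'
#' @param seed Integer seed.
#' @param geometry A [cell_geometry()].
#' @param n_species,abundance_range,lysidine Passed to [gen_trna_pool()].
#' @param wc_strength Passed to [gen_true_model()].
#' @return A list of class `synthetic_truth` with elements `seed`, `pool`,
#'   `model`, `geometry` and `landscape`.
#' @export
synthetic_truth <- function(seed, geometry = geometry_preset("ecoli"),
                            n_species = 42L, abundance_range = c(1e3, 1e5),
                            wc_strength = 6, lysidine = TRUE) {
  pool <- gen_trna_pool(seed, n_species, abundance_range, lysidine)
  model <- gen_true_model(seed + 1L, wc_strength, lysidine)
  structure(
    list(seed = seed, pool = pool, model = model, geometry = geometry,
         landscape = build_landscape(pool, model, geometry)),
    class = "synthetic_truth"
  )
}

#' Simulate misincorporation counts from a model
#'
#' One multinomial draw per sense codon of size `depth_per_codon` over the
#' observable (Leu/Ile-merged) categories of the landscape implied by the
#' model.
#'
#' @param pool A `trna_pool`.
#' @param model An [affinity_model()].
#' @param geometry A [cell_geometry()].
#' @param depth_per_codon Observations per codon.
#' @param seed Optional integer seed.
#' @return A [codon_observations()] object.
#' @export
simulate_observations <- function(pool, model, geometry,
                                  depth_per_codon = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  land <- build_landscape(pool, model, geometry)
  cats <- colnames(land$P_obs)
  rows <- lapply(land$codons, function(cod) {
    counts <- drop(stats::rmultinom(1L, depth_per_codon, land$P_obs[cod, ]))
    own <- .merge_il(translate_codons(cod))
    keep <- cats != own
    data.frame(codon = cod, total_count = depth_per_codon,
               dest_aa = cats[keep], error_count = counts[keep],
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  codon_observations(long$codon, long$total_count, long$dest_aa,
                     long$error_count)
}

#' Generate a random proteome
#'
#' Random coding sequences over the sense codons (an AUG start, no internal
#' stops) with log-normal relative abundances normalized to a proteome
#' fraction.
#'
#' @param seed Integer seed.
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (codons, start included).
#' @return Data.frame with columns `protein_id`, `phi`, `sequence`
#'   (amino acids), `cds` (U-alphabet string) and list column `codons`.
#' @export
gen_proteome <- function(seed, n_proteins = 30L, length_range = c(80L, 300L)) {
  set.seed(seed)
  lens <- sample(length_range[1L]:length_range[2L], n_proteins,
                 replace = TRUE)
  phi <- stats::rlnorm(n_proteins, 0, 1.5)
  phi <- phi / sum(phi)
  codons <- lapply(lens, function(L) {
    c("AUG", sample(SENSE_CODONS, L - 1L, replace = TRUE))
  })
  data.frame(
    protein_id = sprintf("P%03d", seq_len(n_proteins)),
    phi = phi,
    sequence = vapply(codons, function(cs)
      paste(translate_codons(cs), collapse = ""), character(1L)),
    cds = vapply(codons, paste, character(1L), collapse = ""),
    codons = I(codons),
    stringsAsFactors = FALSE
  )
}

# Destination categories and their probabilities for errors at one codon,
# from the observable landscape row (own category excluded, renormalized).
.error_dest_probs <- function(landscape, codon) {
  own <- .merge_il(translate_codons(codon))
  p <- landscape$P_obs[codon, ]
  p <- p[names(p) != own]
  if (sum(p) <= 0) return(NULL)
  p / sum(p)
}

#' Generate a synthetic PSM fixture with ground truth
#'
#' Emits an open-search-style PSM table exercising every detection filter:
#' clean unmodified peptides (Gaussian mass jitter, sd 1 mDa), true
#' substitutions drawn from the landscape's per-codon error probabilities
#' (scaled by `error_scale`), PTM decoys at matching residues,
#' multi-protein decoys and unlocalized shifts. Every true substitution is
#' accompanied by an unmodified peptide covering its position, and
#' substitution destinations whose mass shift would collide with a listed
#' PTM on the original residue are not injected (they are undetectable by
#' design). The injected calls are returned alongside as ground truth.
#'
#' @param truth A [synthetic_truth()] (supplies the landscape).
#' @param proteome A [gen_proteome()] result.
#' @param n_psms Number of primary PSMs (coverage companions are added on
#'   top).
#' @param seed Integer seed.
#' @param error_scale Multiplier on the landscape's per-codon error
#'   probabilities (mass-spectrometry fixtures need more errors per
#'   observation than a cell produces to yield calls at small `n_psms`).
#' @param ptm_decoy_rate,multi_decoy_rate,unlocalized_rate Fractions of
#'   PSMs turned into PTM decoys, multi-protein decoys, and unlocalized
#'   modified peptides.
#' @param ptm_masses PTM table (see [read_ptm_list()]).
#' @param jitter_sd Mass jitter standard deviation in Da (default 0.001).
#' @param dataset_id Dataset identifier stamped on every PSM.
#' @return A list with `psms`, `truth` (the injected, recoverable calls)
#'   and `seed`.
#' @export
gen_psm_fixture <- function(truth, proteome, n_psms = 2000L, seed = 1L,
                            error_scale = 10, ptm_decoy_rate = 0.05,
                            multi_decoy_rate = 0.03,
                            unlocalized_rate = 0.02,
                            ptm_masses = read_ptm_list(),
                            jitter_sd = 0.001, dataset_id = "DS1") {
  stopifnot(inherits(truth, "synthetic_truth"), nrow(proteome) > 0L)
  set.seed(seed)
  land <- truth$landscape
  psms <- vector("list", n_psms)
  calls <- list()
  companions <- list()
  for (r in seq_len(n_psms)) {
    pi_ <- sample.int(nrow(proteome), 1L, prob = proteome$phi)
    prot <- proteome[pi_, ]
    plen <- nchar(prot$sequence)
    len <- min(sample(8:20, 1L), plen)
    start <- sample.int(plen - len + 1L, 1L)
    pep <- substr(prot$sequence, start, start + len - 1L)
    cods <- prot$codons[[1L]][start:(start + len - 1L)]
    u <- stats::runif(1L)
    rec <- data.frame(
      dataset_id = dataset_id, raw_file = dataset_id, peptide = pep,
      protein = prot$protein_id, protein_start = start,
      mass_shift = stats::rnorm(1L, 0, jitter_sd),
      localized_position = NA_real_, stringsAsFactors = FALSE
    )
    if (u < multi_decoy_rate) {
      # substitution-like shift on a peptide assigned to two proteins
      other <- proteome$protein_id[proteome$protein_id != prot$protein_id]
      rec$protein <- paste(prot$protein_id,
                           other[sample.int(length(other), 1L)], sep = ";")
      lp <- sample.int(len, 1L)
      rec$localized_position <- lp
      orig <- substr(pep, lp, lp)
      dest <- sample(setdiff(.AA_CANONICAL, orig), 1L)
      rec$mass_shift <- substitution_mass_delta(orig, dest) +
        stats::rnorm(1L, 0, jitter_sd)
    } else if (u < multi_decoy_rate + ptm_decoy_rate) {
      hit <- which(strsplit(pep, "")[[1L]] %in% ptm_masses$residue)
      if (length(hit)) {
        lp <- hit[sample.int(length(hit), 1L)]
        orig <- substr(pep, lp, lp)
        ptm <- ptm_masses[ptm_masses$residue == orig, ]
        ptm <- ptm[sample.int(nrow(ptm), 1L), ]
        rec$localized_position <- lp
        rec$mass_shift <- ptm$shift + stats::rnorm(1L, 0, jitter_sd)
      }
    } else if (u < multi_decoy_rate + ptm_decoy_rate + unlocalized_rate) {
      lp <- sample.int(len, 1L)
      orig <- substr(pep, lp, lp)
      dest <- sample(setdiff(.AA_CANONICAL, orig), 1L)
      rec$mass_shift <- substitution_mass_delta(orig, dest) +
        stats::rnorm(1L, 0, jitter_sd)
      # localized_position stays NA: ambiguous localization
    } else {
      p_err <- pmin(land$p_error[cods] * error_scale, 0.5)
      hits <- which(stats::runif(len) < p_err)
      if (length(hits)) {
        lp <- hits[1L]
        cod <- cods[lp]
        orig <- substr(pep, lp, lp)
        dp <- .error_dest_probs(land, cod)
        dest <- NULL
        if (!is.null(dp)) {
          for (cand in sample(names(dp), length(dp), prob = dp)) {
            aa <- if (cand == "J") setdiff(c("I", "L"), orig)[1L] else cand
            delta <- substitution_mass_delta(orig, aa)
            ptm_clash <- any(ptm_masses$residue == orig &
                               abs(ptm_masses$shift - delta) <= 0.012)
            if (abs(delta) > 0.012 && !ptm_clash) {
              dest <- aa
              break
            }
          }
        }
        if (!is.null(dest)) {
          rec$localized_position <- lp
          rec$mass_shift <- substitution_mass_delta(orig, dest) +
            stats::rnorm(1L, 0, jitter_sd)
          calls[[length(calls) + 1L]] <- data.frame(
            dataset_id = dataset_id, protein_id = prot$protein_id,
            position = start + lp - 1L, codon = cod, orig_aa = orig,
            dest_aa = .aa_category_label(.merge_il(dest)),
            mass_shift = rec$mass_shift, stringsAsFactors = FALSE
          )
          # guarantee unmodified coverage of the substituted position
          companions[[length(companions) + 1L]] <- data.frame(
            dataset_id = dataset_id, raw_file = dataset_id, peptide = pep,
            protein = prot$protein_id, protein_start = start,
            mass_shift = stats::rnorm(1L, 0, jitter_sd),
            localized_position = NA_real_, stringsAsFactors = FALSE
          )
        }
      }
    }
    psms[[r]] <- rec
  }
  psms <- do.call(rbind, c(psms, companions))
  rownames(psms) <- NULL
  truth_calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(dataset_id = character(), protein_id = character(),
               position = integer(), codon = character(),
               orig_aa = character(), dest_aa = character(),
               mass_shift = numeric(), stringsAsFactors = FALSE)
  list(psms = psms, truth = truth_calls, seed = seed)
}

#' Generate DFE-like variant-effect score tables
#'
#' For every site of every protein and every amino acid other than the
#' encoded one, a score is drawn from a two-component mixture: a
#' near-neutral Gaussian around 0 and a deleterious (negative) log-normal
#' tail. The encoded residue scores exactly 0.
#'
#' @param proteome A [gen_proteome()] result.
#' @param seed Integer seed.
#' @param dfe_params List with `p_neutral` (mixture weight of the
#'   near-neutral component), `neutral_sd`, `del_meanlog`, `del_sdlog`.
#' @return A `fitness_scores` data.frame.
#' @export
gen_fitness_scores <- function(proteome, seed,
                               dfe_params = list(p_neutral = 0.7,
                                                 neutral_sd = 0.05,
                                                 del_meanlog = 0,
                                                 del_sdlog = 0.7)) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    aa_seq <- strsplit(proteome$sequence[i], "")[[1L]]
    L <- length(aa_seq)
    grid <- expand.grid(site = seq_len(L), amino_acid = .AA_CANONICAL,
                        stringsAsFactors = FALSE)
    encoded <- aa_seq[grid$site] == grid$amino_acid
    n <- nrow(grid)
    neutral <- stats::runif(n) < dfe_params$p_neutral
    score <- ifelse(neutral,
                    stats::rnorm(n, 0, dfe_params$neutral_sd),
                    -stats::rlnorm(n, dfe_params$del_meanlog,
                                   dfe_params$del_sdlog))
    score[encoded] <- 0
    data.frame(protein_id = proteome$protein_id[i], site = grid$site,
               amino_acid = grid$amino_acid, deltaE = score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fitness_scores", "data.frame")
  attr(out, "seed") <- seed
  out
}
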