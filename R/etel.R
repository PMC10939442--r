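# Empirical substitution calling on open-search PSM tables: mass-shift
# classification, the ordered filter chain, dataset curation, error
# detection rates, and relative synonymous codon usage.

#' Classify an observed mass shift
#'
#' Peptides with a mass shift within +/- 5 mDa (by default) of zero are
#' considered unmodified; all others modified.
#'
#' @param shift Observed minus theoretical peptide mass, in Da (vectorized).
#' @param tol Half-width of the unmodified window in Da (default 0.005).
#' @return Character vector, `"unmodified"` or `"modified"`.
#' @export
classify_mass_shift <- function(shift, tol = 0.005) {
  if (any(!is.finite(shift))) stop("mass shifts must be finite")
  ifelse(abs(shift) <= tol, "unmodified", "modified")
}

#' Read a PSM table
#'
#' Tolerant tab-separated reader: accepts either the package's minimal
#' column set (`peptide`, `protein`, `protein_start`, `mass_shift`,
#' `localized_position`, optionally `dataset_id` and `raw_file`) or the
#' Philosopher psm.tsv spellings (`Peptide`, `Protein`, `Protein Start`,
#' `Delta Mass`, ...).
#'
#' @param path Path to the table.
#' @param dataset_id Dataset identifier to assign when the table has no
#'   `dataset_id` column; defaults to the file name.
#' @return Data.frame with the minimal column set.
#' @export
read_psm_table <- function(path, dataset_id = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  alias <- list(
    peptide = c("peptide", "Peptide"),
    protein = c("protein", "Protein"),
    protein_start = c("protein_start", "Protein Start"),
    mass_shift = c("mass_shift", "Delta Mass", "delta_mass"),
    localized_position = c("localized_position", "MSFragger Localization",
                           "localization")
  )
  out <- list()
  for (col in names(alias)) {
    hit <- intersect(alias[[col]], names(tab))
    if (!length(hit)) stop("PSM table is missing a '", col, "' column")
    out[[col]] <- tab[[hit[1L]]]
  }
  out$dataset_id <- if ("dataset_id" %in% names(tab)) tab$dataset_id else
    if (is.null(dataset_id)) basename(path) else dataset_id
  out$raw_file <- if ("raw_file" %in% names(tab)) tab$raw_file else
    out$dataset_id
  data.frame(out, stringsAsFactors = FALSE)
}

#' Shipped post-translational-modification exclusion list
#'
#' Residue-specific mass shifts (common Unimod entries) used to exclude
#' substitution calls whose mass shift and localized residue also match a
#' known PTM. Reproducing a specific published analysis exactly requires
#' supplying that analysis's own list.
#'
#' @param path Optional path to a custom TSV with columns `residue`,
#'   `shift`, `name`.
#' @return Data.frame with columns `residue`, `shift`, `name`.
#' @export
read_ptm_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ptm_shifts.tsv", package = "mtel",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "shift", "name")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("PTM list missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}

#' Call amino acid substitutions from open-search PSMs
#'
#' Applies, in order: (1) drop peptides matched to several proteins;
#' (2) split unmodified/modified at the +/- `tol` mass window (unmodified
#' peptides provide coverage, not calls); (3) retain modified peptides only
#' if the modified protein position is covered by an unmodified peptide
#' from the same dataset and raw file; (4) require an unambiguously
#' localized shift; (5) require the shift to match the mass difference
#' between the original residue and some other amino acid within `tol`;
#' (6) drop calls whose shift and localized residue also match a listed
#' PTM. Leucine/isoleucine destinations are reported merged as `I/L`.
#'
#' @param psms Data.frame as returned by [read_psm_table()]. The column
#'   `localized_position` is the 1-based position of the shift within the
#'   peptide; `NA` marks unlocalized or ambiguous shifts.
#' @param protein_db Named character vector: protein id -> amino acid
#'   sequence.
#' @param cds_map Named character vector: protein id -> coding sequence
#'   (U alphabet; may include the stop codon).
#' @param ptm_masses PTM exclusion table (see [read_ptm_list()]).
#' @param tol Mass tolerance in Da, used both for the unmodified window and
#'   for matching shifts to substitution and PTM masses.
#' @return Data.frame of calls (`dataset_id`, `protein_id`, `position`,
#'   `codon`, `orig_aa`, `dest_aa`, `mass_shift`) with attribute
#'   `filter_counts`: how many PSMs each stage removed (every input PSM is
#'   attributed to exactly one outcome).
#' @export
call_substitutions <- function(psms, protein_db, cds_map,
                               ptm_masses = read_ptm_list(), tol = 0.005) {
  stopifnot(is.data.frame(psms))
  need <- c("peptide", "protein", "protein_start", "mass_shift",
            "localized_position")
  miss <- setdiff(need, names(psms))
  if (length(miss)) stop("psms missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"dataset_id" %in% names(psms)) psms$dataset_id <- "dataset1"
  if (!"raw_file" %in% names(psms)) psms$raw_file <- psms$dataset_id

  counts <- c(call = 0L, unmodified = 0L, multi_protein = 0L,
              missing_protein = 0L, uncovered = 0L, unlocalized = 0L,
              no_substitution_match = 0L, ptm_collision = 0L)

  multi <- grepl(";", psms$protein, fixed = TRUE)
  counts[["multi_protein"]] <- sum(multi)
  psms <- psms[!multi, , drop = FALSE]

  known <- psms$protein %in% names(protein_db)
  counts[["missing_protein"]] <- sum(!known)
  psms <- psms[known, , drop = FALSE]

  cls <- classify_mass_shift(psms$mass_shift, tol)
  unmod <- psms[cls == "unmodified", , drop = FALSE]
  mod <- psms[cls == "modified", , drop = FALSE]
  counts[["unmodified"]] <- nrow(unmod)

  # codon lookup, with a length consistency check per referenced protein
  codon_at <- function(protein, pos) {
    cds <- cds_map[[protein]]
    if (is.null(cds)) stop("no coding sequence for protein ", protein)
    plen <- nchar(protein_db[[protein]])
    if (!nchar(cds) %in% (3L * c(plen, plen + 1L))) {
      stop("coding sequence length for ", protein,
           " does not match the protein length")
    }
    substr(cds, 3L * pos - 2L, 3L * pos)
  }

  # unmodified coverage intervals per (dataset, raw file, protein)
  cov_key <- paste(unmod$dataset_id, unmod$raw_file, unmod$protein,
                   sep = "\r")
  cov_start <- split(unmod$protein_start, cov_key)
  cov_end <- split(unmod$protein_start + nchar(unmod$peptide) - 1L, cov_key)

  calls <- vector("list", nrow(mod))
  for (r in seq_len(nrow(mod))) {
    rec <- mod[r, ]
    lp <- rec$localized_position
    if (is.na(lp)) {
      counts[["unlocalized"]] <- counts[["unlocalized"]] + 1L
      next
    }
    pos <- rec$protein_start + lp - 1L
    key <- paste(rec$dataset_id, rec$raw_file, rec$protein, sep = "\r")
    covered <- !is.null(cov_start[[key]]) &&
      any(cov_start[[key]] <= pos & cov_end[[key]] >= pos)
    if (!covered) {
      counts[["uncovered"]] <- counts[["uncovered"]] + 1L
      next
    }
    orig <- substr(rec$peptide, lp, lp)
    if (!orig %in% .AA_CANONICAL) {
      counts[["no_substitution_match"]] <-
        counts[["no_substitution_match"]] + 1L
      next
    }
    deltas <- substitution_mass_delta(orig, .AA_CANONICAL)
    cand <- .AA_CANONICAL[abs(deltas - rec$mass_shift) <= tol &
                            .AA_CANONICAL != orig]
    cand <- setdiff(.merge_il(cand), .merge_il(orig))
    if (!length(cand)) {
      counts[["no_substitution_match"]] <-
        counts[["no_substitution_match"]] + 1L
      next
    }
    ptm_hit <- any(ptm_masses$residue == orig &
                     abs(ptm_masses$shift - rec$mass_shift) <= tol)
    if (ptm_hit) {
      counts[["ptm_collision"]] <- counts[["ptm_collision"]] + 1L
      next
    }
    # nearest-mass destination (merged categories)
    dest <- cand[which.min(vapply(cand, function(d) {
      aa <- if (d == "J") "L" else d
      abs(substitution_mass_delta(orig, aa) - rec$mass_shift)
    }, numeric(1L)))]
    counts[["call"]] <- counts[["call"]] + 1L
    calls[[r]] <- data.frame(
      dataset_id = rec$dataset_id, protein_id = rec$protein,
      position = pos, codon = codon_at(rec$protein, pos),
      orig_aa = orig, dest_aa = .aa_category_label(dest),
      mass_shift = rec$mass_shift, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, calls[!vapply(calls, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(dataset_id = character(), protein_id = character(),
                      position = integer(), codon = character(),
                      orig_aa = character(), dest_aa = character(),
                      mass_shift = numeric(), stringsAsFactors = FALSE)
  }
  attr(out, "filter_counts") <- counts
  out
}

#' Isotopic-label-indicative mass shifts
#'
#' Default SILAC-style shifts (13C/15N labeled Lys and Arg) used by the
#' dataset curation rule.
#' @return Named numeric vector of shifts in Da.
#' @export
label_shifts_default <- function() {
  c("Lys8" = 8.01420, "Arg10" = 10.00827, "Lys6/Arg6" = 6.02013,
    "Lys4" = 4.02511)
}

#' Curate datasets by substitution yield and label contamination
#'
#' A dataset is retained iff it has at least `min_calls` detected
#' substitutions and at most `max_label_fraction` of its detected
#' misincorporations carry a mass shift indicative of isotopic labeling.
#'
#' @param calls Substitution calls (with `dataset_id` and `mass_shift`
#'   columns), e.g. from [call_substitutions()] over several datasets.
#' @param min_calls Minimum substitution count (default 10).
#' @param label_shifts Label-indicative shifts (Da); default
#'   [label_shifts_default()].
#' @param max_label_fraction Maximum tolerated label-like fraction
#'   (default 0.10).
#' @param tol Mass tolerance in Da for matching label shifts.
#' @return Character vector of retained dataset ids.
#' @export
curate_datasets <- function(calls, min_calls = 10L,
                            label_shifts = label_shifts_default(),
                            max_label_fraction = 0.1, tol = 0.005) {
  if (nrow(calls) == 0L) return(character())
  label_like <- vapply(calls$mass_shift, function(s) {
    any(abs(s - label_shifts) <= tol)
  }, logical(1L))
  keep <- vapply(split(label_like, calls$dataset_id), function(lab) {
    length(lab) >= min_calls && sum(lab) <= max_label_fraction * length(lab)
  }, logical(1L))
  names(keep)[keep]
}

#' Per-codon (and per-protein) PSM coverage counts
#'
#' For every PSM — modified or unmodified — every protein position the
#' peptide covers contributes one observation of that position's codon.
#' Multi-protein PSMs and PSMs on proteins absent from the database are
#' skipped, mirroring the call filters.
#'
#' @inheritParams call_substitutions
#' @return A list with `codon` (named counts over codons) and `protein`
#'   (named PSM counts per protein).
#' @export
codon_coverage <- function(psms, protein_db, cds_map) {
  ok <- !grepl(";", psms$protein, fixed = TRUE) &
    psms$protein %in% names(protein_db)
  psms <- psms[ok, , drop = FALSE]
  codons <- character(0)
  for (r in seq_len(nrow(psms))) {
    prot <- psms$protein[r]
    pos <- psms$protein_start[r]:(psms$protein_start[r] +
                                    nchar(psms$peptide[r]) - 1L)
    cds <- cds_map[[prot]]
    codons <- c(codons, substring(cds, 3L * pos - 2L, 3L * pos))
  }
  list(
    codon = table(factor(codons, levels = SENSE_CODONS)),
    protein = table(psms$protein)
  )
}

#' Error detection rates per codon and per protein
#'
#' Per codon: substitution calls at positions with that codon divided by
#' the total number of PSM-level observations of positions with that codon.
#' Per protein: calls on the protein divided by its total PSM count. Codons
#' (proteins) with zero total observations are reported as `NA`, not zero.
#'
#' @param calls Output of [call_substitutions()].
#' @param coverage Output of [codon_coverage()] (counts may be summed
#'   across datasets before calling; the rate of summed counts equals the
#'   count-weighted aggregation of per-dataset rates).
#' @return A list with `codon` and `protein` rate vectors.
#' @export
error_detection_rates <- function(calls, coverage) {
  err_codon <- table(factor(calls$codon, levels = SENSE_CODONS))
  tot_codon <- as.numeric(coverage$codon[SENSE_CODONS])
  rate_codon <- ifelse(tot_codon > 0, as.numeric(err_codon) / tot_codon,
                       NA_real_)
  names(rate_codon) <- SENSE_CODONS
  prots <- names(coverage$protein)
  err_prot <- table(factor(calls$protein_id, levels = prots))
  tot_prot <- as.numeric(coverage$protein)
  rate_prot <- ifelse(tot_prot > 0, as.numeric(err_prot) / tot_prot,
                      NA_real_)
  names(rate_prot) <- prots
  list(codon = rate_codon, protein = rate_prot)
}

#' Relative synonymous codon usage
#'
#' RSCU of each sense codon: observed count divided by the mean count of
#' its synonym family. When expression weights are supplied, usage is
#' computed on the top-`top_fraction` expressed sequences only.
#'
#' @param cds_sequences Character vector of coding sequences (U alphabet,
#'   length divisible by 3). Internal stop codons trigger a warning but are
#'   still counted.
#' @param expression_weights Optional numeric vector (same length or named
#'   like `cds_sequences`) of expression levels.
#' @param top_fraction Fraction of top-expressed sequences used when
#'   weights are given (default 0.05).
#' @return Named numeric vector of RSCU values over the 61 sense codons
#'   (`NaN` where a whole family is unobserved).
#' @export
rscu <- function(cds_sequences, expression_weights = NULL,
                 top_fraction = 0.05) {
  if (any(nchar(cds_sequences) %% 3L != 0L)) {
    stop("coding sequence length(s) not divisible by 3")
  }
  if (!is.null(expression_weights)) {
    stopifnot(length(expression_weights) == length(cds_sequences))
    cut <- stats::quantile(expression_weights, 1 - top_fraction)
    cds_sequences <- cds_sequences[expression_weights >= cut]
  }
  concat <- paste(cds_sequences, collapse = "")
  n <- nchar(concat) / 3L
  codons <- substring(concat, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  .check_codon(codons)
  internal_stop <- GENETIC_CODE_RNA[codons[-length(codons)]] == "*"
  if (length(codons) > 1L && any(internal_stop)) {
    warning("internal stop codon(s) encountered; still counted")
  }
  vals <- seqinr::uco(seqinr::s2c(tolower(chartr("U", "T", concat))),
                      frame = 0, index = "rscu")
  names(vals) <- chartr("T", "U", toupper(names(vals)))
  vals[SENSE_CODONS]
}

#' Write substitution calls to TSV
#' @param calls Output of [call_substitutions()].
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
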