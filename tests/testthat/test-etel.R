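# A small hand-built fixture exercising every detection filter exactly once.
etel_fixture <- function() {
  protein_db <- c(P1 = "MGNKAAGGW", P2 = "MGGGGKKKK")
  cds_map <- c(
    P1 = "AUGGGUAAUAAAGCUGCUGGUGGAUGG",
    P2 = "AUGGGUGGAGGCGGGAAAAAGAAGAAA"
  )
  psms <- data.frame(
    dataset_id = "DS1", raw_file = "run1",
    peptide = c("MGNKAAGGW", "MGNKAAGGW", "MGNKAAGGW", "MGNKAAGGW",
                "MGGGGKKKK", "MGNKAAGGW", "MGNKAAGGW", "AAAA"),
    protein = c("P1", "P1", "P1", "P1;P2", "P2", "P1", "P1", "P9"),
    protein_start = c(1, 1, 1, 1, 1, 1, 1, 1),
    mass_shift = c(0.001, 14.0157, 0.98400, 14.0157, 14.0157, 14.0157,
                   5.0, 14.0157),
    localized_position = c(NA, 2, 3, 2, 2, NA, 2, 2),
    stringsAsFactors = FALSE
  )
  list(psms = psms, protein_db = protein_db, cds_map = cds_map)
}

test_that("mass shifts split into unmodified and modified at +/- 5 mDa", {
  expect_equal(classify_mass_shift(0.004), "unmodified")
  expect_equal(classify_mass_shift(-0.0051), "modified")
  expect_equal(classify_mass_shift(14.0157), "modified")
  expect_equal(classify_mass_shift(c(0.005, -0.005)),
               c("unmodified", "unmodified")) # boundary is inclusive
  expect_error(classify_mass_shift(NaN), "finite")
})

test_that("the filter chain calls true substitutions and drops each decoy class", {
  fx <- etel_fixture()
  calls <- call_substitutions(fx$psms, fx$protein_db, fx$cds_map)
  # exactly one call: the covered, localized G -> A at P1 position 2
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$protein_id, "P1")
  expect_equal(calls$position, 2)
  expect_equal(calls$codon, "GGU")
  expect_equal(calls$orig_aa, "G")
  expect_equal(calls$dest_aa, "A")

  counts <- attr(calls, "filter_counts")
  expect_equal(unname(counts[["call"]]), 1L)
  expect_equal(unname(counts[["unmodified"]]), 1L)
  expect_equal(unname(counts[["multi_protein"]]), 1L)
  expect_equal(unname(counts[["missing_protein"]]), 1L)
  expect_equal(unname(counts[["uncovered"]]), 1L)
  expect_equal(unname(counts[["unlocalized"]]), 1L)
  expect_equal(unname(counts[["no_substitution_match"]]), 1L)
  expect_equal(unname(counts[["ptm_collision"]]), 1L)
  # every PSM is attributed to exactly one outcome
  expect_equal(sum(counts), nrow(fx$psms))
})

test_that("the deamidation-indistinguishable N->D shift is excluded as a PTM", {
  fx <- etel_fixture()
  # without the PTM list the same PSM would be called N -> D
  no_ptm <- data.frame(residue = character(), shift = numeric(),
                       name = character())
  calls <- call_substitutions(fx$psms, fx$protein_db, fx$cds_map,
                              ptm_masses = no_ptm)
  expect_true(any(calls$orig_aa == "N" & calls$dest_aa == "D"))
})

test_that("coordinates check against the coding sequence", {
  fx <- etel_fixture()
  bad_cds <- fx$cds_map
  bad_cds["P1"] <- "AUGGGU" # far too short for a 9-residue protein
  expect_error(call_substitutions(fx$psms, fx$protein_db, bad_cds),
               "length")
})

test_that("dataset curation applies the yield and label-contamination rules", {
  mk <- function(id, n, n_label) {
    data.frame(dataset_id = id,
               mass_shift = c(rep(14.0157, n - n_label),
                              rep(8.0142, n_label)))
  }
  calls <- rbind(mk("small", 9, 0),      # < 10 substitutions: dropped
                 mk("labelled", 100, 11), # > 10% label-like: dropped
                 mk("edge", 10, 0),       # exactly 10, clean: retained
                 mk("ok", 100, 10))       # exactly 10%: retained
  kept <- curate_datasets(calls)
  expect_setequal(kept, c("edge", "ok"))
  expect_identical(curate_datasets(calls[0, , drop = FALSE]), character(0))
})

test_that("error detection rates divide calls by PSM-level coverage", {
  fx <- etel_fixture()
  calls <- call_substitutions(fx$psms, fx$protein_db, fx$cds_map)
  cov <- codon_coverage(fx$psms, fx$protein_db, fx$cds_map)
  rates <- error_detection_rates(calls, cov)
  # GGU (P1 position 2) is covered by 6 single-protein P1 PSMs and one P2
  # PSM at a different position plus P2's own GGU-free codons
  expect_equal(unname(rates$codon[["GGU"]]),
               1 / as.numeric(cov$codon[["GGU"]]))
  expect_true(all(rates$codon >= 0 & rates$codon <= 1, na.rm = TRUE))
  # codons never covered are NA, not zero
  expect_true(anyNA(rates$codon))
  zero_err <- rates$codon[!is.na(rates$codon)]
  expect_true(any(zero_err == 0))

  # associativity: rates from summed counts equal rates from summed tables
  fx2 <- fx
  fx2$psms$dataset_id <- "DS2"
  cov2 <- codon_coverage(fx2$psms, fx$protein_db, fx$cds_map)
  both_cov <- list(codon = cov$codon + cov2$codon,
                   protein = cov$protein + cov2$protein)
  calls2 <- calls
  calls2$dataset_id <- "DS2"
  r_both <- error_detection_rates(rbind(calls, calls2), both_cov)
  expect_equal(unname(r_both$codon[["GGU"]]),
               2 / (2 * as.numeric(cov$codon[["GGU"]])))
})

test_that("RSCU follows the synonym-family definition", {
  # Phe family used 3:1 -> RSCU 1.5 and 0.5
  vals <- rscu("UUUUUUUUUUUC")
  expect_equal(unname(vals["UUU"]), 1.5)
  expect_equal(unname(vals["UUC"]), 0.5)
  # single-codon families are always 1 when observed
  vals2 <- rscu("AUGUGG")
  expect_equal(unname(vals2["AUG"]), 1)
  expect_equal(unname(vals2["UGG"]), 1)
  # uniform usage: all RSCU = 1
  vals3 <- rscu(paste(SENSE_CODONS, collapse = ""))
  expect_equal(unname(vals3), rep(1, 61), tolerance = 1e-12)
  expect_error(rscu("AUGA"), "divisible")
})

test_that("RSCU can be restricted to the top-expressed sequences", {
  seqs <- c(low = "UUUUUU", high = "UUCUUC")
  vals <- rscu(seqs, expression_weights = c(1, 10), top_fraction = 0.5)
  expect_equal(unname(vals["UUC"]), 2)
  expect_equal(unname(vals["UUU"]), 0)
})

test_that("the PSM reader accepts Philosopher-style column names", {
  tmp <- tempfile(fileext = ".tsv")
  tab <- data.frame(check.names = FALSE,
                    Peptide = "MGNK", Protein = "P1", `Protein Start` = 1,
                    `Delta Mass` = 0.001, `MSFragger Localization` = NA)
  utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  psms <- read_psm_table(tmp, dataset_id = "D")
  expect_equal(psms$peptide, "MGNK")
  expect_equal(psms$dataset_id, "D")
  expect_true(all(c("mass_shift", "localized_position") %in% names(psms)))
})
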