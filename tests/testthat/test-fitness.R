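test_that("relative fixation probability matches the closed form and its limits", {
  pg <- popgen_preset("ecoli")
  expect_equal(pg$Ne, 1e8)
  expect_equal(pg$q, 4.19e-7)
  # neutral reference
  expect_identical(fixation_ratio(0, pg), 1)
  # S = -0.5 directly
  pg1 <- popgen_params(Ne = 1, q = 1)
  expect_equal(fixation_ratio(-0.5, pg1), -1 / (1 - exp(1)),
               tolerance = 1e-12)
  expect_equal(fixation_ratio(-0.5, pg1), 0.5820, tolerance = 1e-4)
  # extreme deleterious values underflow gracefully, never to NaN
  expect_gte(fixation_ratio(-10, pg), 0)
  expect_false(is.nan(fixation_ratio(-1e6, pg1)))
  expect_error(fixation_ratio(NA_real_, pg), "finite")
})

test_that("theta is strictly increasing and satisfies the reflection identity", {
  pg <- popgen_params(Ne = 1, q = 1)
  s_grid <- seq(-5, 5, by = 0.25)
  th <- fixation_ratio(s_grid, pg)
  expect_true(all(diff(th) > 0))
  for (S in c(0.1, 0.5, 1, 3, 8)) {
    expect_equal(fixation_ratio(S, pg) / fixation_ratio(-S, pg),
                 exp(2 * S), tolerance = 1e-9)
  }
  # the limit at 0 is approached continuously
  expect_equal(fixation_ratio(1e-12, pg), 1, tolerance = 1e-9)
  expect_equal(fixation_ratio(-1e-12, pg), 1, tolerance = 1e-9)
})

test_that("the neutral band partitions the theta axis exactly", {
  expect_equal(classify_effect(0.96), "neutral")
  expect_equal(classify_effect(0.95), "neutral") # band is inclusive
  expect_equal(classify_effect(0.94), "deleterious")
  expect_equal(classify_effect(1.05), "neutral")
  expect_equal(classify_effect(1.06), "advantageous")
  grid <- c(0, 10^seq(-19, 1, by = 0.37), seq(0.9, 1.1, by = 0.001))
  cls <- classify_effect(grid)
  expect_true(all(cls %in% c("neutral", "deleterious", "advantageous")))
  expect_error(classify_effect(-0.1), ">= 0")
})

test_that("site costs are probability-weighted variant-effect sums", {
  # single-term example: P(A) = 0.01 with score -2 gives -0.02
  P <- matrix(0, 61, 20,
              dimnames = list(SENSE_CODONS, names(AA_MASS_MONO)))
  P[cbind(SENSE_CODONS, translate_codons(SENSE_CODONS))] <- 1
  P["GGU", "A"] <- 0.01
  P["GGU", "G"] <- 0.99
  land <- structure(list(P = P, codons = SENSE_CODONS),
                    class = "error_landscape")
  expect_equal(site_cost("GGU", c(A = -2), land), -0.02)
  # zero error probability: zero cost whatever the scores
  expect_equal(site_cost("AAA", c(A = -2, G = -5), land), 0)

  # brute-force expectation over all 20 amino acids on a real landscape
  tr <- tiny_truth(9)
  set.seed(91)
  for (rep in 1:5) {
    cod <- sample(SENSE_CODONS, 1)
    scores <- stats::setNames(stats::rnorm(20, -1, 1),
                              names(AA_MASS_MONO))
    got <- site_cost(cod, scores, tr$landscape)
    enc <- translate_codons(cod)
    want <- 0
    for (aa in names(AA_MASS_MONO)) {
      want <- want + tr$landscape$P[cod, aa] *
        (if (aa == enc) 0 else scores[[aa]])
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("missing scores are an error unless renormalization is requested", {
  tr <- tiny_truth(9)
  cod <- "AAA"
  probs <- tr$landscape$P[cod, ]
  present <- names(probs)[probs > 0]
  dropped <- setdiff(present, "K")[1]
  scores <- stats::setNames(rep(-1, 20), names(AA_MASS_MONO))
  scores <- scores[setdiff(names(scores), dropped)]
  expect_error(site_cost(cod, scores, tr$landscape), dropped)
  # renormalization preserves the total error mass
  got <- site_cost(cod, scores, tr$landscape, on_missing = "renormalize")
  expect_equal(got, -sum(probs[setdiff(names(probs), "K")]),
               tolerance = 1e-12)
})

test_that("protein burdens scale with abundance and add over sites", {
  costs <- c(-0.1, -0.3, 0.05)
  expect_equal(protein_burden(0, costs), 0)
  expect_equal(protein_burden(0.2, costs), 2 * protein_burden(0.1, costs))
  expect_equal(protein_burden(0.1, costs), 0.1 * sum(costs))
})

test_that("the proteome-level fitness landscape assembles consistently", {
  tr <- tiny_truth(10)
  prot <- gen_proteome(10, n_proteins = 4, length_range = c(30, 50))
  scores <- gen_fitness_scores(prot, 101)
  pg <- popgen_preset("ecoli")
  fl <- fitness_landscape(prot, scores, tr$landscape, pg)
  expect_equal(sort(unique(fl$sites$protein_id)), sort(prot$protein_id))
  expect_true(all(fl$sites$theta >= 0))
  expect_true(all(fl$sites$class %in%
                    c("neutral", "deleterious", "advantageous")))
  # organismal burden equals the flat sum over all (protein, site) terms
  flat <- sum(vapply(seq_len(nrow(prot)), function(i) {
    s <- fl$sites[fl$sites$protein_id == prot$protein_id[i], ]
    prot$phi[i] * sum(s$cost)
  }, numeric(1)))
  expect_equal(sum(fl$proteins$burden), flat, tolerance = 1e-12)
})

test_that("synonymous cost comparisons group, test and annotate codons", {
  set.seed(77)
  # identical distributions: high p, equal medians
  same <- data.frame(codon = rep(c("UUU", "UUC"), each = 200),
                     cost = rep(stats::rnorm(200, -0.5, 0.2), 2))
  out <- synonymous_cost_comparison(same)
  expect_gt(out$tests$p_value, 0.9)
  meds <- out$groups$median_cost
  expect_equal(meds[1], meds[2])

  # a 1-sd shift at n = 500 per group is detected at alpha = 0.01
  shifted <- data.frame(
    codon = rep(c("GAU", "GAC"), each = 500),
    cost = c(stats::rnorm(500, -1, 0.5), stats::rnorm(500, -1.5, 0.5))
  )
  out2 <- synonymous_cost_comparison(shifted)
  expect_lt(out2$tests$p_value, 0.01)
  expect_lt(out2$tests$p_adjusted, 0.01)

  # single-codon amino acids are excluded; RSCU annotation works
  with_met <- rbind(shifted,
                    data.frame(codon = "AUG", cost = stats::rnorm(50)))
  vals <- rscu(paste(c(rep("GAU", 3), "GAC"), collapse = ""))
  out3 <- synonymous_cost_comparison(with_met, rscu_values = vals)
  expect_false("AUG" %in% out3$groups$codon)
  expect_true(out3$groups$preferred[out3$groups$codon == "GAU"])
  expect_false(out3$groups$preferred[out3$groups$codon == "GAC"])
})
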