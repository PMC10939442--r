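test_that("the multinomial likelihood matches direct factorial arithmetic", {
  tr <- tiny_truth(2)
  g <- tr$geometry
  # empty observation set: exactly 0 (coefficient included)
  empty <- codon_observations(character(0), numeric(0), character(0),
                              numeric(0))
  expect_identical(log_likelihood(tr$model, empty, tr$pool, g), 0)

  # small counts against the factorial oracle and stats::dmultinom
  land <- tr$landscape
  set.seed(21)
  for (cod in sample(SENSE_CODONS, 4)) {
    own <- mtel:::.merge_il(translate_codons(cod))
    cats <- colnames(land$P_obs)
    probs <- land$P_obs[cod, ]
    dests <- names(sort(probs[cats != own], decreasing = TRUE))[1:2]
    counts <- c(2, 1)
    total <- 15
    obs <- codon_observations(rep(cod, 2), rep(total, 2),
                              mtel:::.aa_category_label(dests), counts)
    got <- log_likelihood(tr$model, obs, tr$pool, g)
    full_counts <- stats::setNames(numeric(length(cats)), cats)
    full_counts[dests] <- counts
    full_counts[own] <- total - sum(counts)
    expect_equal(got, oracle_multinom_logpmf(full_counts, probs),
                 tolerance = 1e-8)
    expect_equal(got, stats::dmultinom(full_counts, prob = probs,
                                       log = TRUE), tolerance = 1e-8)
  }
})

test_that("the likelihood is gauge invariant, so the anchor is needed", {
  tr <- tiny_truth(3)
  obs <- simulate_observations(tr$pool, tr$model, tr$geometry, 500,
                               seed = 31)
  base <- log_likelihood(tr$model, obs, tr$pool, tr$geometry)
  shifted <- affinity_model(tr$model$a + 2.5, s1 = tr$model$s[["s1"]],
                            s2 = tr$model$s[["s2"]])
  expect_equal(log_likelihood(shifted, obs, tr$pool, tr$geometry), base,
               tolerance = 1e-9)
})

test_that("masked categories are renormalized at likelihood time only", {
  tr <- tiny_truth(4)
  land <- tr$landscape
  cod <- "AAA"
  own <- mtel:::.merge_il("K")
  cats <- colnames(land$P_obs)
  probs <- land$P_obs[cod, ]
  dests <- names(sort(probs[cats != own], decreasing = TRUE))[1:3]
  obs <- codon_observations(rep(cod, 2), rep(30, 2),
                            mtel:::.aa_category_label(dests[1:2]), c(3, 2))
  mask <- data.frame(codon = cod, dest_aa = dests[3])
  got <- log_likelihood(tr$model, obs, tr$pool, tr$geometry, mask = mask)
  # manual renormalization over the unmasked categories
  p <- probs
  p[dests[3]] <- 0
  p <- p / sum(p)
  counts <- stats::setNames(numeric(length(cats)), cats)
  counts[dests[1:2]] <- c(3, 2)
  counts[own] <- 30 - 5
  expect_equal(got, stats::dmultinom(counts, prob = p, log = TRUE),
               tolerance = 1e-8)
  # masking a category with observed counts is an error
  bad_mask <- data.frame(codon = cod, dest_aa = dests[1])
  expect_error(log_likelihood(tr$model, obs, tr$pool, tr$geometry,
                              mask = bad_mask), "masked")
  # the forward landscape itself is untouched by masking
  expect_equal(build_landscape(tr$pool, tr$model, tr$geometry)$P_obs,
               land$P_obs)
})

test_that("unproducible observed destinations are rejected or dropped", {
  g <- geometry_preset("ecoli")
  pool <- trna_pool(c("k", "r"), c("UUU", "UCU"), c("K", "R"), c(100, 100))
  m <- gen_true_model(1)
  obs <- codon_observations("AAA", 50, "W", 2) # no Trp tRNA in pool
  expect_error(log_likelihood(m, obs, pool, g), "not producible")
  expect_warning(ll <- log_likelihood(m, obs, pool, g,
                                      on_impossible = "drop"),
                 "dropping")
  expect_true(is.finite(ll))
})

test_that("sampler runs are seed-deterministic with the configured retention", {
  tr <- tiny_truth(5)
  obs <- simulate_observations(tr$pool, tr$model, tr$geometry, 300,
                               seed = 51)
  ctrl <- mtel_control(steps = 60, burnin = 20, thin = 4)
  f1 <- mtel_fit(obs, tr$pool, tr$geometry, lysidine = TRUE,
                 control = ctrl, seed = 7)
  f2 <- mtel_fit(obs, tr$pool, tr$geometry, lysidine = TRUE,
                 control = ctrl, seed = 7)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$logpost, f2$logpost)
  expect_equal(nrow(f1$samples), (60 - 20) %/% 4)
  # anchor is excluded from the free parameters; s-weights present
  expect_false("aA.U" %in% colnames(f1$samples))
  expect_true(all(c("s1", "s2") %in% colnames(f1$samples)))
  # 20 affinity entries minus the four Watson-Crick row anchors, plus s1, s2
  expect_equal(ncol(f1$samples), 18L)

  f3 <- mtel_fit(obs, tr$pool, tr$geometry, lysidine = TRUE,
                 control = ctrl, seed = 8)
  expect_false(identical(f1$samples, f3$samples))
})

test_that("the retention cap keeps the last thinned samples", {
  tr <- tiny_truth(5)
  obs <- simulate_observations(tr$pool, tr$model, tr$geometry, 200,
                               seed = 52)
  ctrl <- mtel_control(steps = 80, burnin = 20, thin = 2, max_samples = 10)
  fit <- mtel_fit(obs, tr$pool, tr$geometry, control = ctrl, seed = 9)
  expect_equal(nrow(fit$samples), 10L)
})

test_that("posterior summaries behave on the retained samples", {
  tr <- tiny_truth(6)
  obs <- simulate_observations(tr$pool, tr$model, tr$geometry, 500,
                               seed = 61)
  fit <- mtel_fit(obs, tr$pool, tr$geometry,
                  control = mtel_control(steps = 120, burnin = 40,
                                         thin = 2), seed = 3)
  s95 <- posterior_summary(fit, 0.95)
  s50 <- posterior_summary(fit, 0.50)
  expect_equal(nrow(s95), ncol(fit$samples))
  expect_true(all(s95$sd >= 0))
  # interval endpoints are monotone in the credible level
  expect_true(all(s95$lower <= s50$lower + 1e-12))
  expect_true(all(s95$upper >= s50$upper - 1e-12))
  expect_true(all(s95$lower <= s95$mean & s95$mean <= s95$upper))

  # S3 surface
  expect_output(print(fit), "retained samples")
  expect_s3_class(summary(fit), "summary.mtel_fit")
  expect_length(coef(fit), ncol(fit$samples))
  m <- as_affinity_model(fit)
  expect_s3_class(m, "affinity_model")
  expect_identical(m$a["A", "U"], 0)
  land <- predict(fit, "landscape")
  expect_s3_class(land, "error_landscape")
  res <- residuals(fit)
  expect_true(all(c("observed", "expected", "pearson") %in% names(res)))
  sims <- simulate(fit, nsim = 2, seed = 1, depth_per_codon = 50)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "codon_obs")
})

test_that("chain and model serialization round-trip", {
  tr <- tiny_truth(7)
  obs <- simulate_observations(tr$pool, tr$model, tr$geometry, 200,
                               seed = 71)
  fit <- mtel_fit(obs, tr$pool, tr$geometry,
                  control = mtel_control(steps = 30, burnin = 10, thin = 2),
                  seed = 2)
  tmp <- tempfile(fileext = ".jsonl")
  write_chain(fit, tmp)
  lines <- readLines(tmp)
  expect_equal(length(lines), nrow(fit$samples) + 1L)

  tmpm <- tempfile(fileext = ".json")
  write_affinity_model(as_affinity_model(fit), tmpm)
  back <- read_affinity_model(tmpm)
  expect_equal(back$a, as_affinity_model(fit)$a, tolerance = 1e-12)
  expect_equal(back$s, as_affinity_model(fit)$s, tolerance = 1e-12)
})

test_that("Watson-Crick-favoring truth is recovered as such by a short chain", {
  tr <- tiny_truth(8)
  obs <- simulate_observations(tr$pool, tr$model, tr$geometry, 5000,
                               seed = 81)
  fit <- mtel_fit(obs, tr$pool, tr$geometry,
                  control = mtel_control(steps = 400, burnin = 200,
                                         thin = 2), seed = 4)
  # Watson-Crick entries are the gauge anchors (0); recovered mismatch
  # affinities should be positive penalties in nearly all posterior samples
  mm_cols <- setdiff(grep("^a", colnames(fit$samples), value = TRUE),
                     c("aA.L", "aC.L", "aG.L", "aU.L"))
  expect_false(any(c("aA.U", "aC.G", "aG.C", "aU.A") %in%
                     colnames(fit$samples)))
  mm_mean <- rowMeans(fit$samples[, mm_cols, drop = FALSE])
  expect_gt(mean(mm_mean > 0), 0.95)
})
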