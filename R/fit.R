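# Posterior inference for the affinity model: Metropolis-within-Gibbs under
# flat priors, one Gaussian random-walk update per scalar parameter per
# sweep, with proposal scales adapted during burn-in only.

#' MCMC configuration
#'
#' Defaults follow the model-fitting protocol: 10,000 total sweeps of which
#' the first 5,000 are burn-in, every 10th post-burn-in sweep thinned, and
#' the last 500 thinned samples retained as the posterior.
#'
#' @param steps Total sweeps, burn-in included.
#' @param burnin Burn-in sweeps (discarded; proposal adaptation happens
#'   here only).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param max_samples Cap: keep only the last `max_samples` thinned draws.
#' @param prior_affinity Half-width of the flat prior box on nucleotide
#'   affinities (`[-prior_affinity, prior_affinity]`).
#' @param prior_s Upper bound of the flat prior on the site weights
#'   (`[0, prior_s]`).
#' @param adapt_interval Sweeps between proposal-scale updates during
#'   burn-in.
#' @param target_accept Per-parameter acceptance rate targeted by the
#'   adaptation.
#' @return A list of class `mtel_control`.
#' @export
mtel_control <- function(steps = 10000L, burnin = 5000L, thin = 10L,
                         max_samples = 500L, prior_affinity = 50,
                         prior_s = 50, adapt_interval = 50L,
                         target_accept = 0.35) {
  stopifnot(steps > 0, burnin >= 0, burnin < steps, thin > 0,
            max_samples > 0, prior_affinity > 0, prior_s > 0)
  structure(list(steps = as.integer(steps), burnin = as.integer(burnin),
                 thin = as.integer(thin),
                 max_samples = as.integer(max_samples),
                 prior_affinity = prior_affinity, prior_s = prior_s,
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept),
            class = "mtel_control")
}

# Free-parameter bookkeeping. Because binding probabilities are a softmax
# per codon, adding a constant to a whole codon-nucleotide row of the
# affinity matrix is unobservable: there are four independent gauge
# directions. The Watson-Crick entry of every row is therefore anchored at
# 0, so each mismatch entry is the binding penalty relative to the row's
# Watson-Crick pair; remaining entries plus s1, s2 are free.
.param_layout <- function(lysidine) {
  anti <- if (lysidine) .ANTI_NT else .CODON_NT
  na <- 4L * length(anti)
  anchor <- .pair_index(.CODON_NT, .WC_PARTNER[.CODON_NT], lysidine)
  free_a <- setdiff(seq_len(na), anchor)
  grid <- expand.grid(codon = .CODON_NT, anti = anti,
                      stringsAsFactors = FALSE)
  names_a <- paste0("a", grid$codon, ".", grid$anti)
  list(anchor = anchor, free_a = free_a, na = na,
       names = c(names_a[free_a], "s1", "s2"),
       n_free = length(free_a) + 2L)
}

.theta_split <- function(theta, layout) {
  avec <- numeric(layout$na)
  avec[layout$free_a] <- theta[seq_along(layout$free_a)]
  list(avec = avec,
       s1 = theta[[layout$n_free - 1L]],
       s2 = theta[[layout$n_free]])
}

.theta_to_model <- function(theta, layout, lysidine) {
  sp <- .theta_split(theta, layout)
  anti <- if (lysidine) .ANTI_NT else .CODON_NT
  a <- matrix(sp$avec, 4L, length(anti), dimnames = list(.CODON_NT, anti))
  affinity_model(a, s1 = sp$s1, s2 = sp$s2, lysidine = lysidine)
}

#' Fit the translation-error model to misincorporation counts
#'
#' Maximizes nothing: samples the posterior of the nucleotide affinities
#' (gauge-anchored: the Watson-Crick entry of every codon-nucleotide row is
#' held at 0, since per-codon softmax normalization makes row-wise shifts
#' unobservable) and the two site importance weights
#' under a multinomial likelihood and flat priors on a wide box, using
#' Metropolis-within-Gibbs (one Gaussian random-walk update per scalar per
#' sweep). Proposal scales are tuned during burn-in only, so the retained
#' chain is a fixed-kernel Markov chain.
#'
#' @param observations A [codon_observations()] object; multiple datasets
#'   should be pooled (see [pool_observations()]) beforehand.
#' @param pool A `trna_pool`.
#' @param geometry A [cell_geometry()]; default the E. coli preset.
#' @param lysidine Whether the anticodon alphabet includes lysidine;
#'   default: inferred from the pool.
#' @param control An [mtel_control()].
#' @param seed Integer seed; two runs with the same inputs and seed are
#'   bit-identical.
#' @param mask,on_impossible Passed to the likelihood; see
#'   [log_likelihood()].
#' @param init Starting values: `"map"` (default) initializes at the
#'   posterior mode found by box-constrained quasi-Newton ascent of the
#'   log-likelihood, so the chain spends its sweeps exploring the posterior
#'   rather than transiting towards it; `"zero"` starts mismatch affinities
#'   at a moderate penalty (+4) and site weights at 1; or a named numeric
#'   vector of free-parameter values.
#' @return An object of class `mtel_fit` with the retained samples, the
#'   log-posterior trace, per-parameter acceptance rates and the inputs.
#' @export
mtel_fit <- function(observations, pool, geometry = geometry_preset("ecoli"),
                     lysidine = NULL, control = mtel_control(), seed = 1L,
                     mask = NULL, on_impossible = c("error", "drop"),
                     init = "map") {
  stopifnot(inherits(observations, "codon_obs"), nrow(observations) > 0L)
  if (is.null(lysidine)) {
    lysidine <- any(grepl("L", pool$anticodon, fixed = TRUE))
  }
  engine <- .landscape_engine(pool, geometry, lysidine,
                              codons = sort(unique(observations$codon)))
  env <- .loglik_env(observations, engine, mask, on_impossible)
  layout <- .param_layout(lysidine)
  np <- layout$n_free
  is_s <- seq_len(np) > np - 2L
  lower <- ifelse(is_s, 0, -control$prior_affinity)
  upper <- ifelse(is_s, control$prior_s, control$prior_affinity)

  ll <- function(theta) {
    sp <- .theta_split(theta, layout)
    .loglik_eval(env, engine, sp$avec, sp$s1, sp$s2)
  }
  ll_floored <- function(theta) {
    sp <- .theta_split(theta, layout)
    .loglik_eval(env, engine, sp$avec, sp$s1, sp$s2, floor_prob = 1e-12)
  }

  set.seed(as.integer(seed))
  theta <- ifelse(is_s, 1, 4)
  if (is.numeric(init)) {
    stopifnot(all(names(init) %in% layout$names))
    theta[match(names(init), layout$names)] <- init
  } else if (identical(init, "map")) {
    opt <- tryCatch(
      stats::optim(theta, function(th) -ll_floored(th), method = "L-BFGS-B",
                   lower = lower + 1e-9, upper = upper - 1e-9,
                   control = list(maxit = 1000, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      opt2 <- tryCatch(
        stats::optim(opt$par, function(th) -ll_floored(th),
                     method = "L-BFGS-B", lower = lower + 1e-9,
                     upper = upper - 1e-9,
                     control = list(maxit = 1000, factr = 1e4,
                                    ndeps = rep(1e-5, np))),
        error = function(e) opt)
      cand <- if (is.finite(opt2$value)) opt2$par else opt$par
      if (is.finite(ll(cand)) && ll(cand) > ll(theta)) theta <- cand
    }
  } else if (!identical(init, "zero")) {
    stop("init must be \"map\", \"zero\" or a named numeric vector")
  }
  cur <- ll(theta)
  tries <- 0L
  while (!is.finite(cur) && tries < 20L) {
    tries <- tries + 1L
    theta <- ifelse(is_s, stats::runif(np, 0.5, 2), stats::rnorm(np, 0, 0.5))
    cur <- ll(theta)
  }
  if (!is.finite(cur)) {
    stop("likelihood is non-finite at initialization after ", tries,
         " jittered restarts; check observations against the pool")
  }
  if (tries > 0L) {
    message("re-initialized ", tries, " time(s) to reach a finite likelihood")
  }

  scales <- ifelse(is_s, 0.25, 0.5)
  if (identical(init, "map")) {
    # curvature-informed proposal scales at the starting point: diagonal
    # of the negative observed information, floored and capped
    h <- 1e-4
    d2 <- vapply(seq_len(np), function(p) {
      tp <- tm <- theta
      tp[p] <- theta[p] + h
      tm[p] <- theta[p] - h
      (ll_floored(tp) - 2 * ll_floored(theta) + ll_floored(tm)) / h^2
    }, numeric(1L))
    sds <- 1 / sqrt(pmax(-d2, 1e-4))
    scales <- pmin(pmax(2.4 * sds, 1e-3), 10)
  }
  acc_win <- prop_win <- numeric(np)
  acc_post <- prop_post <- 0
  n_thin <- (control$steps - control$burnin) %/% control$thin
  keep_n <- min(n_thin, control$max_samples)
  samples <- matrix(NA_real_, n_thin, np,
                    dimnames = list(NULL, layout$names))
  logpost <- numeric(control$steps)
  k <- 0L
  for (sweep in seq_len(control$steps)) {
    in_burnin <- sweep <= control$burnin
    for (p in seq_len(np)) {
      prop <- theta
      prop[p] <- theta[p] + stats::rnorm(1L, 0, scales[p])
      prop_win[p] <- prop_win[p] + 1
      if (!in_burnin) prop_post <- prop_post + 1
      if (prop[p] < lower[p] || prop[p] > upper[p]) next
      new <- ll(prop)
      if (is.finite(new) && log(stats::runif(1L)) < new - cur) {
        theta <- prop
        cur <- new
        acc_win[p] <- acc_win[p] + 1
        if (!in_burnin) acc_post <- acc_post + 1
      }
    }
    logpost[sweep] <- cur
    if (in_burnin && sweep %% control$adapt_interval == 0L) {
      rate <- acc_win / pmax(prop_win, 1)
      scales <- pmin(pmax(scales * exp(rate - control$target_accept), 1e-3), 10)
      acc_win[] <- prop_win[] <- 0
    }
    if (!in_burnin && (sweep - control$burnin) %% control$thin == 0L) {
      k <- k + 1L
      samples[k, ] <- theta
    }
  }
  samples <- samples[seq_len(k), , drop = FALSE]
  if (nrow(samples) > keep_n) {
    samples <- samples[(nrow(samples) - keep_n + 1L):nrow(samples), ,
                       drop = FALSE]
  }
  accept_rate <- if (prop_post > 0) acc_post / prop_post else NA_real_
  if (is.finite(accept_rate) && (accept_rate < 0.1 || accept_rate > 0.6)) {
    warning(sprintf(
      "post-burn-in acceptance rate %.2f outside the usual [0.1, 0.6] band",
      accept_rate))
  }
  structure(
    list(samples = samples, logpost = logpost, seed = as.integer(seed),
         control = control, layout = layout, lysidine = lysidine,
         pool = pool, geometry = geometry, observations = observations,
         mask = mask, accept_rate = accept_rate, scales = scales),
    class = "mtel_fit"
  )
}

#' Posterior summaries of a fitted model
#'
#' Mean, standard deviation and central credible interval per free
#' parameter, computed on the retained samples only.
#'
#' @param fit An `mtel_fit`.
#' @param level Credible level (default 0.95).
#' @return Data.frame with one row per parameter.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mtel_fit"), nrow(fit$samples) > 0L)
  stopifnot(level > 0, level < 1)
  alpha <- (1 - level) / 2
  qs <- apply(fit$samples, 2L, stats::quantile, probs = c(alpha, 1 - alpha))
  data.frame(
    parameter = colnames(fit$samples),
    mean = colMeans(fit$samples),
    sd = apply(fit$samples, 2L, stats::sd),
    lower = qs[1L, ],
    upper = qs[2L, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Posterior-mean affinity model of a fit
#'
#' @param fit An `mtel_fit`.
#' @return An [affinity_model()] built from the posterior means (the
#'   Watson-Crick gauge anchors stay at 0).
#' @export
as_affinity_model <- function(fit) {
  stopifnot(inherits(fit, "mtel_fit"))
  .theta_to_model(colMeans(fit$samples), fit$layout, fit$lysidine)
}

#' @export
coef.mtel_fit <- function(object, ...) colMeans(object$samples)

#' @export
logLik.mtel_fit <- function(object, ...) {
  m <- as_affinity_model(object)
  val <- log_likelihood(m, object$observations, object$pool,
                        object$geometry, mask = object$mask)
  structure(val, df = object$layout$n_free, class = "logLik")
}

#' @export
print.mtel_fit <- function(x, ...) {
  cat("translation-error model fit (Metropolis-within-Gibbs)\n")
  cat(sprintf(
    "  %d retained samples (steps %d, burn-in %d, thin %d), seed %d\n",
    nrow(x$samples), x$control$steps, x$control$burnin, x$control$thin,
    x$seed))
  cat(sprintf("  %d free parameters%s, acceptance rate %.2f\n",
              x$layout$n_free,
              if (x$lysidine) " (lysidine alphabet)" else "",
              x$accept_rate))
  cat("  site weights (posterior mean): s1 =",
      format(mean(x$samples[, "s1"]), digits = 3),
      ", s2 =", format(mean(x$samples[, "s2"]), digits = 3), "\n")
  invisible(x)
}

#' @export
summary.mtel_fit <- function(object, level = 0.95, ...) {
  out <- list(table = posterior_summary(object, level),
              accept_rate = object$accept_rate,
              n_samples = nrow(object$samples),
              logLik = as.numeric(logLik(object)))
  class(out) <- "summary.mtel_fit"
  out
}

#' @export
print.summary.mtel_fit <- function(x, ...) {
  cat("posterior summary (", x$n_samples, " retained samples, acceptance ",
      sprintf("%.2f", x$accept_rate), ", logLik at posterior mean ",
      sprintf("%.2f", x$logLik), ")\n", sep = "")
  print(x$table, digits = 3)
  invisible(x)
}

#' Predict from a fitted translation-error model
#'
#' @param object An `mtel_fit`.
#' @param type `"landscape"` for the full [build_landscape()] under the
#'   posterior-mean model, `"error_probability"` for the per-codon
#'   non-synonymous incorporation probabilities, or `"error_free"` for
#'   per-protein error-free translation probabilities (requires `newdata`).
#' @param newdata For `"error_free"`: a list of codon-sequence character
#'   vectors (one per protein).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.mtel_fit <- function(object, type = c("landscape",
                                              "error_probability",
                                              "error_free"),
                             newdata = NULL, ...) {
  type <- match.arg(type)
  land <- build_landscape(object$pool, as_affinity_model(object),
                          object$geometry)
  switch(type,
         landscape = land,
         error_probability = land$p_error,
         error_free = {
           if (is.null(newdata)) stop("newdata (codon sequences) required")
           vapply(newdata, protein_error_free_probability,
                  numeric(1L), landscape = land)
         })
}

#' @export
simulate.mtel_fit <- function(object, nsim = 1, seed = NULL,
                              depth_per_codon = 1000L, ...) {
  if (!is.null(seed)) set.seed(seed)
  model <- as_affinity_model(object)
  replicate(nsim, simplify = FALSE,
            simulate_observations(object$pool, model, object$geometry,
                                  depth_per_codon = depth_per_codon))
}

#' @export
plot.mtel_fit <- function(x, which = c("trace", "affinity"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    plot(x$logpost, type = "l", xlab = "sweep", ylab = "log posterior",
         main = "MCMC trace", ...)
    graphics::abline(v = x$control$burnin, lty = 2)
  } else {
    m <- as_affinity_model(x)
    graphics::image(
      seq_len(ncol(m$a)), 1:4, t(m$a)[, 4:1, drop = FALSE],
      axes = FALSE, xlab = "anticodon nucleotide",
      ylab = "codon nucleotide",
      main = "posterior-mean nucleotide affinities", ...)
    graphics::axis(1, at = seq_len(ncol(m$a)), labels = colnames(m$a))
    graphics::axis(2, at = 1:4, labels = rev(rownames(m$a)))
    graphics::box()
  }
  invisible(x)
}

#' Residuals of a fitted translation-error model
#'
#' Pearson residuals of the observed per-codon error counts against the
#' multinomial expectation under the posterior-mean model.
#'
#' @param object An `mtel_fit`.
#' @param ... Unused.
#' @return Data.frame with observed, expected and Pearson residual per
#'   (codon, destination) cell that was observed.
#' @export
residuals.mtel_fit <- function(object, ...) {
  obs <- object$observations
  land <- predict(object, "landscape")
  di <- match(.merge_il(obs$dest_aa), colnames(land$P_obs))
  p <- land$P_obs[cbind(match(obs$codon, rownames(land$P_obs)), di)]
  expected <- obs$total_count * p
  data.frame(
    codon = obs$codon,
    dest_aa = .aa_category_label(obs$dest_aa),
    observed = obs$error_count,
    expected = expected,
    pearson = (obs$error_count - expected) /
      sqrt(pmax(obs$total_count * p * (1 - p), .Machine$double.eps)),
    stringsAsFactors = FALSE
  )
}

#' Store a posterior chain as JSON lines
#'
#' One JSON object per retained sample, plus a header line with the seed
#' and configuration.
#'
#' @param fit An `mtel_fit`.
#' @param path Output path.
#' @export
write_chain <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(seed = fit$seed, steps = fit$control$steps,
                 burnin = fit$control$burnin, thin = fit$control$thin,
                 lysidine = fit$lysidine, parameters = colnames(fit$samples))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (i in seq_len(nrow(fit$samples))) {
    writeLines(jsonlite::toJSON(as.list(fit$samples[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
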