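# Diffusion-limited tRNA arrival rates and exponential-race competition
# probabilities.

#' Cell geometry for diffusion-limited tRNA arrival
#'
#' The cell is discretized into `n = V / l^3` sites of tRNA size; a tRNA
#' occupies any given site with probability `abundance / n` and hops between
#' sites with transition time `tau = l^2 / (6 D)`. The arrival rate of a
#' species at the ribosome is then `lambda = occupancy / tau`.
#'
#' @param volume Cell volume in m^3.
#' @param trna_length Effective tRNA length in m.
#' @param diffusion_coeff tRNA diffusion coefficient in m^2/s.
#' @return An object of class `cell_geometry` with derived fields `n_sites`
#'   and `tau` (seconds).
#' @seealso [geometry_preset()] for the E. coli and S. cerevisiae constants.
#' @export
cell_geometry <- function(volume, trna_length, diffusion_coeff) {
  vals <- c(volume = volume, trna_length = trna_length,
            diffusion_coeff = diffusion_coeff)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry parameters must be strictly positive and finite")
  }
  n_sites <- volume / trna_length^3
  if (n_sites < 1) stop("volume must admit at least one tRNA-sized site")
  structure(
    list(volume = volume, trna_length = trna_length,
         diffusion_coeff = diffusion_coeff,
         n_sites = n_sites,
         tau = trna_length^2 / (6 * diffusion_coeff)),
    class = "cell_geometry"
  )
}

#' Species presets for cell geometry
#'
#' Literature constants: cell volume 0.6e-18 m^3 (E. coli) or 4.2e-17 m^3
#' (S. cerevisiae), effective tRNA length 1.58e-8 m, and tRNA diffusion
#' coefficient 8.42e-11 m^2/s (shared between species).
#'
#' @param species `"ecoli"` or `"scerevisiae"`.
#' @return A `cell_geometry`.
#' @export
geometry_preset <- function(species = c("ecoli", "scerevisiae")) {
  species <- match.arg(species)
  volume <- switch(species, ecoli = 0.6e-18, scerevisiae = 4.2e-17)
  cell_geometry(volume = volume, trna_length = 1.58e-8,
                diffusion_coeff = 8.42e-11)
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "cell geometry: V = %.3g m^3, l = %.3g m, D = %.3g m^2/s\n  n = %.4g sites, tau = %.4g s\n",
    x$volume, x$trna_length, x$diffusion_coeff, x$n_sites, x$tau
  ))
  invisible(x)
}

#' Diffusion-limited arrival rate of a tRNA species
#'
#' `lambda = (abundance / n) / tau`: the per-second rate at which molecules
#' of the species arrive at the ribosome, proportional to abundance.
#'
#' @param abundance Molecules per cell (vectorized); zero gives rate zero.
#' @param geometry A [cell_geometry()].
#' @return Arrival rate(s) in 1/s.
#' @export
arrival_rate <- function(abundance, geometry) {
  if (!inherits(geometry, "cell_geometry")) {
    stop("geometry must be a cell_geometry object")
  }
  if (any(abundance < 0)) stop("abundance must be non-negative")
  (abundance / geometry$n_sites) / geometry$tau
}

# Arrival rates for a whole pool, named by species id.
.pool_rates <- function(pool, geometry) {
  stats::setNames(arrival_rate(pool$abundance, geometry), pool$id)
}

#' Probability that one tRNA arrives before another
#'
#' With exponentially distributed arrival times, the probability that the
#' focal species arrives before its competitor(s) is
#' `lambda_i / (lambda_i + lambda_j)`, where `lambda_j` may be the summed
#' rate of any set of competitors.
#'
#' @param lambda_i Arrival rate of the focal species.
#' @param lambda_j Arrival rate of the competitor, or a vector of competitor
#'   rates (summed).
#' @return Probability in `[0, 1]`.
#' @export
p_arrive_before <- function(lambda_i, lambda_j) {
  if (any(c(lambda_i, lambda_j) < 0)) stop("rates must be non-negative")
  lj <- sum(lambda_j)
  if (lambda_i + lj == 0) {
    stop("both rates are zero: the race is undefined")
  }
  lambda_i / (lambda_i + lj)
}

#' Probability that each tRNA in a pool arrives first
#'
#' @param pool A `trna_pool`.
#' @param geometry A [cell_geometry()].
#' @return Named probability vector over species, summing to 1.
#' @export
p_first <- function(pool, geometry) {
  if (nrow(pool) == 0L) stop("empty tRNA pool")
  lam <- .pool_rates(pool, geometry)
  if (sum(lam) <= 0) stop("pool has no positive arrival rate")
  lam / sum(lam)
}

#' Expected competitor arrivals per focal arrival
#'
#' The expected number of arrival events of a competitor (rate `lambda_k`)
#' before one arrival of the focal species (rate `lambda_i`) is
#' `lambda_k / lambda_i`; used as a continuous exponent in the repeated
#' binding-attempt term of the incorporation probability.
#'
#' @param lambda_k Competitor arrival rate (vectorized).
#' @param lambda_i Focal arrival rate, strictly positive.
#' @return Expected arrival count(s), `lambda_k / lambda_i`.
#' @export
expected_arrivals_before <- function(lambda_k, lambda_i) {
  if (any(lambda_i <= 0)) stop("focal arrival rate must be positive")
  lambda_k / lambda_i
}
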