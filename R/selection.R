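# Spatial selection profile, sequence fitness, and the Wright-Fisher
# fixation probability that couples them to substitution rates.

#' Gaussian spatial selection profile of a UCE
#'
#' The sensitivity to stabilizing selection at site position `x` is
#' `f(x) = nes_max * exp(-(x - center)^2 / (2 width^2))`, where `nes_max` is
#' the composite `Ne * s_max` at the peak, `center` is the (continuous,
#' 1-based) position of the most conserved point, and `width` is the Gaussian
#' standard deviation in site units.
#'
#' @param nes_max Nonnegative peak sensitivity (composite `Ne * s_max`).
#' @param center Real-valued site position of the peak (1-based coordinates).
#' @param width Positive Gaussian width, in sites.
#' @return An object of class `selon_profile`.
#' @export
selection_profile <- function(nes_max, center, width) {
  if (!is.finite(nes_max) || nes_max < 0) stop("nes_max must be >= 0")
  if (!is.finite(width) || width <= 0) stop("width must be > 0")
  if (!is.finite(center)) stop("center must be finite")
  structure(list(nes_max = nes_max, center = center, width = width),
            class = "selon_profile")
}

#' @export
print.selon_profile <- function(x, ...) {
  cat(sprintf("Selection profile: Nes_max = %.4g, center = %.2f, width = %.2f\n",
              x$nes_max, x$center, x$width))
  invisible(x)
}

#' Site-specific sensitivity to selection
#'
#' Evaluates the Gaussian profile `f(x)` at one or more site coordinates.
#'
#' @param profile A [selection_profile()].
#' @param position Numeric vector of site coordinates.
#' @return Nonnegative sensitivities, maximal (`nes_max`) at `x = center`.
#' @export
selection_sensitivity <- function(profile, position) {
  stopifnot(inherits(profile, "selon_profile"))
  profile$nes_max * exp(-(position - profile$center)^2 / (2 * profile$width^2))
}

#' Effective population configuration
#'
#' The effective population size `ne` is a fixed configuration constant, not
#' an estimated parameter: the profile's `nes_max` already estimates the
#' composite `Ne * s_max`, and holding `ne` fixed avoids a near-ridge in the
#' likelihood.  `ploidy` is 1 for a diploid population and 2 for a haploid
#' one, following the convention of the fixation-probability exponent.
#'
#' @param ne Effective population size (> 1). Default `1e6`.
#' @param ploidy 1 (diploid) or 2 (haploid). Default 1.
#' @return An object of class `selon_pop`.
#' @export
population_config <- function(ne = 1e6, ploidy = 1L) {
  if (!is.finite(ne) || ne <= 1) stop("ne must be > 1")
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 (diploid) or 2 (haploid)")
  structure(list(ne = ne, ploidy = as.integer(ploidy)), class = "selon_pop")
}

#' Fitness of an observed sequence given the optimal sequence
#'
#' `W = exp(-sum_k d(n_k, n*_k) f(k))` where the distance `d` is binary (0 on
#' a match, 1 otherwise) and `f(k)` is the profile sensitivity at site `k`.
#' Fitness contributions are independent across positions, so `W` factorizes
#' over mismatched sites.
#'
#' @param observed Character or index vector of observed bases.
#' @param optimal Character or index vector of optimal bases, same length.
#' @param profile A [selection_profile()].
#' @return Fitness in (0, 1].
#' @export
sequence_fitness <- function(observed, optimal, profile) {
  obs <- .base_index(observed)
  opt <- .base_index(optimal)
  if (length(obs) != length(opt))
    stop("observed and optimal sequences differ in length")
  f <- selection_sensitivity(profile, seq_along(obs))
  exp(-sum(f[obs != opt]))
}

#' Wright-Fisher fixation probability of a new mutant
#'
#' For a mutant with resident/mutant fitness ratio \code{r = W_res / W_mut}
#' introduced into a population of effective size `Ne`, the fixation
#' probability is `u = (1 - r^b) / (1 - r^(2 Ne))`, with `b` the ploidy
#' exponent (1 diploid, 2 haploid).  At \code{r = 1} the continuous (neutral)
#' limit `b / (2 Ne)` is returned.  Evaluation is done in log space so the
#' strongly deleterious tail underflows cleanly to 0 rather than overflowing.
#'
#' @param fitness_ratio Positive ratio(s) `W_resident / W_mutant`.
#' @param pop A [population_config()].
#' @return Fixation probabilities in `[0, 1]`, vectorized over
#'   `fitness_ratio`.
#' @export
fixation_probability <- function(fitness_ratio, pop = population_config()) {
  stopifnot(inherits(pop, "selon_pop"))
  if (any(!is.finite(fitness_ratio)) || any(fitness_ratio <= 0))
    stop("fitness_ratio must be positive and finite")
  b <- pop$ploidy
  ne <- pop$ne
  a <- log(fitness_ratio)
  u <- numeric(length(a))
  neutral <- abs(a) < 1e-8
  u[neutral] <- b / (2 * ne)
  big <- !neutral & (2 * ne * a > 700)
  u[big] <- exp(b * a[big] - 2 * ne * a[big])
  rest <- !neutral & !big
  if (any(rest)) {
    den <- expm1(2 * ne * a[rest])
    u[rest] <- ifelse(is.infinite(den), 0, expm1(b * a[rest]) / den)
  }
  pmin(pmax(u, 0), 1)
}
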