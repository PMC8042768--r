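# Per-site substitution models: raw rate matrix, equilibrium frequencies,
# and the dataset-wide rate scaling.

#' Equilibrium frequencies of a rate matrix
#'
#' Solves `pi Q = 0` for the stationary distribution of a 4x4 rate matrix
#' (the left null vector, renormalized to sum 1).  Negative entries smaller
#' than 1e-12 in magnitude are clamped to zero before renormalization.
#'
#' @param q 4x4 rate matrix with zero row sums and nonnegative off-diagonals.
#' @return Length-4 frequency vector named A, C, G, T.
#' @export
equilibrium_frequencies <- function(q) {
  q <- .check_rate_matrix(q)
  st <- cpp_stationary(array(q, c(4, 4, 1)))
  if (!st$unique[1])
    stop("rate matrix has no unique stationary distribution (reducible or degenerate)")
  if (st$resid[1] > 1e-8)
    stop("stationary solve failed: residual ", format(st$resid[1]))
  pi <- st$pi[, 1]
  names(pi) <- NUC_STATES
  pi
}

.check_rate_matrix <- function(q) {
  q <- as.matrix(q)
  if (!all(dim(q) == c(4, 4))) stop("rate matrix must be 4x4")
  off <- q; diag(off) <- 0
  if (any(off < -1e-12)) stop("off-diagonal rates must be nonnegative")
  if (any(abs(rowSums(q)) > 1e-8 * max(1, max(abs(q)))))
    stop("rate matrix rows must sum to zero")
  q
}

#' Per-site SelON substitution model
#'
#' Builds the raw (unscaled) rate matrix of one site:
#' `q_ij = 2 b mu_ij Ne u_ij`, where `u_ij` is the fixation probability of
#' mutant `j` in a resident-`i` population.  The site's sensitivity
#' `f(position)` is the scaled selection differential `Ne s`, so the
#' per-copy fitness ratio entering `u_ij` is `exp(d_delta f / Ne)` and the
#' drift exponent `2 Ne` reconstitutes `2 f`: the effective population size
#' cancels from the substitution rates in the large-`Ne` limit, which is why
#' it is a fixed configuration constant rather than an estimated parameter.
#' The equilibrium frequencies are the left null vector of `q_raw`.
#'
#' @param position 1-based site index (may be fractional for evaluation).
#' @param optimal_base Optimal nucleotide at this site (`"A"`.."T"` or 1..4).
#' @param mut A [mutation_matrix()].
#' @param profile A [selection_profile()].
#' @param pop A [population_config()].
#' @return An object of class `selon_site` with elements `position`,
#'   `sensitivity`, `optimal_base`, `q_raw`, and `pi`.
#' @export
site_rate_matrix <- function(position, optimal_base, mut, profile,
                             pop = population_config()) {
  stopifnot(inherits(mut, "selon_mutation"), inherits(profile, "selon_profile"),
            inherits(pop, "selon_pop"))
  o <- .base_index(optimal_base)
  f <- selection_sensitivity(profile, position)
  Q <- cpp_build_selon_q(mut$M, f, as.integer(o - 1L), pop$ne, pop$ploidy)
  q_raw <- Q[, , 1]
  dimnames(q_raw) <- list(NUC_STATES, NUC_STATES)
  pi <- equilibrium_frequencies(q_raw)
  structure(list(position = position, sensitivity = f,
                 optimal_base = NUC_STATES[o], q_raw = q_raw, pi = pi),
            class = "selon_site")
}

#' Scale site models to one expected substitution per unit branch length
#'
#' Computes the scale factor `C` as the mean over the supplied sites of the
#' per-site equilibrium rate `-sum_i pi_i q_ii`, and divides every site's
#' `q_raw` by it.  Scaling by the dataset-wide mean (rather than per site)
#' preserves relative rate variation among sites while making one unit of
#' branch length equal one expected substitution per site at equilibrium.
#' Equilibrium frequencies are unchanged by scaling.
#'
#' @param sites A list of `selon_site` objects (typically all sites of the
#'   dataset being fit jointly).
#' @return A list with `scale` (the factor `C`) and `sites`, each site gaining
#'   a `q_scaled` element.
#' @export
scale_sites <- function(sites) {
  if (length(sites) == 0) stop("at least one site is required")
  stopifnot(all(vapply(sites, inherits, logical(1), "selon_site")))
  rates <- vapply(sites, function(s) -sum(s$pi * diag(s$q_raw)), numeric(1))
  C <- mean(rates)
  if (!is.finite(C) || C <= 0) stop("scale factor must be positive")
  sites <- lapply(sites, function(s) {
    s$q_scaled <- s$q_raw / C
    s
  })
  list(scale = C, sites = sites)
}

# ---------------------------------------------------------------------------
# Batched internal builder used by the engine: one UCE's site models with
# deduplication of identical (sensitivity, optimum) pairs (all sites of a
# neutral UCE, for instance, share a single rate matrix).
# Returns: Q (4x4xK raw matrices for K unique models), pi (4xK),
#          site_q (length-l map site -> unique model, 1-based), f, rate_k
#          (equilibrium substitution rate of each unique model).
.build_uce_models <- function(l, optima, mut, profile, pop,
                              decompose = TRUE) {
  f <- selection_sensitivity(profile, seq_len(l))
  # sensitivity below machine noise is exactly neutral: Q = M regardless of
  # the optimal base, so such sites share one model
  neutral <- f < 1e-14
  f[neutral] <- 0
  key <- complex(real = f, imaginary = ifelse(neutral, 0, optima))
  uidx <- which(!duplicated(key))
  site_q <- match(key, key[uidx])
  Q <- cpp_build_selon_q(mut$M, f[uidx], as.integer(optima[uidx] - 1L),
                         pop$ne, pop$ploidy)
  out <- list(Q = Q, site_q = site_q, f = f)
  if (decompose) {
    dp <- cpp_decompose_pi(Q)
    if (any(!dp$unique))
      stop("a site rate matrix has no unique stationary distribution")
    if (any(dp$resid > 1e-8))
      stop("stationary solve failed for a site model")
    out <- c(out, list(pi = dp$pi, rate_k = dp$rate, V = dp$V,
                       Vinv = dp$Vinv, lambda = dp$lambda, ok = dp$ok))
  }
  out
}

# Mean equilibrium substitution rate over all sites of a list of UCE models.
.mean_rate <- function(models) {
  tot <- 0; n <- 0
  for (m in models) {
    tot <- tot + sum(m$rate_k[m$site_q])
    n <- n + length(m$site_q)
  }
  tot / n
}
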