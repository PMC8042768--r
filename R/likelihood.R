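# Likelihood operations: transition probabilities, pruning log-likelihoods
# (reference R implementation; fitting uses the compiled batched path),
# Gamma rate categories by generalized Laguerre quadrature, the GTR+Gamma
# partition likelihood, and AICc.

#' Transition probability matrix over a branch
#'
#' `P(t) = exp(Q t)` for a rate matrix `Q` (zero row sums) and branch length
#' `t >= 0` in expected substitutions per site.
#'
#' @param q 4x4 rate matrix.
#' @param t Branch length, `>= 0`.
#' @return A 4x4 stochastic matrix (rows sum to 1).
#' @export
transition_probabilities <- function(q, t) {
  q <- .check_rate_matrix(q)
  if (!is.finite(t) || t < 0) stop("branch length must be >= 0")
  P <- cpp_expm(q, t)
  dimnames(P) <- list(NUC_STATES, NUC_STATES)
  P
}

#' Log-likelihood of one site pattern on a rooted tree
#'
#' Felsenstein pruning with root frequencies equal to the site's equilibrium
#' frequencies `pi` (the model assumes the process starts at equilibrium).
#' Missing tips contribute a partial likelihood of 1 for every state.  This
#' is the plain R reference implementation; dataset-scale fitting uses the
#' compiled engine, which is tested against this function.
#'
#' @param tree Rooted binary `phylo`.
#' @param pattern Named character (or index) vector of observed bases, one
#'   per taxon; `NA`, `"-"`, `"N"` etc. are missing.
#' @param site A `selon_site` with `q_scaled` (see [scale_sites()]), or any
#'   list with elements `q_scaled` (or `q_raw`) and `pi`.
#' @return The site log-likelihood.
#' @export
site_log_likelihood <- function(tree, pattern, site) {
  q <- if (!is.null(site$q_scaled)) site$q_scaled else site$q_raw
  pi <- site$pi
  if (is.character(pattern)) {
    st <- encode_bases(pattern)
    names(st) <- names(pattern)
  } else {
    st <- pattern
  }
  if (is.null(names(st))) stop("pattern must be named by taxon")
  # degenerate single-leaf case: no transitions, just the root frequency
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  n_tip <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, names(st))
  if (length(miss)) stop("pattern is missing taxa: ", paste(miss, collapse = ", "))
  st <- st[tree$tip.label]
  tree <- ape::reorder.phylo(tree, "postorder")
  n_nodes <- n_tip + tree$Nnode
  partial <- matrix(1, 4, n_nodes)
  for (i in seq_len(n_tip)) {
    if (!is.na(st[i])) {
      partial[, i] <- 0
      partial[st[i], i] <- 1
    }
  }
  logsc <- numeric(n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    P <- transition_probabilities(q, tree$edge.length[e])
    partial[, par] <- partial[, par] * as.numeric(P %*% partial[, ch])
    logsc[par] <- logsc[par] + logsc[ch]
    m <- max(partial[, par])
    if (m > 0 && m < 1e-120) {
      partial[, par] <- partial[, par] / m
      logsc[par] <- logsc[par] + log(m)
    }
  }
  root <- n_tip + 1L
  log(sum(pi * partial[, root])) + logsc[root]
}

#' Log-likelihood of a whole UCE
#'
#' Sites evolve independently, so the UCE log-likelihood is the sum of the
#' per-site log-likelihoods.
#'
#' @param tree Rooted binary `phylo`.
#' @param alignment Integer (1..4/`NA`) or character matrix, taxa x sites,
#'   rows named by taxon.
#' @param sites List of per-position site models (length = site count).
#' @return The UCE log-likelihood.
#' @export
uce_log_likelihood <- function(tree, alignment, sites) {
  alignment <- .coerce_alignment(alignment)
  if (length(sites) != ncol(alignment))
    stop("need one site model per alignment column")
  sum(vapply(seq_along(sites), function(k) {
    site_log_likelihood(tree, alignment[, k], sites[[k]])
  }, numeric(1)))
}

#' Discrete Gamma rate categories by generalized Laguerre quadrature
#'
#' Represents a unit-mean Gamma(shape `alpha`, rate `alpha`) rate
#' distribution by the abscissae and weights of generalized Gauss-Laguerre
#' quadrature (weight function `x^(alpha-1) e^(-x)`, rescaled to unit mean),
#' computed by the Golub-Welsch tridiagonal eigenvalue method.
#'
#' @param alpha Positive Gamma shape parameter.
#' @param ncat Number of categories, 4 or 8.
#' @return An object of class `gamma_rates`: `alpha`, `ncat`, `rates`,
#'   `weights` (weights sum to 1; mean rate 1).
#' @export
laguerre_gamma_rates <- function(alpha, ncat = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!ncat %in% c(4L, 8L)) stop("ncat must be 4 or 8")
  a <- alpha - 1          # generalized Laguerre exponent
  k <- 0:(ncat - 1)
  d <- 2 * k + a + 1
  e <- sqrt((1:(ncat - 1)) * ((1:(ncat - 1)) + a))
  J <- diag(d)
  for (i in seq_len(ncat - 1)) {
    J[i, i + 1] <- e[i]
    J[i + 1, i] <- e[i]
  }
  es <- eigen(J, symmetric = TRUE)
  ord <- order(es$values)
  x <- es$values[ord]
  w <- es$vectors[1, ord]^2      # relative weights; mu0 cancels on normalization
  w <- w / sum(w)
  structure(list(alpha = alpha, ncat = as.integer(ncat), rates = x / alpha,
                 weights = w),
            class = "gamma_rates")
}

#' GTR+Gamma log-likelihood of one UCE
#'
#' The site likelihood is the weighted average over rate categories of the
#' pruning likelihood with `Q` scaled by the category rate; the GTR matrix is
#' normalized to mean rate 1 at its stationary frequencies, which also serve
#' as root frequencies.
#'
#' @param tree Rooted binary `phylo`.
#' @param alignment Taxa x sites matrix (see [uce_log_likelihood()]).
#' @param exchangeabilities Length-5 positive vector (`AC, AG, AT, CG, CT`;
#'   `GT = 1`).
#' @param base_freqs Length-4 frequency vector summing to 1.
#' @param gamma A [laguerre_gamma_rates()] object (or `NULL` for a single
#'   unit-rate category, i.e. plain GTR).
#' @return The UCE log-likelihood, with per-site values in attribute
#'   `"sites"`.
#' @export
gtr_gamma_log_likelihood <- function(tree, alignment, exchangeabilities,
                                     base_freqs, gamma = NULL) {
  if (any(exchangeabilities <= 0)) stop("exchangeabilities must be positive")
  if (any(base_freqs < 0) || abs(sum(base_freqs) - 1) > 1e-8)
    stop("base frequencies must be nonnegative and sum to 1")
  alignment <- .coerce_alignment(alignment)
  ds <- uce_dataset(list(u = alignment))
  tree <- validate_tree(tree, taxa = rownames(alignment))
  if (is.null(gamma)) {
    gamma <- list(rates = 1, weights = 1, ncat = 1L)
  }
  td <- .tree_data(tree)
  Q <- .gtr_q(exchangeabilities, base_freqs)
  en <- list(
    decomp = cpp_decompose(array(Q, c(4, 4, 1))),
    tips = .tip_matrix(ds, td$tree),
    td = td,
    site_prof = integer(ncol(alignment)),
    prof_ptr = as.integer(c(0L, gamma$ncat)),
    comp_q = integer(gamma$ncat),
    comp_rate = gamma$rates,
    comp_w = gamma$weights,
    comp_pi = matrix(base_freqs, 4, gamma$ncat),
    uce_sites = ncol(alignment)
  )
  site_lnl <- .engine_site_lnl(en)
  structure(sum(site_lnl), sites = site_lnl)
}

#' Sample-size corrected AIC
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1)` with the sample size
#' `n = n_taxa * n_sites`.
#'
#' @param lnL Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n_taxa Number of taxa.
#' @param n_sites Total number of sites.
#' @return The AICc value.
#' @export
aicc <- function(lnL, k, n_taxa, n_sites) {
  n <- n_taxa * n_sites
  if (n <= k + 1) stop("AICc undefined: sample size n must exceed k + 1")
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
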