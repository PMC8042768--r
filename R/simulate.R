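# Sequence simulation under SelON and GTR+Gamma, and the two long/short
# branch scenario fixtures with per-UCE Gaussian selection profiles.

# internal: simulate one alignment given flattened site models.
# Qcube/pi: distinct models; site_q: 1-based map site -> model;
# rate: scalar multiplier applied to every branch (1/C for SelON).
.simulate_sites <- function(tree, Qcube, pi, site_q, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  td <- .tree_data(tree)
  S <- length(site_q)
  dec <- cpp_decompose(Qcube)
  # root states from each site's equilibrium frequencies
  u <- runif(S)
  cum <- apply(pi, 2, cumsum)
  root_state <- 1L + colSums(cum[, site_q, drop = FALSE] < rep(u, each = 4))
  root_state <- pmin(root_state, 4L)
  states <- matrix(0L, td$n_nodes, S)
  states[td$root, ] <- root_state
  # walk edges root-ward -> tip-ward (reverse postorder)
  for (e in rev(seq_len(nrow(td$edge)))) {
    par <- td$edge[e, 1]; ch <- td$edge[e, 2]
    t_eff <- td$lengths[e] * rate
    nq <- dim(Qcube)[3]
    P <- cpp_transition_cube(dec, 0:(nq - 1), rep(t_eff, nq))
    # per-site categorical draw from row states[par, s] of P[,, site_q[s]]
    u <- runif(S)
    pr <- matrix(0, 4, S)
    for (k in seq_len(nq)) {
      sel <- which(site_q == k)
      if (!length(sel)) next
      pk <- t(P[, , k])        # column i = transition probs from state i
      pr[, sel] <- pk[, states[par, sel], drop = FALSE]
    }
    cumP <- apply(pr, 2, cumsum)
    states[ch, ] <- pmin(1L + colSums(cumP < rep(u, each = 4)), 4L)
  }
  out <- states[seq_len(td$n_tip), , drop = FALSE]
  rownames(out) <- td$tree$tip.label
  out
}

#' Simulate a UCE alignment under per-site substitution models
#'
#' Root states are drawn from each site's equilibrium frequencies, then
#' evolved tip-ward along every branch by sampling from the site's exact
#' transition matrix `P(t)` (no event-level simulation is needed).
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param sites List of `selon_site` models with `q_scaled` (see
#'   [scale_sites()]).
#' @param seed Integer seed.
#' @return Integer alignment matrix (taxa x sites, values 1..4).
#' @export
simulate_uce <- function(tree, sites, seed = 1L) {
  stopifnot(all(vapply(sites, inherits, logical(1), "selon_site")))
  if (is.null(sites[[1]]$q_scaled))
    stop("sites must carry q_scaled; run scale_sites() first")
  S <- length(sites)
  Qcube <- array(0, c(4, 4, S))
  pi <- matrix(0, 4, S)
  for (k in seq_len(S)) {
    Qcube[, , k] <- sites[[k]]$q_scaled
    pi[, k] <- sites[[k]]$pi
  }
  .simulate_sites(tree, Qcube, pi, seq_len(S), rate = 1, seed = seed)
}

# internal: simulate one UCE directly from SelON parameters at scale C
.simulate_selon_uce <- function(tree, mut, profile, optima, pop, C,
                                seed = NULL) {
  l <- length(optima)
  m <- .build_uce_models(l, optima, mut, profile, pop)
  .simulate_sites(tree, m$Q, m$pi, m$site_q, rate = 1 / C, seed = seed)
}

#' Simulate an alignment under GTR+Gamma
#'
#' Root states come from the GTR stationary frequencies; each site's rate is
#' drawn from the discrete Gamma categories (or supplied directly, e.g. the
#' model-averaged per-site rates used in adequacy replication).
#'
#' @param tree Rooted binary `phylo`.
#' @param exchangeabilities Length-5 positive vector (`GT = 1`).
#' @param base_freqs Length-4 frequencies summing to 1.
#' @param gamma A [laguerre_gamma_rates()] object (ignored when `site_rates`
#'   is given).
#' @param n_sites Number of sites to simulate.
#' @param seed Integer seed.
#' @param site_rates Optional fixed per-site rate multipliers.
#' @return Integer alignment matrix (taxa x sites).
#' @export
simulate_gtr_gamma <- function(tree, exchangeabilities, base_freqs,
                               gamma = laguerre_gamma_rates(1, 4), n_sites,
                               seed = 1L, site_rates = NULL) {
  set.seed(seed)
  if (is.null(site_rates)) {
    site_rates <- sample(gamma$rates, n_sites, replace = TRUE,
                         prob = gamma$weights)
  } else {
    stopifnot(length(site_rates) == n_sites)
  }
  Q <- .gtr_q(exchangeabilities, base_freqs)
  # one distinct Q per unique rate: Q * r shares eigenvectors, but building
  # the small cube keeps the sampler uniform
  ur <- sort(unique(site_rates))
  Qcube <- array(0, c(4, 4, length(ur)))
  for (i in seq_along(ur)) Qcube[, , i] <- Q * ur[i]
  pi <- matrix(base_freqs, 4, length(ur))
  .simulate_sites(tree, Qcube, pi, match(site_rates, ur), rate = 1,
                  seed = NULL)
}

# ---------------------------------------------------------------------------
# Scenario fixtures: 9-taxon ingroup plus one outgroup, every branch either
# long (0.10) or short (0.025) expected substitutions/site.  The two
# scenarios differ in where the long branches sit.  The per-UCE generating
# profiles are drawn from documented distributions standing in for the
# unpublished empirical estimates: centers uniform in [0.3 l, 0.7 l], widths
# uniform in [l/10, l/4], nes_max log-uniform in [0.5, 8].

SCENARIO_TREES <- c(
  "(((((t1:0.10,t2:0.025):0.025,t3:0.10):0.025,(t4:0.025,t5:0.10):0.025):0.025,((t6:0.10,t7:0.025):0.10,(t8:0.025,t9:0.025):0.025):0.025):0.025,out:0.10);",
  "(((((t1:0.025,t2:0.025):0.10,(t3:0.10,t4:0.10):0.10):0.025,t5:0.025):0.025,((t6:0.025,t7:0.10):0.025,(t8:0.10,t9:0.10):0.025):0.10):0.025,out:0.10);"
)

#' Scenario tree with long and short branches
#'
#' @param scenario 1 or 2 (different placements of the 0.10 vs 0.025
#'   branches).
#' @return A rooted 10-taxon `phylo` (9 ingroup taxa plus `"out"`).
#' @export
scenario_tree <- function(scenario = 1L) {
  stopifnot(scenario %in% c(1L, 2L))
  read_tree(SCENARIO_TREES[scenario])
}

#' Generate a simulation scenario fixture
#'
#' Draws per-UCE lengths and Gaussian selection profiles (seeded), builds the
#' generating SelON model on the scenario tree, and simulates one dataset per
#' replicate.  The defaults emulate the study conditions: 22 UCEs whose
#' lengths sum to about 10,000 sites; `total_sites` scales the fixture down
#' for desk-size analyses.
#'
#' @param scenario 1 or 2.
#' @param n_uces Number of UCE loci.
#' @param total_sites Approximate total site count across loci.
#' @param replicates Number of simulated datasets sharing the same generating
#'   parameters.
#' @param seed Integer seed; replicate `r` uses `seed + r` for its data.
#' @return A list with `scenario`, `tree`, `outgroup`, `mut`, `pop`, `C`
#'   (generating scale factor), `profiles`, `optima`, `uce_lengths`, and
#'   `datasets` (list of [uce_dataset()]s, one per replicate).
#' @export
generate_scenario_fixture <- function(scenario = 1L, n_uces = 22L,
                                      total_sites = 10000L, replicates = 1L,
                                      seed = 1L) {
  set.seed(seed)
  tree <- scenario_tree(scenario)
  # transition:transversion biased unrestricted mutation matrix (2:1)
  rates <- setNames(rep(1, 11), UNREST_RATE_NAMES)
  rates[c("AG", "GA", "CT", "TC")] <- 2
  mut <- mutation_matrix("UNREST", rates = rates)
  pop <- population_config()
  raw <- runif(n_uces, 0.5, 1.5)
  lens <- pmax(20L, as.integer(round(raw / sum(raw) * total_sites)))
  ids <- sprintf("uce%02d", seq_len(n_uces))
  profiles <- lapply(lens, function(l)
    selection_profile(nes_max = exp(runif(1, log(0.5), log(8))),
                      center = runif(1, 0.3 * l, 0.7 * l),
                      width = runif(1, l / 10, l / 4)))
  names(profiles) <- ids
  optima <- lapply(lens, function(l) sample.int(4L, l, replace = TRUE))
  names(optima) <- ids
  models <- mapply(function(l, pr, op) .build_uce_models(l, op, mut, pr, pop),
                   lens, profiles, optima, SIMPLIFY = FALSE)
  C <- .mean_rate(models)
  datasets <- lapply(seq_len(replicates), function(r) {
    alns <- lapply(seq_len(n_uces), function(i)
      .simulate_selon_uce(tree, mut, profiles[[i]], optima[[i]], pop, C,
                          seed = seed + r * 1000L + i))
    names(alns) <- ids
    uce_dataset(alns)
  })
  list(scenario = as.integer(scenario), tree = tree, outgroup = "out",
       mut = mut, pop = pop, C = C, profiles = profiles, optima = optima,
       uce_lengths = setNames(lens, ids), datasets = datasets, seed = seed)
}
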