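test_that("transition probabilities behave across time scales", {
  set.seed(11)
  q <- random_rate_matrix()
  expect_equal(transition_probabilities(q, 0), diag(4),
               ignore_attr = TRUE)
  # first-order series at tiny t
  P <- transition_probabilities(q, 1e-6)
  expect_lt(max(abs(P - (diag(4) + q * 1e-6))), 1e-9)
  # ergodic limit: every row approaches the stationary distribution
  pi <- equilibrium_frequencies(q)
  Pinf <- transition_probabilities(q, 1e4)
  for (i in 1:4) expect_equal(Pinf[i, ], pi, tolerance = 1e-6)
  expect_equal(unname(rowSums(transition_probabilities(q, 0.37))),
               rep(1, 4), tolerance = 1e-10)
  expect_error(transition_probabilities(q, -0.1), ">= 0")
})

test_that("pruning equals exhaustive enumeration on small random trees", {
  set.seed(23)
  # 2-taxon tree: pruning equals the direct root-state summation
  tr2 <- read_tree("(a:0.12,b:0.3);")
  q2 <- random_rate_matrix()
  pi2 <- equilibrium_frequencies(q2)
  pat2 <- c(a = 2L, b = 4L)
  direct <- log(sum(pi2 * transition_probabilities(q2, 0.12)[, 2] *
                      transition_probabilities(q2, 0.3)[, 4]))
  expect_equal(site_log_likelihood(tr2, pat2, list(q_scaled = q2, pi = pi2)),
               direct, tolerance = 1e-10)
  for (rep in 1:25) {
    n <- sample(3:5, 1)
    tr <- random_rooted_tree(n)
    q <- random_rate_matrix()
    pi <- equilibrium_frequencies(q)
    pat <- setNames(sample(1:4, n, TRUE), tr$tip.label)
    if (rep %% 5 == 0) pat[sample(n, 1)] <- NA  # exercise missing data
    site <- list(q_scaled = q, pi = pi)
    expect_equal(site_log_likelihood(tr, pat, site),
                 brute_force_site_lnl(tr, pat, q, pi), tolerance = 1e-8)
    # compiled engine agrees with the R reference
    ds <- uce_dataset(list(u = matrix(pat, ncol = 1,
                                      dimnames = list(names(pat), NULL))))
    en <- list(decomp = selon:::cpp_decompose(array(q, c(4, 4, 1))),
               tips = selon:::.tip_matrix(ds, selon:::.tree_data(tr)$tree),
               td = selon:::.tree_data(tr), site_prof = 0L,
               prof_ptr = c(0L, 1L), comp_q = 0L, comp_rate = 1,
               comp_w = 1, comp_pi = matrix(pi, 4, 1), uce_sites = 1L)
    expect_equal(selon:::.engine_site_lnl(en)[1],
                 site_log_likelihood(tr, pat, site), tolerance = 1e-10)
  }
})

test_that("UCE log-likelihood is additive over sites and handles missing", {
  set.seed(7)
  tr <- random_rooted_tree(4)
  mu <- mutation_matrix("JC")
  pop <- population_config()
  prof <- selection_profile(3, 4, 2)
  sites <- lapply(1:8, function(k)
    site_rate_matrix(k, sample(c("A", "C", "G", "T"), 1), mu, prof, pop))
  sites <- scale_sites(sites)$sites
  aln <- matrix(sample(1:4, 4 * 8, TRUE), 4, 8,
                dimnames = list(tr$tip.label, NULL))
  total <- uce_log_likelihood(tr, aln, sites)
  halves <- uce_log_likelihood(tr, aln[, 1:4], sites[1:4]) +
    uce_log_likelihood(tr, aln[, 5:8], sites[5:8])
  expect_equal(total, halves)
  expect_equal(uce_log_likelihood(tr, aln[, 1, drop = FALSE], sites[1]),
               site_log_likelihood(tr, aln[, 1], sites[[1]]))
  # an all-missing column carries no information: log-likelihood 0
  aln_na <- aln
  aln_na[, 3] <- NA_integer_
  expect_equal(site_log_likelihood(tr, aln_na[, 3], sites[[3]]), 0)
  expect_error(uce_log_likelihood(tr, aln, sites[1:5]), "per alignment")
})

test_that("likelihood is invariant to consistent taxon permutation", {
  set.seed(19)
  tr <- random_rooted_tree(5)
  q <- random_rate_matrix()
  site <- list(q_scaled = q, pi = equilibrium_frequencies(q))
  pat <- setNames(sample(1:4, 5, TRUE), tr$tip.label)
  perm <- sample(5)
  expect_equal(site_log_likelihood(tr, pat, site),
               site_log_likelihood(tr, pat[perm], site))
})

test_that("an all-missing taxon and joint rescaling leave likelihoods alone", {
  set.seed(47)
  q <- random_rate_matrix()
  site <- list(q_scaled = q, pi = equilibrium_frequencies(q))
  # a taxon that is missing at every site carries no information: the lnL
  # equals that of the tree with the leaf pruned away
  tr5 <- random_rooted_tree(5)
  pat5 <- setNames(sample(1:4, 5, TRUE), tr5$tip.label)
  pat5["t3"] <- NA
  tr4 <- ape::drop.tip(tr5, "t3")
  expect_lt(abs(site_log_likelihood(tr5, pat5, site) -
                  site_log_likelihood(tr4, pat5[tr4$tip.label], site)),
            1e-9)
  # multiplying branch lengths by c and dividing the rate matrix by c
  # changes nothing
  for (cc in c(0.2, 5)) {
    trc <- tr5
    trc$edge.length <- trc$edge.length * cc
    sitec <- list(q_scaled = q / cc, pi = site$pi)
    expect_lt(abs(site_log_likelihood(trc, pat5, sitec) -
                    site_log_likelihood(tr5, pat5, site)), 1e-8)
  }
})

test_that("generalized Laguerre Gamma categories integrate exactly", {
  for (alpha in c(0.3, 0.5, 1, 2.7, 100)) {
    for (nc in c(4L, 8L)) {
      g <- laguerre_gamma_rates(alpha, nc)
      expect_equal(sum(g$weights), 1, tolerance = 1e-10)
      expect_equal(sum(g$weights * g$rates), 1, tolerance = 1e-8)
      expect_true(all(g$rates > 0))
      # Gauss exactness: second moment matches Gamma analytically
      expect_equal(sum(g$weights * g$rates^2), 1 + 1 / alpha,
                   tolerance = 1e-6)
    }
  }
  # a near-degenerate density concentrates all rates near 1
  g100 <- laguerre_gamma_rates(100, 4)
  expect_true(all(g100$rates > 0.7 & g100$rates < 1.3))
  expect_error(laguerre_gamma_rates(0, 4), "alpha")
  expect_error(laguerre_gamma_rates(1, 5), "ncat")
})

test_that("GTR+Gamma likelihood matches phangorn and brute force", {
  set.seed(3)
  tr <- random_rooted_tree(4)
  aln <- matrix(sample(1:4, 4 * 40, TRUE), 4, 40,
                dimnames = list(tr$tip.label, NULL))
  bf <- c(0.3, 0.2, 0.3, 0.2)
  ex <- c(1.5, 3, 0.8, 1.2, 2.5)
  # plain GTR (one unit-rate category) against phangorn's pml
  l1 <- gtr_gamma_log_likelihood(tr, aln, ex, bf, gamma = NULL)
  pd <- phangorn::phyDat(matrix(tolower(decode_bases(aln)), 4, 40,
                                dimnames = dimnames(aln)), type = "DNA")
  pp <- phangorn::pml(tr, pd, bf = bf, Q = c(ex, 1))
  expect_equal(as.numeric(l1), pp$logLik, tolerance = 1e-8)
  # 4-category mixture against direct summation over categories
  g <- laguerre_gamma_rates(0.7, 4)
  l4 <- gtr_gamma_log_likelihood(tr, aln, ex, bf, gamma = g)
  Q <- selon:::.gtr_q(ex, bf)
  manual <- sum(vapply(seq_len(ncol(aln)), function(k) {
    lik <- sum(vapply(1:4, function(c) {
      g$weights[c] * exp(brute_force_site_lnl(tr, aln[, k], Q * g$rates[c],
                                              bf))
    }, numeric(1)))
    log(lik)
  }, numeric(1)))
  expect_equal(as.numeric(l4), manual, tolerance = 1e-8)
  # very large alpha converges to the single-rate likelihood on data
  # simulated under plain GTR
  sim <- simulate_gtr_gamma(tr, ex, bf, n_sites = 200, seed = 9,
                            site_rates = rep(1, 200))
  lbig <- gtr_gamma_log_likelihood(tr, sim, ex, bf,
                                   gamma = laguerre_gamma_rates(100, 4))
  lone <- gtr_gamma_log_likelihood(tr, sim, ex, bf, gamma = NULL)
  expect_lt(abs(as.numeric(lbig) - as.numeric(lone)) / 200, 1e-3)
})

test_that("GTR rerooting invariance holds; the SelON engine keeps the root", {
  set.seed(13)
  aln <- aln_from_strings(c(a = "ACGTACGTAC", b = "ACGTACCTAA",
                            c = "GCGTACGTCC", d = "ACTTACGTAC"))
  t1 <- read_tree("((a:0.1,b:0.2):0.05,(c:0.15,d:0.1):0.05);")
  t2 <- read_tree("(a:0.1,(b:0.2,(c:0.15,d:0.1):0.1):0.0);")  # same unrooted
  bf <- rep(0.25, 4)
  ex <- c(1.2, 2.5, 0.7, 1.1, 2)
  g <- laguerre_gamma_rates(1, 4)
  expect_equal(as.numeric(gtr_gamma_log_likelihood(t1, aln, ex, bf, g)),
               as.numeric(gtr_gamma_log_likelihood(t2, aln, ex, bf, g)),
               tolerance = 1e-8)
  # SelON is non-reversible: the same rerooting changes the likelihood
  mu <- mutation_matrix("UNREST",
                        rates = c(2, 3, 0.5, 1, 1, 4, 1, 1, 1, 2, 1))
  pop <- population_config()
  prof <- selection_profile(5, 5, 3)
  sites <- scale_sites(lapply(1:10, function(k)
    site_rate_matrix(k, "A", mu, prof, pop)))$sites
  d1 <- uce_log_likelihood(t1, aln, sites)
  d2 <- uce_log_likelihood(t2, aln, sites)
  expect_gt(abs(d1 - d2), 1e-6)
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-100, 0, 10, 100), 200)
  expect_equal(aicc(-100, 5, 10, 100), 210 + 60 / 994)
  # large n limit: AICc -> AIC
  expect_equal(aicc(-100, 5, 1000, 1e6), 210, tolerance = 1e-4)
  expect_error(aicc(-100, 10, 2, 5), "sample size")
})
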