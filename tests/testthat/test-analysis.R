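test_that("Fitch parsimony equals brute force on small trees", {
  # canonical example: ((a,b),(c,d)) with pattern AACC needs one change
  tr4 <- read_tree("((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(fitch_parsimony_site(c(a = "A", b = "A", c = "C", d = "C"),
                                    tr4), 1L)
  expect_equal(fitch_parsimony_site(c(a = "G", b = "G", c = "G", d = "G"),
                                    tr4), 0L)
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    tr <- random_rooted_tree(n)
    pat <- setNames(sample(1:4, n, TRUE), tr$tip.label)
    if (rep %% 4 == 0) pat[sample(n, 1)] <- NA
    expect_equal(fitch_parsimony_site(pat, tr),
                 brute_force_fitch(tr, pat))
  }
  # cross-check per-site scores against phangorn on a larger alignment
  set.seed(42)
  tr <- random_rooted_tree(8)
  aln <- matrix(sample(1:4, 8 * 50, TRUE), 8, 50,
                dimnames = list(tr$tip.label, NULL))
  ours <- fitch_parsimony(aln, tr)
  pd <- phangorn::phyDat(matrix(tolower(decode_bases(aln)), 8, 50,
                                dimnames = dimnames(aln)), type = "DNA")
  theirs <- phangorn::fitch(tr, pd, site = "site")
  idx <- attr(pd, "index")
  expect_equal(ours, as.integer(theirs[idx]))
})

test_that("trimming keeps the minimal-parsimony window", {
  set.seed(55)
  tr <- random_rooted_tree(6, 0.1, 0.3)
  # constructed fixture: variable ends, conserved middle
  l <- 40
  aln <- matrix(0L, 6, l, dimnames = list(tr$tip.label, NULL))
  for (k in 1:l) {
    aln[, k] <- if (k >= 14 && k <= 33) 2L else sample(1:4, 6, TRUE)
  }
  tres <- trim_uce(aln, tr, keep_fraction = 0.5)
  expect_equal(tres$end - tres$start + 1L, 20L)
  expect_gte(tres$start, 10)
  expect_lte(tres$end, 36)
  # the chosen window is minimal by exhaustive scan
  w <- 20L
  sums <- vapply(1:(l - w + 1), function(s)
    sum(tres$site_scores[s:(s + w - 1)]), numeric(1))
  expect_equal(tres$score, min(sums))
  expect_equal(tres$start, which.min(sums))  # leftmost tie-break
  # all-constant alignment: leftmost window
  alnc <- matrix(3L, 6, 11, dimnames = list(tr$tip.label, NULL))
  expect_equal(trim_uce(alnc, tr, 0.5)$start, 1L)
  expect_equal(trim_uce(alnc, tr, 0.5)$end, 6L)   # round(0.5 * 11) = 6
  expect_equal(trim_uce(aln[, 1:10], tr, 0.5)$end -
                 trim_uce(aln[, 1:10], tr, 0.5)$start + 1L, 5L)
  # trimming never increases the mean per-site parsimony of the kept window
  expect_lte(tres$score / 20, mean(tres$site_scores))
  expect_error(trim_uce(aln[, 1:3], tr), "too short")
})

test_that("bootstrap proportions match exhaustive enumeration", {
  # all positive deltas: support cannot flip
  b <- bootstrap_topology_support(rep(1, 5), n_boot = 200, seed = 1)
  expect_equal(b$prop_a, 1)
  # two UCEs {+1, -1}: the four equally likely resamples give 1/4, 1/4, 1/2
  b2 <- bootstrap_topology_support(c(1, -1), n_boot = 40000, seed = 2)
  expect_equal(b2$prop_a, 0.25, tolerance = 0.02)
  expect_equal(b2$prop_b, 0.25, tolerance = 0.02)
  expect_equal(b2$prop_tie, 0.5, tolerance = 0.02)
  # three UCEs: compare to exact enumeration over 27 resamples
  d <- c(2, -1, -0.5)
  grid <- expand.grid(1:3, 1:3, 1:3)
  sums <- apply(grid, 1, function(i) sum(d[i]))
  exact_a <- mean(sums > 0)
  b3 <- bootstrap_topology_support(d, n_boot = 60000, seed = 3)
  expect_equal(b3$prop_a, exact_a, tolerance = 0.01)
  # determinism
  expect_identical(bootstrap_topology_support(d, 500, seed = 9),
                   bootstrap_topology_support(d, 500, seed = 9))
  expect_error(bootstrap_topology_support(numeric(0)), "at least one")
})

test_that("model adequacy scores similarity correctly", {
  # self-simulation with the replicate's own seed scores exactly 1
  fx <- tiny_selon_fixture(n_uces = 1, l = 40, n_taxa = 5, seed = 3)
  fit <- list(model = "selon", tree = fx$tree, mut = fx$mut,
              profiles = fx$profiles, optima = fx$optima, pop = fx$pop,
              C = fx$C, lnL = 0, k = 1, aicc = 0, n_taxa = 5, n_sites = 40,
              per_uce_lnL = 0, seed = 1)
  class(fit) <- "selon_fit"
  obs <- selon:::.simulate_selon_uce(fx$tree, fx$mut, fx$profiles$u01,
                                     fx$optima$u01, fx$pop, fx$C,
                                     seed = 500 + 0 * 10000 + 1)
  ds_obs <- uce_dataset(list(u01 = obs))
  adq <- model_adequacy(fit, ds_obs, n_rep = 1, seed = 500)
  expect_equal(adq$mean, 1)
  # independent uniform draws match about a quarter of the time
  set.seed(77)
  tr0 <- read_tree("(a:1e4,(b:1e4,c:1e4):1e4);")
  mu <- mutation_matrix("JC")
  prof0 <- list(x = selection_profile(0, 1, 1))
  opt0 <- list(x = rep(1L, 600))
  fit2 <- fit
  fit2$tree <- tr0
  fit2$profiles <- prof0
  fit2$optima <- opt0
  fit2$mut <- mu
  fit2$C <- 3
  obs2 <- matrix(sample(1:4, 3 * 600, TRUE), 3, 600,
                 dimnames = list(tr0$tip.label, NULL))
  obs2[1, 1:20] <- NA  # missing cells are excluded from both counts
  adq2 <- model_adequacy(fit2, uce_dataset(list(x = obs2)), n_rep = 4,
                         seed = 2)
  expect_true(all(adq2$per_rep > 0.25 - 3 * sqrt(0.25 * 0.75 / 1780) &
                  adq2$per_rep < 0.25 + 3 * sqrt(0.25 * 0.75 / 1780)))
  expect_true(all(adq2$per_rep >= 0 & adq2$per_rep <= 1))
})

test_that("topology comparison bookkeeping and site-wise support add up", {
  fx <- tiny_selon_fixture(n_uces = 3, l = 40, n_taxa = 6, seed = 29)
  cfg <- optimizer_config(outer_cycle_max = 1L, simplex_eval_cap = 80L)
  # identical topologies, same seed: every delta is zero
  sup0 <- suppressWarnings(
    compare_topologies(fx$dataset, fx$tree, fx$tree, "gtr_gamma", cfg,
                       seed = 2))
  expect_true(all(abs(sup0$per_uce$delta) < 1e-9))
  expect_equal(unname(sup0$counts["tie"]), 3L)
  # a genuinely different topology (swap tip 1 with a non-sister tip)
  alt <- fx$tree
  parent_of <- function(i) fx$tree$edge[fx$tree$edge[, 2] == i, 1]
  j <- (2:6)[vapply(2:6, parent_of, 0L) != parent_of(1L)][1]
  alt$tip.label[c(1, j)] <- alt$tip.label[c(j, 1)]
  sup <- suppressWarnings(
    compare_topologies(fx$dataset, fx$tree, alt, "gtr_gamma", cfg, seed = 2))
  expect_equal(sum(sup$counts), 3L)
  expect_equal(sup$total_delta, sum(sup$per_uce$delta), tolerance = 1e-8)
  # data were simulated on fx$tree: it should be favored overall
  expect_gt(sup$total_delta, 0)
  # site-wise deltas sum to the per-UCE deltas
  sw <- sitewise_support(fx$dataset, sup$fit_a, sup$fit_b,
                         centers = setNames(rep(20, 3),
                                            names(fx$dataset$alignments)))
  agg <- tapply(sw$delta_lnl, sw$uce, sum)
  expect_equal(as.numeric(agg[sup$per_uce$uce]), sup$per_uce$delta,
               tolerance = 1e-8)
  expect_true(all(c("uce", "site", "delta_lnl", "dist_center",
                    "gamma_rate") %in% names(sw)))
  expect_equal(sw$dist_center[sw$uce == "u01"], abs(1:40 - 20))
})

test_that("support and trim tables serialize as TSV", {
  dir <- tempfile()
  dir.create(dir)
  sup <- structure(list(per_uce = data.frame(uce = c("a", "b"),
                                             lnl_a = c(-1, -2),
                                             lnl_b = c(-2, -1),
                                             delta = c(1, -1))),
                   class = "topology_support")
  f1 <- file.path(dir, "support.tsv")
  write_support_table(sup, f1)
  tab <- read.table(f1, header = TRUE, sep = "\t")
  expect_equal(tab$delta, c(1, -1))
  tr <- read_tree("((a:1,b:1):1,(c:1,d:1):1);")
  aln <- matrix(sample(1:4, 4 * 12, TRUE), 4, 12,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  trims <- list(u1 = trim_uce(aln, tr, 0.5))
  f2 <- file.path(dir, "trim.tsv")
  write_trim_table(trims, f2)
  tt <- read.table(f2, header = TRUE, sep = "\t")
  expect_equal(tt$bed_start, tt$start - 1L)  # BED companion is 0-based
  expect_equal(tt$bed_end, tt$end)
})
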