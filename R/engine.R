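# Internal glue between the R model objects and the compiled pruning core.
# An "engine" is the flattened array form of a dataset x model combination:
# distinct decomposed rate matrices, mixture components (Q index, rate
# multiplier, weight, root frequencies), a site -> profile map, and the
# alignment columns as an n_tip x S integer matrix ordered like the tree tips.

# tip-state matrix (0..3, -1 missing) for one or more alignments, rows in
# tree tip order
.tip_matrix <- function(dataset, tree, uces = names(dataset$alignments)) {
  cols <- lapply(uces, function(id) dataset$alignments[[id]])
  m <- do.call(cbind, cols)
  m <- m[tree$tip.label, , drop = FALSE]
  m[is.na(m)] <- 0L
  storage.mode(m) <- "integer"
  mm <- m - 1L
  mna <- do.call(cbind, cols)[tree$tip.label, , drop = FALSE]
  mm[is.na(mna)] <- -1L
  mm
}

# Assemble a SelON engine.  `C` fixed if given, else computed from the models
# (mean equilibrium rate across all sites).  Scaling enters as the component
# rate multiplier 1/C: Q_scaled shares eigenvectors with Q_raw.
.selon_engine <- function(dataset, tree, mut, profiles, optima, pop, C = NULL,
                          uces = names(dataset$alignments)) {
  td <- .tree_data(tree)
  models <- lapply(uces, function(id)
    .build_uce_models(ncol(dataset$alignments[[id]]), optima[[id]], mut,
                      profiles[[id]], pop, decompose = FALSE))
  names(models) <- uces
  nq_per <- vapply(models, function(m) dim(m$Q)[3], integer(1))
  M <- sum(nq_per)                       # one component per distinct model
  Qcube <- array(unlist(lapply(models, `[[`, "Q"), use.names = FALSE),
                 c(4, 4, M))
  dp <- cpp_decompose_pi(Qcube)          # one pass: eigensystem + pi + rates
  if (any(!dp$unique))
    stop("a site rate matrix has no unique stationary distribution")
  if (any(dp$resid > 1e-8))
    stop("stationary solve failed for a site model")
  offset <- c(0L, cumsum(nq_per))
  site_prof <- integer(0)
  for (i in seq_along(uces))
    site_prof <- c(site_prof, offset[i] + models[[i]]$site_q)
  if (is.null(C)) C <- mean(dp$rate[site_prof])
  uce_sites <- vapply(uces, function(id) ncol(dataset$alignments[[id]]),
                      integer(1))
  list(
    decomp = dp,
    tips = .tip_matrix(dataset, td$tree, uces),
    td = td,
    site_prof = as.integer(site_prof - 1L),
    prof_ptr = as.integer(0:M),
    comp_q = as.integer(0:(M - 1)),
    comp_rate = rep(1 / C, M),
    comp_w = rep(1, M),
    comp_pi = dp$pi,
    C = C,
    models = models,
    uce_sites = uce_sites
  )
}

# Assemble a GTR+Gamma engine for one or more partitions (UCEs).  Each
# partition p has its own normalized GTR matrix Q_p, base frequencies, and
# Gamma rates; all its sites share one profile of `ncat` components.
.gtr_engine <- function(dataset, tree, params, gamma_cats,
                        uces = names(dataset$alignments)) {
  td <- .tree_data(tree)
  U <- length(uces)
  Qcube <- array(0, c(4, 4, U))
  comp_q <- integer(0); comp_rate <- numeric(0); comp_w <- numeric(0)
  comp_pi <- NULL
  prof_ptr <- 0L
  for (i in seq_len(U)) {
    p <- params[[uces[i]]]
    Qcube[, , i] <- .gtr_q(p$exch, p$bf)
    g <- laguerre_gamma_rates(p$alpha, gamma_cats)
    comp_q <- c(comp_q, rep(i - 1L, gamma_cats))
    comp_rate <- c(comp_rate, g$rates)
    comp_w <- c(comp_w, g$weights)
    comp_pi <- cbind(comp_pi, matrix(p$bf, 4, gamma_cats))
    prof_ptr <- c(prof_ptr, prof_ptr[length(prof_ptr)] + gamma_cats)
  }
  uce_sites <- vapply(uces, function(id) ncol(dataset$alignments[[id]]),
                      integer(1))
  site_prof <- rep(seq_len(U) - 1L, uce_sites)
  list(
    decomp = cpp_decompose(Qcube),
    tips = .tip_matrix(dataset, td$tree, uces),
    td = td,
    site_prof = as.integer(site_prof),
    prof_ptr = as.integer(prof_ptr),
    comp_q = as.integer(comp_q),
    comp_rate = comp_rate,
    comp_w = comp_w,
    comp_pi = comp_pi,
    uce_sites = uce_sites
  )
}

# normalized GTR rate matrix (mean substitution rate 1 at its stationary bf)
.gtr_q <- function(exch, bf) {
  M <- mutation_matrix("GTR", rates = exch, base_freqs = bf)$M
  M / sum(bf * -diag(M))
}

# per-site log-likelihoods of an engine, optionally with replacement branch
# lengths
.engine_site_lnl <- function(en, lengths = NULL) {
  if (is.null(lengths)) lengths <- en$td$lengths
  cpp_site_loglik(en$decomp, en$tips, en$td$edge, lengths, en$td$n_tip,
                  en$td$n_nodes, en$td$root, en$site_prof, en$prof_ptr,
                  en$comp_q, en$comp_rate, en$comp_w, en$comp_pi)
}

# per-site x per-category (unweighted) log-likelihoods; gamma engines only
.engine_site_lnl_bycomp <- function(en, lengths = NULL) {
  if (is.null(lengths)) lengths <- en$td$lengths
  cpp_site_loglik_bycomp(en$decomp, en$tips, en$td$edge, lengths, en$td$n_tip,
                         en$td$n_nodes, en$td$root, en$site_prof, en$prof_ptr,
                         en$comp_q, en$comp_rate, en$comp_w, en$comp_pi)
}

# per-UCE sums of a per-site vector
.per_uce_sums <- function(x, uce_sites) {
  f <- rep(seq_along(uce_sites), uce_sites)
  as.numeric(tapply(x, f, sum))
}

# generation-ordered branch sweeps on an assembled engine
.engine_branch_sweeps <- function(en, bounds, xtol, max_sweeps, rel_tol) {
  cpp_optimize_branches(en$decomp, en$tips, en$td$edge, en$td$lengths,
                        en$td$n_tip, en$td$n_nodes, en$td$root, en$site_prof,
                        en$prof_ptr, en$comp_q, en$comp_rate, en$comp_w,
                        en$comp_pi, as.integer(en$td$sweep_order), bounds[1],
                        bounds[2], xtol, as.integer(max_sweeps), rel_tol)
}
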