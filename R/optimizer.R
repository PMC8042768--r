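# Four-stage hill-climbing maximum-likelihood fit for SelON, and the
# partitioned GTR+Gamma comparison fit.  Stage order per cycle:
#   1. branch lengths (generation-ordered 1-D sweeps, tips -> root)
#   2. per-UCE Gaussian profiles (bounded derivative-free simplex)
#   3. global mutation rates (11 free UNREST rates, G->T pinned at 1)
#   4. per-site optimal nucleotides (argmax over the 4 candidates)
# The scale factor C is held fixed within a stage and refreshed between
# stages with an accept-guard, so the total log-likelihood never decreases.

#' Optimizer configuration
#'
#' @param branch_cycle_max Maximum branch-length sweeps per stage-1 call
#'   (default 10: the first sweep plus up to nine more).
#' @param outer_cycle_max Maximum outer four-stage cycles (default 12: the
#'   first cycle plus up to eleven more).
#' @param rel_tol Relative log-likelihood improvement below which sweeps and
#'   cycles stop (default 0.01, i.e. < 1%).
#' @param branch_bounds Lower/upper bounds of a branch length.
#' @param simplex_eval_cap Function-evaluation cap per simplex stage call.
#' @param simplex_tol Relative convergence tolerance of the simplex searches.
#' @param branch_xtol Absolute tolerance of the 1-D branch searches.
#' @param nes_bounds,width_bounds_factor Bounds of `nes_max` and, as factors
#'   of UCE length, of `width` (width in `[0.1, 10 l]`); centers are bounded
#'   to `[1, l]`.
#' @param count_optima Count each estimated optimal nucleotide as one
#'   parameter in AICc (default `TRUE`).
#' @return An object of class `selon_config`.
#' @export
optimizer_config <- function(branch_cycle_max = 10L, outer_cycle_max = 12L,
                             rel_tol = 0.01, branch_bounds = c(1e-9, 10),
                             simplex_eval_cap = 5000L, simplex_tol = 1e-6,
                             branch_xtol = 1e-7, nes_bounds = c(0, 50),
                             width_bounds_factor = c(0.1, 10),
                             count_optima = TRUE) {
  stopifnot(rel_tol > 0, branch_bounds[1] < branch_bounds[2],
            simplex_tol > 0, branch_xtol > 0)
  structure(list(branch_cycle_max = as.integer(branch_cycle_max),
                 outer_cycle_max = as.integer(outer_cycle_max),
                 rel_tol = rel_tol, branch_bounds = branch_bounds,
                 simplex_eval_cap = as.integer(simplex_eval_cap),
                 simplex_tol = simplex_tol, branch_xtol = branch_xtol,
                 nes_bounds = nes_bounds,
                 width_bounds_factor = width_bounds_factor,
                 count_optima = isTRUE(count_optima)),
            class = "selon_config")
}

#' Read an optimizer configuration from a key-value file
#'
#' Lines of the form `key = value` (or `key: value`; `#` comments and blank
#' lines ignored), with keys matching the [optimizer_config()] arguments.
#' `branch_bounds`, `nes_bounds` and `width_bounds_factor` take two
#' comma-separated numbers; `count_optima` takes `true`/`false`.  Unknown
#' keys are an error, so typos fail loudly.
#'
#' @param path Path to the configuration file.
#' @return An [optimizer_config()].
#' @export
read_optimizer_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    args[[key]] <- if (key == "count_optima") {
      tolower(val) %in% c("true", "1", "yes")
    } else {
      as.numeric(strsplit(val, ",")[[1]])
    }
  }
  unknown <- setdiff(names(args), names(formals(optimizer_config)))
  if (length(unknown))
    stop("unknown optimizer_config key(s): ", paste(unknown, collapse = ", "))
  do.call(optimizer_config, args)
}

# ---------------------------------------------------------------------------
# bounded derivative-free simplex search: Nelder-Mead on a logistic
# transform of the box, honoring an evaluation cap and relative tolerance
.bounded_simplex <- function(par, fn, lower, upper, eval_cap, rel_tol) {
  lower <- rep_len(lower, length(par))
  upper <- rep_len(upper, length(par))
  par <- pmin(pmax(par, lower + 1e-10 * (upper - lower)),
              upper - 1e-10 * (upper - lower))
  to_z <- function(x) stats::qlogis((x - lower) / (upper - lower))
  to_x <- function(z) lower + (upper - lower) * stats::plogis(z)
  z0 <- to_z(par)
  # optimize the offset from the start: Nelder-Mead sizes its initial
  # simplex from the parameter magnitudes, so starting at the zero vector
  # guarantees a sane step on the logit scale
  res <- stats::optim(numeric(length(par)), function(dz) fn(to_x(z0 + dz)),
                      method = "Nelder-Mead",
                      control = list(maxit = eval_cap, reltol = rel_tol))
  list(par = to_x(z0 + res$par), value = res$value)
}

# ---------------------------------------------------------------------------

#' Starting parameter bundle for a SelON fit
#'
#' Starting values: random (seeded) Gaussian profiles within bounds; a
#' Jukes-Cantor mutation process (all UNREST rates 1); majority-rule optimal
#' nucleotides (ties broken toward the alphabetically first tied base); and
#' branch lengths from an F81 fit to the concatenated data.
#'
#' @param dataset A [uce_dataset()].
#' @param tree Rooted binary `phylo` matching the dataset's taxa.
#' @param pop A [population_config()].
#' @param config An [optimizer_config()].
#' @param seed Integer seed for the random profile draws.
#' @return A `selon_state` list with elements `dataset`, `tree`, `mut`,
#'   `profiles`, `optima`, `pop`, `C`, `config`, `lnL`, `per_uce_lnL`.
#' @export
initialize_fit <- function(dataset, tree, pop = population_config(),
                           config = optimizer_config(), seed = 1L) {
  stopifnot(inherits(dataset, "uce_dataset"))
  tree <- validate_tree(tree, taxa = dataset$taxa)
  set.seed(seed)
  uces <- names(dataset$alignments)
  profiles <- lapply(uces, function(id) {
    l <- ncol(dataset$alignments[[id]])
    selection_profile(nes_max = runif(1, 0.5, 10),
                      center = runif(1, 0.25 * l, 0.75 * l),
                      width = runif(1, l / 10, l / 2))
  })
  names(profiles) <- uces
  optima <- lapply(uces, function(id) .majority_optima(dataset$alignments[[id]]))
  names(optima) <- uces
  mut <- mutation_matrix("UNREST", rates = rep(1, 11))
  tree <- .f81_branch_lengths(dataset, tree, config$branch_bounds)
  state <- list(dataset = dataset, tree = tree, mut = mut, profiles = profiles,
                optima = optima, pop = pop, config = config, C = NULL,
                seed = seed)
  class(state) <- "selon_state"
  state <- .refresh_lnl(state)
  if (!is.finite(state$lnL))
    stop("initialization produced a non-finite log-likelihood; ",
         "check alignments and tree for degeneracies")
  state
}

# majority-rule starting optimum per column; ties -> alphabetically first
.majority_optima <- function(alignment) {
  apply(alignment, 2, function(col) {
    counts <- tabulate(col[!is.na(col)], nbins = 4L)
    if (all(counts == 0)) return(1L)  # all-missing column: arbitrary A
    which.max(counts)                 # first max = alphabetically first tie
  })
}

# F81 starting branch lengths on the concatenated data (phangorn).
# optim.pml unroots the tree, so the optimized lengths are carried back onto
# the user's rooted topology by bipartition; the root edge of the unrooted
# tree is split evenly between the two root-adjacent branches.
.f81_branch_lengths <- function(dataset, tree, bounds) {
  chars <- do.call(cbind, lapply(dataset$alignments, function(a) {
    m <- matrix(tolower(decode_bases(a, "-")), nrow(a), ncol(a))
    rownames(m) <- rownames(a)
    m
  }))
  pd <- phangorn::phyDat(chars, type = "DNA")
  fit <- tryCatch(suppressWarnings({
    pml0 <- phangorn::pml(tree, pd)   # pml warns while unrooting internally
    phangorn::optim.pml(pml0, model = "F81", optEdge = TRUE,
                        control = phangorn::pml.control(trace = 0))
  }), error = function(e) NULL)
  if (!is.null(fit))
    tree <- .transfer_branch_lengths(fit$tree, tree)
  tree$edge.length <- pmin(pmax(tree$edge.length, bounds[1]), bounds[2])
  tree
}

# copy branch lengths from `from` (possibly unrooted) onto the rooted `to`
# by matching edge bipartitions; the two root edges of `to` share one
# bipartition of `from` and each receives half its length
.transfer_branch_lengths <- function(from, to) {
  taxa <- to$tip.label
  # canonical bipartition key: lexicographically smaller joined side first
  canon <- function(tr, child) {
    tips <- if (child <= length(tr$tip.label)) {
      tr$tip.label[child]
    } else {
      ape::extract.clade(tr, child)$tip.label
    }
    a <- paste(sort(tips), collapse = ",")
    b <- paste(sort(setdiff(taxa, tips)), collapse = ",")
    if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
  }
  from_keys <- vapply(from$edge[, 2], function(ch) canon(from, ch), "")
  to_keys <- vapply(to$edge[, 2], function(ch) canon(to, ch), "")
  dup <- duplicated(to_keys) | duplicated(to_keys, fromLast = TRUE)
  m <- match(to_keys, from_keys)
  len <- from$edge.length[m]
  len[is.na(len)] <- 0.05
  len[dup] <- len[dup] / 2  # the root bipartition is shared by two edges
  to$edge.length <- len
  to
}

# recompute C and total lnL from the current parameters
.refresh_lnl <- function(state, C = NULL) {
  en <- .selon_engine(state$dataset, state$tree, state$mut, state$profiles,
                      state$optima, state$pop, C = C)
  site_lnl <- .engine_site_lnl(en)
  state$C <- en$C
  state$per_uce_lnL <- setNames(.per_uce_sums(site_lnl, en$uce_sites),
                                names(state$dataset$alignments))
  state$lnL <- sum(site_lnl)
  state
}

# refresh C after a stage; revert to `prev` state if the refreshed total lnL
# dropped (keeps the monotonicity contract exact)
.guarded_refresh <- function(state, prev) {
  new <- .refresh_lnl(state)
  if (new$lnL >= prev$lnL) new else prev
}

# ---------------------------------------------------------------------------

#' Stage 1: optimize branch lengths
#'
#' Bounded one-dimensional searches in generation order (pendant branches
#' first, then the branches that subtend them, up to the root), swept
#' repeatedly until the sweep-to-sweep improvement is below `rel_tol` or
#' `branch_cycle_max` sweeps have run.  The log-likelihood never decreases.
#'
#' @param state A `selon_state` from [initialize_fit()].
#' @return The state with updated tree and log-likelihood; the per-sweep
#'   log-likelihood trace is appended to `state$branch_trace`.
#' @export
optimize_branch_lengths <- function(state) {
  cfg <- state$config
  en <- .selon_engine(state$dataset, state$tree, state$mut, state$profiles,
                      state$optima, state$pop, C = state$C)
  res <- .engine_branch_sweeps(en, cfg$branch_bounds, cfg$branch_xtol,
                               cfg$branch_cycle_max, cfg$rel_tol)
  state$tree$edge.length <- res$lengths[.edge_map(state$tree, en$td$tree)]
  state$branch_trace <- c(state$branch_trace, list(res$trace))
  state <- .refresh_lnl(state, C = state$C)  # same C; lnL from new lengths
  state
}

# map edges of `to` (postorder) onto edges of `from`: row i of from$edge
# equals row .edge_map[i] of to$edge (matched by child node)
.edge_map <- function(from, to) {
  match(from$edge[, 2], to$edge[, 2])
}

#' Stage 2: optimize the per-UCE selection profiles
#'
#' For each UCE in turn, maximizes that UCE's log-likelihood over
#' (`nes_max`, `center`, `width`) with a bounded derivative-free simplex
#' search; other UCEs are untouched and the scale factor is held fixed
#' during the sweep, then refreshed with an accept-guard.
#'
#' @param state A `selon_state`.
#' @return The state with updated `profiles`.
#' @export
optimize_shape_params <- function(state) {
  cfg <- state$config
  prev <- state
  for (id in names(state$dataset$alignments)) {
    l <- ncol(state$dataset$alignments[[id]])
    sub <- uce_dataset(state$dataset$alignments[id])
    p <- state$profiles[[id]]
    obj <- function(x) {
      prof <- selection_profile(x[1], x[2], x[3])
      en <- .selon_engine(sub, state$tree, state$mut,
                          setNames(list(prof), id),
                          state$optima[id], state$pop, C = state$C)
      -sum(.engine_site_lnl(en))
    }
    cur <- obj(c(p$nes_max, p$center, p$width))
    res <- .bounded_simplex(c(p$nes_max, p$center, p$width), obj,
                            lower = c(cfg$nes_bounds[1], 1,
                                      cfg$width_bounds_factor[1]),
                            upper = c(cfg$nes_bounds[2], l,
                                      cfg$width_bounds_factor[2] * l),
                            eval_cap = cfg$simplex_eval_cap,
                            rel_tol = cfg$simplex_tol)
    if (res$value < cur)  # accept only improvements per UCE
      state$profiles[[id]] <- selection_profile(res$par[1], res$par[2],
                                                res$par[3])
  }
  .guarded_refresh(state, prev)
}

#' Stage 3: optimize the global mutation rates
#'
#' Bounded simplex search over the 11 free UNREST rates (the G to T rate
#' stays pinned at 1), maximizing the total log-likelihood across all UCEs
#' with the scale factor held fixed, then refreshed with an accept-guard.
#'
#' @param state A `selon_state`.
#' @return The state with updated `mut`.
#' @export
optimize_mutation_rates <- function(state) {
  cfg <- state$config
  prev <- state
  # C is refreshed inside the objective: with the G->T rate pinned at 1 the
  # magnitude of M is meaningful relative to C, so freezing C would distort
  # the relative rates
  obj <- function(r) {
    mut <- mutation_matrix("UNREST", rates = r)
    en <- .selon_engine(state$dataset, state$tree, mut, state$profiles,
                        state$optima, state$pop, C = NULL)
    -sum(.engine_site_lnl(en))
  }
  r0 <- state$mut$rates
  cur <- obj(r0)
  # the 11-dimensional search is revisited (warm-started) on every outer
  # cycle, so its per-cycle evaluation budget is bounded below the global cap
  res <- .bounded_simplex(log(pmax(r0, 1e-6)),
                          function(z) obj(exp(z)),
                          lower = rep(log(1e-4), 11),
                          upper = rep(log(1e4), 11),
                          eval_cap = min(cfg$simplex_eval_cap, 500L),
                          rel_tol = cfg$simplex_tol)
  if (res$value < cur)
    state$mut <- mutation_matrix("UNREST", rates = exp(res$par))
  .guarded_refresh(state, prev)
}

#' Stage 4: optimize the optimal nucleotide sequence
#'
#' For every site of every UCE, evaluates the site log-likelihood under each
#' of the four candidate optima (the scale factor held fixed during the
#' sweep) and keeps the argmax; ties keep the incumbent.  The scale factor
#' is refreshed after the sweep and, if the refreshed total dropped, the
#' sweep is re-run once before the accept-guard applies.
#'
#' @param state A `selon_state`.
#' @return The state with updated `optima`.
#' @export
optimize_optimal_sequence <- function(state) {
  prev <- state
  state <- .optimal_sequence_sweep(state)
  new <- .refresh_lnl(state)
  if (new$lnL < prev$lnL) {         # re-run once at the refreshed scale
    state <- .optimal_sequence_sweep(new)
    new <- .refresh_lnl(state)
  }
  if (new$lnL >= prev$lnL) new else prev
}

.optimal_sequence_sweep <- function(state) {
  # per-site independence: with C fixed, setting every optimum to candidate b
  # and reading per-site lnL gives each site's score for b in 4 engine calls
  for (id in names(state$dataset$alignments)) {
    sub <- uce_dataset(state$dataset$alignments[id])
    l <- ncol(state$dataset$alignments[[id]])
    scores <- sapply(1:4, function(b) {
      en <- .selon_engine(sub, state$tree, state$mut, state$profiles[id],
                          setNames(list(rep(b, l)), id), state$pop,
                          C = state$C)
      .engine_site_lnl(en)
    })
    if (l == 1L) scores <- matrix(scores, nrow = 1)
    inc <- state$optima[[id]]
    inc_score <- scores[cbind(seq_len(l), inc)]
    best <- max.col(scores, ties.method = "first")
    best_score <- scores[cbind(seq_len(l), best)]
    switch_to <- best_score > inc_score + 1e-12  # ties keep the incumbent
    inc[switch_to] <- best[switch_to]
    state$optima[[id]] <- inc
  }
  state
}

# ---------------------------------------------------------------------------

#' Fit the SelON model by four-stage hill climbing
#'
#' Runs stages 1-4 in order, cycling until fewer than `rel_tol` (default 1%)
#' relative log-likelihood improvement between successive cycles or
#' `outer_cycle_max` cycles.  Parameters counted for AICc: 11 mutation rates,
#' 3 per-UCE profile parameters, one per branch, and (by default) one per
#' estimated optimal nucleotide; the sample size is taxa x total sites.
#'
#' @param dataset A [uce_dataset()].
#' @param tree Rooted binary `phylo`; its topology is fixed throughout.
#' @param config An [optimizer_config()].
#' @param pop A [population_config()].
#' @param seed Integer seed (starting profiles are random).
#' @return An object of class `selon_fit` (`model = "selon"`): `lnL`,
#'   `per_uce_lnL`, `k`, `aicc`, fitted `tree`, `mut`, `profiles`, `optima`,
#'   scale `C`, `pop`, `seed`, and the per-cycle log-likelihood `trace`.
#' @export
fit_selon <- function(dataset, tree, config = optimizer_config(),
                      pop = population_config(), seed = 1L) {
  state <- initialize_fit(dataset, tree, pop, config, seed)
  trace <- state$lnL
  for (cycle in seq_len(config$outer_cycle_max)) {
    before <- state$lnL
    state <- optimize_branch_lengths(state)
    state <- optimize_shape_params(state)
    state <- optimize_mutation_rates(state)
    state <- optimize_optimal_sequence(state)
    trace <- c(trace, state$lnL)
    if (state$lnL - before < config$rel_tol * abs(before)) break
  }
  .as_selon_fit(state, trace)
}

.as_selon_fit <- function(state, trace) {
  uces <- names(state$dataset$alignments)
  lens <- uce_lengths(state$dataset)
  k <- 11 + 3 * length(uces) + nrow(state$tree$edge) +
    if (state$config$count_optima) sum(lens) else 0
  n_taxa <- length(state$dataset$taxa)
  n_sites <- sum(lens)
  fit <- list(model = "selon", lnL = state$lnL,
              per_uce_lnL = state$per_uce_lnL, k = k,
              aicc = aicc(state$lnL, k, n_taxa, n_sites),
              n_taxa = n_taxa, n_sites = n_sites, tree = state$tree,
              mut = state$mut, profiles = state$profiles,
              optima = state$optima, C = state$C, pop = state$pop,
              seed = state$seed, trace = trace, config = state$config)
  class(fit) <- "selon_fit"
  fit
}

#' @export
print.selon_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, AICc = %.4f (%d taxa, %d sites)\n",
              toupper(x$model), x$lnL, x$k, x$aicc, x$n_taxa, x$n_sites))
  invisible(x)
}

#' @export
logLik.selon_fit <- function(object, ...) {
  structure(object$lnL, df = object$k, class = "logLik")
}

# ---------------------------------------------------------------------------

#' Fit a partitioned GTR+Gamma model
#'
#' Each UCE gets its own GTR exchangeabilities, maximum-likelihood base
#' frequencies and Gamma shape (generalized Laguerre categories); branch
#' lengths are shared across UCEs by default (concatenated estimation) or
#' fitted per UCE with `shared_branches = FALSE`.  Optimization alternates
#' generation-ordered branch sweeps with per-UCE bounded simplex searches
#' until < `rel_tol` relative improvement between cycles.
#'
#' @param dataset A [uce_dataset()].
#' @param tree Rooted binary `phylo` (fixed topology).
#' @param gamma_cats 4 or 8 rate categories.
#' @param config An [optimizer_config()].
#' @param seed Integer seed (kept for provenance; the fit is deterministic).
#' @param shared_branches Share one set of branch lengths across UCEs.
#' @return A `selon_fit` with `model = "gtr_gamma"`, per-UCE parameter list
#'   `gtr`, and `k = 9 * #UCEs + #branches` (times the per-UCE branch sets
#'   when `shared_branches = FALSE`).
#' @export
fit_gtr_gamma <- function(dataset, tree, gamma_cats = 4L,
                          config = optimizer_config(), seed = 1L,
                          shared_branches = TRUE) {
  stopifnot(inherits(dataset, "uce_dataset"))
  tree <- validate_tree(tree, taxa = dataset$taxa)
  if (!gamma_cats %in% c(4L, 8L)) stop("gamma_cats must be 4 or 8")
  if (!shared_branches) {
    fits <- lapply(names(dataset$alignments), function(id) {
      fit_gtr_gamma(uce_dataset(dataset$alignments[id]), tree, gamma_cats,
                    config, seed, shared_branches = TRUE)
    })
    names(fits) <- names(dataset$alignments)
    lnL <- sum(vapply(fits, `[[`, numeric(1), "lnL"))
    k <- sum(vapply(fits, `[[`, numeric(1), "k"))
    n_taxa <- length(dataset$taxa)
    n_sites <- sum(uce_lengths(dataset))
    fit <- list(model = "gtr_gamma", lnL = lnL,
                per_uce_lnL = vapply(fits, `[[`, numeric(1), "lnL"), k = k,
                aicc = aicc(lnL, k, n_taxa, n_sites), n_taxa = n_taxa,
                n_sites = n_sites, tree = tree, gamma_cats = gamma_cats,
                gtr = lapply(fits, function(f) f$gtr[[1]]),
                per_uce_trees = lapply(fits, `[[`, "tree"),
                seed = seed, shared_branches = FALSE)
    class(fit) <- "selon_fit"
    return(fit)
  }
  cfg <- config
  tree <- .f81_branch_lengths(dataset, tree, cfg$branch_bounds)
  uces <- names(dataset$alignments)
  params <- lapply(uces, function(id) {
    a <- dataset$alignments[[id]]
    counts <- tabulate(a[!is.na(a)], nbins = 4L) + 1
    list(exch = rep(1, 5), bf = counts / sum(counts), alpha = 1)
  })
  names(params) <- uces
  en <- .gtr_engine(dataset, tree, params, gamma_cats)
  lnL <- sum(.engine_site_lnl(en))
  trace <- lnL
  for (cycle in seq_len(cfg$outer_cycle_max)) {
    before <- lnL
    # branch sweeps
    en <- .gtr_engine(dataset, tree, params, gamma_cats)
    res <- .engine_branch_sweeps(en, cfg$branch_bounds, cfg$branch_xtol,
                                 cfg$branch_cycle_max, cfg$rel_tol)
    tree$edge.length <- res$lengths[.edge_map(tree, en$td$tree)]
    # per-UCE GTR+Gamma parameters
    for (id in uces) {
      sub <- uce_dataset(dataset$alignments[id])
      p <- params[[id]]
      unpack <- function(x) {
        bf_raw <- exp(c(x[6:8], 0))
        list(exch = exp(x[1:5]), bf = bf_raw / sum(bf_raw),
             alpha = exp(x[9]))
      }
      pack <- c(log(p$exch), log(p$bf[1:3] / p$bf[4]), log(p$alpha))
      obj <- function(x) {
        q <- unpack(x)
        enu <- .gtr_engine(sub, tree, setNames(list(q), id), gamma_cats)
        -sum(.engine_site_lnl(enu))
      }
      cur <- obj(pack)
      resu <- .bounded_simplex(pack, obj,
                               lower = c(rep(log(1e-3), 5), rep(-12, 3),
                                         log(0.02)),
                               upper = c(rep(log(1e3), 5), rep(12, 3),
                                         log(100)),
                               eval_cap = cfg$simplex_eval_cap,
                               rel_tol = cfg$simplex_tol)
      if (resu$value < cur) params[[id]] <- unpack(resu$par)
    }
    en <- .gtr_engine(dataset, tree, params, gamma_cats)
    lnL <- sum(.engine_site_lnl(en))
    trace <- c(trace, lnL)
    if (lnL - before < cfg$rel_tol * abs(before)) break
  }
  site_lnl <- .engine_site_lnl(en)
  per_uce <- setNames(.per_uce_sums(site_lnl, en$uce_sites), uces)
  n_taxa <- length(dataset$taxa)
  n_sites <- sum(uce_lengths(dataset))
  k <- 9 * length(uces) + nrow(tree$edge)
  fit <- list(model = "gtr_gamma", lnL = lnL, per_uce_lnL = per_uce, k = k,
              aicc = aicc(lnL, k, n_taxa, n_sites), n_taxa = n_taxa,
              n_sites = n_sites, tree = tree, gamma_cats = gamma_cats,
              gtr = params, seed = seed, trace = trace,
              shared_branches = TRUE)
  class(fit) <- "selon_fit"
  fit
}
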