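# Downstream UCE analytics: topology support, UCE-level bootstrap, Fitch
# parsimony and parsimony-guided trimming, model adequacy, and site-wise
# support profiles.

#' Compare two topologies under SelON or GTR+Gamma
#'
#' Fits the chosen model independently (same seed) on each topology and
#' reports per-UCE and total log-likelihood differences, with the convention
#' `delta = lnL(tree_a) - lnL(tree_b)`, plus the AICc difference (the
#' parameter count is identical across topologies of the same model).  UCEs
#' with `|delta|` below `tie_tol` form a separate tie class.
#'
#' @param dataset A [uce_dataset()].
#' @param tree_a,tree_b Rooted binary `phylo` objects on the same taxon set.
#' @param model `"selon"` or `"gtr_gamma"`.
#' @param config An [optimizer_config()].
#' @param seed Integer seed used for both fits.
#' @param gamma_cats Gamma categories for the GTR+Gamma model.
#' @param tie_tol Absolute delta below which a UCE counts as a tie.
#' @return An object of class `topology_support`: `per_uce` data frame
#'   (`uce`, `lnl_a`, `lnl_b`, `delta`), `total_delta`, `delta_aicc`,
#'   `counts` (favoring a / b / tie), and the two fits.
#' @export
compare_topologies <- function(dataset, tree_a, tree_b,
                               model = c("selon", "gtr_gamma"),
                               config = optimizer_config(), seed = 1L,
                               gamma_cats = 4L, tie_tol = 1e-6) {
  model <- match.arg(model)
  tree_a <- validate_tree(tree_a, taxa = dataset$taxa)
  tree_b <- validate_tree(tree_b, taxa = dataset$taxa)
  fit1 <- if (model == "selon") {
    fit_selon(dataset, tree_a, config, seed = seed)
  } else {
    fit_gtr_gamma(dataset, tree_a, gamma_cats, config, seed = seed)
  }
  fit2 <- if (model == "selon") {
    fit_selon(dataset, tree_b, config, seed = seed)
  } else {
    fit_gtr_gamma(dataset, tree_b, gamma_cats, config, seed = seed)
  }
  delta <- fit1$per_uce_lnL - fit2$per_uce_lnL
  per_uce <- data.frame(uce = names(dataset$alignments),
                        lnl_a = as.numeric(fit1$per_uce_lnL),
                        lnl_b = as.numeric(fit2$per_uce_lnL),
                        delta = as.numeric(delta), row.names = NULL)
  counts <- c(a = sum(delta > tie_tol), b = sum(delta < -tie_tol),
              tie = sum(abs(delta) <= tie_tol))
  out <- list(model = model, per_uce = per_uce,
              total_delta = sum(delta), delta_aicc = fit1$aicc - fit2$aicc,
              counts = counts, fit_a = fit1, fit_b = fit2)
  class(out) <- "topology_support"
  out
}

#' @export
print.topology_support <- function(x, ...) {
  cat(sprintf("Topology support (%s): total delta lnL = %.4f (A - B)\n",
              x$model, x$total_delta))
  cat(sprintf("  UCEs favoring A: %d, favoring B: %d, ties: %d\n",
              x$counts["a"], x$counts["b"], x$counts["tie"]))
  cat(sprintf("  delta AICc (A - B): %.4f\n", x$delta_aicc))
  invisible(x)
}

#' UCE-level bootstrap of topology support
#'
#' Resamples entire UCEs with replacement, sums their log-likelihood
#' differences, and reports the fraction of pseudoreplicates whose summed
#' delta favors each topology (positive: A, negative: B, zero: tie).
#'
#' @param per_uce_deltas Numeric vector of per-UCE `lnL_a - lnL_b` values
#'   (or a `topology_support` object).
#' @param n_boot Number of pseudoreplicates.
#' @param seed Integer seed.
#' @return A list with `prop_a`, `prop_b`, `prop_tie`, `n_boot`.
#' @export
bootstrap_topology_support <- function(per_uce_deltas, n_boot = 1000L,
                                       seed = 1L) {
  if (inherits(per_uce_deltas, "topology_support"))
    per_uce_deltas <- per_uce_deltas$per_uce$delta
  n <- length(per_uce_deltas)
  if (n < 1) stop("at least one UCE delta is required")
  set.seed(seed)
  sums <- vapply(seq_len(n_boot), function(b)
    sum(per_uce_deltas[sample.int(n, n, replace = TRUE)]), numeric(1))
  list(prop_a = mean(sums > 0), prop_b = mean(sums < 0),
       prop_tie = mean(sums == 0), n_boot = as.integer(n_boot))
}

# ---------------------------------------------------------------------------

#' Fitch parsimony score of one site pattern
#'
#' Small-parsimony count of state changes on a binary topology (branch
#' lengths ignored; an unrooted basal trifurcation is resolved arbitrarily,
#' which does not change the score).  Missing states are fully ambiguous.
#'
#' @param pattern Named character or index vector of observed bases.
#' @param tree `phylo`, binary (rooted or unrooted).
#' @return Integer parsimony score.
#' @export
fitch_parsimony_site <- function(pattern, tree) {
  if (is.character(pattern)) {
    st <- encode_bases(pattern)
    names(st) <- names(pattern)
  } else st <- pattern
  m <- matrix(st, ncol = 1, dimnames = list(names(st), NULL))
  fitch_parsimony(m, tree)[1]
}

#' Per-site Fitch parsimony scores of an alignment
#'
#' @param alignment Taxa x sites matrix (character or index form).
#' @param tree `phylo`, binary (rooted or unrooted).
#' @return Integer vector of per-site scores.
#' @export
fitch_parsimony <- function(alignment, tree) {
  alignment <- .coerce_alignment(alignment)
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    tree <- ape::multi2di(tree, random = FALSE)  # resolve basal trifurcation
  if (!ape::is.binary(tree)) stop("tree must be binary (away from the root)")
  tree <- ape::reorder.phylo(tree, "postorder")
  miss <- setdiff(tree$tip.label, rownames(alignment))
  if (length(miss)) stop("alignment is missing taxa: ",
                         paste(miss, collapse = ", "))
  a <- alignment[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  S <- ncol(a)
  # bitmask state sets: A=1, C=2, G=4, T=8; missing = 15
  tipset <- matrix(15L, n_tip, S)
  obs <- !is.na(a)
  tipset[obs] <- bitwShiftL(1L, a[obs] - 1L)
  sets <- matrix(0L, n_nodes, S)
  sets[seq_len(n_tip), ] <- tipset
  score <- integer(S)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (all(sets[par, ] == 0L)) {           # first child seen
      sets[par, ] <- sets[ch, ]
    } else {
      inter <- bitwAnd(sets[par, ], sets[ch, ])
      uni <- bitwOr(sets[par, ], sets[ch, ])
      empty <- inter == 0L
      score <- score + as.integer(empty)
      sets[par, ] <- ifelse(empty, uni, inter)
    }
  }
  score
}

#' Parsimony-guided contiguous trimming of a UCE
#'
#' Keeps the contiguous window of `round(keep_fraction * l)` sites whose
#' summed per-site Fitch parsimony scores are minimal (leftmost window on
#' ties), so the most conserved stretch is retained and the trimmed sites
#' come from the most variable regions; either end may lose more sites than
#' the other.
#'
#' @param alignment Taxa x sites matrix.
#' @param tree Binary `phylo` used for the parsimony scores.
#' @param keep_fraction Fraction of sites to keep (default 0.5).
#' @return An object of class `trim_result`: `start`, `end` (1-based,
#'   inclusive), `score` (window parsimony total), `site_scores`,
#'   `keep_fraction`.
#' @export
trim_uce <- function(alignment, tree, keep_fraction = 0.5) {
  alignment <- .coerce_alignment(alignment)
  l <- ncol(alignment)
  if (l < 4) stop("alignment too short to trim (need >= 4 sites)")
  w <- as.integer(round(keep_fraction * l))
  if (w < 1 || w > l) stop("keep_fraction yields an empty or full window")
  scores <- fitch_parsimony(alignment, tree)
  cs <- c(0, cumsum(scores))
  win <- cs[(w + 1):(l + 1)] - cs[1:(l - w + 1)]
  start <- which.min(win)             # leftmost minimum
  structure(list(start = start, end = start + w - 1L,
                 score = win[start], site_scores = scores,
                 keep_fraction = keep_fraction),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat(sprintf("Trim window [%d, %d] (%d sites, parsimony %d; 0-based half-open [%d, %d))\n",
              x$start, x$end, x$end - x$start + 1L, x$score,
              x$start - 1L, x$end))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Model adequacy by simulation at the fitted parameters
#'
#' Simulates `n_rep` datasets at the maximum-likelihood estimates on the
#' fitted tree (replicate `r` uses `seed + r - 1`), and scores each by its
#' similarity to the observed data: the number of matching alignment cells
#' divided by the number of compared cells; cells missing in the observed
#' data are excluded from both counts.  For GTR+Gamma replicates, each
#' site's rate multiplier is its model-averaged (posterior-weighted) Gamma
#' rate given the observed data.
#'
#' @param fit A `selon_fit`.
#' @param dataset The observed [uce_dataset()] the fit was made on.
#' @param n_rep Number of simulation replicates.
#' @param seed Integer seed.
#' @return A list with `mean`, `sd`, `per_rep`, `n_rep`.
#' @export
model_adequacy <- function(fit, dataset, n_rep = 100L, seed = 1L) {
  stopifnot(inherits(fit, "selon_fit"), inherits(dataset, "uce_dataset"))
  uces <- names(dataset$alignments)
  tree <- validate_tree(fit$tree, taxa = dataset$taxa)
  gtr_rates <- if (fit$model == "gtr_gamma")
    sitewise_gamma_rates(dataset, fit) else NULL
  per_rep <- vapply(seq_len(n_rep), function(r) {
    match_n <- 0; tot_n <- 0
    for (i in seq_along(uces)) {
      id <- uces[i]
      obs <- dataset$alignments[[id]]
      sim <- if (fit$model == "selon") {
        .simulate_selon_uce(tree, fit$mut, fit$profiles[[id]],
                            fit$optima[[id]], fit$pop, fit$C,
                            seed = seed + (r - 1L) * 10000L + i)
      } else {
        p <- fit$gtr[[id]]
        simulate_gtr_gamma(tree, p$exch, p$bf, n_sites = ncol(obs),
                           seed = seed + (r - 1L) * 10000L + i,
                           site_rates = gtr_rates[[id]])
      }
      sim <- sim[rownames(obs), , drop = FALSE]
      cmp <- !is.na(obs)
      match_n <- match_n + sum(sim[cmp] == obs[cmp])
      tot_n <- tot_n + sum(cmp)
    }
    match_n / tot_n
  }, numeric(1))
  list(mean = mean(per_rep), sd = stats::sd(per_rep), per_rep = per_rep,
       n_rep = as.integer(n_rep))
}

#' Model-averaged Gamma rate per site
#'
#' The posterior-weighted mean rate
#' `sum_c r_c w_c L_c / sum_c w_c L_c` per site, given a GTR+Gamma fit:
#' the "best" rate at a site is a weighted average across categories, not
#' the single best-fitting category.
#'
#' @param dataset A [uce_dataset()].
#' @param fit A `selon_fit` with `model = "gtr_gamma"`.
#' @return Named list of per-site rate vectors, one per UCE.
#' @export
sitewise_gamma_rates <- function(dataset, fit) {
  stopifnot(fit$model == "gtr_gamma")
  tree <- validate_tree(fit$tree, taxa = dataset$taxa)
  out <- lapply(names(dataset$alignments), function(id) {
    sub <- uce_dataset(dataset$alignments[id])
    en <- .gtr_engine(sub, tree, fit$gtr[id], fit$gamma_cats)
    ll <- .engine_site_lnl_bycomp(en)           # sites x ncat, unweighted logs
    g <- laguerre_gamma_rates(fit$gtr[[id]]$alpha, fit$gamma_cats)
    wl <- sweep(ll, 2, log(g$weights), "+")
    wl <- exp(wl - apply(wl, 1, max))
    as.numeric((wl %*% g$rates) / rowSums(wl))
  })
  names(out) <- names(dataset$alignments)
  out
}

#' Site-wise topology support profile
#'
#' Per-site log-likelihood differences between two fits of the same model on
#' the same data under two topologies, annotated with each site's distance
#' from the inferred most-conserved center (`|k - center|`, centers from a
#' SelON fit) and, for GTR+Gamma fits, the model-averaged Gamma rate.
#' Per-site deltas sum to the per-UCE deltas.
#'
#' @param dataset A [uce_dataset()].
#' @param fit_a,fit_b Two `selon_fit`s of the same model on `dataset`.
#' @param centers Optional named vector of per-UCE center positions; defaults
#'   to the fitted profile centers when `fit_a` is a SelON fit.
#' @return A data frame with columns `uce`, `site`, `delta_lnl`,
#'   `dist_center`, and (GTR+Gamma only) `gamma_rate`.
#' @export
sitewise_support <- function(dataset, fit_a, fit_b, centers = NULL) {
  stopifnot(fit_a$model == fit_b$model)
  if (is.null(centers)) {
    if (fit_a$model != "selon")
      stop("supply per-UCE centers (e.g. from a SelON fit) for non-SelON fits")
    centers <- vapply(fit_a$profiles, `[[`, numeric(1), "center")
  }
  la <- .fit_site_lnl(fit_a, dataset)
  lb <- .fit_site_lnl(fit_b, dataset)
  rates <- if (fit_a$model == "gtr_gamma")
    sitewise_gamma_rates(dataset, fit_a) else NULL
  rows <- lapply(names(dataset$alignments), function(id) {
    l <- ncol(dataset$alignments[[id]])
    d <- data.frame(uce = id, site = seq_len(l),
                    delta_lnl = la[[id]] - lb[[id]],
                    dist_center = abs(seq_len(l) - centers[[id]]))
    if (!is.null(rates)) d$gamma_rate <- rates[[id]]
    d
  })
  do.call(rbind, rows)
}

# per-site log-likelihoods of a fit, as a named list of vectors per UCE
.fit_site_lnl <- function(fit, dataset) {
  tree <- validate_tree(fit$tree, taxa = dataset$taxa)
  if (fit$model == "selon") {
    en <- .selon_engine(dataset, tree, fit$mut, fit$profiles, fit$optima,
                        fit$pop, C = fit$C)
  } else {
    en <- .gtr_engine(dataset, tree, fit$gtr, fit$gamma_cats)
  }
  site_lnl <- .engine_site_lnl(en)
  split(site_lnl, rep(seq_along(en$uce_sites), en$uce_sites)) |>
    setNames(names(dataset$alignments))
}

# ---------------------------------------------------------------------------
# TSV writers for the analysis tables

#' Write a per-UCE topology support table (TSV)
#' @param support A `topology_support` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_support_table <- function(support, path) {
  write.table(support$per_uce, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a trim-window table (TSV; 1-based inclusive plus BED-like columns)
#' @param trims Named list of `trim_result`s (one per UCE).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trim_table <- function(trims, path) {
  df <- data.frame(uce = names(trims),
                   start = vapply(trims, `[[`, integer(1), "start"),
                   end = vapply(trims, `[[`, integer(1), "end"),
                   bed_start = vapply(trims, function(t) t$start - 1L,
                                      integer(1)),
                   bed_end = vapply(trims, `[[`, integer(1), "end"),
                   parsimony = vapply(trims, function(t) as.integer(t$score),
                                      integer(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
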