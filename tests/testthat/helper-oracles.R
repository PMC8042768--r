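# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately naive (enumeration, direct simulation):
# these routines must stay independent of the package's computational paths.

# exhaustive-enumeration site log-likelihood: sums over every assignment of
# states to internal nodes; root frequencies = pi
brute_force_site_lnl <- function(tree, pattern, q, pi) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  nn <- n_tip + tree$Nnode
  st <- pattern[tree$tip.label]
  internal <- (n_tip + 1):nn
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    expm_ref(q * tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asg <- integer(nn)
    asg[internal] <- grid[g, ]
    # missing tips: sum over their states too (probabilities marginalize
    # automatically because rows of P sum to 1; drop those edge factors)
    p <- pi[asg[n_tip + 1]]
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (ch <= n_tip) {
        if (is.na(st[ch])) next  # marginalizes to 1
        p <- p * Ps[[e]][asg[par], st[ch]]
      } else {
        p <- p * Ps[[e]][asg[par], asg[ch]]
      }
      if (p == 0) { ok <- FALSE; break }
    }
    if (ok) tot <- tot + p
  }
  unname(log(tot))
}

# reference matrix exponential by scaling-and-squaring of the Taylor series
# (independent of the package's eigendecomposition path)
expm_ref <- function(A, order = 16L) {
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1e-300, norm(A, "1")))) + 1L)
  A <- A / 2^s
  X <- diag(n)
  term <- diag(n)
  for (k in 1:order) {
    term <- term %*% A / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# brute-force Fitch parsimony: minimum changes over all internal labelings
brute_force_fitch <- function(tree, pattern) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  nn <- n_tip + tree$Nnode
  st <- pattern[tree$tip.label]
  internal <- (n_tip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    asg <- integer(nn)
    asg[internal] <- grid[g, ]
    asg[seq_len(n_tip)] <- st
    changes <- 0
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (ch <= n_tip && is.na(st[ch])) next  # missing: free choice
      a <- asg[par]
      b <- if (ch <= n_tip) st[ch] else asg[ch]
      if (a != b) changes <- changes + 1
    }
    best <- min(best, changes)
  }
  best
}

# forward simulation of the fixation of a single new mutant.
# moran: birth-death events in a population of n_copies = 2 Ne (the process
#   whose fixation probability the model's closed form describes).
# wf: discrete Wright-Fisher generations (binomial resampling).
# s is the mutant's selective advantage: mutant fitness e^s, resident 1.
simulate_fixation <- function(s, ne, n_intro = 1e5,
                              scheme = c("moran", "wf"), seed = 1) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  N <- 2L * ne
  w <- exp(s)
  count <- rep(1L, n_intro)
  if (scheme == "wf") {
    while (any(act <- count > 0L & count < N)) {
      p <- count[act] / N
      psel <- p * w / (p * w + (1 - p))
      count[act] <- rbinom(sum(act), N, psel)
    }
  } else {
    # embedded jump chain of the Moran process: birth proportional to
    # fitness, death uniform, so conditioned on a change the mutant count
    # moves up with constant probability w / (1 + w).  Steps are simulated
    # in vectorized chunks; a chunk's first boundary crossing absorbs the
    # trajectory (later steps in that chunk are discarded).
    p_up <- w / (1 + w)
    K <- 16L
    guard <- 0L
    while (any(act <- count > 0L & count < N) && guard < 1e4L) {
      guard <- guard + 1L
      idx <- which(act)
      nact <- length(idx)
      steps <- ifelse(runif(nact * K) < p_up, 1L, -1L)
      cs <- cumsum(steps)
      base <- c(0L, cs[seq.int(K, nact * K, by = K)])[seq_len(nact)]
      path <- matrix(cs, K, nact) - rep(base, each = K)
      i0 <- count[idx]
      hit_up <- path >= rep(N - i0, each = K)
      hit_dn <- path <= rep(-i0, each = K)
      fu <- max.col(t(hit_up), ties.method = "first")
      fu[colSums(hit_up) == 0L] <- K + 1L
      fd <- max.col(t(hit_dn), ties.method = "first")
      fd[colSums(hit_dn) == 0L] <- K + 1L
      new_count <- i0 + path[K, ]
      new_count[fu < fd] <- N
      new_count[fd < fu] <- 0L
      count[idx] <- new_count
      # grow the chunk as the active set thins (bounded working memory)
      if (nact * K < 4e6 && K < 4096L) K <- K * 4L
    }
  }
  mean(count == N)
}

# random irreducible rate matrix with zero row sums
random_rate_matrix <- function(scale = 1) {
  q <- matrix(runif(16, 0.2, 2) * scale, 4, 4)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  dimnames(q) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  q
}

# random rooted binary tree with n tips labeled t1..tn
random_rooted_tree <- function(n, min_bl = 0.02, max_bl = 0.4) {
  tr <- ape::rtree(n, rooted = TRUE, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# small simulated SelON dataset for optimizer tests
tiny_selon_fixture <- function(n_uces = 2, l = 80, n_taxa = 6, seed = 5,
                               nes = 6) {
  set.seed(seed)
  tr <- random_rooted_tree(n_taxa, 0.03, 0.15)
  mu <- mutation_matrix("UNREST", rates = rep(1, 11))
  pop <- population_config()
  profiles <- lapply(seq_len(n_uces), function(i)
    selection_profile(nes, l / 2, l / 6))
  optima <- lapply(seq_len(n_uces), function(i)
    sample.int(4L, l, replace = TRUE))
  models <- lapply(seq_len(n_uces), function(i)
    selon:::.build_uce_models(l, optima[[i]], mu, profiles[[i]], pop))
  C <- selon:::.mean_rate(models)
  alns <- lapply(seq_len(n_uces), function(i)
    selon:::.simulate_sites(tr, models[[i]]$Q, models[[i]]$pi,
                            models[[i]]$site_q, 1 / C, seed = seed + i))
  ids <- sprintf("u%02d", seq_len(n_uces))
  names(alns) <- ids
  names(profiles) <- names(optima) <- ids
  list(tree = tr, dataset = uce_dataset(alns), mut = mu, pop = pop,
       profiles = profiles, optima = optima, C = C)
}

# alignment matrix from named sequence strings
aln_from_strings <- function(seqs) {
  l <- nchar(seqs[[1]])
  m <- vapply(strsplit(seqs, ""), encode_bases, integer(l))
  m <- if (l == 1L) matrix(m, ncol = 1L) else t(m)
  rownames(m) <- names(seqs)
  m
}
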