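# Global 4x4 mutation-rate matrix M, shared across all UCEs of a dataset.

# order of the 11 free UNREST rates; the G->T rate is pinned at 1 so the
# remaining entries are relative rates
UNREST_RATE_NAMES <- c("AC", "AG", "AT", "CA", "CG", "CT",
                       "GA", "GC", "TA", "TC", "TG")
GTR_RATE_NAMES <- c("AC", "AG", "AT", "CG", "CT")  # GT exchangeability = 1

#' Build a nucleotide mutation-rate matrix
#'
#' Constructs the global 4x4 mutation matrix `M` with off-diagonal rates
#' `mu_ij >= 0` and diagonals `mu_ii = -sum_j mu_ij`, under one of four
#' parameterizations:
#'
#' * `"UNREST"`: the general unrestricted model; 11 free nonnegative rates in
#'   the order AC, AG, AT, CA, CG, CT, GA, GC, TA, TC, TG, with the G to T
#'   rate fixed at 1 so the free rates are relative to it.
#' * `"GTR"`: 5 exchangeabilities (`AC, AG, AT, CG, CT`; `GT = 1`) plus base
#'   frequencies; `mu_ij = s_ij * pi_j`.
#' * `"HKY"`: a transition/transversion ratio `kappa` plus base frequencies.
#' * `"JC"`: no parameters; all off-diagonal rates equal 1.
#'
#' @param flavor One of `"UNREST"`, `"GTR"`, `"HKY"`, `"JC"`.
#' @param rates Numeric vector of free rates (length 11, 5, 1, or 0 by flavor).
#' @param base_freqs Length-4 frequency vector (GTR and HKY only), summing to 1.
#' @return An object of class `selon_mutation` with elements `flavor`, `rates`,
#'   `base_freqs` and the matrix `M` (dimnames A, C, G, T).
#' @examples
#' mutation_matrix("JC")$M
#' mutation_matrix("UNREST", rates = rep(1, 11))$M  # identical to JC
#' @export
mutation_matrix <- function(flavor = c("UNREST", "GTR", "HKY", "JC"),
                            rates = NULL, base_freqs = NULL) {
  flavor <- match.arg(flavor)
  n_free <- c(UNREST = 11L, GTR = 5L, HKY = 1L, JC = 0L)[[flavor]]
  if (is.null(rates)) rates <- numeric(0)
  if (length(rates) != n_free)
    stop(sprintf("flavor %s requires %d free rate(s), got %d",
                 flavor, n_free, length(rates)))
  if (any(rates < 0)) stop("mutation rates must be nonnegative")
  if (flavor %in% c("GTR", "HKY")) {
    if (is.null(base_freqs) || length(base_freqs) != 4)
      stop(sprintf("flavor %s requires 4 base frequencies", flavor))
    if (any(base_freqs < 0) || abs(sum(base_freqs) - 1) > 1e-8)
      stop("base frequencies must be nonnegative and sum to 1")
  } else {
    base_freqs <- NULL
  }

  M <- matrix(0, 4, 4, dimnames = list(NUC_STATES, NUC_STATES))
  if (flavor == "JC") {
    M[] <- 1
  } else if (flavor == "UNREST") {
    names(rates) <- UNREST_RATE_NAMES
    for (nm in UNREST_RATE_NAMES) {
      i <- substr(nm, 1, 1); j <- substr(nm, 2, 2)
      M[i, j] <- rates[[nm]]
    }
    M["G", "T"] <- 1
  } else if (flavor == "GTR") {
    names(rates) <- GTR_RATE_NAMES
    s <- matrix(0, 4, 4, dimnames = list(NUC_STATES, NUC_STATES))
    for (nm in GTR_RATE_NAMES) {
      i <- substr(nm, 1, 1); j <- substr(nm, 2, 2)
      s[i, j] <- s[j, i] <- rates[[nm]]
    }
    s["G", "T"] <- s["T", "G"] <- 1
    M <- s * rep(base_freqs, each = 4)
  } else {  # HKY
    kappa <- rates[[1]]
    transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
    M <- matrix(rep(base_freqs, each = 4), 4, 4,
                dimnames = list(NUC_STATES, NUC_STATES))
    for (r in seq_len(nrow(transitions)))
      M[transitions[r, 1], transitions[r, 2]] <-
        M[transitions[r, 1], transitions[r, 2]] * kappa
  }
  diag(M) <- 0
  diag(M) <- -rowSums(M)
  structure(list(flavor = flavor, rates = rates, base_freqs = base_freqs,
                 M = M),
            class = "selon_mutation")
}

#' @export
print.selon_mutation <- function(x, ...) {
  cat(sprintf("Mutation model (%s)\n", x$flavor))
  print(round(x$M, 4))
  invisible(x)
}
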