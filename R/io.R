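# Dataset input/output: per-UCE FASTA alignments sharing one taxon set,
# FASTA/JSON/TSV writers, and fit serialization.

#' Construct a UCE dataset from alignments
#'
#' @param alignments Named list of alignments; each is either a character
#'   matrix of bases or an integer matrix of state indices (1..4, `NA`
#'   missing), rows named by taxon.
#' @return An object of class `uce_dataset` with elements `alignments`
#'   (integer matrices) and `taxa` (shared ordered taxon set).
#' @export
uce_dataset <- function(alignments) {
  if (length(alignments) == 0) stop("at least one UCE alignment is required")
  if (is.null(names(alignments)) || anyDuplicated(names(alignments)))
    stop("alignments must have unique names (uce ids)")
  alignments <- lapply(alignments, .coerce_alignment)
  taxa <- rownames(alignments[[1]])
  if (length(taxa) < 3) stop("alignments need at least 3 taxa")
  for (id in names(alignments)) {
    a <- alignments[[id]]
    d <- setdiff(taxa, rownames(a))
    e <- setdiff(rownames(a), taxa)
    if (length(d) || length(e))
      stop(sprintf("taxon set mismatch in UCE '%s': missing [%s], extra [%s]",
                   id, paste(d, collapse = ","), paste(e, collapse = ",")))
    alignments[[id]] <- a[taxa, , drop = FALSE]
  }
  structure(list(alignments = alignments, taxa = taxa), class = "uce_dataset")
}

.coerce_alignment <- function(a) {
  if (is.character(a)) {
    m <- matrix(encode_bases(a), nrow(a), ncol(a), dimnames = dimnames(a))
  } else {
    m <- a
    storage.mode(m) <- "integer"
    if (any(!is.na(m) & (m < 1L | m > 4L))) stop("state indices must be 1..4")
  }
  if (is.null(rownames(m))) stop("alignment rows must be named by taxon")
  m
}

#' Read a directory of per-UCE FASTA alignments
#'
#' Each `.fa`/`.fasta` file is one UCE; the UCE id is the file name without
#' its extension.  Sequences are matched case-insensitively, `U` is read as
#' `T`, and gaps plus all IUPAC ambiguity codes become missing.  Every file
#' must contain exactly the same taxon set, and sequences within a file must
#' be aligned (equal length).
#'
#' @param path Directory containing the FASTA files.
#' @return A [uce_dataset()].
#' @export
read_uce_directory <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (length(files) == 0) stop("no FASTA files (*.fa, *.fasta) in ", path)
  alns <- lapply(files, .read_fasta_alignment)
  names(alns) <- sub("\\.(fa|fasta)$", "", basename(files))
  uce_dataset(alns)
}

.read_fasta_alignment <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("not a FASTA file: ", file)
  taxa <- sub("^>\\s*", "", lines[hdr])
  taxa <- sub("\\s.*$", "", taxa)
  starts <- hdr + 1L
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (ends[i] < starts[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  seqs <- gsub("\\s", "", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf("ragged alignment in %s: sequence '%s' has %d sites, expected %d",
                 basename(file), taxa[bad], lens[bad], lens[1]))
  }
  m <- t(vapply(strsplit(seqs, ""), encode_bases, integer(lens[1])))
  if (lens[1] == 1L) m <- matrix(m, ncol = 1L)
  rownames(m) <- taxa
  m
}

#' Write a UCE dataset as per-UCE FASTA files
#'
#' @param dataset A [uce_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_uce_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "uce_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(dataset$alignments), function(id) {
    a <- dataset$alignments[[id]]
    path <- file.path(dir, paste0(id, ".fasta"))
    con <- file(path, "w")
    on.exit(close(con))
    for (tx in rownames(a)) {
      writeLines(paste0(">", tx), con)
      writeLines(paste(decode_bases(a[tx, ]), collapse = ""), con)
    }
    path
  }, character(1))
  invisible(paths)
}

#' Number of sites per UCE / in total
#' @param dataset A [uce_dataset()].
#' @return Named integer vector of per-UCE lengths.
#' @export
uce_lengths <- function(dataset) {
  vapply(dataset$alignments, ncol, integer(1))
}

#' @export
print.uce_dataset <- function(x, ...) {
  cat(sprintf("UCE dataset: %d loci, %d taxa, %d total sites\n",
              length(x$alignments), length(x$taxa), sum(uce_lengths(x))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Fit serialization (JSON): enough to rebuild the fitted model exactly.

#' Serialize a fit to JSON
#'
#' @param fit A `selon_fit` (from [fit_selon()] or [fit_gtr_gamma()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "selon_fit"))
  payload <- list(
    model = fit$model,
    log_likelihood = fit$lnL,
    per_uce_lnL = as.list(fit$per_uce_lnL),
    n_parameters = fit$k,
    aicc = fit$aicc,
    n_taxa = fit$n_taxa,
    n_sites = fit$n_sites,
    seed = fit$seed,
    lnl_trace = as.list(fit$trace),
    tree = ape::write.tree(fit$tree)
  )
  if (fit$model == "selon") {
    payload$scale <- fit$C
    payload$pop <- list(ne = fit$pop$ne, ploidy = fit$pop$ploidy)
    payload$mutation <- list(flavor = fit$mut$flavor,
                             rates = as.list(fit$mut$rates))
    payload$profiles <- lapply(fit$profiles, function(p)
      list(nes_max = p$nes_max, center = p$center, width = p$width))
    payload$optima <- lapply(fit$optima, function(o)
      paste(NUC_STATES[o], collapse = ""))
  } else {
    payload$gamma_cats <- fit$gamma_cats
    payload$partitions <- lapply(fit$gtr, function(p)
      list(exchangeabilities = as.list(p$exch), base_freqs = as.list(p$bf),
           alpha = p$alpha))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Rebuild a fit object from JSON
#'
#' @param path Path written by [write_fit_json()].
#' @return A `selon_fit` object.
#' @export
read_fit_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  tree <- ape::read.tree(text = p$tree)
  fit <- list(model = p$model, lnL = p$log_likelihood,
              per_uce_lnL = unlist(p$per_uce_lnL), k = p$n_parameters,
              aicc = p$aicc, n_taxa = p$n_taxa, n_sites = p$n_sites,
              seed = p$seed, trace = unlist(p$lnl_trace), tree = tree)
  if (p$model == "selon") {
    fit$C <- p$scale
    fit$pop <- population_config(p$pop$ne, p$pop$ploidy)
    fit$mut <- mutation_matrix(p$mutation$flavor,
                               rates = unlist(p$mutation$rates))
    fit$profiles <- lapply(p$profiles, function(x)
      selection_profile(x$nes_max, x$center, x$width))
    fit$optima <- lapply(p$optima, function(s)
      encode_bases(strsplit(s, "")[[1]]))
    names(fit$profiles) <- names(fit$optima) <- names(p$profiles)
  } else {
    fit$gamma_cats <- p$gamma_cats
    fit$gtr <- lapply(p$partitions, function(x)
      list(exch = unlist(x$exchangeabilities), bf = unlist(x$base_freqs),
           alpha = x$alpha))
    names(fit$gtr) <- names(p$partitions)
  }
  class(fit) <- "selon_fit"
  fit
}
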