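#' Construct a sequence dataset
#'
#' The input of the OOPS motif-finding problem: a set of n sequences over
#' a common alphabet (lengths may differ; simulated datasets use a common
#' length L).
#'
#' @param sequences character vector of sequences (case-folded to upper).
#' @param alphabet an `mb_alphabet`; defaults to DNA.
#' @param names optional per-sequence identifiers (FASTA headers).
#' @return An object of class `mb_dataset` with fields `sequences`,
#'   `lengths`, `alphabet`, `names`.
#' @export
sequence_dataset <- function(sequences, alphabet = dna_alphabet(),
                             names = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 1L) stop("dataset needs at least one sequence")
  if (is.null(names)) names <- paste0("seq", seq_along(sequences))
  bad <- regexpr(sprintf("[^%s]", paste(alphabet$symbols, collapse = "")),
                 sequences)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in record '%s' at offset %d",
                 substr(sequences[i], bad[i], bad[i]), names[i], bad[i]))
  }
  structure(list(sequences = sequences, lengths = nchar(sequences),
                 alphabet = alphabet, names = names),
            class = "mb_dataset")
}

#' @export
print.mb_dataset <- function(x, ...) {
  cat(sprintf("Sequence dataset: n = %d, lengths %s, alphabet {%s}\n",
              length(x$sequences),
              if (length(unique(x$lengths)) == 1L)
                sprintf("L = %d", x$lengths[1L])
              else sprintf("%d-%d", min(x$lengths), max(x$lengths)),
              paste(x$alphabet$symbols, collapse = ",")))
  invisible(x)
}

# sequences as 0-based integer vectors for the compiled search routines
encode_dataset <- function(dataset) {
  lapply(strsplit(dataset$sequences, "", fixed = TRUE), function(ch)
    match(ch, dataset$alphabet$symbols) - 1L)
}

check_positions <- function(dataset, positions, W) {
  positions <- as.integer(positions)
  if (length(positions) != length(dataset$sequences))
    stop("need exactly one position per sequence")
  if (any(positions < 0L) || any(positions > dataset$lengths - W))
    stop("site offset out of range (0-based, 0 <= p <= length - W)")
  positions
}

# count matrix of the W-mers at the given 0-based offsets
alignment_counts <- function(dataset, positions, W) {
  A <- dataset$alphabet
  n <- length(dataset$sequences)
  cnt <- matrix(0L, W, A$size)
  for (i in seq_len(n)) {
    ch <- strsplit(substr(dataset$sequences[i], positions[i] + 1L,
                          positions[i] + W), "", fixed = TRUE)[[1L]]
    k <- match(ch, A$symbols)
    for (j in seq_len(W)) cnt[j, k[j]] <- cnt[j, k[j]] + 1L
  }
  make_count_matrix(cnt, n, A)
}

new_motif_hit <- function(dataset, positions, W, g, finder,
                          seed = NA_integer_, restarts_used = NA_integer_) {
  counts <- alignment_counts(dataset, positions, W)
  pwm <- counts_to_pwm(counts, pseudocount = 0)
  structure(list(positions = as.integer(positions), counts = counts,
                 pwm = pwm,
                 information_content = information_content(pwm, g),
                 finder = finder, seed = seed,
                 restarts_used = restarts_used),
            class = "mb_motif_hit")
}

#' @export
print.mb_motif_hit <- function(x, ...) {
  cat(sprintf("Motif hit [%s]: W = %d, n = %d, D(f,g) = %.4f bits\n",
              x$finder, x$counts$width, x$counts$n, x$information_content))
  cat("  consensus:",
      paste(x$pwm$alphabet$symbols[max.col(x$pwm$freqs, "first")],
            collapse = ""), "\n")
  cat("  sites (0-based):", paste(x$positions, collapse = " "), "\n")
  invisible(x)
}

#' Information content of a specified alignment
#'
#' Builds the count matrix from the width-W sites at the given 0-based
#' offsets (one per sequence) and returns its raw-frequency information
#' content in bits relative to g.
#'
#' @param dataset an `mb_dataset`.
#' @param positions integer vector of 0-based start offsets, one per
#'   sequence; site i occupies `[positions[i], positions[i] + W)`.
#' @param W motif width.
#' @param g an `mb_background` over the dataset's alphabet.
#' @return Numeric, bits.
#' @export
score_alignment <- function(dataset, positions, W, g) {
  W <- as.integer(W)
  positions <- check_positions(dataset, positions, W)
  counts <- alignment_counts(dataset, positions, W)
  information_content(counts_to_pwm(counts, 0), g)
}

#' Exhaustive OOPS motif search
#'
#' The ideal finder: scores all `prod(lengths - W + 1)` one-site-per-
#' sequence alignments and returns the global optimum (ties broken by the
#' lexicographically smallest position tuple).  Feasible only when the
#' candidate space has at most `1e6` tuples; serves as the oracle for
#' [gibbs_site_sampler()].
#'
#' @inheritParams score_alignment
#' @return An `mb_motif_hit`.
#' @export
exhaustive_find <- function(dataset, W, g) {
  W <- as.integer(W)
  if (any(dataset$lengths < W)) stop("every sequence must be at least W long")
  space <- prod(dataset$lengths - W + 1)
  if (space > 1e6)
    stop("search space too large for exhaustive_find (> 1e6 alignments)")
  res <- cpp_exhaustive(encode_dataset(dataset), W, g$probs)
  new_motif_hit(dataset, res$positions, W, g, finder = "exhaustive")
}

#' Gibbs site sampler for OOPS motif finding
#'
#' Classic site-sampler MCMC: per restart, start positions are drawn at
#' random; then, holding out one sequence at a time in round-robin order,
#' the predictive motif model is rebuilt from the remaining n-1 sites
#' (pseudocount `g_k` per column) and the held-out sequence's site is
#' resampled with probability proportional to the model/background odds
#' of the W-mer at each offset.  The best-scoring configuration (by raw
#' information content) seen across all restarts and iterations is
#' returned; ties break toward the lexicographically smallest position
#' tuple.  Fully reproducible given `seed` (an internal RNG stream is
#' used; R's RNG state is untouched).
#'
#' @inheritParams score_alignment
#' @param restarts number of random restarts, >= 1.
#' @param iterations site updates per restart; default `200 * n`.
#' @param seed integer seed for the sampler's RNG stream.
#' @return An `mb_motif_hit`.
#' @export
gibbs_site_sampler <- function(dataset, W, g, restarts = 20L,
                               iterations = NULL, seed = 1L) {
  W <- as.integer(W)
  if (any(dataset$lengths < W)) stop("every sequence must be at least W long")
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("restarts must be at least 1")
  n <- length(dataset$sequences)
  if (is.null(iterations)) iterations <- 200L * n
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be at least 1")
  res <- cpp_gibbs(encode_dataset(dataset), W, g$probs, restarts,
                   iterations, as.double(seed))
  new_motif_hit(dataset, res$positions, W, g, finder = "gibbs",
                seed = as.integer(seed), restarts_used = restarts)
}
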