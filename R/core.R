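#' Construct an alphabet
#'
#' An ordered residue alphabet. Motif and background distributions are
#' indexed by the order given here; for DNA the conventional order is
#' A, C, G, T (see [dna_alphabet()]).
#'
#' @param symbols character vector of unique single-character symbols,
#'   length at least 2.
#' @return An object of class `mb_alphabet` with fields `symbols` and `size`.
#' @export
#' @examples
#' make_alphabet(c("A", "C", "G", "T"))
make_alphabet <- function(symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L)
    stop("an alphabet needs at least 2 symbols")
  if (anyDuplicated(symbols))
    stop("alphabet symbols must be unique")
  if (any(nchar(symbols) != 1L))
    stop("alphabet symbols must be single characters")
  structure(list(symbols = symbols, size = length(symbols)),
            class = "mb_alphabet")
}

#' The DNA alphabet A, C, G, T
#'
#' @return An `mb_alphabet` of size 4 in the order A, C, G, T.
#' @export
dna_alphabet <- function() make_alphabet(c("A", "C", "G", "T"))

#' @export
print.mb_alphabet <- function(x, ...) {
  cat("Alphabet:", paste(x$symbols, collapse = ","),
      sprintf("(|A| = %d)\n", x$size))
  invisible(x)
}

same_alphabet <- function(a, b) {
  identical(a$symbols, b$symbols)
}

#' Construct a background distribution
#'
#' The per-position categorical distribution g from which null sequences
#' are drawn i.i.d.  All probabilities must be strictly positive so that
#' the Kullback-Leibler divergence from any motif column is finite.
#'
#' @param probs numeric vector of probabilities, one per alphabet symbol,
#'   all > 0 and summing to 1 (tolerance 1e-12).
#' @param alphabet an [make_alphabet()] object; defaults to DNA.
#' @return An object of class `mb_background`.
#' @export
#' @examples
#' make_background(c(0.3, 0.2, 0.2, 0.3))
make_background <- function(probs, alphabet = dna_alphabet()) {
  probs <- as.numeric(probs)
  if (length(probs) != alphabet$size)
    stop("background needs one probability per alphabet symbol")
  if (any(probs <= 0))
    stop("all background probabilities must be strictly positive")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("background probabilities must sum to 1 (within 1e-12)")
  structure(list(probs = probs, alphabet = alphabet),
            class = "mb_background")
}

#' Uniform background over an alphabet
#'
#' @inheritParams make_background
#' @return An `mb_background` with equal probabilities.
#' @export
uniform_background <- function(alphabet = dna_alphabet()) {
  make_background(rep(1 / alphabet$size, alphabet$size), alphabet)
}

#' @export
print.mb_background <- function(x, ...) {
  cat("Background g:",
      paste(sprintf("%s=%.4g", x$alphabet$symbols, x$probs), collapse = " "),
      "\n")
  invisible(x)
}

#' Construct a position weight matrix (PWM)
#'
#' A motif model f: one categorical distribution over the alphabet per
#' motif column.  Rows of `freqs` are motif columns (positions), columns
#' are alphabet symbols.
#'
#' @param freqs numeric matrix, W rows by |A| columns; every row sums to 1
#'   (tolerance 1e-12) and all entries lie in `[0, 1]`.
#' @param alphabet an [make_alphabet()] object; defaults to DNA.
#' @return An object of class `mb_pwm` with fields `width`, `freqs`,
#'   `alphabet`.
#' @export
#' @examples
#' make_pwm(rbind(c(1, 0, 0, 0), c(0.5, 0.5, 0, 0)))
make_pwm <- function(freqs, alphabet = dna_alphabet()) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != alphabet$size)
    stop("PWM needs one column per alphabet symbol")
  if (nrow(freqs) < 1L)
    stop("PWM width must be at least 1")
  if (any(freqs < 0) || any(freqs > 1))
    stop("PWM entries must lie in [0, 1]")
  if (any(abs(rowSums(freqs) - 1) > 1e-12))
    stop("every PWM position must sum to 1 (within 1e-12)")
  colnames(freqs) <- alphabet$symbols
  structure(list(width = nrow(freqs), freqs = freqs, alphabet = alphabet),
            class = "mb_pwm")
}

#' @export
print.mb_pwm <- function(x, ...) {
  cat(sprintf("PWM, width %d over {%s}\n", x$width,
              paste(x$alphabet$symbols, collapse = ",")))
  print(round(x$freqs, 4))
  invisible(x)
}

#' Construct a motif count matrix
#'
#' The per-column symbol counts of an ungapped alignment of n sites of
#' width W (one site per sequence in the OOPS setting).
#'
#' @param counts integer matrix, W rows by |A| columns of nonnegative
#'   counts; every row must sum to `n`.
#' @param n integer, the number of aligned sites.
#' @param alphabet an [make_alphabet()] object; defaults to DNA.
#' @return An object of class `mb_count_matrix`.
#' @export
make_count_matrix <- function(counts, n, alphabet = dna_alphabet()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  if (ncol(counts) != alphabet$size)
    stop("count matrix needs one column per alphabet symbol")
  if (any(counts < 0L)) stop("counts must be nonnegative")
  if (any(rowSums(counts) != n))
    stop("every count-matrix row must sum to n")
  colnames(counts) <- alphabet$symbols
  structure(list(width = nrow(counts), counts = counts, n = n,
                 alphabet = alphabet),
            class = "mb_count_matrix")
}

#' Convert a count matrix to a PWM
#'
#' Relative frequencies with an optional additive pseudocount:
#' `f[j,k] = (c[j,k] + pseudocount) / (n + |A| * pseudocount)`.
#' The default pseudocount 0 scores the raw alignment, which is how
#' finder output is turned into the motif model f whose information
#' content is reported.
#'
#' @param counts an [make_count_matrix()] object.
#' @param pseudocount nonnegative number added to every cell.
#' @return An `mb_pwm`.
#' @export
#' @examples
#' cm <- make_count_matrix(rbind(c(2L, 0L, 0L, 0L)), n = 2)
#' counts_to_pwm(cm)                 # (1, 0, 0, 0)
#' counts_to_pwm(cm, pseudocount = 1) # (0.5, 1/6, 1/6, 1/6)
counts_to_pwm <- function(counts, pseudocount = 0) {
  if (!inherits(counts, "mb_count_matrix"))
    stop("counts must be an mb_count_matrix")
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop("pseudocount must be nonnegative")
  f <- (counts$counts + pseudocount) /
    (counts$n + counts$alphabet$size * pseudocount)
  # guard against rounding drift before validation
  f <- f / rowSums(f)
  make_pwm(f, counts$alphabet)
}

#' Information content of a motif (KL divergence from the background)
#'
#' The strength of a motif is the Kullback-Leibler divergence, in bits,
#' between its PWM columns and the background, summed over columns:
#' \deqn{D(f, g) = \sum_{j=1}^{W} \sum_{k} f_{jk} \log_2 (f_{jk} / g_k)}
#' with the convention 0 log 0 = 0.  D is nonnegative, additive over
#' columns, and for a uniform background over |A| = 4 bounded above by
#' 2W bits (attained only by point-mass columns).
#'
#' @param f an `mb_pwm` motif model.
#' @param g an `mb_background` over the same alphabet.
#' @return Nonnegative numeric scalar, in bits.
#' @export
#' @examples
#' g <- uniform_background()
#' information_content(make_pwm(rbind(c(1, 0, 0, 0))), g)  # 2 bits
information_content <- function(f, g) {
  if (!inherits(f, "mb_pwm")) stop("f must be an mb_pwm")
  if (!inherits(g, "mb_background")) stop("g must be an mb_background")
  if (!same_alphabet(f$alphabet, g$alphabet))
    stop("PWM and background are over different alphabets")
  gm <- matrix(g$probs, nrow = f$width, ncol = g$alphabet$size, byrow = TRUE)
  term <- f$freqs * log2(f$freqs / gm)
  term[f$freqs == 0] <- 0
  max(sum(term), 0)
}

# (p/n) log2((p/n)/q) with 0 log 0 = 0, vectorised over matching shapes
xlog2_ratio <- function(p, q) {
  out <- p * log2(p / q)
  out[p == 0] <- 0
  out
}
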