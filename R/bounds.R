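#' @name bounds
#' @title Large-deviations design bounds for chance motifs
#'
#' @description
#' Closed-form results linking the OOPS motif-finding problem parameters
#' (n sequences of length L, motif width W, alphabet size |A|) to the
#' strength of motifs that arise by chance in background-only sequences:
#'
#' * [sanov_pvalue_bound()] - a Sanov (method-of-types) upper bound on the
#'   p-value of a motif of strength D:
#'   `p <= (n+1)^(W(|A|-1)) * 2^(-n D)`.
#' * [expected_fp_count()] - the expected number of chance motifs of
#'   strength at least D among the `(L-W+1)^n` candidate alignments an
#'   ideal OOPS finder implicitly tests.
#' * [max_sequence_length()] - the sequence length below which fewer than
#'   one chance motif of strength D is expected:
#'   `L < (W-1) + 2^D * (n+1)^(-W(|A|-1)/n)`.
#' * [fp_strength_threshold()] - the strength threshold D* above which
#'   fewer than one chance motif is expected:
#'   `D* <= log2(L) + (|A|-1) W log2(n+1) / n`.
#' * [min_sequences()] - the smallest n whose D* falls at or below a
#'   target strength.
#'
#' All bounds are evaluated in log2 space: `(n+1)^(W(|A|-1))` overflows
#' double precision already for moderate W and n (about 2^300 at W = 15,
#' n = 100), while its log2 is perfectly tame.
NULL

check_design <- function(n, W, alphabet_size, L = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (W < 1) stop("W must be at least 1")
  if (alphabet_size < 2) stop("alphabet size must be at least 2")
  if (!is.null(L) && L < W) stop("L must be at least W")
  invisible(TRUE)
}

new_bound <- function(log2_value, clipped = FALSE) {
  structure(list(value = if (clipped) 1 else 2^log2_value,
                 log2_value = if (clipped) 0 else log2_value,
                 clipped = clipped),
            class = "mb_bound")
}

#' @export
print.mb_bound <- function(x, ...) {
  cat(sprintf("bound value %.6g (log2 = %.6g)%s\n", x$value, x$log2_value,
              if (isTRUE(x$clipped)) " [clipped at 1]" else ""))
  invisible(x)
}

#' Sanov upper bound on the p-value of a motif
#'
#' Upper bound on the probability that an alignment of n i.i.d. background
#' sites of width W has information content at least D bits:
#' `(n+1)^(W(|A|-1)) * 2^(-n D)`.  The raw bound can exceed 1; the
#' returned probability is clipped at 1 with an explicit flag.
#'
#' @param n number of aligned sites (sequences).
#' @param W motif width.
#' @param alphabet_size alphabet cardinality |A| (4 for DNA).
#' @param D motif strength in bits, nonnegative.
#' @return An `mb_bound`: list with `value` (clipped to `[0,1]`),
#'   `log2_value`, and `clipped`.
#' @seealso [motif_pvalue_exact()] for the accurate p-value this bounds.
#' @export
#' @examples
#' sanov_pvalue_bound(10, 10, 4, 20.344079)  # ~2^-99.66
sanov_pvalue_bound <- function(n, W, alphabet_size = 4, D) {
  check_design(n, W, alphabet_size)
  if (D < 0) stop("D must be nonnegative")
  lb <- W * (alphabet_size - 1) * log2(n + 1) - n * D
  if (lb > 0) new_bound(lb, clipped = TRUE) else new_bound(lb)
}

#' Expected number of chance motifs of strength at least D
#'
#' An ideal OOPS finder on n sequences of length L implicitly tests all
#' `(L-W+1)^n` alignments; combining that candidate count with the Sanov
#' p-value bound gives the expected number of chance motifs of strength
#' at least D bits.  Computed as
#' `2^(n log2(L-W+1) + W(|A|-1) log2(n+1) - n D)` (the un-clipped bound).
#'
#' @param L sequence length, at least W.
#' @inheritParams sanov_pvalue_bound
#' @return An `mb_bound` (never clipped; `value` may overflow to `Inf`
#'   for weak motifs in large designs, `log2_value` never does).
#' @export
#' @examples
#' expected_fp_count(1000, 30, 10, 4, 14.91998)  # ~1: D at threshold
expected_fp_count <- function(L, n, W, alphabet_size = 4, D) {
  check_design(n, W, alphabet_size, L)
  if (D < 0) stop("D must be nonnegative")
  lb <- n * log2(L - W + 1) + W * (alphabet_size - 1) * log2(n + 1) - n * D
  new_bound(lb)
}

#' Maximum sequence length with fewer than one expected chance motif
#'
#' The length bound `(W-1) + 2^D * (n+1)^(-W(|A|-1)/n)`: for any integer
#' sequence length L strictly below this value, the expected number of
#' chance motifs of strength at least D is below 1.  Monotone increasing
#' in D.
#'
#' @inheritParams sanov_pvalue_bound
#' @return Numeric length bound (may be `Inf` for very strong motifs).
#' @export
#' @examples
#' max_sequence_length(10, 10, 4, 20.344079)  # ~1009
max_sequence_length <- function(n, W, alphabet_size = 4, D) {
  check_design(n, W, alphabet_size)
  if (D < 0) stop("D must be nonnegative")
  (W - 1) + 2^(D - W * (alphabet_size - 1) * log2(n + 1) / n)
}

#' Strength threshold D* for chance motifs
#'
#' The information-content threshold above which fewer than one chance
#' motif is expected in a dataset of n sequences of length L, for motifs
#' of width W.  Two variants are provided:
#'
#' * `"printed"` (default): `log2(L) + (|A|-1) W log2(n+1) / n`, the
#'   headline closed form.
#' * `"exact"`: `log2(L-W+1) + (|A|-1) W log2(n+1) / n`, the algebraic
#'   inverse of [max_sequence_length()], for which
#'   [expected_fp_count()] at D = D* equals exactly 1.
#'
#' D* increases with L and W and decreases with n (with diminishing
#' returns as n grows; the n -> Inf limit is `log2 L`).
#'
#' @param L sequence length, at least W.
#' @inheritParams sanov_pvalue_bound
#' @param variant `"printed"` or `"exact"` (see Details).
#' @return Numeric threshold in bits.
#' @export
#' @examples
#' fp_strength_threshold(1000, 30, 10)  # 14.91998 bits
fp_strength_threshold <- function(L, n, W, alphabet_size = 4,
                                  variant = c("printed", "exact")) {
  variant <- match.arg(variant)
  check_design(n, W, alphabet_size, L)
  lterm <- if (variant == "printed") log2(L) else log2(L - W + 1)
  lterm + (alphabet_size - 1) * W * log2(n + 1) / n
}

#' Smallest number of sequences achieving a target strength threshold
#'
#' Finds the smallest n <= `n_max` for which
#' `fp_strength_threshold(L, n, W, ...) <= D_target`, exploiting the
#' monotone decrease of the threshold in n (bisection).  Returns
#' `NA_integer_` when no such n exists: the n -> Inf limit of the
#' threshold is `log2 L` (printed variant), so targets below that are
#' unreachable by adding sequences alone.
#'
#' @param L sequence length, at least W.
#' @param W motif width.
#' @param alphabet_size alphabet cardinality |A|.
#' @param D_target target strength threshold in bits, > 0.
#' @param n_max largest n considered.
#' @param variant threshold variant, as in [fp_strength_threshold()].
#' @return Integer n, or `NA_integer_`.
#' @export
#' @examples
#' min_sequences(100, 15, 4, D_target = 10.20)  # TATA-box scenario
min_sequences <- function(L, W, alphabet_size = 4, D_target,
                          n_max = 100000L, variant = c("printed", "exact")) {
  variant <- match.arg(variant)
  if (D_target <= 0) stop("D_target must be positive")
  check_design(1, W, alphabet_size, L)
  thr <- function(n) fp_strength_threshold(L, n, W, alphabet_size, variant)
  if (thr(1) <= D_target) return(1L)
  if (thr(n_max) > D_target) return(NA_integer_)
  lo <- 1L; hi <- as.integer(n_max)     # thr(lo) > target >= thr(hi)
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (thr(mid) <= D_target) hi <- mid else lo <- mid
  }
  hi
}
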