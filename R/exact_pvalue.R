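#' @name exact_pvalue
#' @title Exact null distribution of motif information content
#'
#' @description
#' The accurate (non-bound) p-value of a motif's information content under
#' the null of i.i.d. background sequences.  A single alignment column of
#' n sites drawn from g has an empirical composition c (counts summing to
#' n) with multinomial probability, and contributes divergence
#' `sum_k (c_k/n) log2((c_k/n)/g_k)` bits.  [column_divergence_pmf()]
#' enumerates all `C(n+|A|-1, |A|-1)` compositions exactly and bins their
#' divergences on a fixed grid; [motif_pvalue_exact()] convolves that
#' one-column distribution W times (columns of a null alignment are
#' i.i.d.) and takes the upper tail.  [motif_pvalue_bruteforce()] is an
#' independent oracle that enumerates every possible alignment outright.
NULL

# all nonnegative integer k-vectors summing to n, lexicographic rows
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  parts <- lapply(0:n, function(c1) cbind(c1, compositions(n - c1, k - 1L)))
  out <- do.call(rbind, parts)
  dimnames(out) <- NULL
  out
}

new_divergence_pmf <- function(mass, resolution, n, width, background) {
  structure(list(resolution = resolution, mass = mass, n = n,
                 width = width, background = background),
            class = "mb_divergence_pmf")
}

#' @export
print.mb_divergence_pmf <- function(x, ...) {
  nz <- which(x$mass > 0)
  cat(sprintf(
    "Divergence PMF: n = %d, %d column(s), resolution %g bits, %d atoms on [%.4g, %.4g]\n",
    x$n, x$width, x$resolution, length(nz),
    (min(nz) - 1) * x$resolution, (max(nz) - 1) * x$resolution))
  invisible(x)
}

#' Null distribution of single-column divergence
#'
#' Exact probability mass function of the information content of one
#' alignment column of n sites drawn i.i.d. from the background g,
#' discretised on a grid of the given resolution (values rounded half-up
#' to the nearest grid point).
#'
#' @param n number of aligned sites.
#' @param g an `mb_background`.
#' @param resolution grid bin width in bits, > 0.
#' @return An `mb_divergence_pmf`: `mass[i]` is the probability of grid
#'   value `(i-1) * resolution`; masses sum to 1.
#' @export
#' @examples
#' column_divergence_pmf(2, uniform_background())  # {1 bit: 0.75, 2 bits: 0.25}
column_divergence_pmf <- function(n, g, resolution = 1e-3) {
  if (!inherits(g, "mb_background")) stop("g must be an mb_background")
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  if (resolution <= 0) stop("resolution must be positive")
  A <- g$alphabet$size
  comp <- compositions(n, A)
  logp <- lfactorial(n) - rowSums(lfactorial(comp)) +
    as.vector(comp %*% log(g$probs))
  gm <- matrix(g$probs, nrow = nrow(comp), ncol = A, byrow = TRUE)
  div <- rowSums(xlog2_ratio(comp / n, gm))
  idx <- as.integer(floor(div / resolution + 0.5))
  mass <- numeric(max(idx) + 1L)
  agg <- rowsum(exp(logp), idx)
  mass[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  new_divergence_pmf(mass, resolution, n, 1L, g)
}

# open (full) convolution of two gridded pmfs sharing a grid origin at 0
convolve_mass <- function(a, b) {
  nz <- which(b > 0)
  out <- numeric(length(a) + length(b) - 1L)
  la <- length(a)
  for (j in nz) {
    rng <- j:(j + la - 1L)
    out[rng] <- out[rng] + b[j] * a
  }
  out
}

#' Convolve a column divergence PMF across motif columns
#'
#' Columns of a null alignment are independent, so the W-column strength
#' distribution is the W-fold convolution of the single-column PMF on the
#' shared grid.
#'
#' @param pmf an `mb_divergence_pmf` (typically width 1).
#' @param W number of columns in the motif.
#' @return An `mb_divergence_pmf` of width `pmf$width * W`.
#' @export
convolve_divergence_pmf <- function(pmf, W) {
  if (!inherits(pmf, "mb_divergence_pmf")) stop("pmf must be an mb_divergence_pmf")
  W <- as.integer(W)
  if (W < 1L) stop("W must be at least 1")
  acc <- pmf$mass
  if (W > 1L) for (i in 2:W) acc <- convolve_mass(acc, pmf$mass)
  new_divergence_pmf(acc, pmf$resolution, pmf$n, pmf$width * W,
                     pmf$background)
}

#' Exact p-value of motif information content
#'
#' Probability, under the null of n i.i.d. background sites per column
#' and W independent columns, that an alignment's information content is
#' at least D bits.  Computed by exact composition enumeration per column
#' and direct convolution across columns; the upper tail is cut at
#' `D - W * resolution / 2`, so discretisation errs toward larger
#' (conservative) p-values.  The worst-case tail-boundary error is
#' `W * resolution` in the D direction.
#'
#' @inheritParams column_divergence_pmf
#' @param W motif width.
#' @param D strength threshold in bits, nonnegative.
#' @return Probability in `[0, 1]`, nonincreasing in D; 1 at D = 0.
#' @seealso [sanov_pvalue_bound()] for the closed-form upper bound,
#'   [motif_pvalue_bruteforce()] for the enumeration oracle.
#' @export
#' @examples
#' motif_pvalue_exact(2, 1, uniform_background(), D = 2)  # 0.25
motif_pvalue_exact <- function(n, W, g, D, resolution = 1e-3) {
  if (D < 0) stop("D must be nonnegative")
  W <- as.integer(W)
  if (W < 1L) stop("W must be at least 1")
  pmf <- convolve_divergence_pmf(column_divergence_pmf(n, g, resolution), W)
  vals <- (seq_along(pmf$mass) - 1) * resolution
  p <- sum(pmf$mass[vals >= D - W * resolution / 2 - 1e-12])
  min(max(p, 0), 1)
}

#' Brute-force p-value of motif information content
#'
#' Independent oracle for [motif_pvalue_exact()]: enumerates every one of
#' the `|A|^(n W)` possible n-by-W alignments of background symbols,
#' computes each alignment's information content exactly, and returns the
#' probability-weighted mass of alignments with divergence at least D
#' (comparison tolerance 1e-12).  Only feasible for tiny instances.
#'
#' @inheritParams motif_pvalue_exact
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' motif_pvalue_bruteforce(2, 1, uniform_background(), D = 1.5)  # 0.25
motif_pvalue_bruteforce <- function(n, W, g, D) {
  if (!inherits(g, "mb_background")) stop("g must be an mb_background")
  n <- as.integer(n); W <- as.integer(W)
  if (n < 1L || W < 1L) stop("n and W must be at least 1")
  A <- g$alphabet$size
  nW <- n * W
  total <- A^nW
  if (total > 1e7)
    stop("instance too large for brute force (|A|^(n*W) > 1e7)")
  logg <- log(g$probs)
  tail_mass <- 0
  chunk <- 65536
  for (start in seq(0, total - 1, by = chunk)) {
    ids <- start:min(start + chunk - 1, total - 1)
    m <- matrix(0L, length(ids), nW)
    tmp <- ids
    for (t in seq_len(nW)) {
      m[, t] <- as.integer(tmp %% A)
      tmp <- tmp %/% A
    }
    logp <- rowSums(matrix(logg[m + 1L], nrow = length(ids)))
    div <- numeric(length(ids))
    for (j in seq_len(W)) {
      cols <- ((j - 1L) * n + 1L):(j * n)
      for (k in 0:(A - 1)) {
        ck <- rowSums(m[, cols, drop = FALSE] == k)
        div <- div + xlog2_ratio(ck / n, g$probs[k + 1L])
      }
    }
    tail_mass <- tail_mass + sum(exp(logp)[div >= D - 1e-12])
  }
  min(max(tail_mass, 0), 1)
}
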