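---
title: "Design bounds for false-positive motifs in OOPS motif finding"
author: "motifbounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design bounds for false-positive motifs in OOPS motif finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifbounds)
```

## The problem

De novo motif finders routinely report strong-looking motifs even when
fed random DNA.  In the one-occurrence-per-sequence (OOPS) setting — n
sequences of length L, exactly one site of width W per sequence — an
ideal finder implicitly scores all $(L-W+1)^n$ alignments and keeps the
one whose position weight matrix (PWM) $f$ diverges most from the
background $g$, as measured by the information content

$$D(f,g) = \sum_{j=1}^{W} \sum_{k \in A} f_{jk} \log_2 \frac{f_{jk}}{g_k}
\quad \text{(bits)},$$

with the usual $0\log 0 = 0$ convention (so $D$ is finite whenever every
$g_k > 0$, which the `mb_background` constructor enforces).  With so many
candidates, some alignment of pure background sites will diverge
substantially from $g$ by chance alone.  `motifbounds` quantifies how
strong those chance ("false positive") motifs are expected to be, as an
explicit function of $(n, L, W, |A|)$, and validates the prediction by
simulation with its own OOPS finder.

## The model and its bounds

A single alignment column of $n$ sites drawn i.i.d. from $g$ has an
empirical composition whose probability is multinomial.  The method of
types (Sanov's theorem) bounds the probability that a W-column alignment
reaches strength $D$:

$$\Pr\{D(f,g) \ge D\} \;\le\; (n+1)^{W(|A|-1)}\, 2^{-nD},$$

implemented by `sanov_pvalue_bound()`.  The bound is evaluated in
log2 space — $(n+1)^{W(|A|-1)}$ is about $2^{300}$ already at $W = 15$,
$n = 100$ — and clipped at 1 with an explicit flag, since the raw bound
exceeds 1 for weak motifs.  The bound is provably loose; the package
therefore also computes the *accurate* p-value (below) for comparison.

Multiplying by the $(L-W+1)^n$ candidate alignments gives the expected
number of chance motifs at or above strength $D$
(`expected_fp_count()`), and solving "expected count = 1" in closed form
gives two design results:

* `max_sequence_length()` — sequences shorter than
  $(W-1) + 2^{D}(n+1)^{-W(|A|-1)/n}$ yield fewer than one expected
  chance motif of strength $D$;
* `fp_strength_threshold()` — chance motifs, when they occur, are
  expected to stay below
  $D^\* \le \log_2 L + (|A|-1)\,W \log_2(n+1)/n.$

### The two threshold variants

The headline form of $D^\*$ uses $\log_2 L$; the algebraic inverse of the
length bound uses $\log_2(L-W+1)$.  Both are implemented
(`variant = "printed"` and `"exact"`).  The printed form is the default
because it is the form practitioners will have seen and quote; the exact
form satisfies the identity
`expected_fp_count(L, n, W, A, fp_strength_threshold(..., "exact")) == 1`
to machine precision, which the test suite asserts across a 100-point
parameter sweep.  The difference, $\log_2 \frac{L}{L-W+1}$, is at most a
few hundredths of a bit in realistic designs.

```{r thresholds}
fp_strength_threshold(1000, 30, 10)                 # printed: 14.92 bits
fp_strength_threshold(1000, 30, 10, variant = "exact")
expected_fp_count(1000, 30, 10, 4,
                  fp_strength_threshold(1000, 30, 10, variant = "exact"))$value
```

The threshold falls with $n$ with diminishing returns (its $n\to\infty$
limit is $\log_2 L$): going from 10 to 30 sequences at $L = 1000$,
$W = 10$ buys about 5.4 bits, while 30 to 50 buys only about 1.6 bits.
`min_sequences()` inverts this monotone dependence by bisection; targets
below $\log_2 L$ are reported as unreachable.

## Exact p-values

`column_divergence_pmf()` enumerates all $\binom{n+|A|-1}{|A|-1}$
per-column count compositions exactly (multinomial weights, divergences
with $0\log0=0$) and bins the divergence values on a fixed grid.
Because null alignment columns are i.i.d., the W-column distribution is
the W-fold convolution of the single-column PMF
(`convolve_divergence_pmf()`), and `motif_pvalue_exact()` reads off the
upper tail.

Numerical choices:

* **Grid resolution** defaults to $10^{-3}$ bits.  The worst-case
  boundary error in the D direction is $W \times$ resolution.
* **Rounding** is half-up to the nearest grid point; the tail cut is
  made at $D - W \cdot \mathrm{resolution}/2$, so discretisation errs
  toward *larger* (conservative) p-values.
* **Direct convolution**, not FFT: instances are small (the column PMF
  for DNA has at most $\sim 2/\mathrm{resolution}$ occupied bins), the
  nonnegativity of masses is preserved exactly, and the module is
  deterministic — compositions are enumerated lexicographically and no
  randomness is used anywhere.

`motif_pvalue_bruteforce()` is an independent oracle that enumerates
every one of the $|A|^{nW}$ possible alignments outright (capped at
$10^7$); the tests require the convolution route to agree with it within
the discretisation band on all feasible instances, and both to be
dominated by the Sanov bound at every achievable divergence value.

```{r pvalue}
g <- uniform_background()
motif_pvalue_exact(2, 1, g, D = 2)       # exact tail: 0.25
sanov_pvalue_bound(2, 1, 4, D = 2)       # bound: raw 27/16, clipped at 1
```

## The finder

`gibbs_site_sampler()` is a classic OOPS site sampler: per restart,
random start positions; then one sequence at a time (round-robin, for
reproducibility at a fixed seed) is held out, the predictive motif model
is rebuilt from the remaining $n-1$ sites, and the held-out site is
resampled with probability proportional to the model/background odds of
each W-mer.  Design choices:

* **Sampling pseudocount** $g_k$ per column (total mass 1), standard
  site-sampler practice to avoid zero-probability lock-in.  The
  *reported* strength always uses pseudocount 0 — the raw alignment
  frequencies are what $D(f,g)$ is defined on.
* **Best-of-run selection**: the best configuration by raw $D$ seen at
  any point is returned; ties break toward higher $D$, then the
  lexicographically smallest position tuple, making results
  deterministic given the seed.
* **No annealing**, single-strand search only.
* **Defaults**: 20 restarts, $200n$ site updates per restart for
  interactive use.
* The sampler runs on its own `mt19937_64` stream keyed by the seed, so
  results do not depend on (or disturb) R's global RNG state.

`exhaustive_find()` enumerates the full candidate space (capped at
$10^6$ tuples) and is the oracle: the test suite requires the sampler at
50 restarts to attain the exhaustive optimum on at least 95 of 100 tiny
random instances, and never to exceed it.

## The simulation framework and what it emulates

`generate_random_dataset()` draws every position i.i.d. from $g$ — the
null under which *every* found motif is a false positive.
`run_grid_experiment()` sweeps the standard validation grid, which is
also its default configuration: $n \in \{10, 20, 30, 50, 100\}$,
$L \in \{50, 100, 500, 1000\}$, $W \in \{5, 10, 15\}$, uniform $g$
over A,C,G,T.  For each cell it generates datasets, runs the Gibbs
sampler, and records the observed strength next to the predicted $D^\*$;
`bound_agreement()` pools the records and reports the squared Pearson
correlation between prediction and observation plus the fraction of
points at or below the bound ($D^\*$ is an upper bound, so that fraction
should be near 1).

Desk-scale problem sizes: the default is 3 replicates per cell with
20 restarts and 20 sampling sweeps per restart (the compiled sampler
covers the full 180-dataset grid in about a minute); the original
validation protocol used 50 replicates per cell, available via
`replicates` in `experiment_config()`.  Per-cell seeds are derived from
the master seed by a rolling-hash mix (`derive_seed()`, kept below
$2^{31}$), so any single cell can be rerun in isolation.  Cells with
$L < W$ are skipped with a message rather than failing the run.

What the generator does *not* emulate: real genomic sequence is not
i.i.d. — adjacent bases are correlated, composition varies locally, and
repeats abound.  `generate_markov_dataset()` exists precisely to probe
this: with self-transition-heavy chains the discovered chance motifs are
*stronger* than in the i.i.d. case, so the i.i.d. results are a
best-case scenario and passing tests bound real-data false positives
from below, not above.  ZOOPS/TCM site models, two-block or gapped
motifs, and finder-specific heuristics are out of scope.

## Planted-motif design scenarios

`plant_motif()` writes one PWM-sampled site per sequence at a uniform
offset and returns the ground truth.  Combined with
`parse_jaspar_pfm()`, this supports design questions of the form "can a
motif of this strength be found in a dataset of this size, or will it be
buried among chance motifs?"  For example, a weak $W = 15$ motif of
about 10.2 bits (a TATA-box-strength signal) sits far below
$D^\*(L{=}100, n{=}30, W{=}15) \approx 13.2$ bits; `min_sequences()`
reports that about `r min_sequences(100, 15, 4, 10.20)` sequences are
needed before the threshold drops to the motif's strength.  Because the
background and pseudocount conventions used to score a public-database
PFM affect its $D(f,g)$ by a few tenths of a bit, such numbers are
reported here with stated assumptions (uniform $g$, pseudocount 0)
rather than asserted as exact.

## Known limitations

* The bounds assume the ideal finder; practical optimizers find
  somewhat weaker false positives, so observed strengths sit below
  $D^\*$ rather than on it.
* The Sanov bound's polynomial prefactor makes the p-value bound loose
  by orders of magnitude for specific motifs; it is the *scaling* in
  $(n, L, W)$ that is sharp, which is exactly what the grid experiment
  checks.
* Exact p-values are practical for the enumeration-plus-convolution
  sizes ($n$ up to a few hundred compositions-wise); they are p-values
  for a motif's strength, not for matches to a known motif, and carry no
  correction for optimizer search heuristics beyond the $(L-W+1)^n$
  candidate count.
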