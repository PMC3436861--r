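#' @name simulate
#' @title Null simulations and planted-motif experiments
#'
#' @description
#' Random dataset generation under an i.i.d. background (the protocol the
#' bounds are validated against), first-order Markov backgrounds for
#' correlated-sequence comparisons, OOPS motif planting, the Monte-Carlo
#' grid experiment over (n, L, W), and the agreement summary between
#' predicted and observed false-positive strengths.
NULL

# run code under a temporary R RNG state, restoring the caller's state
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-stream seed
#'
#' Mixes a master seed with integer labels (e.g. n, L, W, replicate) into
#' a seed below 2^31, by a polynomial rolling hash modulo the Mersenne
#' prime 2^31 - 1.  Used so every grid cell of
#' [run_grid_experiment()] can be rerun independently.
#'
#' @param master integer master seed.
#' @param ... integer labels identifying the sub-stream.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (x in c(...)) h <- (h * 1009 + as.numeric(x) + 1) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Generate random background sequences
#'
#' n sequences of length L with every position drawn i.i.d. from g --
#' the null model under which every motif found is a false positive.
#'
#' @param n number of sequences.
#' @param L sequence length.
#' @param g an `mb_background`.
#' @param seed integer seed (R RNG, restored afterwards).
#' @return An `mb_dataset`.
#' @export
#' @examples
#' generate_random_dataset(5, 20, uniform_background(), seed = 1)
generate_random_dataset <- function(n, L, g, seed = 1L) {
  if (n < 1 || L < 1) stop("n and L must be at least 1")
  syms <- g$alphabet$symbols
  seqs <- with_local_seed(seed, {
    draws <- sample(syms, n * L, replace = TRUE, prob = g$probs)
    apply(matrix(draws, nrow = n), 1, paste, collapse = "")
  })
  sequence_dataset(seqs, g$alphabet)
}

#' Generate first-order Markov sequences
#'
#' Chains started from the stationary distribution of the transition
#' matrix.  With self-transition-heavy matrices the sequences are locally
#' repetitive, which strengthens the chance motifs a finder discovers --
#' the i.i.d. setting is the best case for motif-finding design.
#'
#' @param n number of sequences.
#' @param L sequence length.
#' @param transition |A| x |A| row-stochastic matrix; entry (a, b) is the
#'   probability of symbol b following symbol a.
#' @param seed integer seed.
#' @param alphabet an `mb_alphabet`; defaults to DNA.
#' @return An `mb_dataset`.
#' @export
generate_markov_dataset <- function(n, L, transition, seed = 1L,
                                    alphabet = dna_alphabet()) {
  transition <- as.matrix(transition)
  A <- alphabet$size
  if (!all(dim(transition) == c(A, A)))
    stop("transition must be |A| x |A|")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must be nonnegative and sum to 1")
  if (n < 1 || L < 1) stop("n and L must be at least 1")
  ev <- eigen(t(transition))
  i1 <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, i1])
  stat <- pmax(stat / sum(stat), 0)
  stat <- stat / sum(stat)
  syms <- alphabet$symbols
  seqs <- with_local_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- integer(L)
      s[1] <- sample.int(A, 1L, prob = stat)
      if (L > 1) for (t in 2:L)
        s[t] <- sample.int(A, 1L, prob = transition[s[t - 1], ])
      paste(syms[s], collapse = "")
    }, character(1))
  })
  sequence_dataset(seqs, alphabet)
}

#' Plant one motif occurrence per sequence
#'
#' OOPS planting: in each sequence, a site is sampled column-by-column
#' from the PWM and written at a uniformly chosen offset, overwriting the
#' background there.  Ground-truth positions are returned for recovery
#' experiments.
#'
#' @param dataset an `mb_dataset`; every sequence at least `pwm$width` long.
#' @param pwm an `mb_pwm` over the dataset's alphabet.
#' @param seed integer seed.
#' @return List with `dataset` (the modified `mb_dataset`) and
#'   `positions` (0-based true site offsets).
#' @export
plant_motif <- function(dataset, pwm, seed = 1L) {
  if (!inherits(pwm, "mb_pwm")) stop("pwm must be an mb_pwm")
  if (!same_alphabet(dataset$alphabet, pwm$alphabet))
    stop("dataset and PWM are over different alphabets")
  W <- pwm$width
  if (any(dataset$lengths < W))
    stop("every sequence must be at least pwm$width long")
  syms <- dataset$alphabet$symbols
  n <- length(dataset$sequences)
  out <- with_local_seed(seed, {
    pos <- integer(n)
    seqs <- dataset$sequences
    for (i in seq_len(n)) {
      p <- sample.int(dataset$lengths[i] - W + 1L, 1L) - 1L
      site <- vapply(seq_len(W), function(j)
        sample(syms, 1L, prob = pwm$freqs[j, ]), character(1))
      substr(seqs[i], p + 1L, p + W) <- paste(site, collapse = "")
      pos[i] <- p
    }
    list(seqs = seqs, pos = pos)
  })
  list(dataset = sequence_dataset(out$seqs, dataset$alphabet, dataset$names),
       positions = out$pos)
}

#' Configure a Monte-Carlo grid experiment
#'
#' Defaults follow the simulation protocol the bounds are validated
#' against: n in \{10, 20, 30, 50, 100\}, L in \{50, 100, 500, 1000\},
#' W in \{5, 10, 15\}, uniform background over A, C, G, T, a
#' one-occurrence-per-sequence Gibbs site sampler with 20 restarts, and
#' per-cell seeds derived from the master seed with [derive_seed()].
#' `replicates` defaults to 3 for desk-scale runs; raise it (the original
#' protocol used 50) for smoother summaries.  `sweeps` is the number of
#' full passes over the sequences per restart.
#'
#' @param n_values,L_values,W_values integer grids.
#' @param replicates datasets per (n, L, W) cell, >= 1.
#' @param background an `mb_background`.
#' @param seed master seed.
#' @param restarts,sweeps Gibbs sampler settings.
#' @param threshold_variant `"printed"` or `"exact"` D* variant recorded
#'   as the prediction.
#' @return An object of class `mb_experiment_config`.
#' @export
experiment_config <- function(n_values = c(10L, 20L, 30L, 50L, 100L),
                              L_values = c(50L, 100L, 500L, 1000L),
                              W_values = c(5L, 10L, 15L),
                              replicates = 3L,
                              background = uniform_background(),
                              seed = 1L,
                              restarts = 20L,
                              sweeps = 20L,
                              threshold_variant = c("printed", "exact")) {
  threshold_variant <- match.arg(threshold_variant)
  stopifnot(length(n_values) >= 1, length(L_values) >= 1,
            length(W_values) >= 1, replicates >= 1, restarts >= 1,
            sweeps >= 1)
  if (!inherits(background, "mb_background"))
    stop("background must be an mb_background")
  structure(list(n_values = as.integer(n_values),
                 L_values = as.integer(L_values),
                 W_values = as.integer(W_values),
                 replicates = as.integer(replicates),
                 background = background, seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 sweeps = as.integer(sweeps),
                 threshold_variant = threshold_variant),
            class = "mb_experiment_config")
}

#' Run the false-positive grid experiment
#'
#' For every (n, L, W) cell and replicate: generate a background-only
#' dataset, run the Gibbs site sampler, and record the observed
#' false-positive strength next to the predicted threshold D*.  Cells
#' with L < W are skipped with a message.  Deterministic given the
#' config: dataset and sampler seeds are derived per cell with
#' [derive_seed()].
#'
#' @param config an [experiment_config()].
#' @param output optional path; when given, records are also written as
#'   TSV.
#' @return A data.frame with columns `n, L, W, replicate, seed,
#'   observed_D, predicted_Dstar, exceeds_bound`, one row per replicate
#'   dataset (class `mb_experiment_records`).
#' @export
run_grid_experiment <- function(config, output = NULL) {
  if (!inherits(config, "mb_experiment_config"))
    stop("config must be an mb_experiment_config")
  g <- config$background
  Asize <- g$alphabet$size
  rows <- list()
  for (n in config$n_values) for (L in config$L_values)
    for (W in config$W_values) {
      if (L < W) {
        message(sprintf("skipping grid cell L = %d < W = %d", L, W))
        next
      }
      dstar <- fp_strength_threshold(L, n, W, Asize,
                                     config$threshold_variant)
      for (rep in seq_len(config$replicates)) {
        ds_seed <- derive_seed(config$seed, n, L, W, rep, 1L)
        gb_seed <- derive_seed(config$seed, n, L, W, rep, 2L)
        ds <- generate_random_dataset(n, L, g, ds_seed)
        hit <- gibbs_site_sampler(ds, W, g, restarts = config$restarts,
                                  iterations = config$sweeps * n,
                                  seed = gb_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, L = L, W = W, replicate = rep, seed = ds_seed,
          observed_D = hit$information_content,
          predicted_Dstar = dstar,
          exceeds_bound = hit$information_content > dstar)
      }
    }
  records <- do.call(rbind, rows)
  class(records) <- c("mb_experiment_records", "data.frame")
  if (!is.null(output))
    write.table(records, output, sep = "\t", quote = FALSE,
                row.names = FALSE)
  records
}

#' Agreement between predicted and observed false-positive strengths
#'
#' Pools all experiment records and summarises how well the threshold D*
#' tracks the strengths actually found on background-only data:
#' the squared Pearson correlation between `predicted_Dstar` and
#' `observed_D`, and the share of records at or below the bound
#' (points at or under the y = x line).
#'
#' @param records output of [run_grid_experiment()] (or any data.frame
#'   with `observed_D` and `predicted_Dstar` columns), >= 3 rows with
#'   >= 2 distinct predicted values.
#' @return List with `r_squared` and `fraction_below_bound`.
#' @export
bound_agreement <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("observed_D", "predicted_Dstar") %in% names(records)))
    stop("records must contain observed_D and predicted_Dstar")
  if (nrow(records) < 3L) stop("need at least 3 records")
  if (stats::var(records$predicted_Dstar) == 0 ||
      stats::var(records$observed_D) == 0)
    stop("degenerate variance: predictions or observations are constant")
  list(r_squared = cor(records$predicted_Dstar, records$observed_D)^2,
       fraction_below_bound =
         mean(records$observed_D <= records$predicted_Dstar))
}
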