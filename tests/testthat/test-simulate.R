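test_that("random datasets are reproducible and match the background", {
  d1 <- generate_random_dataset(10, 1000, unif_g, seed = 4)
  d2 <- generate_random_dataset(10, 1000, unif_g, seed = 4)
  expect_identical(d1$sequences, d2$sequences)
  expect_false(identical(
    d1$sequences, generate_random_dataset(10, 1000, unif_g, 5)$sequences))
  # per-base frequencies within 4 standard errors of 0.25
  chars <- unlist(strsplit(d1$sequences, ""))
  freq <- table(chars) / length(chars)
  se <- sqrt(0.25 * 0.75 / length(chars))
  expect_true(all(abs(freq - 0.25) < 4 * se))
  tiny <- generate_random_dataset(1, 1, unif_g, seed = 1)
  expect_equal(nchar(tiny$sequences), 1)
})

test_that("derived seeds are valid 32-bit integers and label-sensitive", {
  s1 <- derive_seed(20260928, 10, 1000, 5, 1, 1)
  s2 <- derive_seed(20260928, 10, 1000, 5, 1, 2)
  s3 <- derive_seed(20260928, 10, 1000, 5, 2, 1)
  expect_true(all(c(s1, s2, s3) >= 1 & c(s1, s2, s3) < 2^31))
  expect_true(length(unique(c(s1, s2, s3))) == 3)
  expect_identical(s1, derive_seed(20260928, 10, 1000, 5, 1, 1))
})

test_that("markov generator handles degenerate transition structures", {
  # identity transitions yield homopolymer sequences
  d <- generate_markov_dataset(4, 30, diag(4), seed = 6)
  expect_true(all(vapply(strsplit(d$sequences, ""), function(ch)
    length(unique(ch)) == 1L, logical(1))))
  # rank-one transition matrix == i.i.d. draws from g
  trans <- matrix(skew_g$probs, 4, 4, byrow = TRUE)
  d <- generate_markov_dataset(30, 200, trans, seed = 6)
  chars <- unlist(strsplit(d$sequences, ""))
  freq <- as.numeric(table(factor(chars, levels = dna_alphabet()$symbols)))
  freq <- freq / sum(freq)
  se <- sqrt(skew_g$probs * (1 - skew_g$probs) / length(chars))
  expect_true(all(abs(freq - skew_g$probs) < 5 * se))
  expect_error(generate_markov_dataset(2, 5, matrix(1, 4, 4), seed = 1),
               "sum to 1")
})

test_that("correlated backgrounds strengthen chance motifs", {
  trans <- matrix(0.1, 4, 4); diag(trans) <- 0.7
  d_iid <- d_mkv <- numeric(6)
  for (r in 1:6) {
    iid <- generate_random_dataset(10, 100, unif_g, seed = 100 + r)
    mkv <- generate_markov_dataset(10, 100, trans, seed = 100 + r)
    d_iid[r] <- gibbs_site_sampler(iid, 6, unif_g, restarts = 10,
                                   seed = r)$information_content
    d_mkv[r] <- gibbs_site_sampler(mkv, 6, unif_g, restarts = 10,
                                   seed = r)$information_content
  }
  expect_gte(mean(d_mkv), mean(d_iid))
})

test_that("motif planting writes one recoverable site per sequence", {
  base <- generate_random_dataset(5, 25, unif_g, seed = 9)
  res <- plant_motif(base, point_mass_pwm(5, base = 2), seed = 10)
  expect_length(res$positions, 5)
  sites <- substring(res$dataset$sequences, res$positions + 1,
                     res$positions + 5)
  expect_true(all(sites == "CCCCC"))
  expect_equal(res$dataset$lengths, base$lengths)
  # uniform PWM planting leaves the dataset background-distributed
  res_u <- plant_motif(base, uniform_pwm(5), seed = 10)
  expect_equal(res_u$dataset$lengths, base$lengths)
})

test_that("grid experiment is deterministic and shaped by its config", {
  cfg <- experiment_config(n_values = 4, L_values = 20, W_values = 5,
                           replicates = 1, seed = 3, restarts = 3,
                           sweeps = 5)
  rec <- run_grid_experiment(cfg)
  expect_equal(nrow(rec), 1)
  expect_named(rec, c("n", "L", "W", "replicate", "seed", "observed_D",
                      "predicted_Dstar", "exceeds_bound"))
  expect_identical(rec, run_grid_experiment(cfg))
  expect_equal(rec$predicted_Dstar, fp_strength_threshold(20, 4, 5))
  expect_lte(rec$observed_D, 2 * 5)
  # invalid L < W cells are skipped with a message, not an error
  cfg2 <- experiment_config(n_values = 3, L_values = c(4, 20), W_values = 5,
                            replicates = 1, seed = 3, restarts = 2,
                            sweeps = 2)
  expect_message(rec2 <- run_grid_experiment(cfg2), "skipping")
  expect_equal(nrow(rec2), 1)
})

test_that("bound_agreement summarises predicted-vs-observed records", {
  rec <- data.frame(observed_D = c(1, 2, 3, 4),
                    predicted_Dstar = c(1, 2, 3, 4))
  agg <- bound_agreement(rec)
  expect_equal(agg$r_squared, 1)
  expect_equal(agg$fraction_below_bound, 1)
  const <- data.frame(observed_D = c(1, 1, 1), predicted_Dstar = 1:3)
  expect_error(bound_agreement(const), "degenerate")
  expect_error(bound_agreement(rec[1:2, ]), "at least 3")
})
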