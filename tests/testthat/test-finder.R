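test_that("score_alignment evaluates hand-built alignments", {
  # identical sites give point-mass columns: 2W bits under uniform g
  ds <- sequence_dataset(c("ACGTA", "ACGTC", "ACGTG"))
  expect_equal(score_alignment(ds, c(0, 0, 0), 4, unif_g), 8)
  # a single sequence always yields point-mass columns
  ds1 <- sequence_dataset("ACGTACGT")
  expect_equal(score_alignment(ds1, 2, 3, unif_g), 6)
  # one matching column (2 bits) + one half-half column (1 bit)
  ds2 <- sequence_dataset(c("AC", "AG"))
  expect_equal(score_alignment(ds2, c(0, 0), 2, unif_g), 3)
  expect_error(score_alignment(ds2, c(0, 1), 2, unif_g), "out of range")
  expect_error(score_alignment(ds2, 0, 2, unif_g), "one position per")
})

test_that("exhaustive_find recovers planted sites and breaks ties deterministically", {
  base <- generate_random_dataset(4, 30, unif_g, seed = 11)
  planted <- plant_motif(base, point_mass_pwm(6, base = 3), seed = 5)
  hit <- exhaustive_find(planted$dataset, 6, unif_g)
  expect_equal(hit$information_content, 12)
  # every recovered site spells the planted consensus (a neighbouring
  # window can tie when the flanking background base happens to match)
  sites <- substring(planted$dataset$sequences, hit$positions + 1,
                     hit$positions + 6)
  expect_true(all(sites == "GGGGGG"))
  # L = W: singleton candidate space
  ds <- sequence_dataset(c("ACGT", "TGCA"))
  expect_equal(exhaustive_find(ds, 4, unif_g)$positions, c(0L, 0L))
  # optimum score is invariant to sequence order
  ds <- generate_random_dataset(3, 12, unif_g, seed = 3)
  rev_ds <- sequence_dataset(rev(ds$sequences))
  expect_equal(exhaustive_find(ds, 5, unif_g)$information_content,
               exhaustive_find(rev_ds, 5, unif_g)$information_content)
  big <- generate_random_dataset(10, 100, unif_g, seed = 1)
  expect_error(exhaustive_find(big, 5, unif_g), "too large")
})

test_that("gibbs_site_sampler is reproducible and finds planted motifs", {
  base <- generate_random_dataset(5, 40, unif_g, seed = 21)
  planted <- plant_motif(base, point_mass_pwm(7), seed = 22)
  h1 <- gibbs_site_sampler(planted$dataset, 7, unif_g, restarts = 5,
                           seed = 99)
  h2 <- gibbs_site_sampler(planted$dataset, 7, unif_g, restarts = 5,
                           seed = 99)
  expect_identical(h1$positions, h2$positions)
  expect_identical(h1$information_content, h2$information_content)
  expect_equal(h1$information_content, 14)  # the planted optimum, 2W bits
  h3 <- gibbs_site_sampler(planted$dataset, 7, unif_g, restarts = 5,
                           seed = 100)
  expect_equal(h3$information_content, 14)
})

test_that("motif hits honour the one-site-per-sequence contract", {
  ds <- generate_random_dataset(4, 15, skew_g, seed = 8)
  for (hit in list(exhaustive_find(ds, 5, skew_g),
                   gibbs_site_sampler(ds, 5, skew_g, restarts = 10,
                                      seed = 2))) {
    expect_length(hit$positions, 4)
    expect_true(all(hit$positions >= 0 & hit$positions <= 15 - 5))
    expect_equal(rowSums(hit$counts$counts), rep(4, 5),
                 ignore_attr = TRUE)
    # reported strength is the raw-frequency information content
    expect_equal(hit$information_content,
                 information_content(counts_to_pwm(hit$counts, 0), skew_g),
                 tolerance = 1e-9)
    expect_equal(hit$information_content,
                 score_alignment(ds, hit$positions, 5, skew_g),
                 tolerance = 1e-9)
  }
})

test_that("gibbs never exceeds the exhaustive optimum", {
  for (seed in 1:10) {
    ds <- generate_random_dataset(3, 10, unif_g, seed = seed)
    opt <- exhaustive_find(ds, 4, unif_g)$information_content
    got <- gibbs_site_sampler(ds, 4, unif_g, restarts = 10,
                              seed = seed)$information_content
    expect_lte(got, opt + 1e-9)
  }
})
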