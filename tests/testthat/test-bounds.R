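test_that("Sanov p-value bound evaluates and clips correctly", {
  # zero-strength motifs: raw bound (n+1)^positive >= 1, so clipped at 1
  for (n in c(1, 5, 50)) {
    b <- sanov_pvalue_bound(n, 3, 4, 0)
    expect_equal(b$value, 1)
    expect_true(b$clipped)
  }
  # n=2, W=1, DNA, D=2: raw bound 3^3 / 2^4 = 27/16, clipped
  b <- sanov_pvalue_bound(2, 1, 4, 2)
  expect_true(b$clipped)
  expect_equal(3^3 * 2^(-2 * 2), 27 / 16)
  # log-space evaluation stays finite where the raw power overflows
  b <- sanov_pvalue_bound(10, 10, 4, 20.344079)
  expect_equal(b$log2_value, 30 * log2(11) - 10 * 20.344079,
               tolerance = 1e-12)
  expect_equal(b$log2_value, -99.65784, tolerance = 1e-4)
  big <- expected_fp_count(1000, 100, 15, 4, 0)
  expect_true(is.finite(big$log2_value))
  expect_error(sanov_pvalue_bound(2, 1, 4, -0.1), "nonnegative")
})

test_that("maximum sequence length matches closed-form evaluations", {
  # at D = 0 the bound is below W: zero-strength motifs always occur
  expect_lt(max_sequence_length(10, 10, 4, 0), 10)
  expect_equal(max_sequence_length(10, 10, 4, 20.344079),
               9 + 2^20.344079 / 11^3, tolerance = 1e-9)
  expect_equal(max_sequence_length(10, 10, 4, 20.344079), 1009,
               tolerance = 1e-3)
  expect_equal(max_sequence_length(30, 10, 4, 14.91998),
               9 + 2^14.91998 / 31, tolerance = 1e-9)
})

test_that("strength threshold D* reproduces headline design values", {
  expect_equal(fp_strength_threshold(1000, 10, 10), 20.344079,
               tolerance = 1e-6)
  expect_equal(fp_strength_threshold(1000, 30, 10), 14.919980,
               tolerance = 1e-6)
  expect_equal(fp_strength_threshold(1000, 50, 10), 13.369239,
               tolerance = 1e-6)
  # exact variant: L = W leaves one candidate per sequence and the
  # threshold term vanishes as n grows
  expect_lt(fp_strength_threshold(10, 1e7, 10, 4, variant = "exact"), 1e-4)
  expect_error(fp_strength_threshold(5, 10, 10), "at least W")
})

test_that("expected count inverts the exact threshold and respects D = 0", {
  expect_gte(expected_fp_count(10, 3, 5, 4, 0)$value, 1)
  d <- fp_strength_threshold(1000, 30, 10, 4, variant = "exact")
  expect_equal(expected_fp_count(1000, 30, 10, 4, d)$value, 1,
               tolerance = 1e-9)
  # L = W: a single candidate per sequence; D just above the n-term
  # already pushes the expectation below 1
  d_edge <- 3 * 5 * log2(21) / 20 + 0.01
  expect_lt(expected_fp_count(5, 20, 5, 4, d_edge)$value, 1)
})

test_that("min_sequences finds the boundary of the monotone threshold", {
  # target at or above the n = 1 threshold is met immediately
  t1 <- fp_strength_threshold(100, 1, 5)
  expect_identical(min_sequences(100, 5, 4, t1 + 1), 1L)
  # targets below the n -> Inf limit log2(L) are unreachable
  expect_identical(min_sequences(1000, 10, 4, log2(1000) - 0.5,
                                 n_max = 1e6), NA_integer_)
  # TATA-box design scenario: L = 100, W = 15, target 10.20 bits
  n <- min_sequences(100, 15, 4, 10.20)
  expect_lte(fp_strength_threshold(100, n, 15), 10.20)
  expect_gt(fp_strength_threshold(100, n - 1L, 15), 10.20)
})

test_that("tripling n matches ~2 orders of magnitude of L at W = 10", {
  dn <- fp_strength_threshold(1000, 10, 10) - fp_strength_threshold(1000, 30, 10)
  dL <- fp_strength_threshold(1000, 30, 10) - fp_strength_threshold(10, 30, 10)
  expect_lt(abs(dn - dL) / dL, 0.25)
})
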