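# shared fixtures: backgrounds, toy PWMs, temporary FASTA files

unif_g <- uniform_background()
skew_g <- make_background(c(0.4, 0.3, 0.2, 0.1))

point_mass_pwm <- function(W, base = 1L) {
  f <- matrix(0, W, 4)
  f[, base] <- 1
  make_pwm(f)
}

uniform_pwm <- function(W) make_pwm(matrix(0.25, W, 4))

random_pwm <- function(W) {
  f <- matrix(stats::runif(W * 4), W, 4)
  make_pwm(f / rowSums(f))
}

write_tmp_fasta <- function(seqs, names = paste0("s", seq_along(seqs))) {
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", names), seqs)), path)
  path
}

write_tmp_pfm <- function(rows, header = ">MA0001.1 TOY") {
  path <- tempfile(fileext = ".pfm")
  writeLines(c(header, rows), path)
  path
}

# independent enumeration of achievable single-column divergences: all
# 4-part compositions of n, via expand.grid (not the package's internals)
achievable_column_divs <- function(n, g) {
  grid <- expand.grid(a = 0:n, c = 0:n, g = 0:n, t = 0:n)
  grid <- as.matrix(grid[rowSums(grid) == n, ])
  f <- grid / n
  term <- f * log2(sweep(f, 2, g$probs, "/"))
  term[f == 0] <- 0
  sort(unique(round(rowSums(term), 12)))
}
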