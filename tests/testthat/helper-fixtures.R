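# Small in-code fixtures shared across test files.

# 3-feature x 4-sample toy table
toy_table <- function() {
  feature_table(
    mz = c(104.1062, 184.0719, 516.3030),
    rt = c(51, 417, 379),
    intensities = matrix(c(
      1e5, 1.1e5, 0.9e5, 1.2e5,
      2e4, 2.2e4, 1.8e4, 2.4e4,
      3e3, NA, 2.7e3, 3.6e3
    ), nrow = 3, byrow = TRUE),
    sample_ids = paste0("S", 1:4)
  )
}

write_toy_table_file <- function(path = tempfile(fileext = ".txt")) {
  write_feature_table(toy_table(), path)
  path
}

write_lines_tsv <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

# independent brute-force BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# closed-form first-order partial correlation r_12.3
pcor_first_order <- function(r12, r13, r23) {
  (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
}

# random positive-definite 3x3 correlation matrix
random_pd_cor3 <- function() {
  repeat {
    A <- matrix(stats::rnorm(9), 3)
    S <- crossprod(A) + diag(3) * 0.1
    R <- stats::cov2cor(S)
    if (min(eigen(R, only.values = TRUE)$values) > 1e-6) return(R)
  }
}

# wrap a samples x features log10-intensity matrix as a feature table
table_from_log_matrix <- function(L, mz = NULL, rt = NULL) {
  p <- ncol(L)
  if (is.null(mz)) mz <- seq(100, 100 + p - 1) + 0.0001
  if (is.null(rt)) rt <- rep(100, p)
  feature_table(mz, rt, t(10^L), sample_ids = sprintf("S%03d", seq_len(nrow(L))))
}
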