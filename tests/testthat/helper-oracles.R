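# Brute-force index oracles: direct transcriptions of the index definitions,
# kept loop-based and independent of the package implementations.

acv_loop <- function(m) {
  n <- nrow(m)
  total <- sum(m[row(m) != col(m)])
  out <- 0
  for (i in seq_len(n)) {
    v <- m[i, setdiff(seq_len(n), i)]
    mbar <- mean(v)
    if (mbar > 0)
      out <- out + (sqrt(sum((v - mbar)^2) / (n - 1)) / mbar) * sum(v) / total
  }
  out
}

gini_loop <- function(m) {
  n <- nrow(m)
  x <- m[row(m) != col(m)]
  s <- 0
  for (p in seq_along(x)) for (q in seq_along(x)) s <- s + abs(x[p] - x[q])
  s / ((2 * n * (n - 1) - 1) * sum(x))
}

inequality_loop <- function(m) {
  n <- nrow(m)
  x <- m[row(m) != col(m)]
  uniform <- sum(x) / (n * (n - 1))
  s <- 0
  for (p in seq_along(x)) s <- s + abs(x[p] - uniform)
  s / (2 * sum(x))
}

reciprocity_loop <- function(m, mode = "minimum") {
  n <- nrow(m)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- num + switch(mode,
                        minimum = min(m[i, j], m[j, i]),
                        maximum = max(m[i, j], m[j, i]),
                        geometric_mean = sqrt(m[i, j] * m[j, i]))
  }
  num / sum(m[row(m) != col(m)])
}

# Random nonnegative flow matrix with zero diagonal (some zero cells).
random_flow_matrix <- function(n, zero_share = 0.2) {
  m <- matrix(stats::rexp(n * n, rate = 1 / 10), n, n)
  m[stats::runif(n * n) < zero_share] <- 0
  diag(m) <- 0
  flow_matrix(m, labels = sprintf("L%02d", seq_len(n)), year = 2000L)
}

# Hand-worked 3-location example used across the index tests:
# m12=4, m13=1, m21=2, m23=0, m31=1, m32=3 (total 11).
hand_matrix <- function() {
  flow_matrix(matrix(c(0, 4, 1,
                       2, 0, 0,
                       1, 3, 0), nrow = 3, byrow = TRUE),
              labels = c("A", "B", "C"), year = 2000L)
}

# Hand-worked ACV example: rows (., 2, 4), (3, ., 3), (0, 0, .).
acv_hand_matrix <- function() {
  flow_matrix(matrix(c(0, 2, 4,
                       3, 0, 3,
                       0, 0, 0), nrow = 3, byrow = TRUE),
              labels = c("A", "B", "C"), year = 2000L)
}

# Minimal complete two-location, two-year panel.
tiny_panel <- function(flows = c(5, 3, 7, 2)) {
  flow_panel(data.frame(origin = c("A", "B", "A", "B"),
                        destination = c("B", "A", "B", "A"),
                        year = c(2002L, 2002L, 2003L, 2003L),
                        flow = flows))
}
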