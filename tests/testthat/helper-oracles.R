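# Independent brute-force oracles for the enrichment scorers; direct
# enumeration, no shared code with the implementations.

ssgsea_oracle_1sample <- function(expr_vec, genes, set, tau) {
  ord <- order(-expr_vec)
  n <- length(expr_vec)
  es <- 0; cum_in <- 0; cum_out <- 0
  rank_vals <- (n:1)^tau
  total_in <- sum(rank_vals[genes[ord] %in% set])
  n_out <- sum(!genes[ord] %in% set)
  for (i in seq_len(n)) {
    g <- genes[ord][i]
    if (g %in% set) cum_in <- cum_in + rank_vals[i] / total_in
    else cum_out <- cum_out + 1 / n_out
    es <- es + (cum_in - cum_out)
  }
  es
}

gsva_oracle <- function(expr, set, mx_diff = TRUE) {
  n <- nrow(expr); m <- ncol(expr)
  z <- matrix(0, n, m)
  for (g in 1:n) {
    h <- sd(expr[g, ]) / 4
    if (!is.finite(h) || h == 0) h <- 1e-6
    for (j in 1:m) z[g, j] <- mean(pnorm((expr[g, j] - expr[g, ]) / h))
  }
  sapply(1:m, function(j) {
    ord <- order(-z[, j])
    in_set <- rownames(expr)[ord] %in% set
    w <- abs(n / 2 - seq_len(n) + 0.5)
    step_in <- ifelse(in_set, w, 0) / sum(w[in_set])
    step_out <- ifelse(in_set, 0, 1 / sum(!in_set))
    walk <- cumsum(step_in - step_out)
    if (mx_diff) max(c(0, walk)) + min(c(0, walk)) else walk[which.max(abs(walk))]
  })
}
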