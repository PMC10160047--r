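#' Single-sample GSEA (ssGSEA) enrichment scores
#'
#' Per sample, genes are ranked by expression (descending; ties broken by
#' stable input gene order) and assigned the rank value `N - position + 1`.
#' Walking down the ranked list, the enrichment score is the sum over
#' positions of `P_in(i) - P_out(i)`, where `P_in` is the cumulative
#' `rank^tau`-weighted fraction of in-set genes and `P_out` the cumulative
#' fraction of out-of-set genes. With `normalize = TRUE` all scores are
#' divided by the range (max - min) of the whole score matrix, the cited
#' method's convention.
#'
#' @param expr Gene x sample numeric matrix with rownames.
#' @param gene_sets Named list of gene-id vectors.
#' @param tau Rank-weighting exponent (default 0.25).
#' @param normalize Divide by the global score range (default TRUE).
#' @return Sample x gene-set score matrix with attribute `method = "ssgsea"`.
#'   Sets with no gene in `expr` are dropped with a warning.
#' @export
ssgsea <- function(expr, gene_sets, tau = 0.25, normalize = TRUE) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop_invalid("need >= 2 genes")
  genes <- rownames(expr)
  if (is.null(genes)) stop_invalid("`expr` must have gene rownames")
  present <- lapply(gene_sets, intersect, genes)
  empty <- lengths(present) == 0L
  if (any(empty)) {
    warning("dropping gene set(s) with no gene in the matrix: ",
            paste(names(gene_sets)[empty], collapse = ", "))
    present <- present[!empty]
  }
  if (length(present) == 0L) stop_invalid("no usable gene set")
  n <- nrow(expr)
  scores <- matrix(NA_real_, ncol(expr), length(present),
                   dimnames = list(colnames(expr), names(present)))
  for (j in seq_len(ncol(expr))) {
    ord <- order(expr[, j], seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
    rank_val <- (n:1)^tau
    for (k in seq_along(present)) {
      in_set <- genes[ord] %in% present[[k]]
      w_in <- ifelse(in_set, rank_val, 0)
      p_in <- cumsum(w_in) / sum(w_in)
      n_out <- n - sum(in_set)
      p_out <- if (n_out > 0L) cumsum(!in_set) / n_out else rep(0, n)
      scores[j, k] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "method") <- "ssgsea"
  scores
}

#' GSVA-style enrichment scores
#'
#' Per gene, expression is transformed across samples into a relative-rank
#' statistic via a Gaussian-kernel CDF (bandwidth `sd/4`). Per sample, genes
#' are ordered by this statistic (descending) and a weighted KS-like random
#' walk is computed: in-set steps are weighted by the symmetric rank
#' statistic `|N/2 - position + 1/2|`, out-of-set steps by `1/(N - |S|)`.
#' With `mx_diff` the score is the sum of the maximum positive and maximum
#' negative deviations (signed); otherwise it is the deviation of largest
#' magnitude.
#'
#' @param expr Gene x sample numeric matrix (>= 3 samples).
#' @param gene_sets Named list of gene-id vectors.
#' @param kcdf Kernel for the expression CDF; only `"gaussian"` is available.
#' @param mx_diff See description (default TRUE).
#' @return Sample x gene-set score matrix with attribute `method = "gsva"`.
#' @export
gsva_scores <- function(expr, gene_sets, kcdf = c("gaussian"), mx_diff = TRUE) {
  kcdf <- match.arg(kcdf)
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop_invalid("GSVA-style scoring needs >= 3 samples")
  genes <- rownames(expr)
  if (is.null(genes)) stop_invalid("`expr` must have gene rownames")
  present <- lapply(gene_sets, intersect, genes)
  empty <- lengths(present) == 0L
  if (any(empty)) {
    warning("dropping gene set(s) with no gene in the matrix: ",
            paste(names(gene_sets)[empty], collapse = ", "))
    present <- present[!empty]
  }
  if (length(present) == 0L) stop_invalid("no usable gene set")
  n <- nrow(expr); m <- ncol(expr)
  # Gaussian-kernel CDF across samples, bandwidth sd/4 per gene
  z <- matrix(0, n, m, dimnames = dimnames(expr))
  for (g in seq_len(n)) {
    x <- expr[g, ]
    h <- stats::sd(x) / 4
    if (!is.finite(h) || h == 0) h <- 1e-6
    z[g, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
  }
  scores <- matrix(NA_real_, m, length(present),
                   dimnames = list(colnames(expr), names(present)))
  for (j in seq_len(m)) {
    ord <- order(z[, j], seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
    w_rank <- abs(n / 2 - seq_len(n) + 0.5)
    for (k in seq_along(present)) {
      in_set <- genes[ord] %in% present[[k]]
      n_out <- n - sum(in_set)
      step_in <- ifelse(in_set, w_rank, 0)
      denom_in <- sum(step_in)
      if (denom_in == 0 || n_out == 0L) { scores[j, k] <- 0; next }
      walk <- cumsum(step_in / denom_in - (!in_set) / n_out)
      if (mx_diff) {
        scores[j, k] <- max(c(0, walk)) + min(c(0, walk))
      } else {
        scores[j, k] <- walk[which.max(abs(walk))]
      }
    }
  }
  attr(scores, "method") <- "gsva"
  scores
}

#' Pre-ranked GSEA with a permutation null
#'
#' Genes are sorted by the ranking metric (descending). The running sum gains
#' `|metric|^weight_p / sum_set |metric|^weight_p` at in-set genes and loses
#' `1/(N - N_set)` at out-of-set genes; the enrichment score is the extremum
#' of largest magnitude (sign kept). The null distribution comes from
#' `n_perm` random gene sets of the same size; NES is ES divided by the mean
#' |null ES| of the same sign, and the permutation p-value uses the +1
#' correction so it is never zero.
#'
#' @param metric Named numeric vector (e.g. log2 fold changes).
#' @param gene_set Character vector of gene ids.
#' @param n_perm Number of permutations (default 1000).
#' @param weight_p Metric-weighting exponent (default 1).
#' @param seed Integer seed.
#' @return A `gsea_result` list: `ES`, `NES`, `p_value`, `q_value` (NA here;
#'   filled when testing families of sets), `n_permutations`, `leading_edge`.
#' @export
preranked_gsea <- function(metric, gene_set, n_perm = 1000L, weight_p = 1,
                           seed = 1L) {
  if (is.null(names(metric))) stop_invalid("`metric` must be named by gene id")
  hit <- names(metric) %in% gene_set
  if (!any(hit)) stop_invalid("gene set has no gene in the ranking metric")
  ord <- order(metric, decreasing = TRUE)
  m_sorted <- metric[ord]
  hit_sorted <- hit[ord]
  es_stat <- function(is_hit) {
    n <- length(is_hit); n_hit <- sum(is_hit)
    if (n_hit == n) return(list(es = 0, pos = NA_integer_))
    w <- abs(m_sorted)^weight_p
    inc <- ifelse(is_hit, w, 0)
    denom <- sum(inc)
    if (denom == 0) inc[] <- ifelse(is_hit, 1 / n_hit, 0) else inc <- inc / denom
    walk <- cumsum(inc - (!is_hit) / (n - n_hit))
    i <- which.max(abs(walk))
    list(es = walk[i], pos = i)
  }
  obs <- es_stat(hit_sorted)
  n <- length(metric); n_hit <- sum(hit)
  null_es <- if (obs$es == 0) numeric(0) else with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      is_hit <- logical(n)
      is_hit[sample.int(n, n_hit)] <- TRUE
      es_stat(is_hit)$es
    }, numeric(1))
  })
  same_sign <- null_es[sign(null_es) == sign(obs$es)]
  if (length(same_sign) > 0L) {
    nes <- obs$es / mean(abs(same_sign))
    p <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (1 + length(same_sign))
  } else {
    nes <- if (obs$es == 0) 0 else sign(obs$es) * Inf
    p <- 1 / (n_perm + 1)
  }
  p <- max(p, 1 / (n_perm + 1))
  leading <- if (is.na(obs$pos)) character(0)
  else if (obs$es >= 0) names(m_sorted)[seq_len(obs$pos)][hit_sorted[seq_len(obs$pos)]]
  else names(m_sorted)[obs$pos:n][hit_sorted[obs$pos:n]]
  structure(list(ES = obs$es, NES = nes, p_value = p, q_value = NA_real_,
                 n_permutations = n_perm, leading_edge = leading),
            class = "gsea_result")
}
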