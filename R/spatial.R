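#' First-order hexagonal spot adjacency
#'
#' Builds the binary spot adjacency graph by distance filtering: starting at
#' `1.2 * pitch_um` and decreasing in steps of `0.1 * pitch_um`, the largest
#' cutoff at which no spot has more than six contiguous neighbors is used --
#' the defining property of the hexagonal Visium lattice.
#'
#' @param ds A `spatial_dataset` (or a data.frame with `x_um`, `y_um`).
#' @param pitch_um Lattice pitch; defaults to the dataset's.
#' @return An `adjacency_graph` list: `w` (symmetric binary matrix, zero
#'   diagonal), `order = 1`, `W` (total weight), `filter_dist`.
#' @export
hex_adjacency <- function(ds, pitch_um = NULL) {
  spots <- if (inherits(ds, "spatial_dataset")) ds$spots else ds
  pitch_um <- pitch_um %||% (if (inherits(ds, "spatial_dataset")) ds$pitch_um else
    stop_invalid("`pitch_um` is required"))
  if (nrow(spots) < 2L) stop_invalid("need >= 2 spots")
  xy <- cbind(spots$x_um, spots$y_um)
  if (anyDuplicated(xy)) stop_invalid("duplicate spot coordinates")
  d <- as.matrix(stats::dist(xy))
  filter_dist <- NA_real_
  for (mult in seq(1.2, 0.1, by = -0.1)) {
    cand <- mult * pitch_um
    w <- (d <= cand + 1e-9)
    diag(w) <- FALSE
    if (max(rowSums(w)) <= 6L) { filter_dist <- cand; break }
  }
  if (is.na(filter_dist)) stop_invalid("no distance filter satisfies the 6-neighbor bound")
  w <- (d <= filter_dist + 1e-9) * 1
  diag(w) <- 0
  dimnames(w) <- list(spots$spot_id, spots$spot_id)
  structure(list(w = w, order = 1L, W = sum(w), filter_dist = filter_dist),
            class = "adjacency_graph")
}

#' Expand a first-order adjacency graph to a physical neighborhood radius
#'
#' Connects every pair of spots within graph distance
#' `k = round(radius_um / pitch_um)` of each other (k-th order neighborhood,
#' excluding self), matching the "connect a graph to order k" construction
#' used for large-neighborhood spatial statistics.
#'
#' @param g An order-1 [hex_adjacency()] graph.
#' @param radius_um Neighborhood radius in micrometers (e.g. 900).
#' @param pitch_um Lattice pitch in micrometers.
#' @return An `adjacency_graph` of the given order. If `radius_um < pitch_um`
#'   the input graph is returned unchanged with a warning.
#' @export
expand_neighborhood <- function(g, radius_um, pitch_um) {
  if (g$order != 1L) stop_invalid("`g` must be a first-order graph")
  if (radius_um < pitch_um) {
    warning("radius below one pitch; returning the order-1 graph unchanged")
    return(g)
  }
  k <- round(radius_um / pitch_um)
  if (k <= 1L) return(g)
  ig <- igraph::graph_from_adjacency_matrix(g$w, mode = "undirected")
  gd <- igraph::distances(ig)
  w <- (gd >= 1 & gd <= k) * 1
  dimnames(w) <- dimnames(g$w)
  structure(list(w = w, order = as.integer(k), W = sum(w),
                 filter_dist = g$filter_dist),
            class = "adjacency_graph")
}

#' Bivariate Moran spatial cross-correlation
#'
#' `SCC(x, y) = (N / W) * sum_ij w_ij (x_i - xbar)(y_j - ybar) /
#' sqrt(sum_i (x_i - xbar)^2 * sum_j (y_j - ybar)^2)`; symmetric in its
#' arguments for a symmetric weight matrix and invariant to affine transforms
#' of either argument.
#'
#' @param x,y Numeric vectors over spots (non-constant).
#' @param g An [adjacency_graph()].
#' @return The scalar cross-correlation.
#' @export
spatial_cross_correlation <- function(x, y, g) {
  n <- nrow(g$w)
  if (length(x) != n || length(y) != n) stop_invalid("x/y length must match the spot count")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(errorCondition("spatial cross-correlation is undefined for constant input",
                        class = c("tissuestates_undefined_statistic", "error")))
  }
  xc <- x - mean(x); yc <- y - mean(y)
  (n / g$W) * drop(crossprod(xc, g$w %*% yc)) /
    sqrt(sum(xc^2) * sum(yc^2))
}

#' Spatial cross-correlation matrix over all cell-type pairs
#'
#' Computes the SCC for all `T(T+1)/2` unordered pairs, including self-pairs
#' (the diagonal is the spatial autocorrelation, which is not forced to one).
#' Constant cell-type columns give missing entries with a warning.
#'
#' @param ds A `spatial_dataset`.
#' @param g An [adjacency_graph()].
#' @return An `scc_result` list: `scc` (symmetric cell-type matrix), `n_pairs`,
#'   `sample_id`, `n_spots`.
#' @export
scc_matrix <- function(ds, g) {
  props <- ds$proportions
  ct <- colnames(props)
  if (length(ct) < 2L) stop_invalid("need >= 2 cell types")
  constant <- apply(props, 2L, stats::sd) == 0
  if (any(constant)) warning("constant proportion column(s): ",
                             paste(ct[constant], collapse = ", "))
  tt <- length(ct)
  scc <- matrix(NA_real_, tt, tt, dimnames = list(ct, ct))
  xc <- sweep(props, 2L, colMeans(props))
  wy <- g$w %*% xc
  ss <- colSums(xc^2)
  n <- nrow(props)
  for (i in seq_len(tt)) for (j in i:tt) {
    if (constant[i] || constant[j]) next
    v <- (n / g$W) * sum(xc[, i] * wy[, j]) / sqrt(ss[i] * ss[j])
    scc[i, j] <- scc[j, i] <- v
  }
  structure(list(scc = scc, n_pairs = as.integer(tt * (tt + 1L) / 2L),
                 sample_id = ds$sample_id %||% "sample", n_spots = n),
            class = "scc_result")
}

#' Permutation significance for the SCC matrix
#'
#' Spot labels are permuted over the fixed adjacency graph (`n_perm` times,
#' one joint permutation of all cell-type columns per iteration, preserving
#' within-spot composition). The one-sided p-value is the +1-corrected
#' fraction of permutations with SCC at least as high as observed; q-values
#' are BH-adjusted across the `T(T+1)/2` pairs within the sample.
#'
#' @param ds A `spatial_dataset`.
#' @param g An [adjacency_graph()].
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @return The [scc_matrix()] result with `p` and `q` matrices added.
#' @export
scc_permutation_test <- function(ds, g, n_perm = 100L, seed = 1L) {
  if (n_perm < 1L) stop_invalid("`n_perm` must be >= 1")
  res <- withCallingHandlers(scc_matrix(ds, g),
                             warning = function(w) invokeRestart("muffleWarning"))
  props <- ds$proportions
  tt <- ncol(props); n <- nrow(props)
  exceed <- matrix(0L, tt, tt, dimnames = dimnames(res$scc))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      ds_p <- ds
      ds_p$proportions <- props[perm, , drop = FALSE]
      scc_p <- withCallingHandlers(scc_matrix(ds_p, g),
                                   warning = function(w) invokeRestart("muffleWarning"))$scc
      exceed <- exceed + (!is.na(scc_p) & !is.na(res$scc) & scc_p >= res$scc)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  p[is.na(res$scc)] <- NA_real_
  ut <- upper.tri(p, diag = TRUE)
  q <- p
  q[ut] <- bh_adjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  res$p <- p
  res$q <- q
  res$n_permutations <- n_perm
  res
}

#' Pool SCC significance across samples with Fisher's method
#'
#' For every pair, `X^2 = -2 * sum_s log q_s` over the samples where the pair
#' is defined is compared to the upper tail of a chi-squared distribution
#' with `2k` degrees of freedom. By default the per-sample BH-adjusted values
#' are combined; `use_adjusted = FALSE` pools raw p-values and BH-adjusts the
#' pooled values instead. The pooled SCC is the unweighted mean of the
#' per-sample matrices (each already carries its own `N/W` normalization);
#' `per_spot_normalize` divides each sample's matrix by its spot count first.
#'
#' @param results List of [scc_permutation_test()] results on a shared
#'   cell-type universe.
#' @param use_adjusted Combine per-sample q-values (default TRUE).
#' @param per_spot_normalize Divide per-sample SCC by the spot count before
#'   averaging (default FALSE).
#' @param alpha Significance threshold on the pooled value (default 0.05).
#' @return A `pooled_scc` list: `scc` (mean matrix), `pooled_p`,
#'   `significant`, `n_samples_per_pair`.
#' @export
pool_across_samples <- function(results, use_adjusted = TRUE,
                                per_spot_normalize = FALSE, alpha = 0.05) {
  if (length(results) < 1L) stop_invalid("need >= 1 sample result")
  ct <- colnames(results[[1L]]$scc)
  for (r in results) {
    if (!identical(colnames(r$scc), ct)) stop_invalid("cell-type universes differ across samples")
  }
  tt <- length(ct)
  scc_stack <- vapply(results, function(r) {
    if (per_spot_normalize) r$scc / r$n_spots else r$scc
  }, matrix(0, tt, tt))
  sig_stack <- vapply(results, function(r) if (use_adjusted) r$q else r$p,
                      matrix(0, tt, tt))
  mean_scc <- apply(scc_stack, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  k_mat <- apply(sig_stack, c(1, 2), function(v) sum(!is.na(v)))
  x2 <- apply(sig_stack, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else -2 * sum(log(pmax(v, .Machine$double.xmin)))
  })
  pooled <- matrix(NA_real_, tt, tt, dimnames = list(ct, ct))
  def <- !is.na(x2)
  pooled[def] <- stats::pchisq(x2[def], df = 2 * k_mat[def], lower.tail = FALSE)
  if (!use_adjusted) {
    ut <- upper.tri(pooled, diag = TRUE) & !is.na(pooled)
    pooled[ut] <- bh_adjust(pooled[ut])
    pooled[lower.tri(pooled)] <- t(pooled)[lower.tri(pooled)]
  }
  structure(list(scc = mean_scc, pooled_p = pooled,
                 significant = !is.na(pooled) & pooled < alpha,
                 n_samples_per_pair = k_mat, n_pairs = as.integer(tt * (tt + 1L) / 2L)),
            class = "pooled_scc")
}

#' Cluster cell types by their spatial cross-correlation profiles
#'
#' Rows of the (pooled) SCC matrix are used as feature vectors; Euclidean
#' distances are clustered with Ward's method (`ward.D`) and the tree cut to
#' `k` groups. Missing entries are imputed as zero with a warning.
#'
#' @param pooled A [pool_across_samples()] result (or a plain SCC matrix).
#' @param k Number of clusters (default 3).
#' @return List: `cluster` (named integer vector), `tree` (hclust).
#' @export
cluster_scc <- function(pooled, k = 3L) {
  scc <- if (inherits(pooled, "pooled_scc") || inherits(pooled, "scc_result")) {
    pooled$scc
  } else as.matrix(pooled)
  if (k > nrow(scc)) stop_invalid("k exceeds the number of cell types")
  if (anyNA(scc)) {
    warning("imputing missing SCC entries as 0 for clustering")
    scc[is.na(scc)] <- 0
  }
  tree <- stats::hclust(stats::dist(scc, method = "euclidean"), method = "ward.D")
  cl <- stats::cutree(tree, k = k)
  list(cluster = cl, tree = tree)
}
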