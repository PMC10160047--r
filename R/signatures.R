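#' Pseudobulk aggregation of single-nucleus expression
#'
#' Sums (normalized) per-nucleus expression within each sample and rounds
#' half-up to integers, producing one bulk-like profile per sample.
#'
#' @param normalized Gene x nucleus numeric matrix.
#' @param sample_ids Sample id per nucleus (length = ncol).
#' @return Gene x sample integer matrix.
#' @export
pseudobulk <- function(normalized, sample_ids) {
  if (length(sample_ids) != ncol(normalized)) {
    stop_invalid("`sample_ids` must have one entry per nucleus")
  }
  sums <- t(rowsum(t(normalized), group = sample_ids))
  out <- round_half_up(sums)
  storage.mode(out) <- "integer"
  out
}

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, the ratio of each sample's
#' count to the gene's geometric mean is computed; the size factor is the
#' per-sample median of these ratios.
#'
#' @param counts Gene x sample count matrix.
#' @return Positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    stop_invalid("no gene has nonzero counts in all samples; ",
                 "consider adding a pseudocount before normalization")
  }
  lg <- log(counts[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2L, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min_{j >= rank(i)} (m / j) * p_(j)`, capped
#' at one and stable under input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_invalid("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  q <- numeric(m)
  q[ord] <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q[is.na(p)] <- NA_real_
  q
}

# Fit one NB log-linear GLM with known dispersion alpha (Var = mu + alpha mu^2)
# by Fisher-scoring IRLS; returns coefficients and their covariance.
nb_glm_fit <- function(y, X, offset, alpha, max_iter = 50L, tol = 1e-8) {
  beta <- qr.solve(X, log(y + 0.5) - offset)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- eta - offset + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (anyNA(new_beta)) return(NULL)
    if (max(abs(new_beta - beta)) < tol) { beta <- new_beta; break }
    beta <- new_beta
  }
  eta <- drop(X %*% beta) + offset
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X, X * w)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  list(beta = beta, cov = cov)
}

#' Pseudobulk negative-binomial Wald differential expression
#'
#' Per-gene NB log-linear model `mu = s_j exp(b0 + b_state + b_batch)` with
#' median-of-ratios size factors. Dispersions are per-gene method-of-moments
#' estimates shrunk halfway (on the log scale) toward a lowess trend over the
#' mean; the Wald statistic is the state coefficient over its standard error,
#' with a normal reference and BH adjustment.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Tissue-state label per sample.
#' @param contrast Length-2 character vector `(stateX, stateY)`: positive
#'   log2 fold change means higher in `stateX`.
#' @param batch Optional batch factor per sample.
#' @param min_alpha,max_alpha Bounds on the dispersion estimate.
#' @return A `de_result` data.frame: `gene`, `base_mean`, `log2_fold_change`,
#'   `wald_statistic`, `p_value`, `q_value`; attributes `size_factors`,
#'   `dispersions`, `contrast`.
#' @export
nb_wald_de <- function(counts, groups, contrast, batch = NULL,
                       min_alpha = 1e-8, max_alpha = 10) {
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) stop_invalid("`groups` must label every sample")
  if (length(contrast) != 2L || !all(contrast %in% groups)) {
    stop_invalid("`contrast` must name two states present in `groups`")
  }
  keep_s <- groups %in% contrast
  y_all <- counts[, keep_s, drop = FALSE]
  g <- factor(groups[keep_s], levels = c(contrast[2L], contrast[1L]))
  if (any(table(g) < 2L)) stop_invalid("each contrasted state needs >= 2 samples")
  X <- stats::model.matrix(~g)
  if (!is.null(batch)) {
    b <- droplevels(factor(batch[keep_s]))
    if (nlevels(b) > 1L) {
      X2 <- stats::model.matrix(~ g + b)
      if (qr(X2)$rank < ncol(X2)) {
        stop_invalid("design is singular: batch is confounded with the state contrast")
      }
      X <- X2
    }
  }
  sf <- size_factors(y_all)
  offset <- log(sf)
  norm <- sweep(y_all, 2L, sf, "/")
  mu_hat <- rowMeans(norm)
  v_hat <- apply(norm, 1L, stats::var)
  alpha_raw <- (v_hat - mu_hat) / mu_hat^2
  ok <- is.finite(alpha_raw) & alpha_raw > 0 & mu_hat > 0
  alpha_raw[!ok] <- NA_real_
  # lowess trend of log-dispersion over log-mean, 50% shrinkage toward it
  alpha <- rep(stats::median(alpha_raw, na.rm = TRUE) %||% 0.1, nrow(y_all))
  if (sum(ok) >= 10L) {
    tr <- stats::lowess(log(mu_hat[ok]), log(alpha_raw[ok]), f = 0.5)
    trend <- exp(stats::approx(tr$x, tr$y, xout = log(pmax(mu_hat, 1e-8)),
                               rule = 2)$y)
    alpha <- ifelse(ok, exp(0.5 * log(alpha_raw) + 0.5 * log(trend)), trend)
  }
  alpha <- pmin(pmax(alpha, min_alpha), max_alpha)
  n_gene <- nrow(y_all)
  lfc <- stat <- p <- rep(NA_real_, n_gene)
  for (i in seq_len(n_gene)) {
    yi <- y_all[i, ]
    if (all(yi == yi[1L])) {
      if (all(yi == 0)) next
      # identical counts across samples: no evidence of change
      lfc[i] <- 0; stat[i] <- 0; p[i] <- 1
      next
    }
    fit <- nb_glm_fit(yi, X, offset, alpha[i])
    if (is.null(fit)) next
    se <- sqrt(fit$cov[2L, 2L])
    lfc[i] <- fit$beta[2L] / log(2)
    stat[i] <- fit$beta[2L] / se
    p[i] <- 2 * stats::pnorm(-abs(stat[i]))
  }
  q <- rep(NA_real_, n_gene)
  tested <- !is.na(p)
  q[tested] <- bh_adjust(p[tested])
  res <- data.frame(gene = rownames(y_all) %||% sprintf("g%05d", seq_len(n_gene)),
                    base_mean = mu_hat, log2_fold_change = lfc,
                    wald_statistic = stat, p_value = p, q_value = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "size_factors") <- sf
  attr(res, "dispersions") <- alpha
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}

#' Derive unique tissue-state gene signatures
#'
#' The candidate signature of state X is the set of genes significantly
#' up-regulated (q < `q_cut`, log2FC > 0) in both X-vs-Y and X-vs-Z
#' contrasts. Genes qualifying for more than one state are removed from all
#' ("unique" signatures); the survivors are ranked by mean log2 fold change
#' over the two contrasts and truncated to `top_n`.
#'
#' @param de_list List of `de_result` objects (each carries a `contrast`
#'   attribute `(X, Y)` with positive fold changes meaning higher in X). A
#'   result for X-vs-Y also serves as Y-vs-X with negated fold changes; if
#'   several results cover the same pair, a gene must qualify in all of them.
#' @param q_cut Significance cutoff (default 0.05).
#' @param top_n Maximum signature length (default 150).
#' @return Named list (one per state) of ordered gene-id vectors; empty
#'   signatures trigger a warning.
#' @export
derive_state_signatures <- function(de_list, q_cut = 0.05, top_n = 150L) {
  contrasts <- lapply(de_list, function(d) attr(d, "contrast"))
  states <- sort(unique(unlist(contrasts)))
  if (length(states) != 3L) stop_invalid("expected DE results covering exactly 3 states")
  up_table <- function(d, state) {
    ctr <- attr(d, "contrast")
    sgn <- if (ctr[1L] == state) 1 else -1
    data.frame(gene = d$gene, lfc = sgn * d$log2_fold_change, q = d$q_value,
               stringsAsFactors = FALSE)
  }
  candidates <- list()
  for (st in states) {
    per_partner <- lapply(setdiff(states, st), function(other) {
      # prefer tables stated in the X-vs-Y direction; fall back to the
      # reversed table with negated fold changes
      tabs <- Filter(function(d) identical(attr(d, "contrast"), c(st, other)), de_list)
      if (length(tabs) == 0L) {
        tabs <- Filter(function(d) setequal(attr(d, "contrast"), c(st, other)), de_list)
      }
      if (length(tabs) == 0L) {
        stop_invalid("no DE result covers the ", st, " vs ", other, " contrast")
      }
      tabs <- lapply(tabs, up_table, state = st)
      # a gene qualifies against this partner if up and significant in every
      # covering table; rank key is its mean oriented fold change
      genes <- tabs[[1L]]$gene
      ok <- rep(TRUE, length(genes))
      lfc_sum <- rep(0, length(genes))
      for (tb in tabs) {
        tb <- tb[match(genes, tb$gene), ]
        ok <- ok & !is.na(tb$q) & tb$q < q_cut & tb$lfc > 0
        lfc_sum <- lfc_sum + tb$lfc
      }
      data.frame(gene = genes, ok = ok, lfc = lfc_sum / length(tabs),
                 stringsAsFactors = FALSE)
    })
    genes <- intersect(per_partner[[1L]]$gene, per_partner[[2L]]$gene)
    a <- per_partner[[1L]][match(genes, per_partner[[1L]]$gene), ]
    b <- per_partner[[2L]][match(genes, per_partner[[2L]]$gene), ]
    hit <- a$ok & b$ok
    sub <- data.frame(gene = genes[hit],
                      rank_key = (a$lfc[hit] + b$lfc[hit]) / 2,
                      stringsAsFactors = FALSE)
    candidates[[st]] <- sub[order(-sub$rank_key), , drop = FALSE]
  }
  shared <- unlist(lapply(candidates, `[[`, "gene"))
  dup <- unique(shared[duplicated(shared)])
  out <- lapply(candidates, function(tab) {
    genes <- setdiff(tab$gene, dup)
    utils::head(tab$gene[tab$gene %in% genes], top_n)
  })
  if (any(lengths(out) == 0L)) {
    warning("empty signature for state(s): ",
            paste(names(out)[lengths(out) == 0L], collapse = ", "))
  }
  out
}
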