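#' Chromosome-level expression profile
#'
#' Averages `log2(count + 1)` across the genes of each chromosome for every
#' nucleus, yielding the nucleus x chromosome matrix on which the malignancy
#' score operates.
#'
#' @param x An `annotated_counts` object (or a gene x nucleus count matrix).
#' @param panel A [make_gene_panel()] panel covering every counted gene.
#' @return A `chromosome_profile` list: `values` (nucleus x chromosome matrix
#'   of mean log2(count+1)), `chromosomes`, `nucleus_ids`, `sample_ids`.
#' @export
chromosome_profile <- function(x, panel = NULL) {
  if (inherits(x, "annotated_counts")) {
    counts <- x$counts
    panel <- panel %||% x$panel
    sample_ids <- x$nucleus_meta$sample_id
  } else {
    counts <- x
    sample_ids <- rep("S1", ncol(counts))
  }
  if (is.null(panel)) stop_invalid("a gene panel is required")
  missing <- setdiff(rownames(counts), panel$gene_id)
  if (length(missing)) {
    stop_invalid("gene(s) absent from panel: ",
                 paste(utils::head(missing, 5), collapse = ", "))
  }
  chrom <- panel$chromosome[match(rownames(counts), panel$gene_id)]
  lg <- log2(counts + 1)
  sums <- rowsum(lg, group = chrom)                 # chromosome x nucleus
  values <- t(sums / as.vector(table(chrom)[rownames(sums)]))
  values <- values[, levels(droplevels(chrom)), drop = FALSE]
  structure(list(values = values,
                 chromosomes = colnames(values),
                 nucleus_ids = colnames(counts) %||% sprintf("n%06d", seq_len(ncol(counts))),
                 sample_ids = sample_ids),
            class = "chromosome_profile")
}

#' Select gained and lost chromosomes from the PC2 axis
#'
#' PCA (centered, unit-variance) of the nucleus x autosome profile; the second
#' component captures the copy-number contrast (the first is dominated by the
#' common library-size factor). Chromosomes whose Pearson correlation with the
#' PC2 score exceeds `correlation_threshold` in absolute value are selected,
#' at most `max_per_direction` per direction ranked by |r|. A selected
#' chromosome is called gained when its mean profile value among the putative
#' aberrant nuclei (upper PC2 tercile, or the complement of
#' `reference_labels` when supplied) exceeds the mean among the comparison
#' nuclei, otherwise lost. PC2's sign is fixed so the top-|r| chromosome
#' correlates positively, making the result independent of the linear-algebra
#' backend's sign convention.
#'
#' @param profile A [chromosome_profile()].
#' @param reference_labels Optional logical vector (TRUE = known CNV-negative
#'   reference nucleus) aligned with the profile rows.
#' @param correlation_threshold Minimum |r| with PC2 (default 0.5).
#' @param max_per_direction At most this many chromosomes per direction
#'   (default 3).
#' @return A `chromosome_selection` list: `gained`, `lost`,
#'   `pc2_correlation` (named per autosome), `pc2_scores`.
#' @export
select_cnv_chromosomes <- function(profile, reference_labels = NULL,
                                   correlation_threshold = 0.5,
                                   max_per_direction = 3L) {
  values <- profile$values
  autosomes <- setdiff(colnames(values), c("X", "Y"))
  if (length(autosomes) < 2L) stop_invalid("need >= 2 autosomal chromosomes")
  if (nrow(values) < 3L) stop_invalid("need >= 3 nuclei")
  v <- values[, autosomes, drop = FALSE]
  keep <- apply(v, 2L, stats::sd) > 0
  v <- v[, keep, drop = FALSE]
  pca <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  if (ncol(pca$x) < 2L) stop_invalid("profile has fewer than 2 informative components")
  pc2 <- pca$x[, 2L]
  r <- drop(stats::cor(v, pc2))
  top <- which.max(abs(r))
  if (r[top] < 0) { pc2 <- -pc2; r <- -r }
  pass <- names(r)[abs(r) >= correlation_threshold]
  if (length(pass) == 0L) {
    stop(errorCondition(
      paste0("no chromosome reaches |r| >= ", correlation_threshold,
             " with PC2; lower the threshold or supply reference labels"),
      class = c("tissuestates_empty_selection", "error")))
  }
  # library-size-free signal: candidate values relative to the per-nucleus
  # mean over the non-candidate ("neutral") autosomes
  neutral <- setdiff(colnames(v), pass)
  lib <- if (length(neutral)) rowMeans(v[, neutral, drop = FALSE]) else rowMeans(v)
  relv <- v[, pass, drop = FALSE] - lib
  if (is.null(reference_labels)) {
    upper <- pc2 >= stats::quantile(pc2, 2 / 3)
    lower <- pc2 <= stats::quantile(pc2, 1 / 3)
    # Which tercile holds the aberrant nuclei? Copy-number shifts are
    # asymmetric on the log scale (single-copy loss ~ -1, gain ~ +0.58), so
    # the aberrant group has the lower net signal over candidate chromosomes.
    aberrant <- if (sum(rowSums(relv)[upper]) / sum(upper) <
                    sum(rowSums(relv)[lower]) / sum(lower)) upper else lower
    baseline <- !aberrant
  } else {
    stopifnot(length(reference_labels) == nrow(v))
    aberrant <- !reference_labels
    baseline <- reference_labels
  }
  delta <- colMeans(relv[aberrant, , drop = FALSE]) -
    colMeans(relv[baseline, , drop = FALSE])
  gained <- pass[delta > 0]
  lost <- pass[delta <= 0]
  take_top <- function(ch) {
    ch[order(abs(r[ch]), decreasing = TRUE)][seq_len(min(length(ch), max_per_direction))]
  }
  structure(list(gained = take_top(gained), lost = take_top(lost),
                 pc2_correlation = r, pc2_scores = pc2),
            class = "chromosome_selection")
}

#' Chromosome-level malignancy score
#'
#' For each nucleus, the sum of mean log2 expression over the gained
#' chromosomes divided by the sum over the lost chromosomes; the ratio is then
#' z-scaled within each sample. A denominator floor `eps` keeps the score
#' finite for nuclei with no signal on the lost chromosomes.
#'
#' @param profile A [chromosome_profile()].
#' @param selection A [select_cnv_chromosomes()] result (or any list with
#'   `gained` and `lost` chromosome labels).
#' @param eps Denominator floor (default 0.01).
#' @return A `malignancy_calls` data.frame: `nucleus_id`, `sample_id`,
#'   `raw_score`, `z_score`, `label` (all `NA` until [call_neoplastic()]).
#' @export
malignancy_score <- function(profile, selection, eps = 0.01) {
  gained <- selection$gained; lost <- selection$lost
  if (length(gained) == 0L || length(lost) == 0L) {
    stop_invalid("selection must contain at least one gained and one lost chromosome")
  }
  missing <- setdiff(c(gained, lost), colnames(profile$values))
  if (length(missing)) stop_invalid("chromosome(s) not in profile: ", paste(missing, collapse = ", "))
  num <- rowSums(profile$values[, gained, drop = FALSE])
  den <- pmax(rowSums(profile$values[, lost, drop = FALSE]), eps)
  raw <- num / den
  z <- stats::ave(raw, profile$sample_ids, FUN = function(s) {
    if (length(s) >= 2L && stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s - mean(s)
  })
  structure(data.frame(nucleus_id = profile$nucleus_ids,
                       sample_id = profile$sample_ids,
                       raw_score = raw, z_score = z,
                       label = NA_character_, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("malignancy_calls", "data.frame"))
}

#' Label neoplastic nuclei from malignancy scores
#'
#' `kmeans`: per sample, 2-means on the z-scaled scores (10 restarts); the
#' higher-mean cluster is CNVpos. `outlier`: a normal distribution is fitted
#' to the central 5th-95th percentile band of the scores; nuclei above the
#' value z* at which the fitted model expects fewer than `rho` observations
#' are flagged CNVpos (right-tail outlier detection).
#'
#' @param calls A [malignancy_score()] result.
#' @param method `"kmeans"` or `"outlier"`.
#' @param rho Expected-count threshold for the outlier method (default 0.1).
#' @param seed Integer seed for the k-means restarts.
#' @return `calls` with `label` filled in. If a sample's scores are constant,
#'   all its nuclei are labeled CNVneg with a warning.
#' @export
call_neoplastic <- function(calls, method = c("kmeans", "outlier"), rho = 0.1,
                            seed = 1L) {
  method <- match.arg(method)
  out <- calls
  for (s in unique(calls$sample_id)) {
    idx <- which(calls$sample_id == s)
    if (length(idx) < 4L) stop_invalid("sample ", s, " has fewer than 4 nuclei")
    z <- calls$z_score[idx]
    if (stats::sd(z) == 0) {
      warning("sample ", s, ": constant malignancy scores, labeling all CNVneg")
      out$label[idx] <- "CNVneg"
      next
    }
    if (method == "kmeans") {
      km <- with_seed(seed, stats::kmeans(z, centers = 2L, nstart = 10L))
      pos_cluster <- which.max(km$centers)
      out$label[idx] <- ifelse(km$cluster == pos_cluster, "CNVpos", "CNVneg")
    } else {
      band <- z[z >= stats::quantile(z, 0.05) & z <= stats::quantile(z, 0.95)]
      m <- mean(band); sd0 <- stats::sd(band)
      if (sd0 == 0) {
        warning("sample ", s, ": degenerate central band, labeling all CNVneg")
        out$label[idx] <- "CNVneg"
        next
      }
      # z*: expected number of observations >= z* under N(m, sd0) drops below rho
      zstar <- m + sd0 * stats::qnorm(1 - rho / length(z))
      out$label[idx] <- ifelse(z > zstar, "CNVpos", "CNVneg")
    }
  }
  out$method <- method
  out
}

#' Windowed-expression CNV caller
#'
#' A simplified stand-in for window-based CNV-inference tools: counts are
#' depth-normalized to the median library size, log2(x+1)-transformed, and
#' expressed relative to the mean over a reference (known CNV-negative) set of
#' nuclei. The relative values are smoothed by a moving average over `window`
#' genes in genomic order within each chromosome (windows truncated at
#' chromosome ends), then averaged per chromosome. A chromosome is called
#' gained/lost when its mean smoothed value exceeds `+call_threshold` /
#' `-call_threshold`; a nucleus is CNVpos when at least one chromosome is
#' called.
#'
#' @param x An `annotated_counts` object.
#' @param panel Gene panel (defaults to the one stored in `x`).
#' @param reference_ids Character vector of reference nucleus ids.
#' @param window Moving-average width in genes (one of 50, 100, 200 in common
#'   use; any integer >= 2 accepted).
#' @param call_threshold Chromosome-level call threshold on mean smoothed
#'   relative log2 expression (default 0.15).
#' @param clip Cap on per-gene relative log2 values before smoothing
#'   (default 1), the standard guard against isolated cell-state marker
#'   spikes masquerading as copy-number signal; whole-chromosome shifts are
#'   far below the cap and pass through unchanged.
#' @return A `windowed_cnv` list: `label` (named CNVpos/CNVneg per nucleus),
#'   `chromosome_values` (nucleus x chromosome mean smoothed values),
#'   `chromosome_calls` (same shape, "gain"/"loss"/"neutral").
#' @export
windowed_cnv_profile <- function(x, panel = NULL, reference_ids, window = 100L,
                                 call_threshold = 0.15, clip = 1) {
  if (window < 2L) stop_invalid("`window` must be >= 2")
  panel <- panel %||% x$panel
  counts <- x$counts
  if (length(reference_ids) == 0L) stop_invalid("`reference_ids` must be nonempty")
  ref_idx <- match(reference_ids, colnames(counts))
  if (anyNA(ref_idx)) stop_invalid("reference id(s) not found in matrix")
  # depth normalization: the relative-log2 baseline is only meaningful when
  # nuclei are on a common scale
  depth <- colSums(counts)
  norm <- sweep(counts, 2L, stats::median(depth) / pmax(depth, 1), "*")
  lg <- log2(norm + 1)
  rel <- lg - rowMeans(lg[, ref_idx, drop = FALSE])
  rel <- pmin(pmax(rel, -clip), clip)
  chrom <- as.character(panel$chromosome[match(rownames(counts), panel$gene_id)])
  pos <- panel$position_index[match(rownames(counts), panel$gene_id)]
  chroms <- unique(chrom)
  n_nuc <- ncol(counts)
  chrom_vals <- matrix(NA_real_, nrow = n_nuc, ncol = length(chroms),
                       dimnames = list(colnames(counts), chroms))
  for (ch in chroms) {
    gi <- which(chrom == ch)
    gi <- gi[order(pos[gi])]
    w <- window
    if (length(gi) < w) {
      warning("chromosome ", ch, " has fewer genes (", length(gi),
              ") than the window; using a full-chromosome window")
      w <- length(gi)
    }
    sub <- rel[gi, , drop = FALSE]
    # truncated moving average via cumulative sums: mean over genes
    # [max(1, i-w+1+floor(w/2)) .. min(n, i+floor(w/2))] centered windows
    n_g <- length(gi)
    half <- w %/% 2L
    cs <- rbind(0, apply(sub, 2L, cumsum))
    lo <- pmax(seq_len(n_g) - half, 1L)
    hi <- pmin(seq_len(n_g) + (w - 1L - half), n_g)
    smoothed <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
    chrom_vals[, ch] <- colMeans(smoothed)
  }
  calls <- matrix("neutral", nrow = n_nuc, ncol = length(chroms),
                  dimnames = dimnames(chrom_vals))
  calls[chrom_vals > call_threshold] <- "gain"
  calls[chrom_vals < -call_threshold] <- "loss"
  label <- ifelse(rowSums(calls != "neutral") >= 1L, "CNVpos", "CNVneg")
  names(label) <- colnames(counts)
  structure(list(label = label, chromosome_values = chrom_vals,
                 chromosome_calls = calls, window = window,
                 call_threshold = call_threshold),
            class = "windowed_cnv")
}

#' Consensus of two neoplastic-calling procedures
#'
#' Nuclei labeled identically by both callers keep that label; discordant
#' nuclei are excluded from downstream analysis. The discordant fraction is
#' the standard agreement diagnostic between the two procedures.
#'
#' @param labels_a,labels_b Named character vectors (CNVpos/CNVneg) over the
#'   same nucleus universe.
#' @return A `consensus_calls` list: `label` (CNVpos/CNVneg/excluded, named)
#'   and `discordant_fraction`.
#' @export
consensus_calls <- function(labels_a, labels_b) {
  if (is.data.frame(labels_a)) labels_a <- stats::setNames(labels_a$label, labels_a$nucleus_id)
  if (inherits(labels_b, "windowed_cnv")) labels_b <- labels_b$label
  if (is.data.frame(labels_b)) labels_b <- stats::setNames(labels_b$label, labels_b$nucleus_id)
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      stop_invalid("the two callers cover different nucleus sets")
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop_invalid("label vectors differ in length and carry no names")
  }
  agree <- labels_a == labels_b
  label <- ifelse(agree, labels_a, "excluded")
  structure(list(label = label, discordant_fraction = mean(!agree)),
            class = "consensus_calls")
}
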