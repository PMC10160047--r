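#' Per-sample cell-state composition matrix
#'
#' The active variables are the fractions of the 12 non-neoplastic states plus
#' the total CNVpos fraction (glioma states collapsed); the supplementary
#' variables are the fractions of CNVpos nuclei assigned to each of the six
#' glioma states. Supplementary rows are all-zero for samples without
#' neoplastic nuclei.
#'
#' @param annotations A data.frame with columns `sample_id`, `state` (one of
#'   [all_states()]) and `cnv_label` (CNVpos/CNVneg) -- or an
#'   `annotated_counts` object, in which case `true_state`/`true_cnv_label`
#'   are used.
#' @return A `composition_matrix` list: `active` (sample x 13), `supplementary`
#'   (sample x 6), `sample_meta` (condition per sample when available).
#' @export
composition_matrix <- function(annotations) {
  if (inherits(annotations, "annotated_counts")) {
    meta <- annotations$nucleus_meta
    annotations <- data.frame(sample_id = meta$sample_id, state = meta$true_state,
                              cnv_label = meta$true_cnv_label,
                              condition = meta$condition, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_id", "state", "cnv_label") %in% names(annotations)))
  bad <- setdiff(unique(annotations$state), all_states())
  if (length(bad)) stop_invalid("unknown state label(s): ", paste(bad, collapse = ", "))
  samples <- unique(annotations$sample_id)
  empty <- !samples %in% annotations$sample_id
  active_vars <- c(nonneoplastic_states(), "CNVpos")
  active <- matrix(0, nrow = length(samples), ncol = length(active_vars),
                   dimnames = list(samples, active_vars))
  supp <- matrix(0, nrow = length(samples), ncol = length(glioma_states()),
                 dimnames = list(samples, glioma_states()))
  for (s in samples) {
    rows <- annotations[annotations$sample_id == s, ]
    n <- nrow(rows)
    if (n == 0L) next
    for (st in nonneoplastic_states()) active[s, st] <- sum(rows$state == st) / n
    pos <- rows[rows$cnv_label == "CNVpos", ]
    active[s, "CNVpos"] <- nrow(pos) / n
    if (nrow(pos) > 0L) {
      for (st in glioma_states()) supp[s, st] <- sum(pos$state == st) / nrow(pos)
    }
  }
  meta <- NULL
  if ("condition" %in% names(annotations)) {
    meta <- unique(annotations[, c("sample_id", "condition")])
    rownames(meta) <- NULL
  }
  structure(list(active = active, supplementary = supp, sample_meta = meta),
            class = "composition_matrix")
}

#' Compositional PCA with supplementary quantitative variables
#'
#' Active variables are centered and scaled to unit variance and decomposed by
#' SVD; variable coordinates are the Pearson correlations of each variable
#' with the component scores. Supplementary variables do not enter the
#' decomposition -- their coordinates are computed post hoc the same way.
#' Component signs are fixed so the largest-|coordinate| active variable on
#' each component is positive.
#'
#' @param comp A [composition_matrix()] (or a plain sample x variable matrix,
#'   in which case there are no supplementary variables).
#' @param supplementary Optional sample x variable matrix overriding
#'   `comp$supplementary`.
#' @return A `composition_pca` list: `eigenvalues` (sum = number of retained
#'   active variables), `scores`, `variable_coordinates`,
#'   `supplementary_coordinates`, `loadings`, `center`, `scale`.
#' @export
pca_with_supplementary <- function(comp, supplementary = NULL) {
  if (inherits(comp, "composition_matrix")) {
    active <- comp$active
    supplementary <- supplementary %||% comp$supplementary
  } else {
    active <- as.matrix(comp)
  }
  if (nrow(active) < 3L) stop_invalid("PCA needs >= 3 samples")
  sds <- apply(active, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant active variable(s): ",
            paste(colnames(active)[sds == 0], collapse = ", "))
    active <- active[, sds > 0, drop = FALSE]
  }
  pca <- stats::prcomp(active, center = TRUE, scale. = TRUE)
  scores <- pca$x
  loadings <- pca$rotation
  # fix component signs for backend-independent output
  for (k in seq_len(ncol(scores))) {
    vc <- stats::cor(active, scores[, k])
    if (vc[which.max(abs(vc))] < 0) {
      scores[, k] <- -scores[, k]
      loadings[, k] <- -loadings[, k]
    }
  }
  eigenvalues <- pca$sdev^2  # unit-variance scaling: sums to the number of variables
  var_coord <- stats::cor(active, scores)
  supp_coord <- NULL
  if (!is.null(supplementary) && ncol(supplementary) > 0L) {
    ok <- apply(supplementary, 2L, stats::sd) > 0
    supp_coord <- matrix(NA_real_, ncol(supplementary), ncol(scores),
                         dimnames = list(colnames(supplementary), colnames(scores)))
    if (any(ok)) supp_coord[ok, ] <- stats::cor(supplementary[, ok, drop = FALSE], scores)
  }
  structure(list(eigenvalues = eigenvalues, scores = scores,
                 variable_coordinates = var_coord,
                 supplementary_coordinates = supp_coord,
                 loadings = loadings, center = pca$center, scale = pca$scale),
            class = "composition_pca")
}

#' Cluster samples into tissue states
#'
#' Hierarchical clustering of the active composition rows (Manhattan distance
#' by default, average linkage), cut at `k` clusters. For `k = 3` the clusters
#' are named by content: A = highest mean Neuron fraction (brain-like),
#' C = highest mean CNVpos fraction among the remainder (cellular tumor),
#' B = the rest (reactive/inflammatory).
#'
#' @param comp A [composition_matrix()] or sample x variable matrix.
#' @param k Number of tissue states (default 3).
#' @param distance `"manhattan"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return A `tissue_state_assignment` list: `state` (named factor per
#'   sample), `centroids` (state x variable means), `tree` (hclust),
#'   `distance`.
#' @export
cluster_tissue_states <- function(comp, k = 3L, distance = c("manhattan", "euclidean"),
                                  linkage = "average") {
  distance <- match.arg(distance)
  active <- if (inherits(comp, "composition_matrix")) comp$active else as.matrix(comp)
  if (nrow(active) < k) stop_invalid("need at least k = ", k, " samples")
  d <- stats::dist(active, method = distance)
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = k)
  labels <- name_tissue_states(active, cl, k)
  state <- factor(labels[as.character(cl)], levels = sort(unique(labels)))
  names(state) <- rownames(active)
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(active)), state), function(i) {
    colMeans(active[i, , drop = FALSE])
  }))
  structure(list(state = state, centroids = centroids, tree = tree,
                 distance = distance),
            class = "tissue_state_assignment")
}

# Name k clusters: A = highest mean Neuron fraction, C = highest CNVpos among
# the remainder, B (and D, E, ... for k > 3) = the rest.
name_tissue_states <- function(active, cl, k) {
  ids <- sort(unique(cl))
  mean_of <- function(var) {
    if (!var %in% colnames(active)) return(stats::setNames(rep(0, length(ids)), ids))
    stats::setNames(vapply(ids, function(g) mean(active[cl == g, var]), numeric(1)), ids)
  }
  neuron <- mean_of("Neuron"); cnvpos <- mean_of("CNVpos")
  labels <- stats::setNames(rep(NA_character_, length(ids)), ids)
  a <- ids[which.max(neuron)]
  labels[as.character(a)] <- "A"
  rest <- setdiff(ids, a)
  if (length(rest)) {
    cc <- rest[which.max(cnvpos[as.character(rest)])]
    labels[as.character(cc)] <- "C"
    rest <- setdiff(rest, cc)
  }
  if (length(rest)) {
    fill <- c("B", LETTERS[-(1:3)])[seq_along(rest)]
    labels[as.character(rest)] <- fill
  }
  labels
}

#' Assign new samples to tissue states by nearest centroid
#'
#' @param comp_new A [composition_matrix()] or sample x variable matrix with
#'   the same active variables as the training assignment.
#' @param assignment A [cluster_tissue_states()] result.
#' @return Named factor of states; ties broken toward the alphabetically
#'   first state.
#' @export
assign_new_samples <- function(comp_new, assignment) {
  active <- if (inherits(comp_new, "composition_matrix")) comp_new$active else as.matrix(comp_new)
  cen <- assignment$centroids
  if (!identical(colnames(active), colnames(cen))) {
    stop_invalid("active variables of new samples do not match the centroids")
  }
  p <- if (assignment$distance == "manhattan") 1 else 2
  states <- rownames(cen)[order(rownames(cen))]
  cen <- cen[states, , drop = FALSE]
  out <- apply(active, 1L, function(row) {
    d <- apply(cen, 1L, function(c0) sum(abs(row - c0)^p)^(1 / p))
    states[which.min(d)]  # which.min takes the first minimum: tie -> A < B < C
  })
  factor(out, levels = states)
}
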