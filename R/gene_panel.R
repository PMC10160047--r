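#' Construct a synthetic gene panel with chromosome assignments
#'
#' Builds the gene -> chromosome map used by the CNV callers: every gene gets a
#' chromosome label and a strictly increasing position index within its
#' chromosome (genomic order). Genes are distributed round-robin so chromosome
#' sizes differ by at most one gene.
#'
#' @param n_genes Total number of genes (>= `n_chromosomes`).
#' @param n_chromosomes Number of chromosomes, 2..23. The first 22 are the
#'   autosomes "1".."22"; a 23rd, if requested, is "X" (excluded by the
#'   CNV-selection step, which operates on autosomes only).
#' @param seed Integer seed; the panel is deterministic given its arguments,
#'   the seed is accepted for interface symmetry with the other generators.
#'
#' @return A `gene_panel` data.frame with columns `gene_id`, `chromosome`
#'   (factor, levels in genomic order) and `position_index`.
#' @examples
#' panel <- make_gene_panel(200, 10, seed = 1)
#' table(panel$chromosome)
#' @export
make_gene_panel <- function(n_genes, n_chromosomes, seed = 1L) {
  if (n_chromosomes < 2L) stop_invalid("`n_chromosomes` must be >= 2")
  if (n_chromosomes > 23L) stop_invalid("`n_chromosomes` must be <= 23 (22 autosomes + X)")
  if (n_genes < n_chromosomes) {
    stop_invalid("`n_genes` (", n_genes, ") must be >= `n_chromosomes` (", n_chromosomes, ")")
  }
  chrom_labels <- c(as.character(1:22), "X")[seq_len(n_chromosomes)]
  chrom <- rep_len(chrom_labels, n_genes)
  ord <- order(match(chrom, chrom_labels))
  chrom <- chrom[ord]
  pos <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  panel <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    chromosome = factor(chrom, levels = chrom_labels),
    position_index = as.integer(pos),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("gene_panel", "data.frame")
  panel
}

#' Canonical cell-state names
#'
#' The 12 non-neoplastic microenvironment states and the 6 glioma
#' transcriptional states used throughout the pipeline.
#'
#' @return Character vector of state names.
#' @export
nonneoplastic_states <- function() {
  c("Ast1", "Ast2", "Ast3", "Endothelial", "mgTAM", "moTAM",
    "Myel1", "Neuron", "Oligodendrocyte", "OPC", "prTAM", "Tcell")
}

#' @rdname nonneoplastic_states
#' @export
glioma_states <- function() {
  c("gl_PN1", "gl_PN2", "gl_Mes1", "gl_Mes2", "gl_Pro1", "gl_Pro2")
}

#' @rdname nonneoplastic_states
#' @export
all_states <- function() c(nonneoplastic_states(), glioma_states())

#' Generate per-state mean expression profiles with marker genes
#'
#' Each of the 18 canonical cell states receives a shared log-normal baseline
#' expression profile plus a disjoint block of marker genes up-regulated by
#' `marker_fold`. Profiles are normalized to sum to one, so they act as
#' per-gene sampling probabilities at a given library size.
#'
#' @param panel A [make_gene_panel()] panel.
#' @param states Character vector of state names (default all 18).
#' @param n_markers Markers per state (disjoint across states).
#' @param marker_fold Fold-change of marker genes over baseline.
#' @param baseline_sdlog Log-normal spread of the shared baseline expression
#'   (default 0.5, about a 10-fold central dynamic range). On a reduced gene
#'   panel every gene stands in for several real transcripts, so the spread
#'   is kept moderate to preserve per-chromosome signal-to-noise.
#' @param seed Integer seed.
#' @return A `state_profiles` list with `profiles` (gene x state matrix of
#'   mean expression fractions), `markers` (named list of gene-id vectors)
#'   and `panel`.
#' @export
make_state_profiles <- function(panel, states = all_states(), n_markers = 15L,
                                marker_fold = 8, baseline_sdlog = 0.5, seed = 1L) {
  n_genes <- nrow(panel)
  if (length(states) * n_markers > n_genes) {
    stop_invalid("not enough genes for ", length(states), " x ", n_markers, " disjoint markers")
  }
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = baseline_sdlog)
    marker_pool <- sample.int(n_genes, length(states) * n_markers)
    profiles <- matrix(rep(base, length(states)), ncol = length(states),
                       dimnames = list(panel$gene_id, states))
    markers <- vector("list", length(states))
    names(markers) <- states
    for (i in seq_along(states)) {
      idx <- marker_pool[seq.int((i - 1L) * n_markers + 1L, i * n_markers)]
      profiles[idx, i] <- profiles[idx, i] * marker_fold
      markers[[i]] <- panel$gene_id[sort(idx)]
    }
    profiles <- sweep(profiles, 2L, colSums(profiles), "/")
    structure(list(profiles = profiles, markers = markers, panel = panel),
              class = "state_profiles")
  })
}
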