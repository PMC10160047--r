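#' Describe a planted copy-number profile
#'
#' @param gained,lost Character vectors of chromosome labels (disjoint).
#' @param gain_factor Multiplicative factor (> 1) applied to the expected
#'   expression of genes on gained chromosomes in neoplastic nuclei.
#' @param loss_factor Factor in (0, 1) for lost chromosomes.
#' @return A `cnv_profile` list.
#' @export
cnv_profile <- function(gained = "7", lost = "10", gain_factor = 1.5, loss_factor = 0.5) {
  gained <- as.character(gained); lost <- as.character(lost)
  if (length(intersect(gained, lost)) > 0L) stop_invalid("gained and lost chromosomes overlap")
  if (gain_factor <= 1) stop_invalid("`gain_factor` must be > 1")
  if (loss_factor <= 0 || loss_factor >= 1) stop_invalid("`loss_factor` must be in (0, 1)")
  structure(list(gained = gained, lost = lost,
                 gain_factor = gain_factor, loss_factor = loss_factor),
            class = "cnv_profile")
}

#' Describe one simulated snRNA-seq sample
#'
#' @param sample_id Sample identifier.
#' @param condition One of `"primary"`, `"recurrent"`, `"epilepsy"`, `"LGG"`.
#' @param composition Named numeric over cell states, summing to 1.
#' @param n_nuclei Number of nuclei to draw.
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(sample_id, condition, composition, n_nuclei) {
  condition <- match.arg(condition, c("primary", "recurrent", "epilepsy", "LGG"))
  check_prob_vector(composition, paste0("composition of sample ", sample_id))
  if (is.null(names(composition))) stop_invalid("composition must be named by cell state")
  bad <- setdiff(names(composition), all_states())
  if (length(bad)) stop_invalid("unknown cell state(s): ", paste(bad, collapse = ", "))
  if (n_nuclei < 1L) stop_invalid("`n_nuclei` must be >= 1")
  structure(list(sample_id = sample_id, condition = condition,
                 composition = composition, n_nuclei = as.integer(n_nuclei)),
            class = "sample_spec")
}

#' Simulate single-nucleus RNA-seq counts with planted chromosome-level CNVs
#'
#' Nuclei are drawn per sample from the given cell-state composition. Counts
#' for gene g in nucleus n are negative binomial with mean
#' `library_size_n * profile[g, state_n] * cnv_factor(g, n)` and dispersion
#' `theta` (Var = mu + mu^2/theta). The CNV factor applies only to nuclei in
#' glioma states: genes on gained chromosomes are multiplied by
#' `cnv$gain_factor`, genes on lost chromosomes by `cnv$loss_factor`.
#' `true_cnv_label` is `CNVpos` exactly for glioma-state nuclei.
#'
#' @param panel A [make_gene_panel()] panel.
#' @param profiles A [make_state_profiles()] object.
#' @param sample_specs List of [sample_spec()] objects.
#' @param cnv A [cnv_profile()].
#' @param theta NB dispersion (default 10).
#' @param library_size_meanlog,library_size_sdlog Log-normal library-size
#'   parameters. The default median of 2e5 reads per nucleus corresponds to
#'   ~100 reads per panel gene: on a reduced panel (~2000 genes standing in
#'   for a full transcriptome) this preserves the per-chromosome
#'   signal-to-noise a chromosome with several hundred measured genes has in
#'   real data, keeping Poisson noise small against the NB dispersion floor.
#' @param mito_shape1,mito_shape2 Beta parameters of the simulated
#'   mitochondrial read fraction (defaults: mean 0.05).
#' @param seed Integer seed.
#'
#' @return An `annotated_counts` list: `counts` (gene x nucleus integer
#'   matrix), `nucleus_meta` (data.frame: `nucleus_id`, `sample_id`,
#'   `condition`, `true_state`, `true_cnv_label`, `detected_genes`,
#'   `total_reads`, `mito_fraction`) and `panel`.
#' @export
simulate_snrnaseq <- function(panel, profiles, sample_specs, cnv = cnv_profile(),
                              theta = 10, library_size_meanlog = log(2e5),
                              library_size_sdlog = 0.3,
                              mito_shape1 = 2, mito_shape2 = 38, seed = 1L) {
  if (inherits(sample_specs, "sample_spec")) sample_specs <- list(sample_specs)
  prof <- profiles$profiles
  stopifnot(nrow(prof) == nrow(panel))
  gain_idx <- panel$chromosome %in% cnv$gained
  loss_idx <- panel$chromosome %in% cnv$lost
  with_seed(seed, {
    per_sample <- lapply(sample_specs, function(sp) {
      states <- sample(names(sp$composition), sp$n_nuclei, replace = TRUE,
                       prob = sp$composition)
      lib <- stats::rlnorm(sp$n_nuclei, library_size_meanlog, library_size_sdlog)
      counts <- matrix(0L, nrow = nrow(panel), ncol = sp$n_nuclei)
      for (j in seq_len(sp$n_nuclei)) {
        mu <- lib[j] * prof[, states[j]]
        if (states[j] %in% glioma_states()) {
          mu[gain_idx] <- mu[gain_idx] * cnv$gain_factor
          mu[loss_idx] <- mu[loss_idx] * cnv$loss_factor
        }
        counts[, j] <- stats::rnbinom(nrow(panel), mu = mu, size = theta)
      }
      meta <- data.frame(
        sample_id = sp$sample_id, condition = sp$condition,
        true_state = states,
        true_cnv_label = ifelse(states %in% glioma_states(), "CNVpos", "CNVneg"),
        mito_fraction = stats::rbeta(sp$n_nuclei, mito_shape1, mito_shape2),
        stringsAsFactors = FALSE
      )
      list(counts = counts, meta = meta)
    })
    counts <- do.call(cbind, lapply(per_sample, `[[`, "counts"))
    meta <- do.call(rbind, lapply(per_sample, `[[`, "meta"))
    meta$nucleus_id <- sprintf("n%06d", seq_len(nrow(meta)))
    meta$detected_genes <- colSums(counts > 0L)
    meta$total_reads <- colSums(counts)
    rownames(counts) <- panel$gene_id
    colnames(counts) <- meta$nucleus_id
    meta <- meta[, c("nucleus_id", "sample_id", "condition", "true_state",
                     "true_cnv_label", "detected_genes", "total_reads", "mito_fraction")]
    rownames(meta) <- NULL
    structure(list(counts = counts, nucleus_meta = meta, panel = panel),
              class = "annotated_counts")
  })
}

#' Quality-control filtering of nuclei
#'
#' Keeps nuclei with at least `min_genes` detected genes, at least `min_reads`
#' total reads and a mitochondrial read fraction of at most `max_mito`, the
#' standard snRNA-seq cuts for this assay. The number of nuclei removed by
#' each criterion is reported via `message()`.
#'
#' @param x An `annotated_counts` object.
#' @param min_genes,min_reads,max_mito QC thresholds.
#' @return The filtered `annotated_counts`; a warning is issued if no nucleus
#'   survives.
#' @export
qc_filter <- function(x, min_genes = 400L, min_reads = 10000L, max_mito = 0.15) {
  meta <- x$nucleus_meta
  fail_genes <- meta$detected_genes < min_genes
  fail_reads <- meta$total_reads < min_reads
  fail_mito <- meta$mito_fraction > max_mito
  keep <- !(fail_genes | fail_reads | fail_mito)
  message(sprintf("qc_filter: removed %d/%d nuclei (%d low genes, %d low reads, %d high mito)",
                  sum(!keep), length(keep), sum(fail_genes), sum(fail_reads), sum(fail_mito)))
  if (!any(keep)) warning("qc_filter: no nuclei pass QC; returning empty object")
  out <- x
  out$counts <- x$counts[, keep, drop = FALSE]
  out$nucleus_meta <- meta[keep, , drop = FALSE]
  rownames(out$nucleus_meta) <- NULL
  out
}
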