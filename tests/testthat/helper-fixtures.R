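# Shared fixture builders. Everything is generated in code at test time.

small_panel <- function(n_genes = 600L, n_chrom = 22L) {
  make_gene_panel(n_genes, n_chrom, seed = 1L)
}

# A compact two-sample snRNA-seq simulation with the default planted
# chr7 gain / chr10 loss.
small_sim <- function(n_per_sample = 200L, seed = 11L, panel = small_panel(),
                      profiles = make_state_profiles(panel, seed = 2L)) {
  specs <- list(
    sample_spec("S1", "primary",
                c(Neuron = 0.35, Oligodendrocyte = 0.35, gl_PN1 = 0.15, gl_Mes1 = 0.15),
                n_per_sample),
    sample_spec("S2", "recurrent",
                c(Neuron = 0.25, Oligodendrocyte = 0.15, gl_Pro1 = 0.3, gl_Mes2 = 0.3),
                n_per_sample)
  )
  simulate_snrnaseq(panel, profiles, specs, cnv_profile(), seed = seed)
}

# Hand-built annotated_counts with fully controlled counts and QC fields.
manual_counts <- function(counts, chrom, sample_id = rep("S1", ncol(counts)),
                          mito = rep(0.05, ncol(counts))) {
  panel <- data.frame(
    gene_id = rownames(counts),
    chromosome = factor(chrom, levels = unique(chrom)),
    position_index = as.integer(stats::ave(seq_along(chrom), chrom, FUN = seq_along)),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("gene_panel", "data.frame")
  meta <- data.frame(
    nucleus_id = colnames(counts), sample_id = sample_id,
    condition = "primary", true_state = "Neuron", true_cnv_label = "CNVneg",
    detected_genes = colSums(counts > 0), total_reads = colSums(counts),
    mito_fraction = mito, stringsAsFactors = FALSE
  )
  structure(list(counts = counts, nucleus_meta = meta, panel = panel),
            class = "annotated_counts")
}

# Per-sample cell-state draws from a composition matrix -> annotation table.
annotations_from_compositions <- function(comp, n_nuclei = 300L, seed = 1L,
                                          prefix = "") {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(comp)), function(i) {
      st <- sample(colnames(comp), n_nuclei, replace = TRUE, prob = comp[i, ])
      data.frame(sample_id = paste0(prefix, rownames(comp)[i]), state = st,
                 cnv_label = ifelse(st %in% glioma_states(), "CNVpos", "CNVneg"),
                 stringsAsFactors = FALSE)
    }))
  })
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Independent brute-force SCC oracle: dense double loop over all spot pairs.
scc_brute_force <- function(x, y, w) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) acc <- acc + w[i, j] * xc[i] * yc[j]
  (n / sum(w)) * acc / sqrt(sum(xc^2) * sum(yc^2))
}
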