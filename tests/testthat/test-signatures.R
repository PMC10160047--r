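test_that("pseudobulk sums normalized counts per sample with half-up rounding", {
  norm <- matrix(c(1.2, 1.3,
                   0.4, 0.4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("n1", "n2")))
  pb <- pseudobulk(norm, c("S1", "S1"))
  expect_identical(pb["g1", "S1"], 3L)   # 2.5 rounds half-up to 3
  expect_identical(pb["g2", "S1"], 1L)   # 0.8 -> 1

  # one nucleus per sample: rounded copy
  pb1 <- pseudobulk(norm, c("S1", "S2"))
  expect_identical(unname(pb1[, "S1"]), c(1L, 0L))

  # permuting nuclei within a sample changes nothing
  pb2 <- pseudobulk(norm[, c(2, 1)], c("S1", "S1"))
  expect_identical(pb2, pb)

  expect_error(pseudobulk(norm, "S1"), class = "tissuestates_invalid_argument")
})

test_that("size_factors implements median-of-ratios", {
  counts <- matrix(c(1, 2,
                     2, 4), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  same <- matrix(rpois(40, 20) + 1, nrow = 10, ncol = 4)
  same <- same[, c(1, 1, 1, 1)]
  expect_equal(unname(size_factors(same)), rep(1, 4))

  # doubling one sample's counts doubles its factor relative to the others
  doubled <- counts
  doubled[, 2] <- counts[, 2] * 2
  sf2 <- size_factors(doubled)
  expect_equal(sf2[["s2"]] / sf2[["s1"]], 2 * sf[["s2"]] / sf[["s1"]])

  zeros <- matrix(c(0, 5, 5, 0), nrow = 2)
  expect_error(size_factors(zeros), class = "tissuestates_invalid_argument")
})

test_that("bh_adjust matches the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)

  # exact agreement with the independent base-R implementation on random input
  for (n in c(10, 100, 1000)) {
    p <- withr::with_seed(n, runif(n))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
  # stable under input order
  p <- withr::with_seed(4, runif(50))
  ord <- sample(50)
  expect_equal(bh_adjust(p)[ord], bh_adjust(p[ord]))

  expect_error(bh_adjust(c(0.5, 1.2)), class = "tissuestates_invalid_argument")
})

test_that("nb_wald_de handles degenerate genes and singular designs", {
  withr::with_seed(9, {
    counts <- matrix(rnbinom(200 * 8, mu = 50, size = 10), nrow = 200,
                     dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:8)))
  })
  counts[1, ] <- 77L  # identical counts across samples
  groups <- rep(c("A", "B"), each = 4)
  de <- nb_wald_de(counts, groups, c("A", "B"))
  expect_equal(de$log2_fold_change[1], 0)
  expect_equal(de$p_value[1], 1)
  expect_true(all(de$q_value >= de$p_value - 1e-12, na.rm = TRUE))

  # batch confounded with state
  expect_error(nb_wald_de(counts, groups, c("A", "B"), batch = groups),
               class = "tissuestates_invalid_argument")
  expect_error(nb_wald_de(counts, c(rep("A", 7), "B"), c("A", "B")),
               class = "tissuestates_invalid_argument")
})

test_that("nb_wald_de recovers planted fold changes", {
  withr::with_seed(10, {
    n_gene <- 600
    mu <- exp(rnorm(n_gene, log(60), 0.6))
    counts <- matrix(rnbinom(n_gene * 12, mu = mu, size = 10), nrow = n_gene,
                     dimnames = list(sprintf("g%04d", 1:n_gene), sprintf("s%02d", 1:12)))
    de_idx <- 1:40
    groups <- rep(c("A", "B"), each = 6)
    counts[de_idx, groups == "A"] <-
      rnbinom(length(de_idx) * 6, mu = 4 * mu[de_idx], size = 10)
  })
  de <- nb_wald_de(counts, groups, c("A", "B"))
  hits <- which(de$q_value < 0.05 & de$log2_fold_change > 0)
  expect_gte(mean(de_idx %in% hits), 0.8)
  expect_lte(mean(setdiff(seq_len(600), de_idx) %in% hits), 0.02)
})

test_that("derive_state_signatures keeps unique, ranked, truncated gene sets", {
  mk_de <- function(contrast, up_genes, lfc = 2) {
    genes <- sprintf("g%03d", 1:40)
    res <- data.frame(gene = genes, base_mean = 10,
                      log2_fold_change = ifelse(genes %in% up_genes, lfc, 0),
                      wald_statistic = 0,
                      p_value = ifelse(genes %in% up_genes, 1e-6, 0.9),
                      q_value = ifelse(genes %in% up_genes, 1e-5, 0.95),
                      stringsAsFactors = FALSE)
    attr(res, "contrast") <- contrast
    class(res) <- c("de_result", "data.frame")
    res
  }
  # g1, g2 up in B vs A and B vs C; g2 also up in C vs A and C vs B
  # (independently supplied directional tables) -> unique B signature = {g1}
  sigs <- suppressWarnings(derive_state_signatures(list(
    mk_de(c("B", "A"), c("g001", "g002")),
    mk_de(c("B", "C"), c("g001", "g002")),
    mk_de(c("C", "A"), "g002"),
    mk_de(c("C", "B"), "g002"),
    mk_de(c("A", "B"), character(0)),
    mk_de(c("A", "C"), character(0)))))
  expect_identical(sigs$B, "g001")  # g002 removed: also in C's candidate set
  expect_length(sigs$A, 0)

  # truncation to top_n by mean log2FC
  many <- sprintf("g%03d", 1:30)
  lfcs <- seq(5, 2, length.out = 40)
  de1 <- mk_de(c("B", "A"), many); de2 <- mk_de(c("B", "C"), many)
  de1$log2_fold_change <- ifelse(de1$gene %in% many, lfcs, 0)
  de2$log2_fold_change <- ifelse(de2$gene %in% many, lfcs, 0)
  sig_t <- suppressWarnings(
    derive_state_signatures(list(a = de1, b = de2,
                                 c = mk_de(c("C", "A"), character(0))),
                            top_n = 10))
  expect_length(sig_t$B, 10)
  expect_identical(sig_t$B, sprintf("g%03d", 1:10))  # highest mean log2FC kept

  # no significant genes anywhere -> empty signatures with warning
  empty <- list(a = mk_de(c("A", "B"), character(0)),
                b = mk_de(c("B", "C"), character(0)),
                c = mk_de(c("C", "A"), character(0)))
  expect_warning(s0 <- derive_state_signatures(empty), "empty")
  expect_true(all(lengths(s0) == 0))
})

test_that("signature scores track planted composition in bulk mixtures", {
  panel <- make_gene_panel(1500, 22, seed = 1)
  prof <- make_state_profiles(panel, seed = 2)
  cs <- simulate_compositions(c(10, 10, 10), concentration = 100, seed = 81)
  bulk <- simulate_bulk(prof, cs$compositions, library_size = 3e5, seed = 82)
  groups <- as.character(cs$archetype)
  de_AB <- nb_wald_de(bulk, groups, c("A", "B"))
  de_AC <- nb_wald_de(bulk, groups, c("A", "C"))
  de_BC <- nb_wald_de(bulk, groups, c("B", "C"))
  sigs <- derive_state_signatures(list(de_AB, de_AC, de_BC))
  expect_true(all(lengths(sigs) > 0))
  expect_true(all(lengths(sigs) <= 150))
  # pairwise disjoint
  expect_length(intersect(sigs$A, sigs$B), 0)
  expect_length(intersect(sigs$B, sigs$C), 0)

  logexpr <- log2(sweep(bulk, 2, size_factors(bulk), "/") + 1)
  es <- ssgsea(logexpr, sigs)
  # enrichment for the state-B signature tracks the planted fraction of
  # B-archetype cell states across samples
  b_fraction <- rowSums(cs$compositions[, c("Ast3", "moTAM", "mgTAM", "Tcell",
                                            "Myel1", "Ast2")])
  expect_gte(cor(es[, "B"], b_fraction, method = "spearman"), 0.7)
})
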