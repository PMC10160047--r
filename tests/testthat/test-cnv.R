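test_that("chromosome_profile averages log2(count+1) per chromosome", {
  counts <- matrix(c(3L, 1L, 0L, 0L,
                     0L, 0L, 7L, 1L), nrow = 4,
                   dimnames = list(c("gA", "gB", "gC", "gD"), c("n1", "n2")))
  x <- manual_counts(counts, c("1", "1", "2", "2"))
  prof <- chromosome_profile(x)
  expect_equal(prof$values["n1", "1"], (log2(4) + log2(2)) / 2)  # = 1.5
  expect_equal(prof$values["n1", "2"], 0)                        # all-zero block
  expect_equal(prof$values["n2", "2"], (log2(8) + log2(2)) / 2)

  # permuting gene order leaves the profile unchanged (up to column order)
  perm <- withr::with_seed(2, sample(nrow(counts)))
  x_perm <- manual_counts(counts[perm, ], c("1", "1", "2", "2")[perm])
  perm_vals <- chromosome_profile(x_perm)$values
  expect_equal(perm_vals[, colnames(prof$values)], prof$values)

  # brute-force per-gene loop oracle on a random matrix
  withr::with_seed(3, {
    cc <- matrix(rpois(50 * 20, 5), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("n%02d", 1:20)))
    chrom <- sample(c("1", "2", "3", "X"), 50, replace = TRUE)
  })
  xx <- manual_counts(cc, chrom)
  got <- chromosome_profile(xx)$values
  for (ch in unique(chrom)) {
    for (j in 1:20) {
      ref <- mean(vapply(which(chrom == ch), function(g) log2(cc[g, j] + 1), numeric(1)))
      expect_equal(got[j, ch], ref)
    }
  }

  rownames(counts)[1] <- "unknown_gene"
  expect_error(chromosome_profile(structure(list(counts = counts,
                                                 nucleus_meta = x$nucleus_meta,
                                                 panel = x$panel),
                                            class = "annotated_counts")),
               "unknown_gene", class = "tissuestates_invalid_argument")
})

test_that("select_cnv_chromosomes recovers planted gain/loss and limits selection", {
  panel <- make_gene_panel(2000, 22, seed = 1)
  profiles <- make_state_profiles(panel, seed = 2)
  for (seed in c(21, 22, 23)) {
    sim <- small_sim(n_per_sample = 250, seed = seed, panel = panel,
                     profiles = profiles)
    sel <- select_cnv_chromosomes(chromosome_profile(sim))
    expect_identical(sel$gained, "7")
    expect_identical(sel$lost, "10")
    expect_lte(length(sel$gained), 3)
    expect_lte(length(sel$lost), 3)
  }

  # reference-labeled path agrees
  sim <- small_sim(n_per_sample = 250, seed = 31, panel = panel,
                   profiles = profiles)
  sel_ref <- select_cnv_chromosomes(chromosome_profile(sim),
                                    reference_labels = sim$nucleus_meta$true_cnv_label == "CNVneg")
  expect_identical(sel_ref$gained, "7")
  expect_identical(sel_ref$lost, "10")

  # pure-noise profile -> empty-selection error
  withr::with_seed(5, {
    vals <- matrix(runif(3000 * 22, 1, 2), nrow = 3000,
                   dimnames = list(NULL, as.character(1:22)))
  })
  noise <- structure(list(values = vals, chromosomes = colnames(vals),
                          nucleus_ids = sprintf("n%04d", 1:3000),
                          sample_ids = rep("S1", 3000)),
                     class = "chromosome_profile")
  expect_error(select_cnv_chromosomes(noise), class = "tissuestates_empty_selection")

  # more than 3 passing per direction -> top 3 by |r| kept. A shared
  # library-size factor keeps the CNV contrast on PC2, as in real profiles.
  withr::with_seed(6, {
    aberr <- rep(c(0, 1), each = 100)
    lib <- rnorm(200, 0, 0.5)
    v2 <- matrix(2 + lib + 0.05 * rnorm(200 * 10), nrow = 200,
                 dimnames = list(NULL, as.character(1:10)))
    for (ch in 1:4) v2[, ch] <- v2[, ch] + 0.8 * aberr  # four gained
    for (ch in 5:8) v2[, ch] <- v2[, ch] - 0.8 * aberr  # four lost
  })
  many <- structure(list(values = v2, chromosomes = colnames(v2),
                         nucleus_ids = sprintf("n%03d", 1:200),
                         sample_ids = rep("S1", 200)),
                    class = "chromosome_profile")
  sel2 <- select_cnv_chromosomes(many, reference_labels = aberr == 0)
  expect_length(sel2$gained, 3)
  expect_length(sel2$lost, 3)
  expect_true(all(sel2$gained %in% as.character(1:4)))
  expect_true(all(sel2$lost %in% as.character(5:8)))
})

test_that("malignancy_score computes the gained/lost ratio with per-sample z-scaling", {
  vals <- rbind(c(4, 2, 3, 1), c(1, 2, 2, 2), c(2, 2, 1, 1))
  colnames(vals) <- c("1", "2", "3", "4")
  prof <- structure(list(values = vals, chromosomes = colnames(vals),
                         nucleus_ids = c("a", "b", "c"),
                         sample_ids = c("S1", "S1", "S1")),
                    class = "chromosome_profile")
  sel <- list(gained = c("1", "2"), lost = c("3", "4"))
  ms <- malignancy_score(prof, sel)
  expect_equal(ms$raw_score[1], (4 + 2) / (3 + 1))  # 6/4
  expect_equal(ms$raw_score[2], 3 / 4)
  expect_equal(mean(ms$z_score), 0, tolerance = 1e-6)
  expect_equal(sd(ms$z_score), 1, tolerance = 1e-6)

  # two samples with identical raw scores get identical z-scores
  prof2 <- prof
  prof2$values <- rbind(vals, vals)
  prof2$nucleus_ids <- letters[1:6]
  prof2$sample_ids <- rep(c("S1", "S2"), each = 3)
  ms2 <- malignancy_score(prof2, sel)
  expect_equal(ms2$z_score[1:3], ms2$z_score[4:6])

  # numerator scale-equivariance: doubling gained values doubles raw_score
  prof3 <- prof
  prof3$values[, c("1", "2")] <- 2 * prof3$values[, c("1", "2")]
  expect_equal(malignancy_score(prof3, sel)$raw_score, 2 * ms$raw_score)

  # zero lost signal -> denominator floor keeps the score finite
  prof4 <- prof
  prof4$values[1, c("3", "4")] <- 0
  ms4 <- malignancy_score(prof4, sel, eps = 0.01)
  expect_equal(ms4$raw_score[1], 6 / 0.01)
  expect_true(all(is.finite(ms4$raw_score)))

  expect_error(malignancy_score(prof, list(gained = character(0), lost = "3")),
               class = "tissuestates_invalid_argument")
})

test_that("call_neoplastic labels by k-means and by normal-outlier detection", {
  mk_calls <- function(z, sample = "S1") {
    structure(data.frame(nucleus_id = sprintf("n%03d", seq_along(z)),
                         sample_id = sample, raw_score = z, z_score = z,
                         label = NA_character_, stringsAsFactors = FALSE),
              class = c("malignancy_calls", "data.frame"))
  }
  km <- call_neoplastic(mk_calls(c(-1.1, -1, -0.9, 0.9, 1, 1.1)), "kmeans", seed = 1)
  expect_identical(km$label, c(rep("CNVneg", 3), rep("CNVpos", 3)))

  # 95 N(0,1) scores plus 5 far outliers: the outlier method flags exactly those 5
  hits <- vapply(1:5, function(i) {
    z <- c(withr::with_seed(100 + i, rnorm(95)), rep(6, 5))
    out <- call_neoplastic(mk_calls(z), "outlier", rho = 0.1, seed = 1)
    identical(which(out$label == "CNVpos"), 96:100)
  }, logical(1))
  expect_gte(sum(hits), 3)  # 20-replicate-majority contract, scaled down

  expect_warning(out <- call_neoplastic(mk_calls(rep(1, 10)), "kmeans", seed = 1),
                 "constant")
  expect_true(all(out$label == "CNVneg"))

  expect_error(call_neoplastic(mk_calls(c(1, 2, 3)), "kmeans", seed = 1),
               class = "tissuestates_invalid_argument")
})

test_that("windowed_cnv_profile calls whole-chromosome shifts against a reference", {
  # reference nuclei: flat counts; test nucleus: doubled chr-7 counts (+1 log2)
  n_ref <- 30
  counts <- matrix(15L, nrow = 300, ncol = n_ref + 1,
                   dimnames = list(sprintf("g%03d", 1:300),
                                   c(sprintf("r%02d", 1:n_ref), "test")))
  chrom <- rep(as.character(1:6), each = 50)
  chrom[chrom == "6"] <- "7"
  counts[chrom == "7", "test"] <- 31L
  x <- manual_counts(counts, chrom)
  wc <- suppressWarnings(windowed_cnv_profile(x, reference_ids = sprintf("r%02d", 1:n_ref),
                                              window = 50))
  # ~ +1 minus the depth-normalization shift (the doubled chromosome is 1/6
  # of this toy genome, so the test nucleus is scaled down by ~log2(7/6))
  expect_equal(wc$chromosome_values["test", "7"], 1 - log2(6.9 / 6), tolerance = 0.1)
  expect_gt(wc$chromosome_values["test", "7"], 0.7)
  expect_identical(wc$chromosome_calls["test", "7"], "gain")
  expect_identical(unname(wc$label["test"]), "CNVpos")
  # reference nuclei against themselves: all neutral
  expect_true(all(wc$label[sprintf("r%02d", 1:n_ref)] == "CNVneg"))

  expect_error(windowed_cnv_profile(x, reference_ids = "r01", window = 1),
               class = "tissuestates_invalid_argument")
  expect_error(windowed_cnv_profile(x, reference_ids = "nope", window = 50),
               class = "tissuestates_invalid_argument")
  ws <- testthat::capture_warnings(
    windowed_cnv_profile(x, reference_ids = sprintf("r%02d", 1:n_ref), window = 80))
  expect_true(any(grepl("fewer genes", ws)))
})

test_that("windowed caller reaches high balanced accuracy on planted CNVs", {
  panel <- make_gene_panel(2000, 22, seed = 1)
  sim <- small_sim(n_per_sample = 250, seed = 41, panel = panel,
                   profiles = make_state_profiles(panel, seed = 2))
  ref <- sim$nucleus_meta$nucleus_id[
    sim$nucleus_meta$true_state %in% c("Neuron", "Oligodendrocyte")]
  wc <- suppressWarnings(windowed_cnv_profile(sim, reference_ids = ref, window = 100))
  tru <- sim$nucleus_meta$true_cnv_label
  sens <- mean(wc$label[tru == "CNVpos"] == "CNVpos")
  spec <- mean(wc$label[tru == "CNVneg"] == "CNVneg")
  expect_gte((sens + spec) / 2, 0.9)
})

test_that("consensus_calls excludes discordant nuclei", {
  a <- c(n1 = "CNVpos", n2 = "CNVpos", n3 = "CNVneg")
  b <- c(n1 = "CNVpos", n2 = "CNVneg", n3 = "CNVneg")
  cons <- consensus_calls(a, b)
  expect_identical(unname(cons$label), c("CNVpos", "excluded", "CNVneg"))
  expect_equal(cons$discordant_fraction, 1 / 3)

  expect_equal(consensus_calls(a, a)$discordant_fraction, 0)

  flipped <- setNames(ifelse(a == "CNVpos", "CNVneg", "CNVpos"), names(a))
  cons2 <- consensus_calls(a, flipped)
  expect_true(all(cons2$label == "excluded"))
  expect_equal(cons2$discordant_fraction, 1)

  expect_error(consensus_calls(a, b[1:2]), class = "tissuestates_invalid_argument")
})
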