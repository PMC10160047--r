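#' Write single-nucleus counts in MatrixMarket layout
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `metadata.tsv` into
#' `dir`, the conventional sparse exchange layout for droplet count data.
#'
#' @param x An `annotated_counts` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_snrnaseq <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(x$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(x$panel, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(x$nucleus_meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read single-nucleus counts written by [write_snrnaseq()]
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#'   `metadata.tsv`.
#' @return An `annotated_counts` object.
#' @export
read_snrnaseq <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  panel <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  panel$chromosome <- factor(panel$chromosome, levels = unique(panel$chromosome))
  class(panel) <- c("gene_panel", "data.frame")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"), stringsAsFactors = FALSE)
  dimnames(counts) <- list(panel$gene_id, barcodes)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, nucleus_meta = meta, panel = panel),
            class = "annotated_counts")
}

#' Write a spatial dataset as position and proportion tables
#'
#' Produces `tissue_positions.csv` (`spot_id`, `row`, `col`, `x_um`, `y_um`)
#' and `proportions.csv` (spot x cell type) in `dir`.
#'
#' @param ds A `spatial_dataset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_spatial <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$spots, file.path(dir, "tissue_positions.csv"), row.names = FALSE)
  utils::write.csv(data.frame(spot_id = rownames(ds$proportions),
                              ds$proportions, check.names = FALSE),
                   file.path(dir, "proportions.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a spatial dataset written by [write_spatial()]
#'
#' @param dir Directory with `tissue_positions.csv` and `proportions.csv`.
#' @param pitch_um Lattice pitch to record (default 100).
#' @param sample_id Sample id to record (default: the directory name).
#' @return A `spatial_dataset`.
#' @export
read_spatial <- function(dir, pitch_um = 100, sample_id = basename(dir)) {
  spots <- utils::read.csv(file.path(dir, "tissue_positions.csv"),
                           stringsAsFactors = FALSE)
  props <- utils::read.csv(file.path(dir, "proportions.csv"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(props[, -1L, drop = FALSE])
  rownames(m) <- props$spot_id
  structure(list(spots = spots, proportions = m, pitch_um = pitch_um,
                 sample_id = sample_id),
            class = "spatial_dataset")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, `name TAB description TAB genes...`.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop_invalid("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  out
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of gene-id vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
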