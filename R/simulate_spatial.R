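#' Simulate a hexagonal-lattice spatial dataset with planted colocalization
#'
#' Spots are placed on an odd-row-offset hexagonal lattice with
#' center-to-center distance `pitch_um` (the Visium arrangement). Each cell
#' type receives a smooth latent Gaussian random field (squared-exponential
#' kernel, length scale `field_length_scale_um`); pairs named in
#' `colocalization` additionally share a latent component with mixing weight
#' `w`, so their per-spot proportions co-vary. Per-spot proportions are the
#' softmax of the latent fields and therefore sum to one exactly.
#'
#' @param cell_types Character vector of cell-type names.
#' @param lattice_rows,lattice_cols Lattice dimensions (>= 2 each).
#' @param pitch_um Center-to-center spot distance in micrometers.
#' @param colocalization A data.frame (or NULL) with columns `type_a`,
#'   `type_b`, `weight` in `[0, 1]`: the shared-field mixing weight.
#' @param field_length_scale_um Length scale of the latent fields.
#' @param field_amplitude Standard deviation of the latent fields before the
#'   softmax; larger values give patchier proportion maps.
#' @param sample_id Sample identifier stored with the dataset.
#' @param seed Integer seed.
#'
#' @return A `spatial_dataset` list: `spots` (data.frame `spot_id`, `row`,
#'   `col`, `x_um`, `y_um`), `proportions` (spot x cell-type matrix, rows sum
#'   to 1), `pitch_um`, `sample_id`.
#' @export
simulate_spatial <- function(cell_types, lattice_rows, lattice_cols,
                             pitch_um = 100, colocalization = NULL,
                             field_length_scale_um = 3 * pitch_um,
                             field_amplitude = 2, sample_id = "ST1", seed = 1L) {
  if (lattice_rows < 2L || lattice_cols < 2L) {
    stop_invalid("lattice must be at least 2 x 2")
  }
  cell_types <- as.character(cell_types)
  if (!is.null(colocalization)) {
    bad <- setdiff(unique(c(colocalization$type_a, colocalization$type_b)), cell_types)
    if (length(bad)) stop_invalid("unknown cell type(s) in colocalization spec: ",
                                  paste(bad, collapse = ", "))
  }
  grid <- expand.grid(col = seq_len(lattice_cols) - 1L, row = seq_len(lattice_rows) - 1L)
  # odd-row offset hex coordinates: odd rows shifted half a pitch, row spacing
  # pitch * sqrt(3)/2 so every first-ring neighbor sits at exactly one pitch
  x <- grid$col * pitch_um + ifelse(grid$row %% 2L == 1L, pitch_um / 2, 0)
  y <- grid$row * pitch_um * sqrt(3) / 2
  n <- nrow(grid)
  d2 <- as.matrix(stats::dist(cbind(x, y)))^2
  K <- exp(-d2 / (2 * field_length_scale_um^2))
  L <- chol(K + diag(1e-8, n))
  draw_field <- function() as.vector(crossprod(L, stats::rnorm(n)))
  with_seed(seed, {
    fields <- sapply(cell_types, function(ct) draw_field())
    if (!is.null(colocalization)) {
      for (i in seq_len(nrow(colocalization))) {
        w <- colocalization$weight[i]
        if (w < 0 || w > 1) stop_invalid("colocalization weight must be in [0, 1]")
        shared <- draw_field()
        for (ct in c(colocalization$type_a[i], colocalization$type_b[i])) {
          fields[, ct] <- sqrt(1 - w^2) * fields[, ct] + w * shared
        }
      }
    }
    props <- softmax_rows(field_amplitude * fields)
    colnames(props) <- cell_types
    spots <- data.frame(
      spot_id = sprintf("spot%05d", seq_len(n)),
      row = grid$row, col = grid$col, x_um = x, y_um = y,
      stringsAsFactors = FALSE
    )
    rownames(props) <- spots$spot_id
    structure(list(spots = spots, proportions = props, pitch_um = pitch_um,
                   sample_id = sample_id),
              class = "spatial_dataset")
  })
}
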