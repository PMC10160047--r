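# Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("tissuestates_invalid_argument", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one user-facing seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

check_prob_vector <- function(p, what = "composition", tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_invalid(what, " must be finite and nonnegative")
  }
  if (abs(sum(p) - 1) > tol) {
    stop_invalid(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")")
  }
  invisible(p)
}
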