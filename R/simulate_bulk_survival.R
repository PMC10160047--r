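#' Simulate bulk RNA-seq counts as mixtures of cell-state profiles
#'
#' Each sample's expected expression is the convex combination of the state
#' mean-expression profiles weighted by the sample's cell-state fractions,
#' scaled to `library_size`; counts are negative-binomial.
#'
#' @param profiles A [make_state_profiles()] object.
#' @param compositions Sample x state matrix of fractions; rows sum to 1 and
#'   columns must name states present in `profiles`.
#' @param library_size Expected total counts per sample.
#' @param theta NB dispersion (Var = mu + mu^2/theta); `Inf` gives Poisson-free
#'   expectation (counts equal to rounded means is NOT produced; use theta
#'   large for near-deterministic draws).
#' @param seed Integer seed.
#' @return A gene x sample integer matrix.
#' @export
simulate_bulk <- function(profiles, compositions, library_size = 1e6,
                          theta = 10, seed = 1L) {
  compositions <- as.matrix(compositions)
  bad <- setdiff(colnames(compositions), colnames(profiles$profiles))
  if (length(bad)) stop_invalid("unknown state(s) in compositions: ", paste(bad, collapse = ", "))
  for (i in seq_len(nrow(compositions))) {
    check_prob_vector(compositions[i, ], paste0("composition row ", i))
  }
  mu <- profiles$profiles[, colnames(compositions), drop = FALSE] %*% t(compositions) *
    library_size
  with_seed(seed, {
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = theta),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    if (is.null(colnames(counts))) {
      colnames(counts) <- sprintf("bulk%03d", seq_len(ncol(counts)))
    }
    counts
  })
}

#' Simulate per-sample compositions around tissue-state archetypes
#'
#' Draws sample compositions from Dirichlet distributions centered on three
#' archetypes over the 18 cell states: brain-like (neuron/oligodendrocyte
#' dominated), reactive/inflammatory (reactive astrocytes, myeloid, T cells)
#' and cellular-tumor (glioma-state dominated) -- the compositional structure
#' the tissue-state clustering is expected to recover.
#'
#' @param n_per_state Samples per archetype (length-3 integer or scalar).
#' @param concentration Dirichlet concentration multiplier; larger = tighter
#'   around the archetype mean.
#' @param seed Integer seed.
#' @return List with `compositions` (sample x 18 matrix), `archetype`
#'   (factor A/B/C per sample) and `archetype_means`.
#' @export
simulate_compositions <- function(n_per_state = c(3L, 3L, 3L), concentration = 100,
                                  seed = 1L) {
  n_per_state <- rep_len(as.integer(n_per_state), 3L)
  states <- all_states()
  arch <- matrix(0.005, nrow = 3, ncol = length(states),
                 dimnames = list(c("A", "B", "C"), states))
  arch["A", c("Neuron", "Oligodendrocyte", "OPC", "Ast1")] <- c(0.40, 0.25, 0.10, 0.10)
  arch["B", c("Ast3", "moTAM", "mgTAM", "Tcell", "Myel1", "Ast2")] <-
    c(0.25, 0.20, 0.15, 0.10, 0.10, 0.05)
  arch["C", glioma_states()] <- c(0.20, 0.15, 0.20, 0.15, 0.10, 0.10)
  arch <- arch / rowSums(arch)
  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
  }
  with_seed(seed, {
    rows <- list(); labels <- character(0)
    for (k in 1:3) {
      for (i in seq_len(n_per_state[k])) {
        rows[[length(rows) + 1L]] <- rdirichlet1(concentration * arch[k, ])
        labels <- c(labels, rownames(arch)[k])
      }
    }
    comp <- do.call(rbind, rows)
    colnames(comp) <- states
    rownames(comp) <- sprintf("S%02d", seq_len(nrow(comp)))
    list(compositions = comp, archetype = factor(labels, levels = c("A", "B", "C")),
         archetype_means = arch)
  })
}

#' Simulate survival data with an enrichment-dependent hazard
#'
#' Event times are exponential with hazard
#' `exp(log_hr * enrichment) / baseline_scale`. Censoring times are drawn
#' independently from `Uniform(0, c_max)`, with `c_max` solved so the
#' expected fraction of censored subjects equals `censor_rate`; independence
#' keeps the Cox and Kaplan-Meier estimators unbiased.
#'
#' @param enrichment Numeric enrichment score per subject.
#' @param log_hr Log hazard ratio per unit enrichment.
#' @param baseline_scale Baseline mean survival time (days) at enrichment 0.
#' @param censor_rate Probability of censoring, in `[0, 1)`.
#' @param covariates Optional data.frame of extra per-subject covariates
#'   carried into the output (e.g. age, sex, MGMT status).
#' @param seed Integer seed.
#' @return A data.frame with `time` (> 0), `event` (0/1), `enrichment` and any
#'   extra covariates.
#' @export
simulate_survival <- function(enrichment, log_hr = 1, baseline_scale = 500,
                              censor_rate = 0.3, covariates = NULL, seed = 1L) {
  if (censor_rate < 0 || censor_rate >= 1) stop_invalid("`censor_rate` must be in [0, 1)")
  n <- length(enrichment)
  with_seed(seed, {
    rate <- exp(log_hr * enrichment) / baseline_scale
    t_event <- stats::rexp(n, rate = rate)
    if (censor_rate > 0) {
      # P(censored | c_max) = mean_i (1 - exp(-r_i c_max)) / (r_i c_max)
      expected_cens <- function(cmax) mean((1 - exp(-rate * cmax)) / (rate * cmax))
      cmax <- stats::uniroot(function(cm) expected_cens(cm) - censor_rate,
                             lower = 1e-6 / max(rate),
                             upper = 1e6 / min(rate))$root
      t_cens <- stats::runif(n, 0, cmax)
    } else {
      t_cens <- rep(Inf, n)
    }
    event <- as.integer(t_event <= t_cens)
    time <- pmax(pmin(t_event, t_cens), .Machine$double.eps)
    out <- data.frame(time = time, event = event, enrichment = enrichment)
    if (!is.null(covariates)) out <- cbind(out, covariates)
    out
  })
}
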