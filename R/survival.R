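#' Binarize enrichment scores
#'
#' Subjects with strictly positive enrichment are "positive"; zero or
#' negative scores are "negative".
#'
#' @param scores Finite numeric vector.
#' @return Factor with levels `negative`, `positive`.
#' @export
binarize_enrichment <- function(scores) {
  if (any(!is.finite(scores))) stop_invalid("enrichment scores must be finite")
  factor(ifelse(scores > 0, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators.
#' @param groups Optional grouping factor (one curve per group).
#' @return A `km_curves` list of per-group data.frames with columns `time`,
#'   `n_risk`, `n_event`, `survival` (S(0) = 1 implicit; S nonincreasing).
#' @export
km_estimate <- function(time, event, groups = NULL) {
  if (any(time <= 0)) stop_invalid("times must be positive")
  if (!all(event %in% c(0, 1))) stop_invalid("`event` must be 0/1")
  groups <- if (is.null(groups)) factor(rep("all", length(time))) else factor(groups)
  out <- lapply(levels(groups), function(gl) {
    idx <- groups == gl
    t_g <- time[idx]; e_g <- event[idx]
    ts <- sort(unique(t_g[e_g == 1]))
    n_risk <- vapply(ts, function(tk) sum(t_g >= tk), numeric(1))
    n_event <- vapply(ts, function(tk) sum(t_g == tk & e_g == 1), numeric(1))
    data.frame(time = ts, n_risk = n_risk, n_event = n_event,
               survival = cumprod(1 - n_event / n_risk))
  })
  names(out) <- levels(groups)
  structure(out, class = "km_curves")
}

#' Two-group log-rank test
#'
#' Chi-squared statistic `(O - E)^2 / V` with observed, expected and
#' hypergeometric variance summed over distinct event times; p-value from a
#' chi-squared distribution with one degree of freedom.
#'
#' @param time,event As in [km_estimate()].
#' @param groups Factor with exactly two levels, each containing at least one
#'   event.
#' @return List: `chi2`, `p`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(time, event, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2L) stop_invalid("log-rank test requires exactly 2 groups")
  for (gl in levels(groups)) {
    if (sum(event[groups == gl]) == 0L) {
      stop_invalid("group ", gl, " has no events")
    }
  }
  g1 <- groups == levels(groups)[1L]
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (tk in ts) {
    at_risk <- time >= tk
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = c(o1, sum(event) - o1), expected = c(e1, sum(event) - e1))
}

#' Cox proportional hazards by Breslow partial likelihood
#'
#' Newton-Raphson maximization of the Breslow partial likelihood; standard
#' errors from the inverse observed information; Wald p-values and 95%
#' confidence intervals.
#'
#' @param time,event As in [km_estimate()].
#' @param covariates Numeric matrix or data.frame of covariates (factors and
#'   characters are expanded to treatment-coded dummies).
#' @param max_iter,tol Newton-Raphson controls; convergence when the maximum
#'   absolute score component falls below `tol`.
#' @return A `cox_result` data.frame: `coef`, `hazard_ratio`, `se`, `z`,
#'   `p_value`, `ci_lower`, `ci_upper`; attributes `loglik`, `iterations`,
#'   `tie_method = "breslow"`.
#' @export
cox_ph <- function(time, event, covariates, max_iter = 50L, tol = 1e-8) {
  if (any(time <= 0)) stop_invalid("times must be positive")
  if (sum(event) < 1L) stop_invalid("need at least one event")
  X <- build_design(covariates)
  const <- apply(X, 2L, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0L) stop_invalid("no non-constant covariate")
  if (qr(X)$rank < ncol(X)) {
    stop_invalid("covariate matrix is rank deficient; remove collinear covariates")
  }
  Xs <- scale(X, center = TRUE, scale = FALSE)
  p <- ncol(Xs)
  beta <- rep(0, p)
  partial <- function(beta) {
    eta <- drop(Xs %*% beta)
    r <- exp(eta)
    score <- rep(0, p); info <- matrix(0, p, p); ll <- 0
    for (tk in sort(unique(time[event == 1]))) {
      at_risk <- time >= tk
      dead <- time == tk & event == 1
      d <- sum(dead)
      s0 <- sum(r[at_risk])
      s1 <- colSums(Xs[at_risk, , drop = FALSE] * r[at_risk])
      s2 <- crossprod(Xs[at_risk, , drop = FALSE],
                      Xs[at_risk, , drop = FALSE] * r[at_risk])
      ll <- ll + sum(eta[dead]) - d * log(s0)
      score <- score + colSums(Xs[dead, , drop = FALSE]) - d * s1 / s0
      info <- info + d * (s2 / s0 - tcrossprod(s1 / s0))
    }
    list(ll = ll, score = score, info = info)
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pl <- partial(beta)
    if (max(abs(pl$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(pl$info, pl$score), error = function(e) NULL)
    if (is.null(step)) {
      stop_invalid("singular information matrix at iteration ", it)
    }
    beta <- beta + step
    if (max(abs(beta)) > 15) {
      worst <- colnames(Xs)[which.max(abs(beta))]
      stop_invalid("monotone likelihood (separation) involving covariate `", worst, "`")
    }
  }
  if (!converged) {
    pl <- partial(beta)
    if (max(abs(pl$score)) >= sqrt(tol)) {
      stop_invalid("Newton-Raphson failed to converge in ", max_iter,
                   " iterations (last max score ", format(max(abs(pl$score))), ")")
    }
  }
  cov <- solve(pl$info)
  se <- sqrt(diag(cov))
  z <- beta / se
  res <- data.frame(coef = beta, hazard_ratio = exp(beta), se = se, z = z,
                    p_value = 2 * stats::pnorm(-abs(z)),
                    ci_lower = exp(beta - 1.96 * se),
                    ci_upper = exp(beta + 1.96 * se),
                    row.names = colnames(Xs))
  attr(res, "loglik") <- pl$ll
  attr(res, "iterations") <- it
  attr(res, "tie_method") <- "breslow"
  attr(res, "vcov") <- cov
  class(res) <- c("cox_result", "data.frame")
  res
}

build_design <- function(covariates) {
  if (is.null(dim(covariates))) covariates <- data.frame(covariate = covariates)
  covariates <- as.data.frame(covariates)
  X <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  storage.mode(X) <- "double"
  X
}

#' Covariate adjustment ("regressing out") of an extra enrichment score
#'
#' Refits the Cox model with the extra score appended as a covariate and
#' reports how the focal covariate's coefficient and p-value change --
#' the standard way to ask whether an association survives adjustment.
#'
#' @param time,event As in [cox_ph()].
#' @param covariates Covariates of the base model; the first column is the
#'   focal covariate unless `focal` names another.
#' @param extra Numeric vector: the enrichment score to adjust for.
#' @param focal Name of the focal covariate column (default: first).
#' @return List: `adjusted` (the full `cox_result`), `unadjusted`, `focal`,
#'   `focal_change` (data.frame of coef/p before vs after).
#' @export
regress_out_covariate <- function(time, event, covariates, extra, focal = NULL) {
  if (is.null(dim(covariates))) covariates <- data.frame(covariate = covariates)
  covariates <- as.data.frame(covariates)
  focal <- focal %||% names(covariates)[1L]
  base_fit <- cox_ph(time, event, covariates)
  covariates$.adjusted_for <- extra
  full_fit <- cox_ph(time, event, covariates)
  focal_rows <- grep(paste0("^", focal), rownames(base_fit))
  change <- data.frame(
    term = rownames(base_fit)[focal_rows],
    coef_unadjusted = base_fit$coef[focal_rows],
    p_unadjusted = base_fit$p_value[focal_rows],
    coef_adjusted = full_fit$coef[match(rownames(base_fit)[focal_rows], rownames(full_fit))],
    p_adjusted = full_fit$p_value[match(rownames(base_fit)[focal_rows], rownames(full_fit))],
    row.names = NULL
  )
  list(adjusted = full_fit, unadjusted = base_fit, focal = focal,
       focal_change = change)
}
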