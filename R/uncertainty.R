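# Confidence intervals on the raw score, decomposed into model uncertainty
# (spread across patient-level bootstrap refits) and feature uncertainty
# (spread of the primary model's score when every imputed or masked variable
# is redrawn from its training marginal). The model abstains when the
# interval straddles the decision threshold.

#' Uncertainty configuration
#'
#' @param n_bootstrap number of bootstrap ensembles (default 50).
#' @param n_feature_draws joint redraws for feature uncertainty (default 20).
#' @param z normal quantile for the interval half-width (default 1.96).
#' @param seed RNG seed.
#' @return config list.
#' @export
uncertainty_config <- function(n_bootstrap = 50, n_feature_draws = 20,
                               z = 1.96, seed = 1L) {
  stopifnot(n_bootstrap >= 2, n_feature_draws >= 2, z >= 0)
  list(n_bootstrap = as.integer(n_bootstrap),
       n_feature_draws = as.integer(n_feature_draws), z = z,
       seed = as.integer(seed))
}

#' Fit bootstrap ensembles for model uncertainty
#'
#' Resamples stays (not rows) with replacement and refits the standard
#' boosting on each resample. The spread of the resulting scores on a fixed
#' vector estimates how much the model itself is under-determined by the
#' training data.
#'
#' @param features training feature table (must carry \code{stay_id}).
#' @param labels training labels.
#' @param config [uncertainty_config()].
#' @param ... passed to [fit_hsi()] (e.g. \code{n_rounds}).
#' @return list of \code{hsi_ensemble}s.
#' @export
fit_bootstrap_ensembles <- function(features, labels, config = uncertainty_config(),
                                    ...) {
  if (config$n_bootstrap < 2) stop("need at least 2 bootstrap resamples")
  ft <- data.table::as.data.table(features)
  ids <- unique(ft$stay_id)
  y <- as.numeric(labels)
  set.seed(config$seed)
  lapply(seq_len(config$n_bootstrap), function(b) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(lapply(take, function(s) which(ft$stay_id == s)))
    fit_hsi(ft[rows], y[rows], ...)
  })
}

#' Score with a confidence interval and an abstention flag
#'
#' \code{sigma_model} is the standard deviation of raw scores across the
#' bootstrap ensembles. \code{sigma_feature} is the standard deviation of the
#' primary ensemble's raw score over \code{n_feature_draws} joint redraws in
#' which every variable whose provenance is \code{imputed}, \code{masked} or
#' \code{absent} is resampled from its training empirical marginal (measured
#' and forward-filled values are never touched). The interval is
#' \code{raw_score +/- z * sqrt(sigma_model^2 + sigma_feature^2)}, also
#' mapped through the Platt sigmoid to the probability and HSI scales.
#'
#' @param ensembles bootstrap ensembles from [fit_bootstrap_ensembles()].
#' @param ensemble the primary (full-data) ensemble.
#' @param features feature table to score.
#' @param stats training [population_stats()] (supplies the marginals).
#' @param config [uncertainty_config()].
#' @param threshold decision threshold on the raw-score scale (scores at or
#'   above it call "unstable"); used by the abstention rule.
#' @return \code{data.table}: scoring columns of [hsi_score()] plus
#'   \code{sigma_model}, \code{sigma_feature}, \code{ci_low}, \code{ci_high}
#'   (raw scale), \code{p_low}, \code{p_high}, \code{abstain}.
#' @export
predict_with_ci <- function(ensembles, ensemble, features, stats,
                            config = uncertainty_config(), threshold = NULL) {
  base <- hsi_score(ensemble, features)
  X <- feature_matrix(features, ensemble$registry)
  n <- nrow(X)

  boots <- vapply(ensembles, function(e) hsi_score(e, X)$raw_score,
                  numeric(n))
  sigma_model <- apply(as.matrix(boots), 1, stats::sd)

  prov <- as.matrix(as.data.frame(features)[,
    paste0(ensemble$registry$name, "_prov"), drop = FALSE])
  redraw <- prov %in% c("imputed", "masked", "absent")
  dim(redraw) <- dim(prov)
  set.seed(config$seed)
  if (any(redraw)) {
    draws <- matrix(0, n, config$n_feature_draws)
    for (k in seq_len(config$n_feature_draws)) {
      Xk <- X
      for (f in seq_len(ncol(X))) {
        r <- which(redraw[, f])
        if (!length(r)) next
        marg <- stats$quantiles[[ensemble$registry$name[f]]]
        if (!length(marg)) {
          stop("no training marginal for variable ",
               ensemble$registry$name[f])
        }
        Xk[r, f] <- sample(marg, length(r), replace = TRUE)
      }
      draws[, k] <- hsi_score(ensemble, Xk)$raw_score
    }
    sigma_feature <- apply(draws, 1, stats::sd)
    sigma_feature[rowSums(redraw) == 0] <- 0
  } else {
    sigma_feature <- numeric(n)
  }

  half <- config$z * sqrt(sigma_model^2 + sigma_feature^2)
  out <- data.table::copy(base)
  out[, sigma_model := sigma_model]
  out[, sigma_feature := sigma_feature]
  out[, ci_low := raw_score - half]
  out[, ci_high := raw_score + half]
  # probability scale: the Platt map is monotone decreasing in a*s for a<0
  p1 <- sigmoid(-(ensemble$platt_a * out$ci_low + ensemble$platt_b))
  p2 <- sigmoid(-(ensemble$platt_a * out$ci_high + ensemble$platt_b))
  out[, p_low := pmin(p1, p2)]
  out[, p_high := pmax(p1, p2)]
  if (!is.null(threshold)) {
    out[, abstain := decide_abstain(ci_low, ci_high, threshold)]
  }
  out[]
}

#' Abstention rule
#'
#' Abstain when the raw-score confidence interval contains the decision
#' threshold: the model cannot distinguish "call" from "no call" at its own
#' stated uncertainty.
#'
#' @param ci_low,ci_high interval bounds on the raw-score scale.
#' @param threshold decision threshold on the raw-score scale.
#' @return logical vector.
#' @export
decide_abstain <- function(ci_low, ci_high, threshold) {
  ci_low <= threshold & threshold <= ci_high
}
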