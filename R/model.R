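# Boosted-stump risk model. An ensemble of depth-one decision trees is fit by
# gradient boosting on the logistic loss; because every stump splits on a
# single variable, the ensemble decomposes exactly into one univariate risk
# function per variable, and the raw score is the training-prevalence
# log-odds baseline plus the sum of per-variable risks. The score is mapped
# to a probability by Platt scaling and reported as the Hemodynamic
# Stability Index, HSI = 100 * (1 - P(unstable)), so higher values mean
# greater stability.

sigmoid <- function(x) 1 / (1 + exp(-x))

LEAF_CLIP <- 4  # Newton leaf values are clipped to +/- 4 before lr scaling

#' Fit a boosted stump ensemble
#'
#' Each boosting round scans every variable; candidate thresholds are the
#' midpoints of up to \code{max_bins} quantile bins of that variable's
#' present values, the winning (variable, threshold) maximizes the
#' squared-error gain on the negative gradients, and the two leaf values are
#' Newton-step estimates scaled by the learning rate. Samples missing the
#' chosen variable take contribution 0 from that stump and are excluded from
#' its split search, so missingness itself is never a learned signal. Ties
#' break toward the lowest variable index and lowest threshold; the fit is
#' deterministic given the input order.
#'
#' @param features feature table from [build_features()] or a numeric matrix
#'   with one column per registry variable (NA = absent).
#' @param labels 0/1 vector (1 = unstable).
#' @param n_rounds boosting rounds; one stump per round (default 200).
#' @param learning_rate shrinkage on leaf values (default 0.1).
#' @param max_bins quantile bins for threshold candidates (default 256).
#' @param registry variable registry.
#' @return object of class \code{hsi_ensemble}: \code{baseline} (log-odds of
#'   training prevalence), \code{stumps} (data.table: round, feature,
#'   threshold, left_value, right_value), Platt coefficients
#'   (\code{platt_a = -1, platt_b = 0} until [calibrate_hsi()] is applied),
#'   the registry and its hash, and the per-round training log loss.
#' @export
fit_hsi <- function(features, labels, n_rounds = 200, learning_rate = 0.1,
                    max_bins = 256, registry = hsi_registry()) {
  X <- if (is.matrix(features)) features else feature_matrix(features, registry)
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("labels are single-class; cannot boost")
  if (!ncol(X)) stop("empty feature set")
  if (n_rounds < 1 || learning_rate <= 0) {
    stop("n_rounds must be >= 1 and learning_rate > 0")
  }
  n <- nrow(X); nf <- ncol(X)
  feat_names <- colnames(X)

  # per-feature candidate thresholds (midpoints of quantile-bin boundaries)
  # and per-sample bin assignments; built once
  thr <- vector("list", nf)
  bins <- vector("list", nf)      # bin index per present sample
  prows <- vector("list", nf)     # present sample indices
  for (f in seq_len(nf)) {
    idx <- which(!is.na(X[, f]))
    x <- X[idx, f]
    qs <- unique(stats::quantile(x, probs = seq(0, 1,
                                                length.out = max_bins + 1),
                                 names = FALSE, type = 7))
    if (length(qs) < 2) { thr[[f]] <- numeric(0); next }
    t_f <- (qs[-1] + qs[-length(qs)]) / 2
    thr[[f]] <- t_f
    prows[[f]] <- idx
    bins[[f]] <- findInterval(x, t_f) + 1L  # 1..K+1; x < t_f[k] <=> bin <= k
  }
  active <- which(lengths(thr) > 0)
  if (!length(active)) stop("no feature has at least two distinct values")
  nbin <- integer(nf); nbin[active] <- lengths(thr)[active] + 1L
  offset <- c(0L, cumsum(nbin))[seq_len(nf)]
  erow <- unlist(prows[active], use.names = FALSE)
  ebin <- unlist(lapply(active, function(f) offset[f] + bins[[f]]),
                 use.names = FALSE)
  btot <- sum(nbin)

  prev <- mean(y)
  baseline <- log(prev / (1 - prev))
  F_ <- rep(baseline, n)
  eps <- 1e-12
  stumps <- vector("list", n_rounds)
  loss <- numeric(n_rounds)

  for (round in seq_len(n_rounds)) {
    p <- sigmoid(F_)
    g <- p - y
    h <- p * (1 - p)
    gh <- rowsum(cbind(g[erow], h[erow]), ebin, reorder = FALSE)
    G <- numeric(btot); H <- numeric(btot)
    ids <- as.integer(rownames(gh))
    G[ids] <- gh[, 1]; H[ids] <- gh[, 2]

    best <- list(gain = -Inf)
    for (f in active) {
      k <- nbin[f]
      Gf <- G[(offset[f] + 1):(offset[f] + k)]
      Hf <- H[(offset[f] + 1):(offset[f] + k)]
      GL <- cumsum(Gf)[-k]; HL <- cumsum(Hf)[-k]
      Gt <- sum(Gf); Ht <- sum(Hf)
      GR <- Gt - GL; HR <- Ht - HL
      gain <- ifelse(HL > eps & HR > eps,
                     GL^2 / (HL + eps) + GR^2 / (HR + eps) -
                       Gt^2 / (Ht + eps),
                     -Inf)
      j <- which.max(gain)  # first max: lowest threshold wins ties
      if (length(j) && gain[j] > best$gain) {
        best <- list(gain = gain[j], f = f, j = j,
                     vl = -GL[j] / max(HL[j], eps),
                     vr = -GR[j] / max(HR[j], eps))
      }
    }
    if (!is.finite(best$gain)) {
      # no admissible split remains; stop early with what we have
      stumps <- stumps[seq_len(round - 1)]
      loss <- loss[seq_len(round - 1)]
      break
    }
    vl <- learning_rate * max(-LEAF_CLIP, min(LEAF_CLIP, best$vl))
    vr <- learning_rate * max(-LEAF_CLIP, min(LEAF_CLIP, best$vr))
    f <- best$f
    contrib <- numeric(n)
    contrib[prows[[f]]] <- ifelse(bins[[f]] <= best$j, vl, vr)
    F_ <- F_ + contrib
    stumps[[round]] <- data.table::data.table(
      round = round, feature = feat_names[f], threshold = thr[[f]][best$j],
      left_value = vl, right_value = vr)
    p2 <- sigmoid(F_)
    loss[round] <- -mean(y * log(pmax(p2, eps)) +
                           (1 - y) * log(pmax(1 - p2, eps)))
  }

  structure(list(
    baseline = baseline,
    stumps = data.table::rbindlist(stumps),
    learning_rate = learning_rate,
    n_rounds = length(stumps),
    platt_a = -1, platt_b = 0,
    registry = registry,
    registry_hash = registry_hash(registry),
    train_loss = loss,
    train_prevalence = prev
  ), class = "hsi_ensemble")
}

# per-feature summed stump contributions for a feature matrix;
# absent values contribute 0
risk_matrix <- function(ensemble, X) {
  R <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  st <- ensemble$stumps
  for (i in seq_len(nrow(st))) {
    f <- st$feature[i]
    x <- X[, f]
    ct <- ifelse(is.na(x), 0, ifelse(x < st$threshold[i],
                                     st$left_value[i], st$right_value[i]))
    R[, f] <- R[, f] + ct
  }
  R
}

#' Score feature vectors with an ensemble
#'
#' The raw score is exactly \code{baseline + sum of per-variable risks};
#' the calibrated probability is \code{1 / (1 + exp(platt_a * raw +
#' platt_b))} and \code{hsi = 100 * (1 - p_unstable)}.
#'
#' @param ensemble an \code{hsi_ensemble}.
#' @param features feature table ([build_features()]) or numeric matrix.
#' @param check_valid error on rows whose snapshot is invalid (no usable
#'   heart rate / systolic pressure); only possible for feature tables.
#' @return \code{data.table} with \code{raw_score}, \code{p_unstable},
#'   \code{hsi}, \code{top_features} (top five |contribution| variables,
#'   semicolon-joined); the full per-variable risk matrix is attached as
#'   \code{attr(, "per_feature_risk")}.
#' @export
hsi_score <- function(ensemble, features, check_valid = TRUE) {
  if (!inherits(ensemble, "hsi_ensemble")) stop("not an hsi_ensemble")
  if (is.matrix(features)) {
    X <- features
  } else {
    if (check_valid && any(!features$valid)) {
      stop("cannot score invalid feature vectors (heart rate or systolic ",
           "blood pressure unavailable); filter on the valid column")
    }
    X <- feature_matrix(features, ensemble$registry)
  }
  R <- risk_matrix(ensemble, X)
  raw <- ensemble$baseline + rowSums(R)
  p <- sigmoid(-(ensemble$platt_a * raw + ensemble$platt_b))
  top <- apply(R, 1, function(r) {
    nz <- order(-abs(r))[1:min(5, length(r))]
    paste(colnames(R)[nz], collapse = ";")
  })
  out <- data.table::data.table(raw_score = raw, p_unstable = p,
                                hsi = 100 * (1 - p), top_features = top)
  data.table::setattr(out, "per_feature_risk", R)
  out
}

#' @export
predict.hsi_ensemble <- function(object, newdata, ...) {
  hsi_score(object, newdata)
}

#' Platt-scale an ensemble
#'
#' Fits \code{(a, b)} minimizing the log loss of \code{sigmoid(-(a s + b))}
#' against Platt's smoothed targets \code{(N+ + 1)/(N+ + 2)} and
#' \code{1/(N- + 2)} on a calibration set that must be patient-disjoint from
#' the boosting set. After calibration the mean predicted probability matches
#' the calibration-set prevalence to within a percentage point.
#'
#' @param ensemble fitted \code{hsi_ensemble}.
#' @param features calibration feature table or matrix.
#' @param labels calibration 0/1 labels.
#' @return the ensemble with \code{platt_a}, \code{platt_b} set.
#' @export
calibrate_hsi <- function(ensemble, features, labels) {
  s <- hsi_score(ensemble, features)$raw_score
  ab <- platt_fit(s, labels)
  ensemble$platt_a <- ab[1]
  ensemble$platt_b <- ab[2]
  ensemble
}

#' @rdname calibrate_hsi
#' @param scores raw scores (higher = more unstable).
#' @return \code{platt_fit}: numeric \code{c(a, b)} such that
#'   \code{p = 1 / (1 + exp(a * s + b))}.
#' @export
platt_fit <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("calibration set is single-class")
  np <- sum(y == 1); nn <- sum(y == 0)
  t <- ifelse(y == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- -(par[1] * scores + par[2])
    # log(1+exp(.)) computed stably
    lp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))   # -log(1-p)
    lq <- lp - z                                             # -log(p)
    sum(t * lq + (1 - t) * lp)
  }
  fit <- stats::optim(c(-1, 0), nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  fit$par
}

#' Univariate risk curve
#'
#' The model's additive decomposition gives each variable a piecewise-
#' constant risk function: the sum over that variable's stumps of the branch
#' value at x (the right branch at the threshold itself). Variables never
#' selected by boosting have the identically-zero curve.
#'
#' @param ensemble fitted \code{hsi_ensemble}.
#' @param variable registry variable name.
#' @param grid numeric vector of evaluation points.
#' @return numeric vector of risk contributions along \code{grid}.
#' @export
risk_curve <- function(ensemble, variable, grid) {
  if (!variable %in% ensemble$registry$name) {
    stop("unknown variable: ", variable)
  }
  st <- ensemble$stumps[ensemble$stumps$feature == variable, ]
  out <- numeric(length(grid))
  for (i in seq_len(nrow(st))) {
    out <- out + ifelse(grid < st$threshold[i], st$left_value[i],
                        st$right_value[i])
  }
  out
}

MODEL_SCHEMA_VERSION <- 1L

#' Save / load an ensemble as JSON
#'
#' The document records the schema version and a hash of the variable panel;
#' loading against a different panel fails loudly. A round-tripped model
#' scores any vector bit-identically.
#'
#' @param ensemble fitted \code{hsi_ensemble}.
#' @param path JSON file path.
#' @export
save_model <- function(ensemble, path) {
  doc <- list(schema_version = MODEL_SCHEMA_VERSION,
              registry_hash = ensemble$registry_hash,
              baseline = ensemble$baseline,
              learning_rate = ensemble$learning_rate,
              n_rounds = ensemble$n_rounds,
              platt_a = ensemble$platt_a, platt_b = ensemble$platt_b,
              train_prevalence = ensemble$train_prevalence,
              train_loss = ensemble$train_loss,
              stumps = ensemble$stumps)
  # 17 significant digits round-trip IEEE doubles exactly, so a loaded model
  # scores bit-identically
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @param registry registry the loaded model will be used with.
#' @export
load_model <- function(path, registry = hsi_registry()) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) ||
      doc$schema_version != MODEL_SCHEMA_VERSION) {
    stop("model schema version mismatch")
  }
  if (doc$registry_hash != registry_hash(registry)) {
    stop("model was trained against a different variable registry ",
         "(hash mismatch)")
  }
  structure(list(
    baseline = doc$baseline,
    stumps = data.table::as.data.table(doc$stumps),
    learning_rate = doc$learning_rate,
    n_rounds = doc$n_rounds,
    platt_a = doc$platt_a, platt_b = doc$platt_b,
    registry = registry,
    registry_hash = doc$registry_hash,
    train_loss = doc$train_loss,
    train_prevalence = doc$train_prevalence
  ), class = "hsi_ensemble")
}
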