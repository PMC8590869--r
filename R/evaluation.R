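# Evaluation protocol: ROC/PR summaries, the breakeven operating point
# (precision = recall), fixed-specificity operating points (90% / 95%),
# single-parameter baselines (shock index, systolic pressure), and
# operating-mode / lead-time / subgroup breakdowns. Scores call "unstable"
# when >= threshold.

#' AUC and AUPRC
#'
#' AUC via the rank statistic (midranks handle ties, so it equals the
#' pairwise concordance probability with ties counted half); AUPRC by
#' step-wise integration of the precision-recall curve over distinct score
#' thresholds.
#'
#' @param scores numeric risk scores (higher = more unstable).
#' @param labels 0/1 labels.
#' @return list with \code{auc}, \code{auprc}, \code{n_pos}, \code{n_neg},
#'   \code{prevalence} and the \code{roc} / \code{pr} curve tables.
#' @export
roc_pr <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("both classes required")
  np <- sum(y == 1); nn <- sum(y == 0)
  r <- rank(scores)  # midranks
  auc <- (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)

  ord <- order(-scores)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE)  # one point per distinct threshold
  tp <- tp[last]; fp <- fp[last]; thr <- ss[last]
  rec <- tp / np
  prec <- tp / (tp + fp)
  spec <- 1 - fp / nn
  # step integral: precision at each threshold times recall gained there
  auprc <- sum(prec * diff(c(0, rec)))
  list(auc = auc, auprc = auprc, n_pos = np, n_neg = nn,
       prevalence = np / (np + nn),
       roc = data.table::data.table(threshold = thr, sensitivity = rec,
                                    specificity = spec),
       pr = data.table::data.table(threshold = thr, recall = rec,
                                   precision = prec))
}

#' Breakeven and fixed-specificity operating points
#'
#' The breakeven point is the threshold minimizing |precision - recall|
#' (exact equality is rarely attainable on finite data; ties go to the
#' higher-specificity threshold). The 90\% / 95\% points use the smallest
#' threshold whose specificity is at least the target, which maximizes
#' sensitivity under the constraint. A degenerate score distribution that
#' cannot reach a specificity target is flagged.
#'
#' @param scores,labels as in [roc_pr()].
#' @return \code{data.table} with one row per operating point (\code{name},
#'   \code{threshold}, \code{sensitivity}, \code{specificity}, \code{ppv},
#'   \code{degenerate}).
#' @export
operating_points <- function(scores, labels) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("both classes required")
  np <- sum(y == 1); nn <- sum(y == 0)
  ord <- order(-scores)
  ys <- y[ord]; ss <- scores[ord]
  # predict positive when score >= threshold; one row per distinct threshold
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  idx <- which(!duplicated(ss, fromLast = TRUE))
  thr <- ss[idx]; tp <- tp[idx]; fp <- fp[idx]
  se <- tp / np
  sp <- 1 - fp / nn
  ppv <- tp / (tp + fp)

  point <- function(i, name, degenerate = FALSE) {
    data.table::data.table(name = name, threshold = thr[i],
                           sensitivity = se[i], specificity = sp[i],
                           ppv = ppv[i], degenerate = degenerate)
  }
  gap <- abs(ppv - se)
  cand <- which(gap == min(gap))
  be <- cand[which.max(sp[cand])]
  out <- list(point(be, "breakeven"))
  for (tgt in c(0.90, 0.95)) {
    ok <- which(sp >= tgt)
    nm <- paste0("sp", tgt * 100)
    if (length(ok)) {
      # thresholds are in decreasing order; the last qualifying row is the
      # smallest threshold still meeting the specificity floor
      out[[length(out) + 1]] <- point(max(ok), nm)
    } else {
      out[[length(out) + 1]] <- data.table::data.table(
        name = nm, threshold = NA_real_, sensitivity = NA_real_,
        specificity = NA_real_, ppv = NA_real_, degenerate = TRUE)
    }
  }
  data.table::rbindlist(out)
}

#' Single-parameter baseline scores
#'
#' Classic bedside comparators: shock index (heart rate / systolic pressure,
#' higher = riskier) and systolic blood pressure (lower = riskier, so its
#' score is the negated pressure).
#'
#' @param features feature table from [build_features()].
#' @return \code{data.table} with \code{shock_index} and \code{neg_systolic_bp}
#'   score columns.
#' @export
baseline_scores <- function(features) {
  data.table::data.table(
    shock_index = features$heart_rate / features$systolic_bp,
    neg_systolic_bp = -features$systolic_bp)
}

eval_report <- function(scores, labels) {
  m <- roc_pr(scores, labels)
  op <- operating_points(scores, labels)
  data.table::data.table(
    auc = m$auc, auprc = m$auprc, prevalence = m$prevalence,
    n_pos = m$n_pos, n_neg = m$n_neg,
    sp_be = op$specificity[op$name == "breakeven"],
    ppv_be = op$ppv[op$name == "breakeven"],
    se_sp90 = op$sensitivity[op$name == "sp90"],
    ppv_sp90 = op$ppv[op$name == "sp90"],
    se_sp95 = op$sensitivity[op$name == "sp95"],
    ppv_sp95 = op$ppv[op$name == "sp95"])
}

#' Evaluate a model under the four operating modes
#'
#' The model is trained once on all features; each mode masks the
#' out-of-mode variables at snapshot time and rescoring measures how the
#' restricted view degrades discrimination.
#'
#' @param ensemble fitted, calibrated \code{hsi_ensemble}.
#' @param observations observation table for the evaluated stays.
#' @param samples sample table (test split only).
#' @param stats training [population_stats()].
#' @param modes mode names to evaluate.
#' @return \code{data.table}, one report row per mode.
#' @export
evaluate_modes <- function(ensemble, observations, samples, stats,
                           modes = hsi_modes()) {
  out <- lapply(modes, function(m) {
    fv <- build_features(observations, samples[, c("stay_id", "time")],
                         stats, ensemble$registry, mode = m)
    keep <- fv$valid
    sc <- hsi_score(ensemble, fv[keep])
    cbind(data.table::data.table(mode = m),
          eval_report(sc$raw_score, samples$label[keep]))
  })
  data.table::rbindlist(out)
}

#' Evaluate across lead times
#'
#' One model (trained at a fixed lead) is scored on positives re-sampled at
#' each earlier lead time, with the same negatives throughout.
#'
#' @param ensemble fitted \code{hsi_ensemble}.
#' @param stays,segments,observations labeled cohort tables (test stays).
#' @param stats training [population_stats()].
#' @param leads lead times in hours.
#' @param seed seed for the negative draws (fixed across leads).
#' @return \code{data.table}, one report row per lead.
#' @export
evaluate_leads <- function(ensemble, stays, segments, observations, stats,
                           leads = 1:12, seed = 1L) {
  out <- lapply(leads, function(L) {
    smp <- suppressWarnings(
      draw_samples(stays, segments, observations, stats, lead = L,
                   seed = seed, registry = ensemble$registry))
    fv <- build_features(observations, smp[, c("stay_id", "time")], stats,
                         ensemble$registry, mode = "all")
    keep <- fv$valid
    sc <- hsi_score(ensemble, fv[keep])
    cbind(data.table::data.table(lead = L),
          eval_report(sc$raw_score, smp$label[keep]))
  })
  data.table::rbindlist(out)
}

#' Subgroup evaluation
#'
#' @param scores,labels test-set scores and labels.
#' @param groups \code{data.frame} of grouping columns aligned with the
#'   samples (e.g. unit_type, admission_source, ventilated).
#' @return \code{data.table} with one report row per (key, level); levels
#'   with a single class are omitted (with a message).
#' @export
evaluate_subgroups <- function(scores, labels, groups) {
  groups <- as.data.frame(groups)
  out <- list()
  for (key in names(groups)) {
    for (lev in unique(groups[[key]])) {
      sel <- groups[[key]] == lev
      if (length(unique(labels[sel])) < 2) {
        message("subgroup ", key, "=", lev,
                " omitted (single class or empty)")
        next
      }
      out[[length(out) + 1]] <- cbind(
        # "key" is an argument of data.table(), so the column is "grouping"
        data.table::data.table(grouping = key, level = as.character(lev)),
        eval_report(scores[sel], labels[sel]))
    }
  }
  data.table::rbindlist(out)
}
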