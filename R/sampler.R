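# Supervised sample construction: one positive snapshot per unstable stay,
# taken a fixed lead time before its first intervention segment, and one
# negative snapshot at a random stable time per stable stay. Nothing is ever
# sampled from the first 6 h of a stay, DNR stays and minors are excluded,
# and train/test splits are patient-disjoint and label-stratified.

MIN_SAMPLE_TIME_H <- 6

#' Draw labeled samples from a labeled cohort
#'
#' For each unstable stay one positive sample is taken at
#' \code{first segment start - lead}; it is dropped when that time falls in
#' the first 6 h of the stay or when the feature snapshot there is invalid
#' (no usable heart rate or systolic pressure). For each stable stay one
#' negative sample is drawn uniformly in \code{[6, los]}, re-drawn up to 10
#' times until the snapshot is valid, then the stay is dropped. Stays with a
#' DNR indication or age below 18 are excluded entirely.
#'
#' @param stays stay metadata table.
#' @param segments output of [label_cohort()]; stays absent are stable.
#' @param observations long observation table.
#' @param stats training [population_stats()] (used only to test snapshot
#'   validity, which does not depend on imputed values).
#' @param lead hours between the sample and the segment start (positives).
#' @param seed RNG seed for the negative draws.
#' @param registry variable registry.
#' @param label_filter optional criterion id (e.g. \code{"PRESSOR_ANY"}):
#'   positives are restricted to stays whose first qualifying segment
#'   includes that criterion, emulating a pressors-only outcome label.
#' @return \code{data.table} of samples: \code{stay_id}, \code{time},
#'   \code{label} (0/1), \code{lead} (NA for negatives) plus subgroup columns
#'   \code{unit_type}, \code{admission_source}, \code{ventilated}. Dropped
#'   stays are reported via \code{attr(, "drops")}.
#' @export
draw_samples <- function(stays, segments, observations, stats, lead = 1,
                         seed = 1L, registry = hsi_registry(),
                         label_filter = NULL) {
  if (lead <= 0) stop("lead must be positive (hours)")
  stays <- data.table::as.data.table(stays)
  segments <- data.table::as.data.table(segments)
  eligible <- stays[!(dnr) & age >= 18]
  if (!nrow(eligible)) stop("no eligible stays (all DNR or under 18)")
  unstable_ids <- unique(segments$stay_id)
  if (!is.null(label_filter) && nrow(segments)) {
    # restrict positives to the filtered criterion; stays that are unstable
    # only via other criteria contribute no sample at all (negatives must
    # come from genuinely stable patients)
    segments <- segments[vapply(strsplit(criteria, ";"),
                                function(x) label_filter %in% x, logical(1))]
  }
  first_seg <- if (nrow(segments)) {
    segments[, .(seg_start = min(start)), by = stay_id]
  } else {
    data.table::data.table(stay_id = character(0), seg_start = numeric(0))
  }

  drops <- list()
  pos <- first_seg[stay_id %in% eligible$stay_id]
  pos[, time := seg_start - lead]
  ok6 <- pos$time >= MIN_SAMPLE_TIME_H
  if (any(!ok6)) {
    drops[["positive_before_6h"]] <- pos$stay_id[!ok6]
  }
  pos <- pos[ok6]

  neg <- eligible[!stay_id %in% unstable_ids & los > MIN_SAMPLE_TIME_H]

  set.seed(seed)
  # negatives: up to 10 seeded uniform draws per stay until the snapshot at
  # the drawn time is valid
  neg_rows <- NULL
  if (nrow(neg)) {
    draws <- matrix(stats::runif(nrow(neg) * 10), nrow = nrow(neg))
    times <- MIN_SAMPLE_TIME_H + draws * (neg$los - MIN_SAMPLE_TIME_H)
    chosen <- rep(NA_real_, nrow(neg))
    pending <- seq_len(nrow(neg))
    for (attempt in 1:10) {
      if (!length(pending)) break
      qt <- data.table::data.table(stay_id = neg$stay_id[pending],
                                   time = times[pending, attempt])
      fv <- build_features(
        observations[observations$stay_id %in% qt$stay_id, ],
        qt, stats, registry, mode = "all")
      good <- fv$valid
      chosen[pending[good]] <- qt$time[good]
      pending <- pending[!good]
    }
    if (length(pending)) {
      drops[["negative_no_valid_snapshot"]] <- neg$stay_id[pending]
    }
    keep <- !is.na(chosen)
    neg_rows <- data.table::data.table(stay_id = neg$stay_id[keep],
                                       time = chosen[keep], label = 0L,
                                       lead = NA_real_)
  }

  pos_rows <- NULL
  if (nrow(pos)) {
    fv <- build_features(
      observations[observations$stay_id %in% pos$stay_id, ],
      pos[, .(stay_id, time)], stats, registry, mode = "all")
    if (any(!fv$valid)) {
      drops[["positive_invalid_snapshot"]] <- pos$stay_id[!fv$valid]
    }
    pos_rows <- data.table::data.table(stay_id = pos$stay_id[fv$valid],
                                       time = pos$time[fv$valid], label = 1L,
                                       lead = lead)
  }

  out <- data.table::rbindlist(list(pos_rows, neg_rows), use.names = TRUE)
  if (!nrow(out)) stop("no eligible samples could be drawn")
  out <- merge(out,
               stays[, .(stay_id, unit_type, admission_source, ventilated)],
               by = "stay_id", sort = FALSE)
  data.table::setorder(out, stay_id)
  for (r in names(drops)) {
    warning(sprintf("dropped %d stay(s): %s", length(drops[[r]]), r),
            call. = FALSE)
  }
  data.table::setattr(out, "drops", drops)
  out[]
}

#' Patient-level stratified train/test split
#'
#' Assigns each stay to exactly one of train or test, holding out
#' \code{test_fraction} of stays within each label stratum so that test-set
#' prevalence tracks overall prevalence.
#'
#' @param samples sample table from [draw_samples()] (one row per stay).
#' @param test_fraction held-out proportion (default 0.20).
#' @param seed RNG seed.
#' @return \code{data.table} with \code{stay_id} and \code{split}
#'   (\code{"train"}/\code{"test"}).
#' @export
split_patients <- function(samples, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  s <- data.table::as.data.table(samples)[, .(label = label[1]), by = stay_id]
  set.seed(seed)
  parts <- lapply(split(s$stay_id, s$label), function(ids) {
    n_test <- round(length(ids) * test_fraction)
    if (n_test < 1 || n_test >= length(ids)) {
      stop("class starvation: a label stratum cannot be split at ",
           test_fraction)
    }
    test_ids <- sample(ids, n_test)
    data.table::data.table(stay_id = ids,
                           split = ifelse(ids %in% test_ids, "test", "train"))
  })
  out <- data.table::rbindlist(parts)
  data.table::setorder(out, stay_id)
  out[]
}
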