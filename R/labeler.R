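# Rule-based labeling of hemodynamic-intervention segments from treatment
# records. A stay is "unstable" if any of the consensus triggers fires:
# any dose of six vasopressor/inotrope drugs; fluid therapy of 700 cc in 1 h,
# 1500 cc in 4 h, 2400 cc in 8 h, 3000 cc in 12 h, or 500 cc twice within
# 4 h; PRBC transfusion of 800 cc within 24 h, of 500 cc within 2 h followed
# by fluid therapy within 12 h, or of 500 cc within 2 h not followed by fluid
# therapy within 24 h. A segment opens at the first trigger and closes when
# more than 12 h pass between consecutive treatment records.

PRESSOR_DRUGS <- c("dobutamine", "dopamine", "epinephrine", "norepinephrine",
                   "phenylephrine", "vasopressin")

FLUID_RULES <- data.frame(
  criterion_id = c("FLUID_1H_700", "FLUID_4H_1500", "FLUID_8H_2400",
                   "FLUID_12H_3000"),
  window = c(1, 4, 8, 12),
  threshold = c(700, 1500, 2400, 3000),
  stringsAsFactors = FALSE
)

SEGMENT_GAP_H <- 12      # > 12 h between consecutive records closes a segment
PRBC_24H_THRESHOLD <- 800
PRBC_2H_THRESHOLD <- 500
FLUID_TWICE_VOL <- 500
FLUID_TWICE_WINDOW <- 4

# Cumulative volume over half-open windows (t - w, t] ending at each record
# time. Sums change only at record times, so record times are the only
# candidate window ends.
window_sums <- function(times, volumes, w) {
  if (!length(times)) return(numeric(0))
  cum <- cumsum(volumes)
  # number of records with time <= t - w, for each record end t
  below <- findInterval(times - w, times)
  cum - c(0, cum)[below + 1L]
}

#' Evaluate every intervention criterion on one stay's treatment records
#'
#' @param records \code{data.frame} with columns \code{stay_id},
#'   \code{category} (\code{pressor}/\code{fluid}/\code{prbc}), \code{drug},
#'   \code{time} (hours since ICU admission) and \code{volume} (cc; ignored
#'   for pressors, where any quantity triggers). Must be a single stay, sorted
#'   by time.
#' @return \code{data.table} of criterion hits: \code{criterion_id},
#'   \code{time} (hours at which the criterion is satisfied) and
#'   \code{records} (list column of contributing row indices). A criterion may
#'   hit at several times; segment construction uses them all.
#' @export
evaluate_criteria <- function(records) {
  records <- as.data.frame(records)
  empty <- data.table::data.table(criterion_id = character(0),
                                  time = numeric(0), records = list())
  if (!nrow(records)) return(empty)
  if (length(unique(records$stay_id)) > 1L) {
    stop("evaluate_criteria() expects records of a single stay")
  }
  if (is.unsorted(records$time)) stop("treatment records must be sorted by time")
  bad <- setdiff(unique(records$category), c("pressor", "fluid", "prbc"))
  if (length(bad)) stop("unknown treatment category: ", paste(bad, collapse = ", "))
  pr <- records$category == "pressor"
  if (any(pr) && !all(tolower(records$drug[pr]) %in% PRESSOR_DRUGS)) {
    stop("pressor drug outside the six-drug list")
  }

  hits <- list()
  add <- function(id, time, idx) {
    hits[[length(hits) + 1L]] <<- data.table::data.table(
      criterion_id = id, time = time, records = list(idx))
  }

  # Any quantity of any of the six pressor/inotrope drugs.
  for (i in which(pr)) add("PRESSOR_ANY", records$time[i], i)

  fl <- which(records$category == "fluid")
  ft <- records$time[fl]
  fv <- records$volume[fl]
  for (r in seq_len(nrow(FLUID_RULES))) {
    ws <- window_sums(ft, fv, FLUID_RULES$window[r])
    for (j in which(ws >= FLUID_RULES$threshold[r])) {
      in_w <- which(ft > ft[j] - FLUID_RULES$window[r] & ft <= ft[j])
      add(FLUID_RULES$criterion_id[r], ft[j], fl[in_w])
    }
  }
  # Two distinct administrations of >= 500 cc each within 4 h of each other.
  big <- which(fv >= FLUID_TWICE_VOL)
  if (length(big) >= 2L) {
    for (k in 2:length(big)) {
      j <- big[k]
      prev <- big[big < j & ft[big] >= ft[j] - FLUID_TWICE_WINDOW]
      if (length(prev)) add("FLUID_TWICE_500_4H", ft[j], fl[c(prev[1L], j)])
    }
  }

  pb <- which(records$category == "prbc")
  pt <- records$time[pb]
  pv <- records$volume[pb]
  ws24 <- window_sums(pt, pv, 24)
  for (j in which(ws24 >= PRBC_24H_THRESHOLD)) {
    in_w <- which(pt > pt[j] - 24 & pt <= pt[j])
    add("PRBC_24H_800", pt[j], pb[in_w])
  }
  # The two conditional PRBC rules share the 500 cc / 2 h transfusion event.
  fluid_hit_times <- if (length(hits)) {
    h <- data.table::rbindlist(hits)
    sort(h$time[startsWith(h$criterion_id, "FLUID_")])
  } else numeric(0)
  ws2 <- window_sums(pt, pv, 2)
  for (j in which(ws2 >= PRBC_2H_THRESHOLD)) {
    in_w <- pb[which(pt > pt[j] - 2 & pt <= pt[j])]
    follow12 <- fluid_hit_times[fluid_hit_times > pt[j] &
                                fluid_hit_times <= pt[j] + 12]
    any24 <- any(fluid_hit_times > pt[j] & fluid_hit_times <= pt[j] + 24)
    if (length(follow12)) {
      add("PRBC_500_2H_THEN_FLUID_12H", follow12[1L], in_w)
    }
    # Absence of fluid therapy through end of stay counts as "not followed".
    if (!any24) add("PRBC_500_NO_FLUID_24H", pt[j], in_w)
  }

  if (!length(hits)) return(empty)
  out <- data.table::rbindlist(hits)
  data.table::setorder(out, time, criterion_id)
  out[]
}

#' Group treatment records into intervention segments
#'
#' A segment starts at the earliest criterion hit, extends over consecutive
#' treatment records separated by at most 12 h, and ends at the last record of
#' that run; a gap of more than 12 h closes it, and a later hit opens a new
#' segment.
#'
#' @param records single-stay treatment records, sorted by time.
#' @param hits output of [evaluate_criteria()] on the same records.
#' @return \code{data.table} with \code{start}, \code{end} and a list column
#'   \code{criteria} of criterion ids firing within each segment.
#' @export
build_segments <- function(records, hits = evaluate_criteria(records)) {
  empty <- data.table::data.table(start = numeric(0), end = numeric(0),
                                  criteria = list())
  if (!nrow(hits)) return(empty)
  rt <- sort(records$time)
  # runs of records with inter-record gaps <= 12 h
  run_id <- cumsum(c(1, diff(rt) > SEGMENT_GAP_H))
  runs <- data.table::data.table(time = rt, run = run_id)
  run_end <- tapply(runs$time, runs$run, max)

  segs <- list()
  open_until <- -Inf
  for (i in order(hits$time)) {
    t0 <- hits$time[i]
    if (t0 <= open_until) next
    run <- run_id[findInterval(t0, rt)]
    end <- unname(run_end[as.character(run)])
    in_seg <- hits$time >= t0 & hits$time <= end
    segs[[length(segs) + 1L]] <- data.table::data.table(
      start = t0, end = max(t0, end),
      criteria = list(sort(unique(hits$criterion_id[in_seg]))))
    open_until <- end
  }
  data.table::rbindlist(segs)
}

#' Label one stay as stable or unstable
#'
#' A stay is unstable if and only if at least one intervention segment exists.
#'
#' @param records all treatment records of one stay (any order).
#' @return list with \code{label} (\code{"stable"}/\code{"unstable"}) and
#'   \code{segments}.
#' @export
label_stay <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records)) records <- records[order(records$time), , drop = FALSE]
  segs <- build_segments(records)
  list(label = if (nrow(segs)) "unstable" else "stable", segments = segs)
}

#' Label a whole cohort of treatment records
#'
#' @param treatments treatment table for many stays.
#' @param stay_ids optional vector of stay ids to label (stays without any
#'   treatment record are stable); defaults to the ids present in
#'   \code{treatments}.
#' @return \code{data.table} of segments with columns \code{stay_id},
#'   \code{start}, \code{end}, \code{criteria} (semicolon-joined ids). Stays
#'   absent from the result are stable.
#' @export
label_cohort <- function(treatments, stay_ids = NULL) {
  treatments <- data.table::as.data.table(treatments)
  out <- if (nrow(treatments)) {
    treatments[order(time),
      {
        s <- build_segments(.SD)
        if (nrow(s)) {
          list(start = s$start, end = s$end,
               criteria = vapply(s$criteria, paste, "", collapse = ";"))
        } else {
          list(start = numeric(0), end = numeric(0), criteria = character(0))
        }
      },
      by = stay_id]
  } else {
    data.table::data.table(stay_id = character(0), start = numeric(0),
                           end = numeric(0), criteria = character(0))
  }
  data.table::setorder(out, stay_id, start)
  out[]
}
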