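# Construction of the 33-variable feature snapshot at arbitrary query times.
# For each variable the most recent measurement no staler than its
# forward-fill limit (2 h vitals, 26 h labs/ventilator settings) is carried
# forward; otherwise the imputation policy applies: training population mean
# for most variables, 0.21 (room air) for FiO2, and nothing for MAWP/PIP.
# A snapshot is valid for scoring only if heart rate and systolic blood
# pressure are measured or forward-filled; shock index is recomputed as
# HR / SBP on the final values.

#' Merge invasive and noninvasive blood pressure channels
#'
#' Collapses \code{<bp>_invasive} / \code{<bp>_noninvasive} series into a
#' single \code{<bp>} series, keeping the invasive value whenever both are
#' charted in the same 1-minute time bin.
#'
#' @param observations long observation table (\code{stay_id, variable, time,
#'   value}).
#' @return observation table with no invasive/noninvasive-suffixed variables.
#' @export
merge_blood_pressure <- function(observations) {
  obs <- data.table::as.data.table(observations)
  if (!nrow(obs)) return(obs)
  suff <- "_(invasive|noninvasive)$"
  is_bp <- grepl(suff, obs$variable)
  if (!any(is_bp)) return(obs)
  bp <- obs[is_bp]
  bp[, base := sub(suff, "", variable)]
  bp[, invasive := grepl("_invasive$", variable)]
  bp[, bin := round(time * 60)]
  # invasive first within a bin, then keep the first row per bin
  data.table::setorder(bp, stay_id, base, bin, -invasive, time)
  bp <- bp[!duplicated(bp[, .(stay_id, base, bin)])]
  bp <- bp[, .(stay_id, variable = base, time, value)]
  out <- rbind(obs[!is_bp], bp)
  data.table::setorder(out, stay_id, variable, time)
  out[]
}

#' Training-population statistics
#'
#' Per-variable mean of raw measured values (forward-filled copies are never
#' counted, which would bias means toward slowly-charted patients), plus an
#' empirical quantile sketch used by the feature-uncertainty redraws. Compute
#' only on training-split stays.
#'
#' @param observations merged long observation table (training stays only).
#' @param registry variable registry.
#' @param n_quantiles size of the per-variable quantile sketch.
#' @return object of class \code{hsi_stats}: list with \code{mean} and
#'   \code{quantiles} per variable.
#' @export
population_stats <- function(observations, registry = hsi_registry(),
                             n_quantiles = 128) {
  obs <- clip_to_range(merge_blood_pressure(observations), registry)
  means <- list(); qs <- list()
  for (v in registry$name) {
    x <- obs$value[obs$variable == v]
    x <- x[is.finite(x)]
    if (v == "shock_index") next
    if (length(x)) {
      means[[v]] <- mean(x)
      qs[[v]] <- unname(stats::quantile(x, probs = seq(0, 1, length.out = n_quantiles)))
    } else {
      means[[v]] <- NA_real_
      qs[[v]] <- numeric(0)
    }
  }
  # shock index derived from paired HR/SBP means
  means$shock_index <- means$heart_rate / means$systolic_bp
  qs$shock_index <- if (length(qs$heart_rate) && length(qs$systolic_bp)) {
    unname(stats::quantile(qs$heart_rate / rev(qs$systolic_bp),
                           probs = seq(0, 1, length.out = n_quantiles)))
  } else numeric(0)
  structure(list(mean = means, quantiles = qs), class = "hsi_stats")
}

#' @rdname population_stats
#' @param stats an \code{hsi_stats} object.
#' @param path JSON file path.
#' @export
write_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname population_stats
#' @export
read_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$mean <- as.list(x$mean)
  x$quantiles <- as.list(x$quantiles)
  structure(x, class = "hsi_stats")
}

clip_to_range <- function(obs, registry) {
  obs <- data.table::as.data.table(obs)
  if (!nrow(obs)) return(obs)
  m <- match(obs$variable, registry$name)
  lo <- registry$lo[m]; hi <- registry$hi[m]
  obs[, value := pmin(pmax(value, lo), hi)]
  obs[]
}

#' Build feature snapshots at query times
#'
#' Vectorized snapshot construction for many (stay, time) queries. Only
#' measurements at or before the query time are ever used (strict causality);
#' staleness beyond the variable's forward-fill limit voids the carried value.
#' Operating-mode masking treats out-of-mode variables as never measured, so
#' they fall through to imputation; masking can therefore never create data.
#'
#' @param observations long observation table of the queried stays (invasive /
#'   noninvasive pressures are merged internally).
#' @param queries \code{data.frame} with \code{stay_id} and \code{time}.
#' @param stats training [population_stats()].
#' @param registry variable registry.
#' @param mode operating-mode name (see [operating_mode()]).
#' @return wide \code{data.table}: one row per query, a numeric column per
#'   variable (NA only where the policy leaves the value absent or the row is
#'   invalid), a \code{<var>_prov} provenance column per variable with values
#'   \code{measured}, \code{forward_filled}, \code{imputed}, \code{masked} or
#'   \code{absent}, and a logical \code{valid} column (heart rate and
#'   systolic pressure available).
#' @export
build_features <- function(observations, queries, stats,
                           registry = hsi_registry(), mode = "all") {
  visible <- operating_mode(mode, registry)
  obs <- clip_to_range(merge_blood_pressure(observations), registry)
  bad <- setdiff(unique(obs$variable), registry$name)
  if (length(bad)) {
    stop("unknown observation variable(s): ", paste(bad, collapse = ", "))
  }
  q <- data.table::as.data.table(queries)[, .(stay_id, time)]
  if (any(q$time < 0)) stop("query times must be >= 0")
  nq <- nrow(q)
  out <- data.table::data.table(stay_id = q$stay_id, time = q$time)
  q[, .qid := seq_len(.N)]
  data.table::setkey(obs, stay_id, variable, time)
  for (v in setdiff(registry$name, "shock_index")) {
    spec <- registry[registry$name == v]
    val <- rep(NA_real_, nq)
    prov <- rep("never", nq)
    if (v %in% visible) {
      vo <- obs[variable == v, .(stay_id, otime = time, value, src = time)]
      if (nrow(vo)) {
        data.table::setkey(vo, stay_id, otime)
        j <- vo[q[, .(stay_id, otime = time, .qid)], roll = TRUE,
                on = c("stay_id", "otime")]
        data.table::setorder(j, .qid)
        stale <- q$time - j$src
        ok <- !is.na(j$value) & stale <= spec$fill_limit
        val[ok] <- j$value[ok]
        prov[ok] <- ifelse(stale[ok] <= 0, "measured", "forward_filled")
      }
      miss <- prov == "never"
      prov[miss] <- "expired_or_missing"
    } else {
      prov[] <- "masked_pending"
    }
    # imputation policy for anything without a usable carried value
    need <- !(prov %in% c("measured", "forward_filled"))
    if (any(need)) {
      masked <- prov == "masked_pending"
      if (spec$impute == "population_mean") {
        val[need] <- stats$mean[[v]]
        prov[need] <- ifelse(masked[need], "masked", "imputed")
      } else if (spec$impute == "constant") {
        val[need] <- spec$impute_value
        prov[need] <- ifelse(masked[need], "masked", "imputed")
      } else { # leave_absent
        val[need] <- NA_real_
        prov[need] <- ifelse(masked[need], "masked", "absent")
      }
    }
    data.table::set(out, j = v, value = val)
    data.table::set(out, j = paste0(v, "_prov"), value = prov)
  }
  hr_ok <- out$heart_rate_prov %in% c("measured", "forward_filled")
  sbp_ok <- out$systolic_bp_prov %in% c("measured", "forward_filled")
  out[, valid := hr_ok & sbp_ok]
  if ("shock_index" %in% registry$name) {
    si <- rep(NA_real_, nq)
    siprov <- rep("absent", nq)
    ok <- out$valid
    si[ok] <- out$heart_rate[ok] / out$systolic_bp[ok]
    siprov[ok] <- "measured"
    if (!"shock_index" %in% visible) {
      si[] <- stats$mean$shock_index
      siprov[] <- "masked"
    } else if (any(!ok)) {
      si[!ok] <- stats$mean$shock_index
      siprov[!ok] <- "imputed"
    }
    out[, shock_index := si]
    out[, shock_index_prov := siprov]
  }
  # invalid rows carry no scoreable values
  data.table::setcolorder(
    out, c("stay_id", "time", registry$name,
           paste0(registry$name, "_prov"), "valid"))
  out[]
}

#' Single-stay snapshot
#'
#' Convenience wrapper over [build_features()] for one stay and one time.
#'
#' @param observations observations of one stay.
#' @param stats training [population_stats()].
#' @param time query time, hours since admission.
#' @param mode operating-mode name.
#' @param registry variable registry.
#' @return one-row feature \code{data.table} (see [build_features()]).
#' @export
snapshot <- function(observations, stats, time, mode = "all",
                     registry = hsi_registry()) {
  obs <- data.table::as.data.table(observations)
  sid <- if (nrow(obs)) obs$stay_id[1] else "stay"
  build_features(obs, data.frame(stay_id = sid, time = time), stats,
                 registry, mode)
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param features output of [build_features()].
#' @param registry variable registry.
#' @return numeric matrix, one column per registry variable; NA marks absent.
#' @export
feature_matrix <- function(features, registry = hsi_registry()) {
  as.matrix(as.data.frame(features)[, registry$name, drop = FALSE])
}
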