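# Seeded synthetic ICU cohort: per-stay metadata, irregular observation
# streams over the 33-variable panel, and treatment records with planted
# stable/deteriorating structure. The generator emulates the shape of the
# source cohort (18% of stays receive a hemodynamic intervention; stable
# stays are shorter than unstable ones), not its clinical realism: trends are
# piecewise-linear drifts plus Gaussian noise, and variables are independent
# apart from the planted deterioration.

#' Generator configuration
#'
#' Defaults encode the emulated cohort: 18\% intervention prevalence; stable
#' length of stay with median about 29 h and unstable about 95 h; vitals on a
#' 5-minute grid with per-record dropout; labs redrawn every 6-24 h (so the
#' 2 h / 26 h forward-fill limits are consequential); deterioration onset
#' drawn uniformly so that a 1-h-lead positive sample always survives the
#' first-6-h exclusion. Unstable archetypes (\code{pressor}, \code{fluid},
#' \code{prbc}) follow the source mix of intervention types (roughly
#' 53/33/14). Neuro and stepdown units receive attenuated deterioration
#' signal, mirroring the reported subgroup degradation.
#'
#' @param n_stays number of ICU stays.
#' @param unstable_fraction target fraction of stays with an intervention.
#' @param seed integer RNG seed.
#' @param vital_interval,lab_interval_range sampling spacing, hours.
#' @param vital_dropout per-record probability a scheduled vital is not charted.
#' @param deterioration per-archetype drift rates per hour of deterioration
#'   (negative = falling).
#' @param attenuated_units unit types whose planted signal is scaled by
#'   \code{attenuation}.
#' @param attenuation multiplier on drift rates for \code{attenuated_units}.
#' @return a config list.
#' @export
generator_config <- function(n_stays = 1000, unstable_fraction = 0.18,
                             seed = 1L,
                             vital_interval = 5 / 60,
                             lab_interval_range = c(6, 24),
                             vital_dropout = 0.10,
                             deterioration = list(
                               duration_range = c(6, 18),  # h of decline
                               late_vital_window = 3, # h of decompensation
                               hr_slope = 4,          # bpm/h up
                               sbp_slope = -5,        # mmHg/h down
                               lactate_slope = 0.5,   # mmol/L/h up (pressor/fluid)
                               bicarb_slope = -0.9,   # mEq/L/h down (pressor/fluid)
                               ph_slope = -0.005,     # /h down (pressor/fluid)
                               creatinine_slope = 0.06, # mg/dL/h up (pressor/fluid)
                               hct_slope = -1.2,      # %/h down (prbc)
                               fio2_slope = 0.012     # /h up (ventilated)
                             ),
                             attenuated_units = c("neuro", "stepdown"),
                             attenuation = 0.5) {
  if (!is.numeric(n_stays) || length(n_stays) != 1 || n_stays < 0) {
    stop("n_stays must be a non-negative count")
  }
  if (unstable_fraction < 0 || unstable_fraction > 1) {
    stop("unstable_fraction must lie in [0, 1]")
  }
  stopifnot(vital_interval > 0, all(lab_interval_range > 0),
            vital_dropout >= 0, vital_dropout < 1, attenuation >= 0)
  list(n_stays = as.integer(n_stays), unstable_fraction = unstable_fraction,
       seed = as.integer(seed), vital_interval = vital_interval,
       lab_interval_range = lab_interval_range, vital_dropout = vital_dropout,
       deterioration = deterioration, attenuated_units = attenuated_units,
       attenuation = attenuation)
}

# population baselines (mean, sd, measurement noise sd) per variable
VAR_BASELINES <- list(
  heart_rate = c(85, 12, 3), systolic_bp = c(122, 14, 4),
  diastolic_bp = c(68, 9, 3), mean_bp = c(86, 10, 3),
  respiratory_rate = c(18, 4, 1.5), spo2 = c(96.5, 1.8, 0.8),
  temperature = c(37, 0.5, 0.15), hematocrit = c(33, 5, 0.8),
  hemoglobin = c(11, 1.8, 0.3), wbc = c(11, 4, 0.8),
  platelets = c(220, 80, 10), sodium = c(139, 4, 1),
  potassium = c(4.1, 0.5, 0.15), chloride = c(104, 5, 1),
  bicarbonate = c(24, 4, 1), bun = c(22, 12, 2),
  creatinine = c(1.2, 0.6, 0.1), glucose = c(140, 45, 10),
  lactate = c(1.6, 0.8, 0.2), albumin = c(3.2, 0.6, 0.1),
  total_bilirubin = c(0.9, 0.7, 0.1), calcium = c(8.6, 0.7, 0.15),
  magnesium = c(2, 0.3, 0.08), inr = c(1.2, 0.3, 0.05),
  ph = c(7.38, 0.05, 0.01), pao2 = c(95, 25, 6),
  paco2 = c(40, 7, 2), base_excess = c(0, 3, 0.7),
  fio2 = c(0.4, 0.1, 0.02), mawp = c(10, 3, 0.7), pip = c(22, 5, 1)
)

#' Generate a synthetic ICU cohort
#'
#' Draws stays, observation records and treatment records. Unstable stays
#' carry a deterioration window (heart rate rising, systolic pressure
#' falling, plus an archetype-specific lab drift) that ends at the first
#' treatment; the emitted treatments exceed their trigger thresholds with
#' margin so labeling is unambiguous. Stable stays receive at most sparse
#' sub-threshold fluid boluses that can never satisfy any trigger. The
#' archetype column in the stay table is generator ground truth for
#' evaluation only and must never be fed to the model.
#'
#' @param config from [generator_config()].
#' @return list of \code{data.table}s: \code{stays} (stay_id, age, unit_type,
#'   admission_source, ventilated, dnr, los, archetype), \code{observations}
#'   (stay_id, variable, time, value; long format) and \code{treatments}
#'   (stay_id, category, drug, time, volume).
#' @export
generate_cohort <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- config$n_stays
  empty <- list(
    stays = data.table::data.table(
      stay_id = character(0), age = integer(0), unit_type = character(0),
      admission_source = character(0), ventilated = logical(0),
      dnr = logical(0), los = numeric(0), archetype = character(0)),
    observations = data.table::data.table(
      stay_id = character(0), variable = character(0), time = numeric(0),
      value = numeric(0)),
    treatments = data.table::data.table(
      stay_id = character(0), category = character(0), drug = character(0),
      time = numeric(0), volume = numeric(0)))
  if (n == 0L) return(empty)

  unstable <- stats::runif(n) < config$unstable_fraction
  archetype <- ifelse(unstable,
    sample(c("pressor", "fluid", "prbc"), n, replace = TRUE,
           prob = c(0.53, 0.33, 0.14)),
    "stable")
  # medians 29 h (stable) / 95 h (unstable); lognormal spread
  los <- exp(stats::rnorm(n, mean = ifelse(unstable, log(95), log(29)),
                          sd = 0.45))
  los <- pmax(los, ifelse(unstable, 24, 10))

  stays <- data.table::data.table(
    stay_id = sprintf("S%05d", seq_len(n)),
    age = pmin(95L, 18L + stats::rpois(n, 45)),
    unit_type = sample(c("med-surg", "cardiac", "neuro", "stepdown", "other"),
                       n, replace = TRUE, prob = c(0.5, 0.2, 0.1, 0.1, 0.1)),
    admission_source = sample(c("floor", "ED", "OR", "other-ICU"), n,
                              replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1)),
    ventilated = stats::runif(n) < 0.35,
    dnr = stats::runif(n) < 0.05,
    los = los,
    archetype = archetype)

  det <- config$deterioration
  obs_list <- vector("list", n)
  trt_list <- vector("list", n)
  for (i in seq_len(n)) {
    st <- stays[i]
    atten <- if (st$unit_type %in% config$attenuated_units) config$attenuation else 1
    # deterioration window [onset, t_trt]; onset >= 6 h keeps 1-h-lead
    # positives clear of the first-6-h exclusion
    if (st$archetype == "stable") {
      onset <- Inf; t_trt <- Inf
    } else {
      dr <- det$duration_range
      dur <- stats::runif(1, dr[1], min(dr[2], max(dr[1] + 0.1, st$los - 9)))
      onset <- stats::runif(1, 6, max(6.01, st$los - dur - 2))
      t_trt <- min(onset + dur, st$los - 1)
    }

    # labs reflect hypoperfusion across the whole deterioration window;
    # vitals hold up (compensation) until the last hours before treatment
    drift <- function(times, slope, from = onset) {
      pmax(0, pmin(times, t_trt) - from) * slope * atten
    }
    vital_onset <- max(onset, t_trt - det$late_vital_window)
    vdrift <- function(times, slope) drift(times, slope, from = vital_onset)

    rows <- list()
    emit <- function(variable, times, values) {
      keep <- is.finite(values) & times <= st$los
      if (any(keep)) {
        rows[[length(rows) + 1L]] <<- data.table::data.table(
          stay_id = st$stay_id, variable = variable,
          time = round(times[keep], 4), value = round(values[keep], 3))
      }
    }

    base <- function(v) {
      b <- VAR_BASELINES[[v]]
      stats::rnorm(1, b[1], b[2])
    }
    noise <- function(v, k) stats::rnorm(k, 0, VAR_BASELINES[[v]][3])

    vt <- seq(0, st$los, by = config$vital_interval)
    keep_v <- stats::runif(length(vt)) >= config$vital_dropout
    hr0 <- base("heart_rate"); sbp0 <- base("systolic_bp")
    hr <- hr0 + vdrift(vt, det$hr_slope) + noise("heart_rate", length(vt))
    sbp <- sbp0 + vdrift(vt, det$sbp_slope) + noise("systolic_bp", length(vt))
    sbp <- pmax(sbp, 45)
    emit("heart_rate", vt[keep_v], hr[keep_v])
    # systolic charted through two routes; invasive only on a subset of stays
    if (stats::runif(1) < 0.3) {
      emit("systolic_bp_invasive", vt[keep_v], sbp[keep_v])
      keep_n <- stats::runif(length(vt)) >= 0.5
      emit("systolic_bp_noninvasive", vt[keep_n],
           sbp[keep_n] + stats::rnorm(sum(keep_n), 2, 3))
    } else {
      emit("systolic_bp_noninvasive", vt[keep_v], sbp[keep_v])
    }
    dbp0 <- base("diastolic_bp")
    dbp <- dbp0 + vdrift(vt, det$sbp_slope * 0.5) + noise("diastolic_bp", length(vt))
    emit("diastolic_bp", vt[keep_v], pmax(dbp[keep_v], 25))
    emit("mean_bp", vt[keep_v],
         pmax((sbp[keep_v] + 2 * pmax(dbp[keep_v], 25)) / 3, 30))
    for (v in c("respiratory_rate", "spo2", "temperature")) {
      kv <- stats::runif(length(vt)) >= config$vital_dropout
      val <- base(v) + noise(v, sum(kv))
      if (v == "respiratory_rate") {
        val <- val + vdrift(vt[kv], det$hr_slope * 0.3)
      }
      if (v == "spo2") val <- pmin(val, 100)
      emit(v, vt[kv], val)
    }

    labs <- c("hematocrit", "hemoglobin", "wbc", "platelets", "sodium",
              "potassium", "chloride", "bicarbonate", "bun", "creatinine",
              "glucose", "lactate", "albumin", "total_bilirubin", "calcium",
              "magnesium", "inr", "ph", "pao2", "paco2", "base_excess")
    for (v in labs) {
      gap <- stats::runif(1, config$lab_interval_range[1],
                          config$lab_interval_range[2])
      lt <- seq(stats::runif(1, 0, 2), st$los, by = gap)
      val <- base(v) + noise(v, length(lt))
      if (v == "lactate" && st$archetype %in% c("pressor", "fluid")) {
        val <- val + drift(lt, det$lactate_slope)
      }
      if (v == "bicarbonate" && st$archetype %in% c("pressor", "fluid")) {
        val <- val + drift(lt, det$bicarb_slope)
      }
      if (v == "base_excess" && st$archetype %in% c("pressor", "fluid")) {
        val <- val + drift(lt, det$bicarb_slope * 0.8)
      }
      if (v == "ph" && st$archetype %in% c("pressor", "fluid")) {
        val <- val + drift(lt, det$ph_slope)
      }
      if (v == "creatinine" && st$archetype %in% c("pressor", "fluid")) {
        val <- val + drift(lt, det$creatinine_slope)
      }
      if (v == "hematocrit" && st$archetype == "prbc") {
        val <- val + drift(lt, det$hct_slope)
      }
      if (v == "hemoglobin" && st$archetype == "prbc") {
        val <- val + drift(lt, det$hct_slope / 3)
      }
      emit(v, lt, val)
    }

    if (st$ventilated) {
      for (v in c("fio2", "mawp", "pip")) {
        gap <- stats::runif(1, 2, 8)
        wt <- seq(stats::runif(1, 0, 1), st$los, by = gap)
        val <- base(v) + noise(v, length(wt))
        if (v == "fio2") val <- val + drift(wt, det$fio2_slope)
        emit(v, wt, pmax(val, if (v == "fio2") 0.21 else 2))
      }
    }
    emit("age", 0, as.numeric(st$age))
    obs_list[[i]] <- data.table::rbindlist(rows)

    trt <- treatment_schedule(st, t_trt)
    if (!is.null(trt)) trt_list[[i]] <- trt
  }

  observations <- data.table::rbindlist(obs_list)
  treatments <- data.table::rbindlist(trt_list)
  if (!nrow(treatments)) treatments <- empty$treatments
  data.table::setorder(observations, stay_id, variable, time)
  data.table::setorder(treatments, stay_id, time)
  list(stays = stays, observations = observations, treatments = treatments)
}

# Treatment records for one stay. Unstable archetypes emit doses above their
# Table-of-triggers threshold with margin; stable stays emit only sparse
# boluses that stay below every rule (each < 500 cc and spaced > 13 h, so no
# 12-h window can accumulate more than one bolus).
treatment_schedule <- function(st, t_trt) {
  rec <- function(category, drug, time, volume) {
    data.table::data.table(stay_id = st$stay_id, category = category,
                           drug = drug, time = round(time, 4),
                           volume = volume)
  }
  if (st$archetype == "stable") {
    if (stats::runif(1) < 0.3 && st$los > 14) {
      k <- sample(1:2, 1)
      t1 <- stats::runif(1, 1, st$los - 1)
      times <- t1
      if (k == 2 && t1 + 13.5 < st$los) times <- c(t1, t1 + 13.5)
      return(rec("fluid", NA_character_, times,
                 sample(seq(100, 400, by = 50), length(times), replace = TRUE)))
    }
    return(NULL)
  }
  out <- list()
  if (st$archetype == "pressor") {
    drug <- sample(c("norepinephrine", "vasopressin", "phenylephrine",
                     "epinephrine", "dopamine", "dobutamine"), 1,
                   prob = c(0.45, 0.15, 0.15, 0.1, 0.1, 0.05))
    times <- seq(t_trt, min(t_trt + stats::runif(1, 8, 30), st$los), by = 4)
    out[[1]] <- rec("pressor", drug, times, 0)
  } else if (st$archetype == "fluid") {
    # opening bolus clears the 700 cc / 1 h rule outright
    out[[1]] <- rec("fluid", NA_character_, t_trt,
                    sample(seq(800, 1200, by = 100), 1))
    if (stats::runif(1) < 0.6 && t_trt + 3 < st$los) {
      out[[2]] <- rec("fluid", NA_character_, t_trt + stats::runif(1, 1, 3),
                      sample(seq(300, 600, by = 100), 1))
    }
  } else { # prbc
    out[[1]] <- rec("prbc", NA_character_, t_trt, 500)
    if (stats::runif(1) < 0.5 && t_trt + 8 < st$los) {
      out[[2]] <- rec("prbc", NA_character_, t_trt + stats::runif(1, 4, 8), 350)
    }
  }
  data.table::rbindlist(out)
}

#' Write / read a cohort as CSV files
#'
#' \code{write_cohort()} writes \code{stays.csv}, \code{observations.csv} and
#' \code{treatments.csv}; \code{read_cohort()} reads them back. The round trip
#' is an identity (column order in the files is immaterial; parsing is
#' header-driven). Time stamps are written at full precision.
#'
#' @param cohort list as returned by [generate_cohort()].
#' @param directory target directory (created if needed).
#' @return \code{write_cohort}: invisible named vector of file paths;
#'   \code{read_cohort}: cohort list.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stays = file.path(directory, "stays.csv"),
             observations = file.path(directory, "observations.csv"),
             treatments = file.path(directory, "treatments.csv"))
  for (nm in names(paths)) {
    data.table::fwrite(cohort[[nm]], paths[[nm]])
  }
  invisible(paths)
}

COHORT_SCHEMAS <- list(
  stays = c("stay_id", "age", "unit_type", "admission_source", "ventilated",
            "dnr", "los", "archetype"),
  observations = c("stay_id", "variable", "time", "value"),
  treatments = c("stay_id", "category", "drug", "time", "volume"))

#' @rdname write_cohort
#' @param registry registry used to validate observation variable names.
#' @export
read_cohort <- function(directory, registry = hsi_registry()) {
  out <- list()
  for (nm in names(COHORT_SCHEMAS)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing cohort file: ", path)
    x <- data.table::fread(path, colClasses = list(character = "stay_id"))
    miss <- setdiff(COHORT_SCHEMAS[[nm]], names(x))
    if (length(miss)) {
      stop(nm, ".csv is missing required column(s): ",
           paste(miss, collapse = ", "))
    }
    out[[nm]] <- x[, COHORT_SCHEMAS[[nm]], with = FALSE]
  }
  known <- c(registry$name, "systolic_bp_invasive", "systolic_bp_noninvasive",
             "diastolic_bp_invasive", "diastolic_bp_noninvasive",
             "mean_bp_invasive", "mean_bp_noninvasive")
  bad <- setdiff(unique(out$observations$variable), known)
  if (length(bad)) {
    stop("unknown observation variable(s): ", paste(bad, collapse = ", "))
  }
  out
}
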