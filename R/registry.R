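#' Default 33-variable registry
#'
#' The model operates on 33 physiological variables routinely charted in the
#' ICU: vital signs, laboratory and blood-gas measurements, ventilator
#' settings, one demographic (age) and one derived variable (shock index,
#' heart rate / systolic blood pressure). Each variable carries a class, a
#' forward-fill staleness limit in hours (2 h for vitals, 26 h for labs and
#' ventilator settings, unlimited for demographics), an imputation policy for
#' when no sufficiently fresh measurement exists, and a plausible-range used
#' to clip gross charting artifacts.
#'
#' Imputation policies are: \code{"population_mean"} (training-set mean of
#' measured values), \code{"constant"} (a fixed value; FiO2 imputes to room
#' air, 0.21), and \code{"leave_absent"} (no value is substituted; mean airway
#' pressure and peak inspiratory pressure stay missing on unventilated
#' patients so that ventilator settings are never invented).
#'
#' @param path optional path to a CSV or YAML file with columns/fields
#'   \code{name, class, fill_limit, impute, impute_value, lo, hi} overriding
#'   the built-in registry (the exact variable panel differs between source
#'   databases, so the panel is configurable).
#' @return a \code{data.table} with one row per variable.
#' @export
hsi_registry <- function(path = NULL) {
  if (!is.null(path)) {
    reg <- if (grepl("\\.ya?ml$", path)) {
      data.table::rbindlist(yaml::read_yaml(path), fill = TRUE)
    } else {
      data.table::fread(path)
    }
    reg <- data.table::as.data.table(reg)
    need <- c("name", "class", "fill_limit", "impute", "impute_value", "lo", "hi")
    miss <- setdiff(need, names(reg))
    if (length(miss)) {
      stop("registry file is missing column(s): ", paste(miss, collapse = ", "))
    }
    return(validate_registry(reg[, need, with = FALSE]))
  }

  vital <- function(name, lo, hi) {
    list(name = name, class = "vital", fill_limit = 2,
         impute = "population_mean", impute_value = NA_real_, lo = lo, hi = hi)
  }
  lab <- function(name, lo, hi) {
    list(name = name, class = "lab", fill_limit = 26,
         impute = "population_mean", impute_value = NA_real_, lo = lo, hi = hi)
  }
  rows <- list(
    vital("heart_rate", 20, 250),
    vital("systolic_bp", 30, 300),
    vital("diastolic_bp", 10, 200),
    vital("mean_bp", 20, 250),
    list(name = "shock_index", class = "derived", fill_limit = Inf,
         impute = "population_mean", impute_value = NA_real_, lo = 0.1, hi = 5),
    list(name = "age", class = "demographic", fill_limit = Inf,
         impute = "population_mean", impute_value = NA_real_, lo = 0, hi = 120),
    vital("respiratory_rate", 2, 80),
    vital("spo2", 40, 100),
    vital("temperature", 28, 43),
    lab("hematocrit", 10, 65),
    lab("hemoglobin", 3, 22),
    lab("wbc", 0.1, 100),
    lab("platelets", 5, 1500),
    lab("sodium", 110, 180),
    lab("potassium", 1.5, 9),
    lab("chloride", 70, 140),
    lab("bicarbonate", 5, 50),
    lab("bun", 1, 200),
    lab("creatinine", 0.1, 20),
    lab("glucose", 20, 1000),
    lab("lactate", 0.2, 25),
    lab("albumin", 0.5, 6),
    lab("total_bilirubin", 0.1, 40),
    lab("calcium", 4, 16),
    lab("magnesium", 0.5, 6),
    lab("inr", 0.5, 15),
    lab("ph", 6.7, 7.8),
    lab("pao2", 20, 600),
    lab("paco2", 10, 150),
    lab("base_excess", -30, 30),
    list(name = "fio2", class = "vent", fill_limit = 26,
         impute = "constant", impute_value = 0.21, lo = 0.21, hi = 1),
    list(name = "mawp", class = "vent", fill_limit = 26,
         impute = "leave_absent", impute_value = NA_real_, lo = 0, hi = 60),
    list(name = "pip", class = "vent", fill_limit = 26,
         impute = "leave_absent", impute_value = NA_real_, lo = 0, hi = 80)
  )
  validate_registry(data.table::rbindlist(rows))
}

validate_registry <- function(reg) {
  stopifnot(
    !anyDuplicated(reg$name),
    all(reg$fill_limit > 0),
    all(reg$impute %in% c("population_mean", "constant", "leave_absent")),
    all(reg$lo < reg$hi)
  )
  if (!all(c("heart_rate", "systolic_bp") %in% reg$name)) {
    stop("registry must contain heart_rate and systolic_bp")
  }
  data.table::setkey(reg, NULL)
  reg[]
}

#' Operating modes
#'
#' An operating mode restricts which variables the scorer may see, emulating
#' deployment sites where only a subset of data feeds is integrated. Variables
#' outside the mode are treated as never measured and fall through to their
#' imputation policy. \code{basic} is vital signs only (heart rate, the three
#' blood pressures, shock index, age); \code{basic+labs} adds every lab-class
#' variable; \code{basic+ventilation} adds the ventilator settings; \code{all}
#' imposes no mask.
#'
#' @param name one of \code{"basic"}, \code{"basic+labs"},
#'   \code{"basic+ventilation"}, \code{"all"}.
#' @param registry variable registry (see [hsi_registry()]).
#' @return character vector of visible variable names.
#' @export
operating_mode <- function(name, registry = hsi_registry()) {
  basic <- c("heart_rate", "systolic_bp", "diastolic_bp", "mean_bp",
             "shock_index", "age")
  basic <- intersect(registry$name, basic)
  switch(name,
    "basic" = basic,
    "basic+labs" = union(basic, registry$name[registry$class == "lab"]),
    "basic+ventilation" = union(basic, registry$name[registry$class == "vent"]),
    "all" = registry$name,
    stop("unknown operating mode: ", name)
  )
}

#' Names of the four operating modes
#' @return character vector.
#' @export
hsi_modes <- function() c("basic", "basic+labs", "basic+ventilation", "all")

# Polynomial rolling hash of the registry's variable panel; stored in saved
# models so a model is never scored against a different panel.
content_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

registry_hash <- function(registry) {
  content_hash(paste(registry$name, registry$class, registry$fill_limit,
                     registry$impute, collapse = ";"))
}
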