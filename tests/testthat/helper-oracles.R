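# Independent brute-force oracles. These re-derive expected results from the
# rule definitions by naive enumeration and never share code with the package
# implementation paths they check.

# --- labeling oracle ---------------------------------------------------------

# every record time is tried as a window end; volumes summed by double loop
oracle_criteria <- function(records) {
  records <- records[order(records$time), , drop = FALSE]
  hits <- data.frame(criterion_id = character(0), time = numeric(0))
  add <- function(id, t) {
    hits <<- rbind(hits, data.frame(criterion_id = id, time = t))
  }
  n <- nrow(records)
  for (i in seq_len(n)) {
    if (records$category[i] == "pressor") add("PRESSOR_ANY", records$time[i])
  }
  rules <- list(c(1, 700, "FLUID_1H_700"), c(4, 1500, "FLUID_4H_1500"),
                c(8, 2400, "FLUID_8H_2400"), c(12, 3000, "FLUID_12H_3000"))
  for (i in seq_len(n)) {
    if (records$category[i] != "fluid") next  # sums change only at fluid records
    t <- records$time[i]
    for (r in rules) {
      w <- as.numeric(r[1]); thr <- as.numeric(r[2])
      s <- 0
      for (j in seq_len(n)) {
        if (records$category[j] == "fluid" &&
            records$time[j] > t - w && records$time[j] <= t) {
          s <- s + records$volume[j]
        }
      }
      if (s >= thr) add(r[3], t)
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && records$category[i] == "fluid" &&
          records$category[j] == "fluid" &&
          records$volume[i] >= 500 && records$volume[j] >= 500 &&
          abs(records$time[j] - records$time[i]) <= 4) {
        add("FLUID_TWICE_500_4H", max(records$time[i], records$time[j]))
      }
    }
  }
  prbc_sum <- function(t, w) {
    s <- 0
    for (j in seq_len(n)) {
      if (records$category[j] == "prbc" &&
          records$time[j] > t - w && records$time[j] <= t) {
        s <- s + records$volume[j]
      }
    }
    s
  }
  fluid_hits <- hits$time[grepl("^FLUID_", hits$criterion_id)]
  for (i in seq_len(n)) {
    if (records$category[i] != "prbc") next  # sums change only at prbc records
    t <- records$time[i]
    if (prbc_sum(t, 24) >= 800) add("PRBC_24H_800", t)
    if (prbc_sum(t, 2) >= 500) {
      f12 <- fluid_hits[fluid_hits > t & fluid_hits <= t + 12]
      f24 <- fluid_hits[fluid_hits > t & fluid_hits <= t + 24]
      if (length(f12)) add("PRBC_500_2H_THEN_FLUID_12H", min(f12))
      if (!length(f24)) add("PRBC_500_NO_FLUID_24H", t)
    }
  }
  unique(hits[order(hits$time, hits$criterion_id), , drop = FALSE])
}

# distinct (criterion, time) pairs for comparison
hit_set <- function(hits) {
  if (!nrow(hits)) return(character(0))
  sort(unique(paste(hits$criterion_id, round(hits$time, 9))))
}

random_records <- function(n_max = 50, stay = "r") {
  n <- sample.int(n_max, 1)
  cat_p <- c(pressor = 0.2, fluid = 0.55, prbc = 0.25)
  category <- sample(names(cat_p), n, replace = TRUE, prob = cat_p)
  data.frame(
    stay_id = stay,
    category = category,
    drug = ifelse(category == "pressor",
                  sample(c("dobutamine", "dopamine", "epinephrine",
                           "norepinephrine", "phenylephrine", "vasopressin"),
                         n, replace = TRUE), NA),
    time = round(sort(runif(n, 0, 48)), 3),
    volume = ifelse(category == "pressor", 0,
                    50 * sample.int(16, n, replace = TRUE))  # 50-cc grid
  )
}

# --- AUC oracle --------------------------------------------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# --- round-1 stump oracle ----------------------------------------------------

# exhaustive Newton split search under logistic loss at the constant baseline
# prediction: for every feature and every inter-point split, solve the
# weighted least-squares leaf values and score by the weighted squared-error
# reduction on the negative gradients
oracle_round1_stump <- function(X, y, learning_rate = 0.1, clip = 4) {
  p0 <- mean(y)
  g <- p0 - y
  h <- rep(p0 * (1 - p0), length(y))
  best <- NULL
  for (f in seq_len(ncol(X))) {
    x <- X[, f]
    pres <- which(!is.na(x))
    xs <- sort(unique(x[pres]))
    if (length(xs) < 2) next
    cuts <- (xs[-1] + xs[-length(xs)]) / 2
    for (ct in cuts) {
      L <- pres[x[pres] < ct]; R <- pres[x[pres] >= ct]
      GL <- sum(g[L]); HL <- sum(h[L])
      GR <- sum(g[R]); HR <- sum(h[R])
      # weighted SSE of -g/h targets before vs after the split
      base_sse <- -(GL + GR)^2 / (HL + HR)
      split_sse <- -GL^2 / HL - GR^2 / HR
      gain <- base_sse - split_sse
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = f, cut = ct,
                     left = pmin(pmax(-GL / HL, -clip), clip) * learning_rate,
                     right = pmin(pmax(-GR / HR, -clip), clip) * learning_rate,
                     left_set = sort(L))
      }
    }
  }
  best
}

# gain and Newton leaf values for one specific (feature, threshold) split
oracle_gain_and_leaves <- function(X, y, feature, cut, learning_rate = 0.1,
                                   clip = 4) {
  p0 <- mean(y)
  g <- p0 - y
  h <- rep(p0 * (1 - p0), length(y))
  x <- X[, feature]
  pres <- which(!is.na(x))
  L <- pres[x[pres] < cut]; R <- pres[x[pres] >= cut]
  GL <- sum(g[L]); HL <- sum(h[L])
  GR <- sum(g[R]); HR <- sum(h[R])
  list(gain = GL^2 / HL + GR^2 / HR - (GL + GR)^2 / (HL + HR),
       left = pmin(pmax(-GL / HL, -clip), clip) * learning_rate,
       right = pmin(pmax(-GR / HR, -clip), clip) * learning_rate)
}

# --- small shared fixtures ---------------------------------------------------

# tiny observation stream for snapshot tests: one stay, hand-placed times
tiny_obs <- function() {
  data.frame(
    stay_id = "T1",
    variable = c("heart_rate", "systolic_bp_noninvasive", "lactate", "age"),
    time = c(1, 1, 1, 0),
    value = c(90, 120, 2.0, 60))
}

# stats object with fixed means, usable without a training cohort
fixed_stats <- function(registry = hsi_registry()) {
  means <- as.list(stats::setNames(
    (registry$lo + registry$hi) / 2, registry$name))
  means$fio2 <- 0.4
  qs <- lapply(means, function(m) seq(m * 0.8, m * 1.2, length.out = 16))
  structure(list(mean = means, quantiles = qs), class = "hsi_stats")
}

# infimum of sample times emitted by the sampler: unstable stays whose
# segment start sweeps a fine grid around the exclusion boundary (lead 1),
# plus stable stays whose negative draws crowd the lower bound
min_sample_time_by_search <- function(seed = 1) {
  starts <- seq(6, 9, by = 0.25)
  meta <- function(ids, los, archetype) {
    data.frame(stay_id = ids, age = 50, unit_type = "med-surg",
               admission_source = "ED", ventilated = FALSE, dnr = FALSE,
               los = los, archetype = archetype)
  }
  ids_u <- sprintf("U%02d", seq_along(starts))
  ids_s <- sprintf("N%02d", 1:60)
  stays <- rbind(meta(ids_u, 40, "pressor"), meta(ids_s, 6.6, "stable"))
  obs <- do.call(rbind, lapply(stays$stay_id, function(s) {
    los <- stays$los[stays$stay_id == s]
    tt <- seq(0.5, los, by = 1)
    data.frame(stay_id = s,
               variable = rep(c("heart_rate", "systolic_bp_noninvasive"),
                              each = length(tt)),
               time = rep(tt, 2), value = rep(c(80, 120), each = length(tt)))
  }))
  segments <- data.frame(stay_id = ids_u, start = starts, end = starts + 1,
                         criteria = "PRESSOR_ANY")
  out <- lapply(seed + 0:4, function(sd) {
    suppressWarnings(draw_samples(stays, segments, obs, fixed_stats(),
                                  lead = 1, seed = sd))$time
  })
  min(unlist(out))
}

# memoised small cohort shared by several test files (generated once per run)
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(generator_config(n_stays = 250, seed = 99))
    }
    cache
  }
})
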