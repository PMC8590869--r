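test_that("invasive pressure wins within a 1-minute bin, else passthrough", {
  obs <- data.frame(
    stay_id = "A",
    variable = c("systolic_bp_invasive", "systolic_bp_noninvasive"),
    time = c(5, 5), value = c(90, 100))
  m <- merge_blood_pressure(obs)
  expect_equal(m$variable, "systolic_bp")
  expect_equal(m$value, 90)

  only_n <- data.frame(stay_id = "A", variable = "systolic_bp_noninvasive",
                       time = c(1, 2), value = c(100, 105))
  m <- merge_blood_pressure(only_n)
  expect_equal(m$value, c(100, 105))
  expect_true(all(m$variable == "systolic_bp"))

  expect_equal(nrow(merge_blood_pressure(only_n[0, ])), 0)

  # different bins: both kept as separate time points
  apart <- data.frame(
    stay_id = "A",
    variable = c("systolic_bp_invasive", "systolic_bp_noninvasive"),
    time = c(5, 5.1), value = c(90, 100))
  expect_equal(nrow(merge_blood_pressure(apart)), 2)
})

test_that("forward-fill limits are 2 h for vitals and 26 h for labs", {
  st <- fixed_stats()
  fv <- snapshot(tiny_obs(), st, time = 3.0)
  expect_equal(fv$heart_rate_prov, "forward_filled")
  expect_true(fv$valid)

  fv <- snapshot(tiny_obs(), st, time = 3.01)
  expect_false(fv$valid)
  expect_equal(fv$heart_rate_prov, "imputed")

  fv <- snapshot(tiny_obs(), st, time = 27.0)   # lactate staleness 26 h
  expect_equal(fv$lactate_prov, "forward_filled")
  fv <- snapshot(tiny_obs(), st, time = 27.5)   # 26.5 h > 26 h: expired
  expect_equal(fv$lactate_prov, "imputed")
  expect_equal(fv$lactate, st$mean$lactate)
})

test_that("imputation policy: FiO2 constant, MAWP/PIP left absent, mean else", {
  st <- fixed_stats()
  fv <- snapshot(tiny_obs(), st, time = 1)
  expect_equal(fv$fio2, 0.21)
  expect_equal(fv$fio2_prov, "imputed")
  expect_true(is.na(fv$mawp))
  expect_equal(fv$mawp_prov, "absent")
  expect_true(is.na(fv$pip))
  expect_equal(fv$sodium, st$mean$sodium)
  expect_equal(fv$sodium_prov, "imputed")
  expect_equal(fv$age, 60)
  # demographics never expire; carried value at any staleness
  expect_true(fv$age_prov %in% c("measured", "forward_filled"))
})

test_that("operating modes mask variables without creating data", {
  reg <- hsi_registry()
  expect_length(operating_mode("all", reg), 33)
  expect_false("lactate" %in% operating_mode("basic", reg))
  expect_true("lactate" %in% operating_mode("basic+labs", reg))
  expect_setequal(setdiff(operating_mode("basic+ventilation", reg),
                          operating_mode("basic", reg)),
                  c("fio2", "mawp", "pip"))
  expect_error(operating_mode("turbo", reg), "unknown")

  st <- fixed_stats()
  fv <- snapshot(tiny_obs(), st, time = 1, mode = "basic")
  expect_equal(fv$lactate, st$mean$lactate)   # masked -> population mean
  expect_equal(fv$lactate_prov, "masked")
  # masking cannot create ventilator data on an unventilated stay
  fv <- snapshot(tiny_obs(), st, time = 1, mode = "basic+ventilation")
  expect_true(is.na(fv$mawp))
  expect_true(is.na(fv$pip))

  # mode nesting on real snapshots: measured-or-filled sets are nested
  co <- shared_cohort()
  stct <- population_stats(co$observations)
  q <- data.frame(stay_id = co$stays$stay_id[1:20], time = 8)
  got <- lapply(c("basic", "basic+labs", "all"), function(m) {
    fv <- build_features(co$observations, q, stct, mode = m)
    prov <- as.matrix(as.data.frame(fv)[, paste0(hsi_registry()$name, "_prov")])
    prov %in% c("measured", "forward_filled")
  })
  expect_true(all(got[[2]][got[[1]]]))
  expect_true(all(got[[3]][got[[2]]]))
})

test_that("snapshots are causal, idempotent, and match a naive scan oracle", {
  co <- shared_cohort()
  stct <- population_stats(co$observations)
  reg <- hsi_registry()
  set.seed(77)
  ids <- sample(co$stays$stay_id, 15)
  q <- data.frame(stay_id = ids,
                  time = runif(15, 1, co$stays$los[match(ids, co$stays$stay_id)]))
  fv1 <- build_features(co$observations, q, stct)
  fv2 <- build_features(co$observations, q, stct)
  expect_identical(fv1, fv2)

  obs <- merge_blood_pressure(co$observations)
  for (i in seq_len(nrow(q))) {
    for (v in c("heart_rate", "systolic_bp", "lactate", "fio2", "mawp")) {
      spec <- reg[reg$name == v, ]
      x <- obs[obs$stay_id == q$stay_id[i] & obs$variable == v &
                 obs$time <= q$time[i], ]
      expected <- NA_real_
      if (nrow(x)) {
        last <- x[which.max(x$time), ]
        stale <- q$time[i] - last$time
        if (stale <= spec$fill_limit) {
          expected <- min(max(last$value, spec$lo), spec$hi)
        }
      }
      got <- fv1[[v]][i]
      if (!is.na(expected)) {
        expect_equal(got, expected, info = paste(v, i))
      } else {
        prov <- fv1[[paste0(v, "_prov")]][i]
        expect_false(prov %in% c("measured", "forward_filled"),
                     info = paste(v, i))
      }
    }
  }

  # causality: appending a future extreme value changes nothing
  fut <- data.frame(stay_id = q$stay_id, variable = "heart_rate",
                    time = q$time + 0.5, value = 240)
  fv3 <- build_features(rbind(co$observations, fut), q, stct)
  expect_equal(fv3$heart_rate, fv1$heart_rate)
})

test_that("shock index equals HR/SBP on every valid vector", {
  co <- shared_cohort()
  stct <- population_stats(co$observations)
  q <- data.frame(stay_id = co$stays$stay_id[1:50], time = 7)
  fv <- build_features(co$observations, q, stct)
  ok <- fv$valid
  expect_true(any(ok))
  expect_equal(fv$shock_index[ok], fv$heart_rate[ok] / fv$systolic_bp[ok])
})

test_that("population stats use measured values only and serialize", {
  obs <- data.frame(stay_id = "A", variable = "lactate",
                    time = c(0, 10), value = c(1, 3))
  st <- population_stats(obs)
  expect_equal(st$mean$lactate, 2)   # not staleness-weighted
  p <- withr::local_tempfile(fileext = ".json")
  write_stats(st, p)
  back <- read_stats(p)
  expect_equal(back$mean$lactate, 2)
  expect_equal(back$quantiles$lactate, st$quantiles$lactate)
})

test_that("registry is configurable and validated", {
  reg <- hsi_registry()
  expect_equal(nrow(reg), 33)
  d <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(reg, d)
  expect_equal(hsi_registry(d)$name, reg$name)
  data.table::fwrite(reg[, -"impute"], d)
  expect_error(hsi_registry(d), "impute")
})
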