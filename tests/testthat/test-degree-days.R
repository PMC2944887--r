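test_that("daily degree-days handle the fully-below, fully-between and fully-above cases", {
  expect_equal(daily_degree_days(10, 11, base = 12, upper = 38), 0)
  expect_equal(daily_degree_days(14, 22, base = 12, upper = 38), 6)
  expect_equal(daily_degree_days(40, 45, base = 12, upper = 38), 26)
})

test_that("intercept cases agree with the quadrature oracle", {
  # base intercepted only
  expect_equal(daily_degree_days(8, 20, base = 12, upper = 38),
               quad_degree_days(8, 20, 12, 38), tolerance = 1e-6)
  # cutoff intercepted only
  expect_equal(daily_degree_days(20, 44, base = 12, upper = 38),
               quad_degree_days(20, 44, 12, 38), tolerance = 1e-6)
  # both thresholds intercepted
  expect_equal(daily_degree_days(5, 45, base = 12, upper = 38),
               quad_degree_days(5, 45, 12, 38), tolerance = 1e-6)
})

test_that("randomized cases match the oracle within 1e-6 and stay in [0, upper - base]", {
  cases <- random_sine_cases(400, seed = 42)
  for (i in seq_len(nrow(cases))) {
    dd <- daily_degree_days(cases$tmin[i], cases$tmax[i],
                            base = cases$base[i], upper = cases$upper[i])
    expect_lt(abs(dd - quad_degree_days(cases$tmin[i], cases$tmax[i],
                                        cases$base[i], cases$upper[i])),
              1e-6)
    expect_gte(dd, 0)
    expect_lte(dd, cases$upper[i] - cases$base[i])
  }
})

test_that("degree-days are monotone in tmax, tmin and base", {
  tmaxes <- seq(10, 44, by = 2)
  dd_tmax <- daily_degree_days(rep(8, length(tmaxes)), tmaxes)
  expect_true(all(diff(dd_tmax) >= 0))
  tmins <- seq(-5, 25, by = 2)
  dd_tmin <- daily_degree_days(tmins, rep(25, length(tmins)))
  expect_true(all(diff(dd_tmin) >= 0))
  bases <- seq(5, 24, by = 1)
  dd_base <- vapply(bases, function(b) daily_degree_days(8, 25, base = b),
                    numeric(1))
  expect_true(all(diff(dd_base) <= 0))
})

test_that("limits recover the no-cutoff and no-threshold forms", {
  # upper far above tmax: cutoff can never bind
  expect_equal(daily_degree_days(8, 20, base = 12, upper = 1e6),
               quad_degree_days(8, 20, 12, 1e6), tolerance = 1e-6)
  # thresholds outside [tmin, tmax]: exactly mean minus base
  expect_equal(daily_degree_days(13, 21, base = 5, upper = 40), 12)
})

test_that("the cutoff never engages when tmax stays below it", {
  # mirror of the field observation that 38 degC was never reached: values
  # must be identical with and without the cutoff
  set.seed(7)
  tmin <- runif(50, -10, 25)
  tmax <- tmin + runif(50, 0, 37.9 - tmin)
  tmax <- pmin(tmax, 37.9)
  expect_identical(daily_degree_days(tmin, tmax, 12, 38),
                   daily_degree_days(tmin, tmax, 12, 1e6))
})

test_that("invalid temperature input is rejected", {
  expect_error(daily_degree_days(20, 10), "tmin > tmax")
  expect_error(daily_degree_days(NA, 10), "non-finite")
  expect_error(daily_degree_days(5, 10, base = 20, upper = 15), "below")
})

test_that("season accumulation is a monotone cumulative sum with the window's first day included", {
  w <- constant_weather("2001-03-01", "2001-08-31", 14, 22)
  cs <- season_accumulation(w)
  expect_s3_class(cs, "cum_gdd")
  expect_equal(cs$cum_gdd[1], cs$daily_gdd[1])
  expect_true(all(diff(cs$cum_gdd) >= 0))
  expect_equal(cs$doy[1], 60)  # March 1, non-leap year
  # 10-day sub-check: constant 6 GDD/day
  expect_equal(cs$cum_gdd[10], 60)
  expect_equal(gdd_at_day(cs, cs$doy[5]), 30)
})

test_that("all-cold days give an all-zero series", {
  w <- constant_weather("2001-03-01", "2001-03-03", 2, 8)
  w <- rbind(w, constant_weather("2001-03-04", "2001-08-31", 2, 8))
  cs <- season_accumulation(w)
  expect_true(all(cs$cum_gdd == 0))
})

test_that("missing days contribute zero and are counted", {
  w <- constant_weather("2001-03-01", "2001-08-31", 14, 22)
  w_gap <- w[-(3:5), ]                      # three absent days
  w_gap$tmax[10] <- NA                      # partial record = missing day
  cs <- season_accumulation(w_gap)
  expect_equal(attr(cs, "n_missing"), 4L)
  expect_equal(cs$cum_gdd[nrow(cs)],
               (nrow(w) - 4) * 6)
})

test_that("baseline mean accumulation averages aligned days", {
  w1 <- constant_weather("2001-03-01", "2001-08-31", 14, 22)  # 6 GDD/day
  w2 <- constant_weather("2002-03-01", "2002-08-31", 16, 28)  # 10 GDD/day
  s1 <- season_accumulation(w1)
  s2 <- season_accumulation(w2)
  expect_equal(baseline_mean_accumulation(list(s1))$cum_gdd, s1$cum_gdd)
  expect_equal(baseline_mean_accumulation(list(s1, s1))$cum_gdd, s1$cum_gdd)
  m <- baseline_mean_accumulation(list(s1, s2))
  expect_equal(m$cum_gdd, (s1$cum_gdd + s2$cum_gdd) / 2)
  s3 <- season_accumulation(w2, base = 14)
  expect_error(baseline_mean_accumulation(list(s1, s3)), "thresholds")
})

test_that("leap years align on calendar month-day", {
  w_leap <- constant_weather("2000-03-01", "2000-08-31", 14, 22)
  w_nonleap <- constant_weather("2001-03-01", "2001-08-31", 14, 22)
  s_leap <- season_accumulation(w_leap)
  s_nonleap <- season_accumulation(w_nonleap)
  expect_equal(s_leap$doy[1], 61)   # leap-year March 1
  m <- baseline_mean_accumulation(list(s_leap, s_nonleap))
  expect_equal(nrow(m), 184)
  expect_equal(m$mday[1], "03-01")
})

test_that("running differential is zero against itself and shifts by a constant", {
  w1 <- constant_weather("2001-03-01", "2001-08-31", 14, 22)
  s1 <- season_accumulation(w1)
  d0 <- running_differential(s1, s1)
  expect_true(all(d0$gdd_diff == 0))
  s_up <- s1
  s_up$cum_gdd <- s1$cum_gdd + 10
  d10 <- running_differential(s_up, s1)
  expect_true(all(d10$gdd_diff == 10))
})

test_that("divergence day finds the first persistent exceedance (scan oracle)", {
  doy <- 60:243
  diff0 <- structure(data.frame(doy = doy, gdd_diff = 0),
                     class = c("gdd_diff", "data.frame"))
  expect_true(is.na(divergence_day(diff0)))

  # flat through day 150, then strictly increasing
  vals <- ifelse(doy <= 150, 0, (doy - 150) * 0.8)
  dser <- structure(data.frame(doy = doy, gdd_diff = vals),
                    class = c("gdd_diff", "data.frame"))
  got <- divergence_day(dser, epsilon = 5, persistence = 7)
  # exhaustive scan oracle
  scan <- NA_integer_
  for (i in seq_along(doy)) {
    if (i + 6 <= length(doy) && all(vals[i:(i + 6)] > 5)) { scan <- doy[i]; break }
  }
  expect_identical(got, scan)

  const <- structure(data.frame(doy = doy, gdd_diff = 10),
                     class = c("gdd_diff", "data.frame"))
  expect_identical(divergence_day(const, epsilon = 5, persistence = 7), 60L)
  # a single-day spike must not trigger
  spike <- structure(data.frame(doy = doy,
                                gdd_diff = ifelse(doy == 100, 50, 0)),
                     class = c("gdd_diff", "data.frame"))
  expect_true(is.na(divergence_day(spike, epsilon = 5, persistence = 2)))
})

test_that("year completeness filter applies the monthly and seasonal caps exactly", {
  full <- constant_weather("2001-03-01", "2001-08-31", 14, 22)
  drop_days <- function(w, dates) w[!(as.Date(w$date) %in% as.Date(dates)), ]

  miss3 <- drop_days(full, sprintf("2001-04-%02d", 1:3))
  miss4 <- drop_days(full, sprintf("2001-04-%02d", 1:4))
  # 10 missing spread under the monthly cap: 3 in Apr, 3 in May, 3 in Jun, 1 Jul
  miss10 <- drop_days(full, c(sprintf("2001-04-%02d", 1:3),
                              sprintf("2001-05-%02d", 1:3),
                              sprintf("2001-06-%02d", 1:3), "2001-07-01"))
  miss11 <- drop_days(miss10, "2001-08-01")
  whole_month <- drop_days(full, sprintf("2001-06-%02d", 1:30))

  res <- year_completeness_filter(list(`2001` = full, `2002` = miss3,
                                       `2003` = miss4, `2004` = miss10,
                                       `2005` = miss11,
                                       `2006` = whole_month))
  expect_setequal(res$included, c("2001", "2002", "2004"))
  expect_match(res$report$reason[res$report$year == "2003"], "month 04")
  expect_match(res$report$reason[res$report$year == "2005"], "season missing 11")
  expect_match(res$report$reason[res$report$year == "2006"], "month 06")
})

test_that("seasonal mean temperature averages daily midpoints over the window", {
  w <- constant_weather("2001-01-01", "2001-12-31", 10, 20)
  expect_equal(seasonal_mean_temperature(w), 15)
  w2 <- constant_weather("2001-03-01", "2001-08-31", 10, 20)
  w2$tmin[50] <- NA
  expect_equal(seasonal_mean_temperature(w2), 15)
})
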