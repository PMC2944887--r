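mk_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(site = r[[1]], date = as.Date(r[[2]]), species = r[[3]],
               stage = r[[4]], count = as.integer(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("accidental screening accepts adults with a prior or same-day late-instar trail", {
  rec <- mk_records(
    list("S", "2007-06-25", "spA", "i5", 3),     # doy 176
    list("S", "2007-07-02", "spA", "adult", 2),  # doy 183
    list("S", "2007-06-25", "spB", "i4", 1),
    list("S", "2007-06-25", "spB", "adult", 1))  # same-visit late instar
  fa <- screen_accidentals(rec)
  expect_equal(fa$doy[fa$species == "spA"], 183L)
  expect_false(fa$adjusted[fa$species == "spA"])
  expect_equal(fa$doy[fa$species == "spB"], 176L)
})

test_that("an accidental first adult is skipped in favour of a later verified date", {
  # first adult record with no prior late instars; 13 days later a second
  # adult follows the late-instar trail
  rec <- mk_records(
    list("B", "2007-07-02", "spC", "adult", 1),  # doy 183, accidental
    list("B", "2007-07-08", "spC", "i5", 4),
    list("B", "2007-07-15", "spC", "adult", 3))  # doy 196
  fa <- screen_accidentals(rec)
  expect_equal(fa$doy, 196L)
  expect_equal(fa$raw_doy, 183L)
  expect_true(fa$adjusted)
  expect_gt(nrow(attr(fa, "screened")), 0)

  # with no qualifying adult at all, the species-year is absent
  rec2 <- mk_records(list("B", "2007-07-02", "spD", "adult", 1))
  fa2 <- screen_accidentals(rec2)
  expect_equal(nrow(fa2), 0L)
})

test_that("zero-count rows mark visits but are never observations", {
  rec <- mk_records(
    list("S", "2007-06-20", "spE", "i5", 0),
    list("S", "2007-06-27", "spE", "adult", 2))
  expect_equal(nrow(screen_accidentals(rec)), 0L)
})

test_that("advancement deltas and the 7-day window rule follow the sampling-week convention", {
  fa <- data.frame(site = "S",
                   species = rep(c("a", "b", "c"), each = 2),
                   year = rep(c(1959, 2006), 3),
                   doy = c(172, 159,   # -13: advancement beyond window
                           155, 155,   # 0: unchanged
                           195, 205))  # +10: delay beyond window
  adv <- advancement(fa, baseline_years = c(1959, 1960),
                     resurvey_years = 2006)
  expect_equal(adv$delta[match(c("a", "b", "c"), adv$species)],
               c(-13, 0, 10))
  expect_equal(adv$exceeds_window[match(c("a", "b", "c"), adv$species)],
               c(TRUE, FALSE, TRUE))
  # exactly 7 days is within the sampling window: no change
  fa7 <- data.frame(site = "S", species = "d", year = c(1959, 2006),
                    doy = c(150, 157))
  expect_false(advancement(fa7, 1959, 2006)$exceeds_window)
})

test_that("advancement is antisymmetric under period exchange", {
  fa <- data.frame(site = "S", species = rep(c("a", "b"), each = 2),
                   year = rep(c(1959, 2006), 2),
                   doy = c(172, 159, 150, 163))
  fwd <- advancement(fa, 1959, 2006)
  rev <- advancement(fa, 2006, 1959)
  expect_equal(fwd$delta, -rev$delta)
  expect_equal(fwd$exceeds_window, rev$exceeds_window)
})

test_that("baseline uses the earliest day over baseline years and unmatched species are logged", {
  fa <- data.frame(site = "S", species = c("a", "a", "a", "b"),
                   year = c(1959, 1960, 2006, 2006),
                   doy = c(180, 172, 170, 200))
  adv <- advancement(fa, c(1959, 1960), 2006)
  expect_equal(adv$baseline_doy, 172L)
  expect_equal(adv$delta, -2)
  expect_equal(attr(adv, "dropped")$species, "b")
})

test_that("site mean advancement reproduces the published per-year summaries", {
  b1_2006 <- c(-13, -13, -14, -19, -27, -28, -21)
  m <- site_mean_advancement(b1_2006)
  expect_equal(m$mean, -19.2857, tolerance = 1e-4)
  expect_equal(m$se, 2.4, tolerance = 0.02)
  expect_equal(m$n, 7)

  c1_2008 <- c(-3, -5, -3, -10)
  m2 <- site_mean_advancement(c1_2008)
  expect_equal(m2$mean, -5.25)
  expect_equal(m2$se, 1.7, tolerance = 0.03)

  m3 <- site_mean_advancement(rep(-4, 5))
  expect_equal(m3$mean, -4)
  expect_equal(m3$se, 0)
  expect_error(site_mean_advancement(numeric(0)), "no advancement")
})

test_that("the paired timing test reproduces the highest-site statistics", {
  tab <- advancement_table()
  c1 <- tab[tab$site == "C1", ]
  mean_resurvey <- c1$baseline_doy +
    rowMeans(c1[, c("delta_2006", "delta_2007", "delta_2008")])
  res <- paired_advancement_test(c1$baseline_doy, mean_resurvey)
  expect_equal(res$t, -5.24, tolerance = 0.001)
  expect_equal(res$df, 3)
  expect_equal(res$p, 0.0135, tolerance = 0.01)
  expect_false(res$zero_variance)
})

test_that("the paired test flags zero-variance differences and scale invariance holds", {
  expect_error(paired_advancement_test(150, 140), "two paired")
  res <- paired_advancement_test(c(150, 160, 170), c(145, 155, 165))
  expect_true(res$zero_variance)
  expect_true(is.na(res$t))
  # t is invariant to scaling all differences by a positive constant
  b <- c(150, 160, 170, 185)
  d <- c(-3, -8, -1, -12)
  t1 <- paired_advancement_test(b, b + d)$t
  t2 <- paired_advancement_test(b, b + 3 * d)$t
  expect_equal(t1, t2)
  expect_equal(paired_advancement_test(b, b - d)$t, -t1)
})

test_that("decade warming test recovers configured offsets", {
  expect_equal(decade_warming_test(rep(10, 5), rep(10, 5))$t, 0)
  res <- decade_warming_test(rep(10, 5), rep(11, 5))
  expect_equal(res$mean_diff, 1)
  expect_lt(res$p, 1e-10)
  set.seed(3)
  a <- rnorm(10, 9, 0.5)
  b <- rnorm(10, 10.4, 0.5)
  res2 <- decade_warming_test(a, b)
  expect_equal(res2$df, 18)
  expect_equal(res2$mean_diff, mean(b) - mean(a))
  expect_error(decade_warming_test(1, c(2, 3)), "two years")
})

test_that("decade test power matches a Monte-Carlo two-sample oracle", {
  # offset 1.4 degC, sd 0.5, n = 10 + 10: rejection should be near-certain
  set.seed(9)
  rej <- replicate(40, {
    a <- rnorm(10, 9, 0.5); b <- rnorm(10, 10.4, 0.5)
    decade_warming_test(a, b)$p < 0.05
  })
  diffs <- replicate(40, {
    a <- rnorm(10, 9, 0.5); b <- rnorm(10, 10.4, 0.5)
    decade_warming_test(a, b)$mean_diff
  })
  expect_equal(mean(diffs), 1.4, tolerance = 0.1)
  oracle_power <- power.t.test(n = 10, delta = 1.4, sd = 0.5)$power
  expect_equal(mean(rej), oracle_power, tolerance = 0.1)
})

test_that("the timing model recovers an exact linear relationship in one year", {
  d <- data.frame(baseline_doy = c(150, 170, 190, 210),
                  year = 2006,
                  delta = -0.2 * c(150, 170, 190, 210) + 12)
  m <- suppressWarnings(advancement_timing_model(d))  # exact fit
  expect_equal(m$timing_slope, -0.2)
  expect_true(is.na(m$year_F))
})

test_that("the timing model rejects degenerate designs and keeps nominal size under the null", {
  dg <- data.frame(baseline_doy = rep(150, 4), year = 2006, delta = 1:4)
  expect_error(advancement_timing_model(dg), "degenerate")
  # type-I: independent deltas, slope should rarely be declared significant
  set.seed(21)
  pvals <- replicate(60, {
    d <- expand.grid(baseline_doy = seq(150, 220, by = 10),
                     year = 2006:2008)
    d$delta <- rnorm(nrow(d), -5, 4)
    advancement_timing_model(d)$timing_p
  })
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.075)
})

test_that("abundance change uses only the overlap window and baseline means", {
  rec <- rbind(
    mk_records(list("B", "1959-06-10", "ac", "adult", 120),
               list("B", "1959-07-10", "ac", "adult", 80),    # 1959: 200
               list("B", "1960-06-12", "ac", "adult", 212),   # 1960: 212
               list("B", "2006-06-15", "ac", "adult", 115)),  # 2006: 115
    mk_records(list("B", "2006-05-01", "ac", "adult", 999)))  # outside window
  ch <- abundance_change(rec, "05-15", "09-26",
                         baseline_years = c(1959, 1960), resurvey_years = 2006)
  expect_equal(ch$baseline_mean, 206)
  expect_equal(ch$difference, -91)
  # identical totals give zero change
  rec2 <- mk_records(list("S", "1959-06-01", "x", "adult", 50),
                     list("S", "1960-06-01", "x", "adult", 50),
                     list("S", "2006-06-01", "x", "adult", 50))
  expect_equal(abundance_change(rec2, "05-15", "09-20",
                                c(1959, 1960), 2006)$difference, 0)
})

test_that("rank correlation matches a brute-force average-rank computation", {
  mono <- data.frame(site = "S", species = letters[1:6], year = 2006,
                     difference = 1:6)
  adv <- data.frame(site = "S", species = letters[1:6], year = 2006,
                    delta = c(2, 5, 9, 14, 20, 27))
  res <- abundance_advancement_correlation(mono, adv)
  expect_equal(res$rho, 1)

  const <- within(mono, difference <- 5)
  expect_true(abundance_advancement_correlation(const, adv)$degenerate)

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    ch <- data.frame(site = "S", species = letters[1:n], year = 2006,
                     difference = sample(1:4, n, replace = TRUE))
    ad <- data.frame(site = "S", species = letters[1:n], year = 2006,
                     delta = rnorm(n))
    got <- abundance_advancement_correlation(ch, ad)
    if (got$degenerate) next
    r1 <- rank(ch$difference); r2 <- rank(ad$delta)   # average-rank ties
    brute <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
      sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
    expect_equal(got$rho, brute, tolerance = 1e-12)
  }
})

test_that("rank correlation is invariant under monotone transforms and bounded", {
  set.seed(32)
  ch <- data.frame(site = "S", species = letters[1:8], year = 2006,
                   difference = rnorm(8))
  ad <- data.frame(site = "S", species = letters[1:8], year = 2006,
                   delta = rnorm(8))
  r0 <- abundance_advancement_correlation(ch, ad)$rho
  ch2 <- within(ch, difference <- exp(difference))
  expect_equal(abundance_advancement_correlation(ch2, ad)$rho, r0)
  expect_gte(r0, -1); expect_lte(r0, 1)
})

test_that("the requirement regression detects conserved GDD needs", {
  past <- c(137, 289, 315, 367, 389)
  same <- suppressWarnings(gdd_requirement_regression(past, past))
  expect_equal(same$slope, 1)
  expect_equal(same$r_squared, 1)
  shifted <- suppressWarnings(gdd_requirement_regression(past, past + 25))
  expect_equal(shifted$slope, 1)
  expect_gt(shifted$p_slope_eq_1, 0.99)
  expect_error(gdd_requirement_regression(1:2, 1:2), "three species")
})

test_that("the elevation regression reproduces the 0.25 GDD per metre community gradient", {
  tab <- advancement_table()
  comm <- tapply(tab$gdd_baseline, tab$site, mean)
  elev <- tapply(tab$elevation_m, tab$site, function(x) x[1])
  fit <- gdd_elevation_regression(as.numeric(comm),
                                  as.numeric(elev[names(comm)]))
  expect_equal(round(fit$slope_magnitude, 2), 0.25)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p, 0.05)

  flat <- suppressWarnings(gdd_elevation_regression(c(100, 100, 100), c(1000, 2000, 3000)))
  expect_equal(flat$slope, 0)
  exact <- suppressWarnings(gdd_elevation_regression(c(500, 400, 300), c(1000, 2000, 3000)))
  expect_equal(exact$slope, -0.1)
  expect_equal(exact$r_squared, 1)
})
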