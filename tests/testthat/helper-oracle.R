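# Numerical quadrature oracle for single-sine degree-days: trapezoidal
# integration of the clipped sine curve over one day at `step_sec` seconds.
# Periodic, so the plain grid mean is the trapezoid rule.
quad_degree_days <- function(tmin, tmax, base, upper, step_sec = 3) {
  dt <- step_sec / 86400
  x <- seq(0, 1 - dt, by = dt)
  temp <- (tmin + tmax) / 2 + (tmax - tmin) / 2 * sin(2 * pi * x)
  mean(pmax(pmin(temp, upper), base) - base)
}

# Random (tmin, tmax, base, upper) cases spanning all six analytic cases,
# including exact threshold-boundary configurations.
random_sine_cases <- function(n, seed) {
  set.seed(seed)
  tmin <- runif(n, -25, 45)
  tmax <- tmin + runif(n, 0, 35)
  base <- runif(n, -5, 25)
  upper <- base + runif(n, 0.5, 30)
  # overwrite a slice with boundary cases
  k <- seq_len(min(n, 60))
  bcase <- k %% 6
  tmax[k][bcase == 0] <- base[k][bcase == 0]          # tmax == base
  tmin[k][bcase == 1] <- base[k][bcase == 1]          # tmin == base
  tmax[k][bcase == 2] <- upper[k][bcase == 2]         # tmax == upper
  tmin[k][bcase == 3] <- upper[k][bcase == 3]         # tmin == upper
  tmin[k][bcase == 4] <- tmax[k][bcase == 4]          # flat day
  # bcase == 5 left random
  bad <- tmin > tmax
  tmin[bad] <- tmax[bad]
  data.frame(tmin = tmin, tmax = tmax, base = base, upper = upper)
}

# Constant-temperature weather over a date range.
constant_weather <- function(from, to, tmin, tmax) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  data.frame(date = dates, tmin = tmin, tmax = tmax)
}
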