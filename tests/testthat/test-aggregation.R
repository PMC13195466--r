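random_convex_polygon <- function(n = 8, center = c(100, 100), radius = 60) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.4, 1) * radius
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

test_that("coverage weights reproduce simple and random polygon areas", {
  g <- grid_definition(20, 20, cell_size_km = 12)

  # one full cell
  full <- cbind(c(12, 24, 24, 12), c(12, 12, 24, 24))
  w <- compute_coverage_weights(g, full)
  expect_equal(nrow(w), 1)
  expect_equal(w$fraction, 1, tolerance = 1e-12)
  expect_equal(w$cell, cell_index(g, 2, 2))

  # half a cell, axis aligned
  half <- cbind(c(12, 18, 18, 12), c(12, 12, 24, 24))
  expect_equal(compute_coverage_weights(g, half)$fraction, 0.5,
               tolerance = 1e-12)

  # random convex polygons against the shoelace oracle
  set.seed(23)
  for (i in 1:10) {
    poly <- random_convex_polygon()
    w <- compute_coverage_weights(g, poly)
    area_w <- sum(w$fraction) * g$cell_area_km2
    area_true <- pfsmoke:::shoelace_area(poly)
    expect_lt(abs(area_w / area_true - 1), 0.001)
  }

  expect_error(compute_coverage_weights(g, cbind(c(-90, -80, -80),
                                                 c(-90, -90, -80))),
               "does not intersect")
})

test_that("coverage weights agree with a fine-subsampling area oracle", {
  g <- grid_definition(20, 20, cell_size_km = 12)
  set.seed(31)
  # convex polygon: vertices on a circle
  ang <- sort(runif(7, 0, 2 * pi))
  poly <- cbind(110 + 65 * cos(ang), 110 + 65 * sin(ang))
  w <- compute_coverage_weights(g, poly)
  inside_frac <- function(rc) {
    m <- 100
    xs <- (rc$col - 1) * 12 + (seq_len(m) - 0.5) * 12 / m
    ys <- (rc$row - 1) * 12 + (seq_len(m) - 0.5) * 12 / m
    px <- rep(xs, times = m); py <- rep(ys, each = m)
    n <- nrow(poly); ok <- rep(TRUE, m * m)
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      cr <- (poly[i, 1] - poly[j, 1]) * (py - poly[j, 2]) -
            (poly[i, 2] - poly[j, 2]) * (px - poly[j, 1])
      ok <- ok & cr >= -1e-9       # counter-clockwise convex polygon
    }
    mean(ok)
  }
  for (k in sample(nrow(w), 6)) {
    rc <- cell_rowcol(g, w$cell[k])
    expect_lt(abs(inside_frac(rc) - w$fraction[k]), 0.005)
  }
})

test_that("weighted daily means honor weights and constants", {
  g <- grid_definition(4, 4, cell_size_km = 10)
  d <- as.Date("2021-06-01") + 0:2
  f <- field_series(g, d, "PM25_TOT", "all", matrix(3.7, 3, 16))
  whole <- cbind(c(0, 40, 40, 0), c(0, 0, 40, 40))
  w <- compute_coverage_weights(g, whole)
  m <- weighted_daily_mean(f, w)
  expect_equal(m$value, rep(3.7, 3))

  v <- matrix(runif(48), 3, 16)
  f2 <- field_series(g, d, "PM25_TOT", "all", v)
  expect_equal(weighted_daily_mean(f2, w)$value, rowMeans(v))

  # two equal-weight cells with values 2 and 4 average to 3
  two <- cbind(c(0, 20, 20, 0), c(0, 0, 10, 10))
  w2 <- compute_coverage_weights(g, two)
  v3 <- matrix(0, 3, 16)
  v3[, w2$cell] <- rep(c(2, 4), each = 3)
  f3 <- field_series(g, d, "PM25_TOT", "all", v3)
  expect_equal(weighted_daily_mean(f3, w2)$value, rep(3, 3))
})

test_that("period summaries stratify by season and year", {
  daily <- data.frame(date = as.Date(c("2021-01-01", "2021-01-02",
                                       "2021-01-03", "2021-06-10",
                                       "2021-11-05")),
                      value = c(1, 2, 3, 7, 9))
  s <- period_summary(daily)
  jfma <- s[s$year == "2021" & s$season == "JFMA", ]
  expect_equal(jfma$mean, 2)
  expect_equal(jfma$median, 2)
  expect_equal(jfma$sd, 1)
  expect_equal(jfma$n, 3)
  overall <- s[s$year == "all" & s$season == "all", ]
  expect_equal(overall$n, 5)
  expect_false(any(s$season == "OND" & s$n == 0))  # empty strata absent, not zero

  const <- data.frame(date = daily$date, value = 4)
  sc <- period_summary(const)
  expect_true(all(sc$sd[sc$n > 1] == 0))
  expect_true(all(sc$mean == 4 & sc$median == 4))

  # invariant to day order within strata
  perm <- daily[c(3, 1, 5, 2, 4), ]
  expect_equal(period_summary(perm), s)
})

test_that("PF shares are ratios of period means", {
  d <- as.Date("2021-01-01") + 0:9
  pf <- data.frame(date = d, value = rep(0.50, 10))
  amb <- data.frame(date = d, value = rep(6.25, 10))
  expect_equal(pf_share(pf, amb)$period_pct, 8)
  expect_equal(pf_share(amb, amb)$period_pct, 100)
  expect_equal(pf_share(transform(pf, value = 0), amb)$period_pct, 0)
  expect_error(pf_share(pf, transform(amb, value = 0)), "degenerate")
})

test_that("exceedance statistics count cell-days and regional days", {
  g <- grid_definition(5, 5)
  d <- as.Date("2021-01-01") + 0:3
  v <- matrix(0.5, 4, 25)
  v[1, 1:2] <- 5; v[3, 7] <- 3.5
  f <- field_series(g, d, "PM25_TOT", "all", v)
  e <- exceedance_stats(f, 3.5)
  expect_equal(e$cell_day_fraction, 3 / 100)
  # brute-force loop oracle
  cnt <- 0
  for (i in 1:4) for (j in 1:25) if (v[i, j] >= 3.5) cnt <- cnt + 1
  expect_equal(e$cell_day_fraction * e$n_cell_days, cnt)

  low <- exceedance_stats(f, 100)
  expect_equal(low$cell_day_fraction, 0)
  # monotone non-increasing in the threshold
  ths <- c(0.1, 0.5, 3.5, 5, 6)
  fr <- vapply(ths, function(t) exceedance_stats(f, t)$cell_day_fraction, 1)
  expect_true(all(diff(fr) <= 0))

  daily <- data.frame(date = d, value = c(4, 1, 3.5, 2))
  expect_equal(exceedance_stats(f, 3.5, daily)$n_days_regional, 2)
})
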