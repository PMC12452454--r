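toy_grf <- function(v = c(600, 400, 9.9, 0, 0, 5, 9, 300), rate = 100) {
  uniform_series(v, rate, units = "N")
}

test_that("SLS detection finds the first strict below-threshold run", {
  sls <- detect_sls(toy_grf(), threshold = 10)
  expect_equal(sls$start_index, 3L)  # sample 2 in 0-based counting
  expect_equal(sls$end_index, 7L)    # sample 6 in 0-based counting
  expect_equal(sls$start_time, 2 / 100)
  expect_equal(sls$end_time, 6 / 100)
  # a sample exactly at the threshold terminates the run ("rose above")
  sls10 <- detect_sls(toy_grf(c(600, 5, 5, 10, 5, 600)), 10)
  expect_equal(c(sls10$start_index, sls10$end_index), c(2L, 3L))
})

test_that("SLS detection rejects absent and truncated runs", {
  expect_error(detect_sls(toy_grf(c(600, 500, 700, 300))), "no SLS")
  expect_error(detect_sls(toy_grf(c(9, 0, 0, 300))), "truncated")
  expect_error(detect_sls(toy_grf(c(300, 0, 0, 9))), "truncated")
})

test_that("SLS detection is invariant to scaling and padding", {
  base <- c(600, 400, 9.9, 0, 0, 5, 9, 300)
  a <- detect_sls(toy_grf(base))
  # scaling samples at/above threshold does not move the window
  scaled <- ifelse(base >= 10, base * 3.7, base)
  b <- detect_sls(toy_grf(scaled))
  expect_equal(b$start_index, a$start_index)
  expect_equal(b$end_index, a$end_index)
  # padding outside the detected run only shifts indices by the pad length
  padded <- detect_sls(toy_grf(c(500, 800, base, 700)))
  expect_equal(padded$start_index, a$start_index + 2L)
  expect_equal(padded$end_index, a$end_index + 2L)
})

test_that("early/late split shares the boundary grid point", {
  sls <- detect_sls(toy_grf())
  s50 <- split_early_late(sls, 0.5, n_points = 101)
  expect_equal(s50$early, c(1L, 51L))   # grid points 0..50
  expect_equal(s50$late, c(51L, 101L))  # grid points 50..100
  expect_equal(diff(s50$early) + 1L, 51L)
  s30 <- split_early_late(sls, 0.3, n_points = 101)
  expect_equal(s30$early, c(1L, 31L))   # nearest grid point to 30 %
  expect_equal(s30$late, c(31L, 101L))
  expect_error(split_early_late(sls, 0), "fraction")
  expect_error(split_early_late(sls, 1.2), "fraction")
  # normalization precedes splitting: even a 2-sample support window yields
  # segments with at least 2 grid points each
  tiny <- detect_sls(toy_grf(c(600, 4, 5, 300)))
  expect_equal(tiny$end_index - tiny$start_index, 1L)
  st <- split_early_late(tiny, 0.5, n_points = 101)
  expect_gte(diff(st$early) + 1L, 2L)
  expect_gte(diff(st$late) + 1L, 2L)
})

test_that("time normalization maps the window onto a 0-100 % grid", {
  sls <- detect_sls(toy_grf())
  const <- uniform_series(rep(7, 10), 100, units = "N")
  w <- normalize_time(const, sls)
  expect_length(w$values, 101L)
  expect_equal(range(w$grid), c(0, 100))
  expect_true(all(w$values == 7))

  ramp <- uniform_series(seq(0, 9, by = 1), 100)
  wr <- normalize_time(ramp, sls)
  expect_lt(max(abs(wr$values - seq(2, 6, length.out = 101))), 1e-12)
  # endpoints equal the series values at the interval bounds
  expect_equal(wr$values[1], ramp$values[sls$start_index])
  expect_equal(wr$values[101], ramp$values[sls$end_index])
  # monotone segments keep their extrema at the ends
  expect_equal(min(wr$values), wr$values[1])
  expect_equal(max(wr$values), wr$values[101])

  out <- detect_sls(toy_grf())
  shorty <- uniform_series(rep(1, 3), 100)
  expect_error(normalize_time(shorty, out), "outside")
})

test_that("normalization is independent of the source sampling rate", {
  f <- function(t) 2 + sin(2 * pi * 1.3 * t) + 0.4 * cos(2 * pi * 3 * t)
  s200 <- uniform_series(f((0:400) / 200), 200)
  s100 <- uniform_series(f((0:200) / 100), 100)
  sls <- structure(list(start_index = 51L, end_index = 151L,
                        start_time = 0.5, end_time = 1.5, rate = 100,
                        threshold = 10, runs = NULL, split_fraction = NULL,
                        n_points = NULL, early = NULL, late = NULL),
                   class = "sls_interval")
  w200 <- normalize_time(s200, sls)
  w100 <- normalize_time(s100, sls)
  expect_lt(max(abs(w200$values - w100$values)), 1e-3)
})

test_that("spatiotemporal parameters follow from contact events", {
  st <- spatiotemporal(c(0, 0.5, 1.0, 1.5), c(0, 0.6, 1.2, 1.8))
  expect_equal(st$step_rate, 120)
  expect_equal(st$step_length, 0.6)
  expect_equal(st$walking_speed, 1.2)
  expect_error(spatiotemporal(c(0, 0.7)), "at least 3")
  expect_error(spatiotemporal(c(0, 0.7, 0.6)), "increasing")
})

test_that("cadence is recovered from simulated trials", {
  for (cad in c(115, 100, 85)) {
    tr <- cached_trial(cad)
    st <- spatiotemporal(tr$events$contacts$time, tr$events$contacts$position)
    expect_lt(abs(st$step_rate - cad), 2)
  }
})
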