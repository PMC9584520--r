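test_that("dominant period finds the strongest spectral component", {
  s <- make_fixture("sine", t_end = 5000, dt = 1, period = 100)
  Tdom <- dominant_period(s$states[, 1], dt = 1)
  expect_lt(abs(Tdom - 100), 5000 / 50)      # within one frequency bin
  expect_equal(dominant_period(rep(3, 1000)), Inf)
  m <- make_fixture("multi_tone", t_end = 5000, period = c(100, 500),
                    amplitude = c(1, 3))
  expect_lt(abs(dominant_period(m$states[, 1]) - 500), 5000 / 9)
  expect_error(dominant_period(c(1, 2, 3)), "4 samples")
})

test_that("peak detection and amplitudes behave on analytic signals", {
  s <- make_fixture("sine", t_end = 2000, period = 100, amplitude = 0.2)
  pk <- peak_amplitudes(s$states[, 1])
  expect_true(all(abs(pk$amplitudes - 0.4) < 0.01))  # peak-to-trough = 2a
  # one amplitude per completed oscillation
  expect_equal(length(pk$amplitudes), 2000 %/% 100, tolerance = 0.1)
  mono <- peak_amplitudes(seq(0, 1, length.out = 100))
  expect_equal(length(mono$amplitudes), 0)
  expect_equal(mono$A_F, 0)
})

test_that("above-threshold amplitude count matches a constructed decay", {
  # decay tuned so exactly the first 3 amplitudes exceed 0.05
  tt <- seq(0, 2000, by = 1)
  x <- 0.5 + 0.06 * exp(-tt / 700) * sin(2 * pi * tt / 200)
  st <- oscillation_stats(x, dt = 1, K = 0.05)
  expect_equal(st$A_K, 3)
  expect_equal(st$p, 2000 / st$T, tolerance = 1e-12)
})

test_that("oscillation distances implement the zeroing rules", {
  mk <- function(mat) structure(list(times = seq_len(nrow(mat)) - 1,
                                     states = mat,
                                     termination = list(status = "completed")),
                                class = "chaoscope_trajectory")
  tt <- 0:5000
  sine3 <- cbind(N1 = 0.5 + 0.2 * sin(2 * pi * tt / 100),
                 N2 = 0.5 + 0.2 * sin(2 * pi * tt / 100),
                 N3 = 0.5 + 0.2 * sin(2 * pi * tt / 100))
  d <- oscillation_distances(mk(sine3))
  expect_equal(d[1], 0)               # T = 100 < t/2 = 2500
  expect_equal(d[3], 0)               # |A_F - K| = 0.35 > K, zeroed
  expect_true(all(d < EPS_OSCILLATION))  # sustained oscillator is accepted
  # extinction maps to the sentinel on every component
  ext <- mk(sine3); ext$termination$status <- "extinction"
  expect_equal(oscillation_distances(ext), rep(DIST_SENTINEL, 3))
  # one flat strain dominates the componentwise maximum (no finite period)
  flat1 <- sine3; flat1[, 2] <- 0.5
  d2 <- oscillation_distances(mk(flat1))
  expect_gt(d2[1], EPS_OSCILLATION[1])
})

test_that("chaos distance is the stated transform with its rejections", {
  expect_equal(chaos_distance(0)$d, 1)
  expect_equal(round(chaos_distance(0.003)$d, 3), 0.997)
  expect_equal(chaos_distance(1)$d, 0.5)
  expect_true(chaos_distance(-1)$reject)
  expect_true(chaos_distance(-1.5)$reject)
  # strictly decreasing for lambda1 > -1, so the threshold is equivalent
  # to a lambda1 cut
  l <- seq(-0.9, 1, by = 0.01)
  d <- vapply(l, function(x) chaos_distance(x)$d, numeric(1))
  expect_true(all(diff(d) < 0))
  # the threshold brackets the lambda1 = 0.003 boundary
  expect_lt(chaos_distance(0.0031)$d, EPS_CHAOS)
  expect_gt(chaos_distance(0.0029)$d, EPS_CHAOS)
})

test_that("the chaos prescreen gates on per-strain sustained oscillations", {
  mk <- function(mat, status = "completed")
    structure(list(times = seq_len(nrow(mat)) - 1, states = mat,
                   termination = list(status = status)),
              class = "chaoscope_trajectory")
  tt <- 0:3000
  osc <- 0.5 + 0.2 * sin(2 * pi * tt / 100)
  expect_true(chaos_prescreen(mk(cbind(N1 = osc, N2 = osc, N3 = osc))))
  expect_false(chaos_prescreen(mk(cbind(N1 = osc, N2 = osc, N3 = osc),
                                  status = "extinction")))
  flat <- rep(0.5, length(tt))
  expect_false(chaos_prescreen(mk(cbind(N1 = osc, N2 = flat, N3 = osc))))
  # a stable washout-like trajectory is rejected outright
  expect_false(chaos_prescreen(mk(cbind(N1 = flat, N2 = flat, N3 = flat))))
})
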