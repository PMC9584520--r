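test_that("Monod growth follows the saturating form", {
  expect_equal(monod_growth(2, S = 3.9e-5, K = 3.9e-5), 1.0)
  expect_equal(monod_growth(1.5, S = 0, K = 1e-5), 0)
  expect_equal(monod_growth(1.17, S = 0.02, K = 3.9e-5),
               1.17 * 0.02 / (0.02 + 3.9e-5))
  expect_error(monod_growth(1, S = -1e-3, K = 1e-5), "non-negative")
  # monotone in S, bounded by mu_max
  s <- seq(0, 0.1, length.out = 50)
  v <- monod_growth(2, s, 3.9e-5)
  expect_true(all(diff(v) > 0) && all(v < 2))
})

test_that("bacteriocin killing is Hill-shaped and gated by sensitivity", {
  expect_equal(kill_rate(0.8, 1.6e-7, 1.6e-7, 1.87), 0.4)
  expect_equal(kill_rate(0.8, 1e-5, 1.6e-7, 1.87, sensitive = FALSE), 0)
  expect_lt(abs(kill_rate(0.8, 1, 1.6e-7, 1.87) - 0.8), 1e-6)  # saturation
  expect_equal(kill_rate(0.8, 0, 1.6e-7, 1.87), 0)
})

test_that("QS regulation covers induced and repressed forms", {
  expect_equal(bacteriocin_expression(2e-16, 1e-8, 1e-8, 1.5, "induced"), 1e-16)
  expect_equal(bacteriocin_expression(2e-16, 0, 1e-8, 1.5, "repressed"), 2e-16)
  expect_equal(bacteriocin_expression(2e-16, 0, 1e-8, 1.5, "induced"), 0)
  expect_equal(bacteriocin_expression(2e-16, 1e-2, 1e-8, 1.5, "repressed"), 0,
               tolerance = 1e-8)
})

test_that("community derivative matches an independent focal-topology oracle", {
  # hand-coded directly from the seven focal equations, written without
  # reference to community_rhs
  focal_oracle <- function(p, y) {
    N1 <- y[1]; N2 <- y[2]; N3 <- y[3]; S <- y[4]
    B1 <- y[5]; B2 <- y[6]; A1 <- y[7]
    A1m <- A1 * p$C_A; B1m <- B1 * p$C_B; B2m <- B2 * p$C_B
    mu <- function(x) p$mu_max[x] * S / (p$K + S)
    om <- function(Bm) p$omega_max * Bm^p$n_omega /
      (p$K_omega^p$n_omega + Bm^p$n_omega)
    kb <- function(z) p$KBmax[z] * A1m^p$n_z[z] /
      (p$K_AB[z]^p$n_z[z] + A1m^p$n_z[z])
    c(N1 * mu(1) - N1 * om(B1m) - N1 * p$D,
      N2 * mu(2) - N2 * p$D,
      N3 * mu(3) - N3 * om(B2m) - N3 * p$D,
      p$D * (p$S0 - S) - (mu(1) * N1 + mu(2) * N2 + mu(3) * N3) * p$C_N / p$gamma,
      kb(1) * (N1 + N2) * p$C_N / p$C_B - p$D * B1,
      kb(2) * N3 * p$C_N / p$C_B - p$D * B2,
      p$kA[1] * N1 * p$C_N / p$C_A - p$D * A1)
  }
  rv <- chaos_reference_vector()
  set.seed(3)
  for (i in 1:10) {
    y <- c(runif(3, 0, 2), runif(1, 0, 0.02), runif(2, 0, 500), runif(1, 0, 200))
    expect_equal(community_rhs(rv$structure, rv$params, y),
                 focal_oracle(rv$params, y), tolerance = 1e-12)
  }
})

test_that("community derivative limiting cases", {
  rv <- chaos_reference_vector()
  # no cells: substrate relaxes to the feed, signals dilute away
  y <- c(0, 0, 0, 0.01, 50, 20, 10)
  d <- community_rhs(rv$structure, rv$params, y)
  expect_equal(d[4], rv$params$D * (rv$params$S0 - 0.01))
  expect_equal(d[5:7], -rv$params$D * y[5:7])
  # no cells at feed substrate: nothing moves the substrate
  y2 <- c(0, 0, 0, rv$params$S0, 0, 0, 0)
  expect_equal(community_rhs(rv$structure, rv$params, y2), rep(0, 7))
})

test_that("compiled and reference right-hand sides produce the same flow", {
  rv <- chaos_reference_vector()
  tr_c <- simulate_community(rv$structure, rv$params, rv$state0, t_end = 50)
  tr_r <- deSolve::lsoda(unname(rv$state0), 0:50,
                         function(t, y, parms)
                           list(community_rhs(rv$structure, rv$params, y)),
                         parms = NULL, atol = 1e-11, rtol = 1e-8)
  expect_equal(unname(tr_c$states[51, ]), unname(tr_r[51, -1]),
               tolerance = 1e-4)
})

test_that("gLV derivative and logistic limit", {
  gl <- glv_chaotic_attractor()
  expect_equal(glv_rhs(gl$params, rep(0, 4)), rep(0, 4))
  # one-species system with alpha = 1 is logistic with fixed point 1
  p1 <- glv_params(r = 0.8, alpha = matrix(1))
  expect_equal(glv_rhs(p1, 1), 0)
  tr <- simulate_glv(p1, c(N1 = 0.05), t_end = 40, dt_out = 0.5)
  closed <- 1 / (1 + (1 / 0.05 - 1) * exp(-0.8 * tr$times))
  expect_equal(unname(tr$states[, 1]), closed, tolerance = 1e-4)
  # derivative at the published chaotic point matches direct evaluation
  y <- gl$state0
  expect_equal(glv_rhs(gl$params, y),
               gl$params$r * y * (1 - as.numeric(gl$params$alpha %*% y)),
               tolerance = 1e-12)
})

test_that("washout dilution drives every strain extinct", {
  rv <- chaos_reference_vector()
  p <- rv$params
  p$D <- 1.05 * max(p$mu_max) * p$S0 / (p$S0 + p$K)  # above every growth rate
  tr <- simulate_community(rv$structure, p, rv$state0)
  expect_equal(tr$termination$status, "extinction")
  expect_lt(tr$termination$time, 5000)
})

test_that("a single unkilled strain settles at S = DK/(mu - D)", {
  rv <- chaos_reference_vector()
  s0 <- rv$state0
  s0[c("N1", "N3")] <- 0
  tr <- simulate_community(rv$structure, rv$params, s0, t_end = 2000,
                           extinction = NULL)
  p <- rv$params
  expect_equal(unname(tr$states[nrow(tr$states), "S"]),
               p$D * p$K / (p$mu_max[2] - p$D), tolerance = 1e-3)
})

test_that("trajectories stay non-negative with bounded substrate", {
  rv <- chaos_reference_vector()
  thetas <- sample_focal_theta(6, seed = 11)
  st <- focal_structure()
  for (th in thetas) {
    pp <- particle_to_params(st, th)
    tr <- simulate_community(st, pp$params, pp$state0, t_end = 300)
    expect_true(all(tr$states > -1e-8))
    expect_lt(max(tr$states[, "S"]),
              max(pp$state0["S"], pp$params$S0) + 1e-6)
  }
})

test_that("endpoint of a non-chaotic run is stable under tighter tolerances", {
  rv <- chaos_reference_vector()
  p <- rv$params
  p$kA <- 3.5e-18   # stable-coexistence regime
  a <- simulate_community(rv$structure, p, rv$state0, t_end = 2000)
  b <- simulate_community(rv$structure, p, rv$state0, t_end = 2000,
                          atol = 1e-10, rtol = 1e-5)
  end_a <- a$states[nrow(a$states), 1:3]
  end_b <- b$states[nrow(b$states), 1:3]
  expect_lt(max(abs(end_a - end_b) / pmax(abs(end_b), 1e-12)), 1e-3)
})

test_that("the focal reference vector survives the full horizon", {
  rv <- chaos_reference_vector()
  tr <- simulate_community(rv$structure, rv$params, rv$state0)
  expect_equal(tr$termination$status, "completed")
  expect_true(all(tr$states[nrow(tr$states), 1:3] > 1e-5))
  # sustained movement, not a fixed point
  late <- tr$states[tr$times >= 2500, 2]
  expect_gt(diff(range(late)), 0.05)
})
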