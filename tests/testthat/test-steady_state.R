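test_that("washout state matches its closed-form eigenvalues", {
  p <- chaos_reference_vector()$params
  P0 <- trivial_state(p)
  expect_equal(unname(P0$state$coordinates),
               c(0, 0, 0, p$S0, 0, 0, 0))
  # -D is among the analytic eigenvalues, and the analytic set is found in
  # the finite-difference Jacobian spectrum
  expect_true(any(abs(P0$stability$analytic_eigenvalues + p$D) < 1e-12))
  num <- sort(Re(P0$stability$eigenvalues))
  for (ev in P0$stability$analytic_eigenvalues)
    expect_lt(min(abs(num - ev)), 1e-6 * max(1, abs(ev)))
  # the reference dilution rate is far below the washout point
  expect_false(P0$stable_condition$holds)
  expect_false(P0$stability$stable)
  # raising D above every growth rate stabilises washout
  p2 <- p; p2$D <- 0.99 * max(p$mu_max) * p$S0 / (p$S0 + p$K) * 1.05
  P0b <- trivial_state(p2)
  expect_true(P0b$stable_condition$holds)
  expect_true(P0b$stability$stable)
})

test_that("single-survivor states match closed forms and conditions", {
  p <- chaos_reference_vector()$params
  ss <- single_strain_states(p)
  # P2 substrate level
  expect_equal(unname(ss$P2$state$coordinates["S"]),
               p$D * p$K / (p$mu_max[2] - p$D), tolerance = 1e-12)
  expect_lt(ss$P2$state$residual, 1e-8)
  # analytic eigenvalues agree with the numerical Jacobian
  num <- sort(Re(ss$P2$stability$eigenvalues))
  for (ev in ss$P2$stability$analytic_eigenvalues)
    expect_lt(min(abs(num - ev)), 1e-6 * max(1, abs(ev)))
  # P2 cannot be stable: mu2 is not the fastest grower
  expect_false(ss$P2$stability$stable)
  expect_true(p$mu_max[2] < max(p$mu_max[1], p$mu_max[3]))
  # P3 exists with its own substrate level
  expect_equal(unname(ss$P3$state$coordinates["S"]),
               p$D * p$K / (p$mu_max[3] - p$D), tolerance = 1e-12)
  # P1 exists (condition holds at the reference) with a tiny residual
  expect_true(p$D < p$mu_max[1] * p$S0 / (p$K + p$S0))
  expect_true(ss$P1$state$exists)
  expect_lt(ss$P1$state$residual, 1e-8)
  expect_true(all(ss$P1$state$coordinates[c("N1", "B1", "A1")] > 0))
})

test_that("survival-state existence matches the analytic dichotomy over D", {
  p <- chaos_reference_vector()$params
  for (D in seq(0.01, 0.5, length.out = 100)) {
    p2 <- p; p2$D <- D
    predicted <- D < p$mu_max[1] * p$S0 / (p$K + p$S0)
    got <- tryCatch(single_strain_states(p2)$P1$state$exists,
                    error = function(e) NA)
    expect_identical(got, predicted)
  }
})

test_that("coexistence conditions evaluate the printed inequalities", {
  p <- chaos_reference_vector()$params
  cc <- coexistence_conditions(p)
  # mu2 below both competitors
  expect_equal(cc$upper, min(p$mu_max[1], p$mu_max[3]))
  expect_true(cc$mu2 < cc$upper)
  # lower bound assembled from washout and killing limits
  expect_equal(cc$lower,
               max(p$D * (p$K + p$S0) / p$S0,
                   p$mu_max[1] * p$D / (p$D + p$omega_max),
                   p$mu_max[3] * p$D / (p$D + p$omega_max)))
  expect_true(cc$holds)
  # a fast-growing middle strain violates the necessary condition
  p2 <- p; p2$mu_max[2] <- p$mu_max[1] + 0.5
  expect_false(coexistence_conditions(p2)$holds)
})

test_that("the coexistence state exists at the reference and pins S", {
  p <- chaos_reference_vector()$params
  co <- find_coexistence_state(p)
  expect_true(co$state$exists)
  expect_lt(co$state$residual, 1e-8)
  expect_true(all(co$state$coordinates[c("N1", "N2", "N3")] > 0))
  expect_equal(unname(co$state$coordinates["S"]),
               p$D * p$K / (p$mu_max[2] - p$D), tolerance = 1e-10)
  # chaotic attractor coexists with an unstable interior fixed point
  expect_false(co$stability$stable)
})

test_that("coexistence persists under small perturbations of the reference", {
  p0 <- chaos_reference_vector()$params
  set.seed(9)
  for (i in 1:10) {
    p <- p0
    jit <- function(x) x * runif(length(x), 0.97, 1.03)
    p$mu_max <- jit(p$mu_max); p$kA <- jit(p$kA); p$KBmax <- jit(p$KBmax)
    p$K_AB <- jit(p$K_AB); p$omega_max <- jit(p$omega_max)
    if (!coexistence_conditions(p)$holds) next
    co <- find_coexistence_state(p)
    expect_true(co$state$exists)
    expect_lt(co$state$residual, 1e-8)
  }
})

test_that("a state reported stable holds up in simulation", {
  p <- chaos_reference_vector()$params
  p$D <- 1.05 * max(p$mu_max) * p$S0 / (p$S0 + p$K)  # stable washout regime
  P0 <- trivial_state(p)
  expect_true(P0$stability$stable)
  s0 <- P0$state$coordinates + 1e-6
  tr <- simulate_community(focal_structure(), p, s0, t_end = 1000,
                           extinction = NULL)
  drift <- abs(tr$states[nrow(tr$states), ] - P0$state$coordinates)
  expect_true(all(drift < 1e-3))
})
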