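test_that("prior sampling respects bounds, scales and constants", {
  pr <- prior_spec(name = c("a", "c", "k"),
                   min = c(0.01, 0.02, 1e-9), max = c(0.5, 0.02, 1e-6),
                   scale = c("linear", "linear", "log10"))
  priors <- list(m1 = pr)
  set.seed(1)
  draws <- replicate(5000, sample_prior(priors)$theta)
  expect_true(all(draws["a", ] >= 0.01 & draws["a", ] <= 0.5))
  expect_true(all(draws["c", ] == 0.02))          # constant row
  expect_true(all(draws["k", ] >= 1e-9 & draws["k", ] <= 1e-6))
  # log10 sampling spreads mass across decades
  expect_gt(mean(draws["k", ] < 1e-7), 0.5)
  expect_lt(abs(mean(draws["a", ]) - 0.255), 0.01)
  expect_error(prior_spec("x", 2, 1), "min exceeds max")
})

test_that("perturbation stays in support and honours its switches", {
  pr <- prior_spec(c("a", "b"), c(0, 1), c(1, 1))   # b constant
  priors <- list(m1 = pr, m2 = pr)
  part <- list(model_id = "m1", theta = c(a = 0.999, b = 1))  # boundary
  set.seed(2)
  for (i in 1:2000) {
    q <- perturb_particle(part, priors, kernel_frac = 0.1, p_model = 0)
    expect_true(q$theta["a"] >= 0 && q$theta["a"] <= 1)
    expect_identical(q$model_id, "m1")
  }
  # zero-width kernel is the identity
  q0 <- perturb_particle(part, priors, kernel_frac = 0, p_model = 0)
  expect_equal(q0$theta, part$theta)
  # model switching happens with p_model = 1 and never with 0
  set.seed(3)
  q1 <- perturb_particle(part, priors, kernel_frac = 0.1, p_model = 1)
  expect_identical(q1$model_id, "m2")
})

test_that("importance weights follow the stated formula", {
  pr <- prior_spec("a", 0, 1)
  priors <- list(m1 = pr)
  p <- list(model_id = "m1", theta = c(a = 0.5))
  # generation 0
  expect_equal(compute_weight(p, NULL, NULL, priors), 1)
  # single previous particle, symmetric kernel: w = pi / (1 * K) = 2h
  prev <- list(list(model_id = "m1", theta = c(a = 0.52)))
  w <- compute_weight(p, prev, 1, priors, kernel_frac = 0.1)
  expect_equal(w, 1 / (1 / (2 * 0.1)))
  # out-of-support proposals carry zero weight
  p_out <- list(model_id = "m1", theta = c(a = 1.2))
  expect_equal(compute_weight(p_out, prev, 1, priors), 0)
  # unreachable proposals are an error (kernel support violation)
  p_far <- list(model_id = "m1", theta = c(a = 0.9))
  expect_error(compute_weight(p_far, prev, 1, priors, kernel_frac = 0.05),
               "denominator")
})

test_that("threshold updates use the lower quantile with a final floor", {
  up <- update_epsilon(cbind(c(1, 2, 3, 4)), alpha = 0.5, eps_final = 0.1)
  expect_equal(up$eps, 2)
  expect_false(up$final)
  up2 <- update_epsilon(cbind(c(0.01, 0.02)), alpha = 0.5, eps_final = 0.1)
  expect_equal(up2$eps, 0.1)
  expect_true(up2$final)
  up3 <- update_epsilon(cbind(c(1, 2, 3, 4)), alpha = 1, eps_final = 0.1)
  expect_equal(up3$eps, 4)
  # componentwise on matrices
  d <- cbind(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(update_epsilon(d, 0.5, c(0, 0))$eps, c(2, 20))
})

test_that("SMC recovers a toy posterior against a rejection-ABC oracle", {
  pr <- prior_spec("theta", 0, 1)
  priors <- list(m1 = pr)
  dist_fn <- function(model_id, theta) abs(theta[["theta"]] - 0.5)
  set.seed(42)
  res <- abc_smc(priors, dist_fn, n_particles = 500, eps_final = 0.05,
                 alpha = 0.5, kernel_frac = 0.1, p_model = 0)
  f <- res$final
  expect_true(f$final)
  expect_true(all(f$distances < 0.05))
  # epsilon schedule is monotone non-increasing
  eps_seq <- vapply(res$populations, function(p) p$eps[1], numeric(1))
  expect_true(all(diff(eps_seq) <= 0))
  # weights normalised in every generation; generation 0 weights equal
  for (p in res$populations)
    expect_equal(sum(p$weights), 1, tolerance = 1e-12)
  expect_true(all(abs(res$populations[[1]]$weights -
                        1 / length(res$populations[[1]]$weights)) < 1e-12))
  # posterior is approximately U(0.45, 0.55)
  th <- vapply(f$particles, function(p) p$theta[["theta"]], numeric(1))
  expect_lt(abs(sum(th * f$weights) - 0.5), 0.01)
  # rejection-ABC oracle: direct accept-reject from the prior
  set.seed(7)
  oracle <- runif(200000)
  oracle <- oracle[abs(oracle - 0.5) < 0.05][1:2000]
  ks <- suppressWarnings(stats::ks.test(sample(th, 2000, replace = TRUE,
                                               prob = f$weights), oracle))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("model selection concentrates on the only feasible model", {
  pr <- prior_spec("theta", 0, 1)
  priors <- list(A = pr, B = pr)
  # model A can reach the target, model B structurally cannot
  dist_fn <- function(model_id, theta) {
    if (model_id == "A") abs(theta[["theta"]] - 0.5) else 10
  }
  set.seed(5)
  res <- abc_smc(priors, dist_fn, n_particles = 100, eps_final = 0.05,
                 alpha = 0.5, kernel_frac = 0.1, p_model = 0.1)
  post <- model_posterior(list(res$final), c("A", "B"))
  expect_equal(post$posterior[post$model_id == "A"], 1)
  expect_equal(post$posterior[post$model_id == "B"], 0)
})

test_that("community priors instantiate the table per structure", {
  st <- focal_structure()
  pr <- community_priors(st)
  expect_true(all(c("D", "mu_max1", "mu_max2", "mu_max3", "kA1", "KBmax1",
                    "KBmax2", "K_AB1", "K_AB2", "n_z1", "n_z2",
                    "N1_0", "N2_0", "N3_0") %in% pr$name))
  expect_equal(pr$min[pr$name == "S0"], pr$max[pr$name == "S0"])
  expect_equal(pr$scale[pr$name == "kA1"], "log10")
  th <- chaoscope:::.prior_sample(pr)
  pp <- particle_to_params(st, th)
  expect_s3_class(pp$params, "community_params")
  expect_equal(length(pp$state0), 7)
  expect_equal(unname(pp$state0["S"]), 0.02)
})
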