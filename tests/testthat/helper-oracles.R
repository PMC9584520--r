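# Independent oracles used across the suite. These deliberately avoid the
# package's solver path: fixed-step RK4 on the state plus the exact tangent
# (variational) equation with per-step renormalisation (Benettin's method),
# using hand-derived Jacobians.

rk4_step <- function(f, y, h) {
  k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
  k4 <- f(y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# lambda1 in bits per unit time from state rhs f and Jacobian J
benettin_lambda1 <- function(f, J, y0, t_total = 1000, h = 0.005,
                             transient = 100, renorm_every = 1) {
  y <- y0
  nt <- round(transient / h)
  for (i in seq_len(nt)) y <- rk4_step(f, y, h)
  v <- rep(1, length(y)); v <- v / sqrt(sum(v^2))
  S <- 0; tacc <- 0
  n_steps <- round((t_total - transient) / h)
  steps_per_renorm <- max(1, round(renorm_every / h))
  for (i in seq_len(n_steps)) {
    # classical RK4 on the augmented (state, tangent) system
    k1 <- f(y);               l1 <- J(y) %*% v
    y2 <- y + h / 2 * k1
    k2 <- f(y2);              l2 <- J(y2) %*% (v + h / 2 * l1)
    y3 <- y + h / 2 * k2
    k3 <- f(y3);              l3 <- J(y3) %*% (v + h / 2 * l2)
    y4 <- y + h * k3
    k4 <- f(y4);              l4 <- J(y4) %*% (v + h * l3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    v <- as.numeric(v + h / 6 * (l1 + 2 * l2 + 2 * l3 + l4))
    if (i %% steps_per_renorm == 0) {
      nv <- sqrt(sum(v^2))
      S <- S + log2(nv)
      v <- v / nv
      tacc <- tacc + steps_per_renorm * h
    }
  }
  S / tacc
}

lorenz_f <- function(sigma = 10, rho = 28, beta = 8 / 3) {
  function(y) c(sigma * (y[2] - y[1]),
                y[1] * (rho - y[3]) - y[2],
                y[1] * y[2] - beta * y[3])
}
lorenz_J <- function(sigma = 10, rho = 28, beta = 8 / 3) {
  function(y) matrix(c(-sigma, sigma, 0,
                       rho - y[3], -1, -y[1],
                       y[2], y[1], -beta), 3, 3, byrow = TRUE)
}

glv_f <- function(r, alpha) {
  function(y) r * y * (1 - as.numeric(alpha %*% y))
}
glv_J <- function(r, alpha) {
  function(y) {
    n <- length(r)
    J <- -r * y * alpha          # -r_i y_i alpha_ij  (rows scaled)
    diag(J) <- diag(J) + r * (1 - as.numeric(alpha %*% y))
    J
  }
}

# reference vector shared by many tests
ref_vec <- chaos_reference_vector()

# small deterministic m850-like prior sample for property tests
sample_focal_theta <- function(n, seed = 1) {
  st <- focal_structure()
  pr <- community_priors(st)
  set.seed(seed)
  replicate(n, chaoscope:::.prior_sample(pr), simplify = FALSE)
}
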