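## Steady-state analysis of the focal chaotic topology (3 strains, states
## (N1, N2, N3, S, B1, B2, A1)): closed forms for the washout state and the
## single-survivor states of the unkilled strains, scalar root-finding for
## the killed strain's survival state, and a reduced solve for the
## three-strain coexistence state, with numerical Jacobian stability checks.

.focal_rhs <- function(params, state) {
  community_rhs(focal_structure(), params, state)
}

#' Central finite-difference Jacobian
#'
#' @param f function of a numeric vector returning a numeric vector.
#' @param x evaluation point.
#' @param rel relative step size.
#' @return Jacobian matrix.
#' @export
numeric_jacobian <- function(f, x, rel = 1e-6) {
  n <- length(x)
  J <- matrix(0, length(f(x)), n)
  for (i in seq_len(n)) {
    h <- rel * max(abs(x[i]), 1e-4)
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

.stability_report <- function(params, state, analytic_eigs = NULL) {
  J <- numeric_jacobian(function(s) .focal_rhs(params, s), state)
  ev <- eigen(J, only.values = TRUE)$values
  list(eigenvalues = ev, stable = max(Re(ev)) < 1e-10,
       analytic_eigenvalues = analytic_eigs)
}

.mk_state <- function(params, coords, label, exists = TRUE) {
  res <- if (exists) sqrt(sum(.focal_rhs(params, coords)^2)) else NA_real_
  structure(list(label = label, coordinates = coords, exists = exists,
                 residual = res),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state ", x$label, "> exists: ", x$exists, sep = "")
  if (x$exists) cat(", residual ", format(x$residual, digits = 3), sep = "")
  cat("\n")
  if (x$exists) print(signif(x$coordinates, 4))
  invisible(x)
}

#' Washout (trivial) steady state
#'
#' `P0 = (0, 0, 0, S0, 0, 0, 0)` always exists; it is linearly stable iff
#' the dilution rate exceeds every strain's growth rate at the feed
#' substrate, `D > S0/(S0+K) * max(mu_max)`.
#'
#' @param params a `community_params` for the focal topology.
#' @return list with `state` (a `steady_state`), `stability` (numerical
#'   Jacobian report with the closed-form eigenvalues attached) and
#'   `stable_condition` (the analytic inequality, evaluated).
#' @export
trivial_state <- function(params) {
  p <- params
  coords <- c(N1 = 0, N2 = 0, N3 = 0, S = p$S0, B1 = 0, B2 = 0, A1 = 0)
  gr <- p$S0 / (p$S0 + p$K)
  analytic <- c(-p$D, -(p$D - p$mu_max[1] * gr), -(p$D - p$mu_max[2] * gr),
                -(p$D - p$mu_max[3] * gr))
  st <- .mk_state(p, coords, "P0")
  rep <- .stability_report(p, coords, analytic)
  cond <- p$D > gr * max(p$mu_max)
  list(state = st, stability = rep,
       stable_condition = list(holds = cond,
                               lhs = p$D, rhs = gr * max(p$mu_max)))
}

.single_unkilled <- function(params, x, label) {
  ## survivor x in {2, 3} has no bacteriocin pressure at its survival state
  p <- params
  mu <- p$mu_max[x]
  exists <- p$D < mu * p$S0 / (p$S0 + p$K)
  coords <- c(N1 = 0, N2 = 0, N3 = 0, S = p$S0, B1 = 0, B2 = 0, A1 = 0)
  analytic <- NULL
  if (exists) {
    S <- p$D * p$K / (mu - p$D)
    Nx <- p$gamma / p$C_N * (p$S0 * mu - p$D * (p$S0 + p$K)) / (mu - p$D)
    coords[x] <- Nx
    coords["S"] <- S
    oth <- setdiff(1:3, x)
    analytic <- c(-p$D,
                  -p$D * (1 - p$mu_max[oth[1]] / mu),
                  -p$D * (1 - p$mu_max[oth[2]] / mu),
                  -(1 / p$K) / mu * (mu - p$D) *
                    (mu * p$S0 - p$D * (p$S0 + p$K)))
  }
  st <- .mk_state(p, coords, label, exists)
  rep <- if (exists) .stability_report(p, coords, analytic) else NULL
  list(state = st, stability = rep)
}

## scalar balance for the killed survivor N1: growth net of dilution equals
## bacteriocin killing, both expressed as functions of the substrate S
.p1_curves <- function(params, S) {
  p <- params
  muS <- p$mu_max[1] * S / (p$K + S)
  L <- muS - p$D
  Nc <- p$gamma * p$D * (p$S0 - S) / muS            # cells, from dS = 0
  A1m <- p$kA[1] * Nc / p$D                         # molar QS
  kb <- bacteriocin_expression(p$KBmax[1], A1m, p$K_AB[1], p$n_z[1], "induced")
  B1m <- kb * Nc / p$D                              # molar bacteriocin
  R <- kill_rate(p$omega_max, B1m, p$K_omega, p$n_omega)
  list(L = L, R = R, Nc = Nc, A1m = A1m, B1m = B1m)
}

#' Single-strain survival steady states
#'
#' The unkilled strains' states (`P2`, `P3`) are closed-form; the killed,
#' QS-producing strain's state (`P1`) solves a scalar balance in the
#' substrate on `(0, S0)`: net growth `mu1(S) - D` (increasing in S) equals
#' the self-killing rate (decreasing in S), so a unique root exists exactly
#' when `D < mu1_max S0/(K + S0)`.
#'
#' @param params a `community_params` for the focal topology.
#' @return named list of `P1`, `P2`, `P3`, each with `state` and
#'   `stability` (for `P1` the Jacobian is numerical).
#' @export
single_strain_states <- function(params) {
  p <- params
  P2 <- .single_unkilled(p, 2, "P2")
  P3 <- .single_unkilled(p, 3, "P3")
  exists1 <- p$D < p$mu_max[1] * p$S0 / (p$K + p$S0)
  coords <- c(N1 = 0, N2 = 0, N3 = 0, S = p$S0, B1 = 0, B2 = 0, A1 = 0)
  if (exists1) {
    eps <- p$S0 * 1e-10
    g <- function(S) { cv <- .p1_curves(p, S); cv$L - cv$R }
    root <- stats::uniroot(g, c(eps, p$S0 - eps), tol = 1e-14)
    S <- root$root
    cv <- .p1_curves(p, S)
    coords <- c(N1 = cv$Nc / p$C_N, N2 = 0, N3 = 0, S = S,
                B1 = cv$B1m / p$C_B, B2 = 0, A1 = cv$A1m / p$C_A)
    if (sqrt(sum(.focal_rhs(p, coords)^2)) > 1e-6)
      stop("P1 root-finder converged to a non-steady point")
  }
  P1 <- list(state = .mk_state(p, coords, "P1", exists1),
             stability = if (exists1) .stability_report(p, coords) else NULL)
  list(P1 = P1, P2 = P2, P3 = P3)
}

#' Necessary conditions for three-strain coexistence
#'
#' At any coexistence state the unkilled strain N2 pins the substrate at
#' `S = DK/(mu2 - D)`, which requires `mu2` to lie between a lower bound
#' (washout and killing limits) and the growth rates of the killed strains:
#' `max(D(K+S0)/S0, mu1 D/(D+omega_max), mu3 D/(D+omega_max)) < mu2 <
#' min(mu1, mu3)`.
#'
#' @param params a `community_params` for the focal topology.
#' @return list with the evaluated bounds, margins and overall `holds`.
#' @export
coexistence_conditions <- function(params) {
  p <- params
  lower <- max(p$D * (p$K + p$S0) / p$S0,
               p$mu_max[1] * p$D / (p$D + p$omega_max),
               p$mu_max[3] * p$D / (p$D + p$omega_max))
  upper <- min(p$mu_max[1], p$mu_max[3])
  d_bound <- min(p$mu_max[2] * p$S0 / (p$K + p$S0),
                 if (p$mu_max[1] > p$mu_max[2])
                   p$omega_max * p$mu_max[2] / (p$mu_max[1] - p$mu_max[2])
                 else Inf,
                 if (p$mu_max[3] > p$mu_max[2])
                   p$omega_max * p$mu_max[2] / (p$mu_max[3] - p$mu_max[2])
                 else Inf)
  holds <- lower < p$mu_max[2] && p$mu_max[2] < upper && p$D < d_bound
  list(lower = lower, mu2 = p$mu_max[2], upper = upper,
       margin_lower = p$mu_max[2] - lower, margin_upper = upper - p$mu_max[2],
       D = p$D, D_bound = d_bound, holds = holds)
}

#' Three-strain coexistence steady state
#'
#' Exploits the structure of the focal topology: the substrate is pinned by
#' the unkilled strain (`S = DK/(mu2 - D)`), the bacteriocin levels follow
#' from the killed strains' growth balances, and the remaining unknown (the
#' QS level) solves a scalar substrate-balance equation; the full-state
#' residual and a numerical Jacobian are evaluated at the solution.
#'
#' @param params a `community_params` for the focal topology.
#' @param check_conditions require [coexistence_conditions()] to hold
#'   (returns non-existence immediately otherwise).
#' @return list with `state` (a `steady_state`) and `stability` (or `NULL`
#'   when the state does not exist).
#' @export
find_coexistence_state <- function(params, check_conditions = TRUE) {
  p <- params
  cond <- coexistence_conditions(p)
  empty <- c(N1 = 0, N2 = 0, N3 = 0, S = p$S0, B1 = 0, B2 = 0, A1 = 0)
  if (check_conditions && !cond$holds)
    return(list(state = .mk_state(p, empty, "P123", exists = FALSE),
                stability = NULL, conditions = cond))
  S <- p$D * p$K / (p$mu_max[2] - p$D)
  mu <- monod_growth(p$mu_max, S, p$K)
  q1 <- mu[1] - p$D; q3 <- mu[3] - p$D   # required killing rates
  if (q1 <= 0 || q3 <= 0 || q1 >= p$omega_max || q3 >= p$omega_max)
    return(list(state = .mk_state(p, empty, "P123", exists = FALSE),
                stability = NULL, conditions = cond))
  inv_kill <- function(q) p$K_omega * (q / (p$omega_max - q))^(1 / p$n_omega)
  B1m <- inv_kill(q1); B2m <- inv_kill(q3)
  ## scalar balance in the QS level A1m: strain cell counts implied by the
  ## bacteriocin/QS balances must also satisfy the substrate balance
  resid <- function(A1m) {
    N1c <- p$D * A1m / p$kA[1]
    kb1 <- bacteriocin_expression(p$KBmax[1], A1m, p$K_AB[1], p$n_z[1], "induced")
    kb2 <- bacteriocin_expression(p$KBmax[2], A1m, p$K_AB[2], p$n_z[2], "induced")
    if (kb1 <= 0 || kb2 <= 0) return(NA_real_)
    N2c <- p$D * B1m / kb1 - N1c
    N3c <- p$D * B2m / kb2
    p$D * (p$S0 - S) - (mu[1] * N1c + mu[2] * N2c + mu[3] * N3c) / p$gamma
  }
  ## bracket in log10(A1m) around the biologically relevant range
  grid <- 10^seq(-14, -4, by = 0.05)
  vals <- vapply(grid, resid, numeric(1))
  ok <- which(is.finite(vals))
  sgn <- sign(vals[ok])
  flip <- which(sgn[-1] != sgn[-length(sgn)])
  if (!length(flip))
    return(list(state = .mk_state(p, empty, "P123", exists = FALSE),
                stability = NULL, conditions = cond, note = "no root bracket"))
  i <- ok[flip[1]]
  root <- stats::uniroot(resid, c(grid[i], grid[i + 1]), tol = 1e-16)
  A1m <- root$root
  N1c <- p$D * A1m / p$kA[1]
  kb1 <- bacteriocin_expression(p$KBmax[1], A1m, p$K_AB[1], p$n_z[1], "induced")
  kb2 <- bacteriocin_expression(p$KBmax[2], A1m, p$K_AB[2], p$n_z[2], "induced")
  N2c <- p$D * B1m / kb1 - N1c
  N3c <- p$D * B2m / kb2
  if (N1c <= 0 || N2c <= 0 || N3c <= 0)
    return(list(state = .mk_state(p, empty, "P123", exists = FALSE),
                stability = NULL, conditions = cond,
                note = "root implies a non-positive strain"))
  coords <- c(N1 = N1c / p$C_N, N2 = N2c / p$C_N, N3 = N3c / p$C_N, S = S,
              B1 = B1m / p$C_B, B2 = B2m / p$C_B, A1 = A1m / p$C_A)
  st <- .mk_state(p, coords, "P123")
  list(state = st, stability = .stability_report(p, coords),
       conditions = cond)
}

#' All steady states of the focal topology
#'
#' @param params a `community_params` for the focal topology.
#' @return list with `P0`, `P1`, `P2`, `P3`, `P123`.
#' @export
steady_states <- function(params) {
  sss <- single_strain_states(params)
  list(P0 = trivial_state(params), P1 = sss$P1, P2 = sss$P2, P3 = sss$P3,
       P123 = find_coexistence_state(params))
}
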