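## ODE right-hand sides and integration for the chemostat community model
## and the competitive generalised Lotka-Volterra (gLV) model.
##
## Community state layout: (N_1..N_n, S, B_1..B_nB, A_1..A_nA) where N is
## strain density (OD), S the limiting substrate (M), and B/A are scaled
## bacteriocin / QS-signal states whose physical molar concentrations are
## B' = B * C_B and A' = A * C_A.

#' Community model parameters
#'
#' Assemble and validate the parameter set of the rescaled chemostat
#' community model. Vector-valued entries are per strain (`mu_max`), per QS
#' species (`kA`) and per bacteriocin species (`KBmax`, `K_AB`, `n_z`).
#'
#' @param D dilution rate (1/h).
#' @param S0 feed substrate concentration (M).
#' @param K Monod half-saturation constant (M).
#' @param gamma substrate yield (cells per M).
#' @param C_N OD-to-cell scaling factor.
#' @param C_B,C_A scaling factors linking the bacteriocin/QS states to molar
#'   concentrations (`B' = B * C_B`, `A' = A * C_A`).
#' @param K_omega half-maximal killing concentration (M).
#' @param n_omega Hill coefficient of killing.
#' @param omega_max maximal killing rate (1/h).
#' @param mu_max per-strain maximal growth rates (1/h).
#' @param kA per-QS production rate (M/h per cell).
#' @param KBmax per-bacteriocin maximal expression rate (M/h per cell).
#' @param K_AB per-bacteriocin half-maximal regulation concentration (M).
#' @param n_z per-bacteriocin regulation Hill coefficient.
#' @return a named list of class `community_params`.
#' @export
community_params <- function(D, S0 = 0.02, K = 3.9e-5, gamma = 1e11,
                             C_N = 1e9, C_B = 1e-9, C_A = 1e-9,
                             K_omega, n_omega, omega_max,
                             mu_max, kA = numeric(), KBmax = numeric(),
                             K_AB = numeric(), n_z = numeric()) {
  p <- list(D = D, S0 = S0, K = K, gamma = gamma, C_N = C_N, C_B = C_B,
            C_A = C_A, K_omega = K_omega, n_omega = n_omega,
            omega_max = omega_max, mu_max = as.numeric(mu_max),
            kA = as.numeric(kA), KBmax = as.numeric(KBmax),
            K_AB = as.numeric(K_AB), n_z = as.numeric(n_z))
  scal <- unlist(p[c("D", "S0", "K", "gamma", "C_N", "C_B", "C_A",
                     "K_omega", "n_omega", "omega_max")])
  if (any(!is.finite(scal)) || any(scal <= 0))
    stop("all scalar community parameters must be finite and positive")
  if (any(p$mu_max <= 0)) stop("mu_max must be positive")
  class(p) <- "community_params"
  p
}

#' Reference chaotic input vector for the focal community topology
#'
#' The fixed parameterisation and initial state of the four-part focal
#' topology (one QS produced by strain 1 positively inducing two
#' bacteriocins; B1 made by strains 1 and 2, killing strain 1; B2 made and
#' felt by strain 3) that places the community on a chaotic attractor.
#' Used as the base vector for scans, bifurcation diagrams and ramps.
#'
#' @return list with elements `structure`, `params` and `state0`.
#' @export
chaos_reference_vector <- function() {
  params <- community_params(
    D = 0.167, S0 = 0.02, K = 3.9e-5, gamma = 1e11,
    C_N = 1e9, C_B = 1e-9, C_A = 1e-9,
    K_omega = 1.6e-7, n_omega = 1.87, omega_max = 0.79,
    mu_max = c(2.61, 1.17, 1.48),
    kA = 3.5e-17,
    KBmax = c(3.58e-17, 8.89e-16),
    K_AB = c(3.37e-9, 4.26e-8),
    n_z = c(1.2, 1.43))
  state0 <- c(N1 = 0.24, N2 = 0.25, N3 = 0.27, S = 0.02,
              B1 = 1e-71, B2 = 1e-71, A1 = 1e-10)
  list(structure = focal_structure(), params = params, state0 = state0)
}

#' Equation structure of the focal chaotic topology
#'
#' @return a `community_structure` with 3 strains, 2 bacteriocins, 1 QS.
#' @export
focal_structure <- function() {
  structure(list(
    n_strains = 3L, n_bact = 2L, n_qs = 1L,
    sens = c(1L, 0L, 2L),
    EB = matrix(c(1, 0, 1, 0, 0, 1), nrow = 3, byrow = TRUE),
    EA = matrix(c(1, 0, 0), nrow = 3),
    reg = c(1L, 1L),
    mode = c(0L, 0L)),
    class = "community_structure")
}

#' Monod growth rate
#'
#' @param mu_max maximal growth rate (1/h).
#' @param S substrate concentration (M), non-negative.
#' @param K half-saturation constant (M), positive.
#' @return growth rate `mu_max * S / (K + S)` (1/h).
#' @export
monod_growth <- function(mu_max, S, K) {
  if (any(S < 0)) stop("substrate concentration must be non-negative")
  if (any(K <= 0)) stop("K must be positive")
  mu_max * S / (K + S)
}

#' Hill-type bacteriocin killing rate
#'
#' @param omega_max maximal killing rate (1/h).
#' @param B_molar molar bacteriocin concentration (`B' = B * C_B`).
#' @param K_omega half-maximal killing concentration (M).
#' @param n_omega Hill coefficient.
#' @param sensitive logical; insensitive strains are not killed.
#' @return killing rate (1/h); 0 if `sensitive` is `FALSE`.
#' @export
kill_rate <- function(omega_max, B_molar, K_omega, n_omega, sensitive = TRUE) {
  if (!sensitive) return(0 * B_molar)
  bn <- ifelse(B_molar > 0, B_molar^n_omega, 0)
  omega_max * bn / (K_omega^n_omega + bn)
}

#' QS-regulated bacteriocin expression rate
#'
#' @param KB_max maximal expression rate (M/h per cell).
#' @param A_molar molar QS concentration (`A' = A * C_A`).
#' @param K_AB half-maximal regulation concentration (M).
#' @param n_z Hill coefficient.
#' @param mode `"induced"` or `"repressed"`.
#' @return per-cell expression rate (M/h).
#' @export
bacteriocin_expression <- function(KB_max, A_molar, K_AB, n_z,
                                   mode = c("induced", "repressed")) {
  mode <- match.arg(mode)
  an <- ifelse(A_molar > 0, A_molar^n_z, 0)
  h <- an / (K_AB^n_z + an)
  KB_max * if (mode == "induced") h else 1 - h
}

#' Community model derivative (reference implementation)
#'
#' Pure-R evaluation of the community right-hand side; the integrator uses
#' an equivalent compiled version, and the two are cross-checked in the
#' test suite.
#'
#' @param structure a `community_structure`.
#' @param params a `community_params` matching the structure.
#' @param state numeric state `(N, S, B, A)`.
#' @return the state derivative.
#' @export
community_rhs <- function(structure, params, state) {
  st <- structure; p <- params
  nN <- st$n_strains; nB <- st$n_bact; nA <- st$n_qs
  if (length(p$mu_max) < nN || length(p$KBmax) < nB || length(p$kA) < nA ||
      length(p$K_AB) < nB || length(p$n_z) < nB)
    stop("parameter vector incomplete for this model structure")
  N <- state[seq_len(nN)]
  S <- max(state[nN + 1], 0)
  B <- if (nB) state[nN + 1 + seq_len(nB)] else numeric()
  A <- if (nA) state[nN + 1 + nB + seq_len(nA)] else numeric()

  mu <- monod_growth(p$mu_max[seq_len(nN)], S, p$K)
  kb <- if (nB) vapply(seq_len(nB), function(z) {
    bacteriocin_expression(p$KBmax[z], A[st$reg[z]] * p$C_A, p$K_AB[z],
                           p$n_z[z],
                           if (st$mode[z] == 0) "induced" else "repressed")
  }, numeric(1)) else numeric()

  kill <- vapply(seq_len(nN), function(x) {
    z <- st$sens[x]
    if (z == 0) 0 else
      kill_rate(p$omega_max, B[z] * p$C_B, p$K_omega, p$n_omega)
  }, numeric(1))

  dN <- N * (mu - kill - p$D)
  dS <- p$D * (p$S0 - S) - sum(mu * pmax(N, 0) * p$C_N) / p$gamma
  dB <- if (nB) vapply(seq_len(nB), function(z) {
    sum(st$EB[, z] * kb[z] * pmax(N, 0) * p$C_N) / p$C_B - p$D * B[z]
  }, numeric(1)) else numeric()
  dA <- if (nA) vapply(seq_len(nA), function(a) {
    sum(st$EA[, a] * p$kA[a] * pmax(N, 0) * p$C_N) / p$C_A - p$D * A[a]
  }, numeric(1)) else numeric()
  c(dN, dS, dB, dA)
}

#' gLV parameters
#'
#' @param r per-species growth rates.
#' @param alpha square interaction matrix (the diagonal plays the role of a
#'   shared dilution/self-limitation term).
#' @return object of class `glv_params`.
#' @export
glv_params <- function(r, alpha) {
  alpha <- as.matrix(alpha)
  if (nrow(alpha) != ncol(alpha) || nrow(alpha) != length(r))
    stop("alpha must be square with dimension length(r)")
  if (any(!is.finite(alpha)) || any(!is.finite(r)) || any(r <= 0))
    stop("r must be positive and alpha finite")
  structure(list(r = as.numeric(r), alpha = alpha, n = length(r)),
            class = "glv_params")
}

#' Four-species competitive gLV chaotic attractor
#'
#' The published four-species competitive Lotka-Volterra parameterisation
#' of Vano et al. (2006) whose attractor is chaotic, together with an
#' initial state on the attractor.
#'
#' @return list with `params` (a `glv_params`) and `state0`.
#' @export
glv_chaotic_attractor <- function() {
  r <- c(1, 0.72, 1.53, 1.27)
  alpha <- matrix(c(
    1,    1.09, 1.52, 0,
    0,    1,    0.44, 1.36,
    2.33, 0,    1,    0.47,
    1.21, 0.51, 0.35, 1), nrow = 4, byrow = TRUE)
  list(params = glv_params(r, alpha),
       state0 = c(N1 = 0.3013, N2 = 0.4586, N3 = 0.1307, N4 = 0.3557))
}

#' gLV derivative
#'
#' @param params a `glv_params`.
#' @param state species abundances.
#' @return the state derivative `r_i N_i (1 - sum_j alpha_ij N_j)`.
#' @export
glv_rhs <- function(params, state) {
  params$r * state * (1 - drop(params$alpha %*% state))
}

## ---- parameter-vector packing for the compiled model ----

.P <- list(FAMILY = 1L, DUAL = 2L, M = 3L, DELTA0 = 4L, EXT = 5L,
           NSTRAIN = 6L, RAMP_ON = 7L, RAMP_IDX = 8L, RAMP_NK = 9L,
           RAMP_T = 10L, RAMP_V = 18L, FSTART = 26L)  # 1-based

.community_offsets <- list(
  NN = 0L, NB = 1L, NA_ = 2L, D = 3L, S0 = 4L, K = 5L, GAM = 6L, CN = 7L,
  CB = 8L, CA = 9L, KW = 10L, NW = 11L, WMAX = 12L, MU = 13L, SENS = 16L,
  KA = 19L, EA = 21L, KBMAX = 27L, NZ = 30L, KAB = 33L, REG = 36L,
  MODE = 39L, EB = 42L)

.pack_community <- function(structure, params) {
  st <- structure; p <- params; o <- .community_offsets
  v <- numeric(51)
  set <- function(off, val) v[off + seq_along(val)] <<- val
  set(o$NN, st$n_strains); set(o$NB, st$n_bact); set(o$NA_, st$n_qs)
  set(o$D, p$D); set(o$S0, p$S0); set(o$K, p$K); set(o$GAM, p$gamma)
  set(o$CN, p$C_N); set(o$CB, p$C_B); set(o$CA, p$C_A)
  set(o$KW, p$K_omega); set(o$NW, p$n_omega); set(o$WMAX, p$omega_max)
  set(o$MU, c(p$mu_max, numeric(3 - st$n_strains)))
  set(o$SENS, c(st$sens, numeric(3 - st$n_strains)))
  set(o$KA, c(p$kA, numeric(2 - st$n_qs)))
  ea <- matrix(0, 3, 2); ea[seq_len(st$n_strains), seq_len(st$n_qs)] <- st$EA
  set(o$EA, as.numeric(t(ea)))
  set(o$KBMAX, c(p$KBmax, numeric(3 - st$n_bact)))
  set(o$NZ, c(p$n_z, numeric(3 - st$n_bact)))
  set(o$KAB, c(p$K_AB, numeric(3 - st$n_bact)))
  set(o$REG, c(st$reg, numeric(3 - st$n_bact)))
  set(o$MODE, c(st$mode, numeric(3 - st$n_bact)))
  eb <- matrix(0, 3, 3); eb[seq_len(st$n_strains), seq_len(st$n_bact)] <- st$EB
  set(o$EB, as.numeric(t(eb)))
  v
}

.pack_glv <- function(params) {
  v <- numeric(43)
  n <- params$n
  v[1] <- n
  v[1 + seq_len(n)] <- params$r
  al <- matrix(0, 6, 6); al[seq_len(n), seq_len(n)] <- params$alpha
  v[7 + seq_len(36)] <- as.numeric(t(al))
  v
}

.parms_vector <- function(family, block, m, dual = FALSE, delta0 = 1e-10,
                          extinction = 0, n_monitor = 0, ramp = NULL) {
  v <- numeric(128)
  v[.P$FAMILY] <- family
  v[.P$DUAL] <- as.numeric(dual)
  v[.P$M] <- m
  v[.P$DELTA0] <- delta0
  v[.P$EXT] <- extinction
  v[.P$NSTRAIN] <- n_monitor
  v[.P$FSTART - 1L + seq_along(block)] <- block
  if (!is.null(ramp)) {
    v[.P$RAMP_ON] <- 1
    v[.P$RAMP_IDX] <- ramp$idx0   # 0-based index into the C parms vector
    nk <- length(ramp$times)
    if (nk > 8) stop("at most 8 ramp knots are supported")
    v[.P$RAMP_NK] <- nk
    v[.P$RAMP_T + seq_len(nk) - 1L] <- ramp$times
    v[.P$RAMP_V + seq_len(nk) - 1L] <- ramp$values
  }
  v
}

## map a community parameter name (possibly indexed, e.g. "kA1", "mu_max2")
## to its 0-based slot in the C parms vector
.community_param_idx0 <- function(name) {
  o <- .community_offsets; f0 <- .P$FSTART - 1L  # 0-based family start
  scalars <- c(D = o$D, S0 = o$S0, K = o$K, gamma = o$GAM, C_N = o$CN,
               C_B = o$CB, C_A = o$CA, K_omega = o$KW, n_omega = o$NW,
               omega_max = o$WMAX)
  if (name %in% names(scalars)) return(f0 + scalars[[name]])
  m <- regmatches(name, regexec("^(mu_max|kA|KBmax|K_AB|n_z)([0-9]+)$", name))[[1]]
  if (length(m) == 3) {
    base <- c(mu_max = o$MU, kA = o$KA, KBmax = o$KBMAX,
              K_AB = o$KAB, n_z = o$NZ)[[m[2]]]
    return(f0 + base + as.integer(m[3]) - 1L)
  }
  stop("unknown community parameter: ", name)
}

.state_names <- function(structure) {
  st <- structure
  c(paste0("N", seq_len(st$n_strains)), "S",
    if (st$n_bact) paste0("B", seq_len(st$n_bact)),
    if (st$n_qs) paste0("A", seq_len(st$n_qs)))
}

.integrate <- function(parms, state0, times, atol, rtol, use_root = FALSE,
                       events_times = NULL) {
  args <- list(y = state0, times = times, func = "chaoscope_derivs",
               parms = parms, dllname = "chaoscope",
               initfunc = "chaoscope_init", atol = atol, rtol = rtol,
               maxsteps = 50000)
  if (use_root) {
    args$rootfunc <- "chaoscope_root"
    args$nroot <- 1L
  }
  if (!is.null(events_times))
    args$events <- list(func = "chaoscope_event", time = events_times,
                        root = FALSE)
  out <- suppressWarnings(do.call(deSolve::lsoda, args))
  out
}

#' Simulate a community model
#'
#' Stiff-capable integration of the chemostat community ODEs on a uniform
#' output grid, stopping early if any strain density falls below the
#' extinction threshold.
#'
#' @param structure a `community_structure`.
#' @param params a `community_params`.
#' @param state0 named initial state `(N, S, B, A)`, non-negative.
#' @param t_end simulation horizon (h).
#' @param dt_out output grid spacing (h).
#' @param atol,rtol absolute/relative integration tolerances.
#' @param extinction strain-density threshold terminating the run
#'   (set to `NULL` to disable).
#' @param ramp optional ramp schedule from [ramp_schedule()].
#' @return a `chaoscope_trajectory`: list with `times`, `states` (matrix),
#'   `termination` (`status` is `"completed"`, `"extinction"` or `"error"`).
#' @export
simulate_community <- function(structure, params, state0, t_end = 5000,
                               dt_out = 1, atol = 1e-9, rtol = 1e-4,
                               extinction = 1e-5, ramp = NULL) {
  if (any(state0 < 0)) stop("initial state must be non-negative")
  m <- structure$n_strains + 1L + structure$n_bact + structure$n_qs
  if (length(state0) != m) stop("state0 has wrong length for this structure")
  rampc <- NULL
  if (!is.null(ramp)) {
    rampc <- list(idx0 = .community_param_idx0(ramp$param),
                  times = ramp$times, values = ramp$values)
  }
  parms <- .parms_vector(0, .pack_community(structure, params), m,
                         extinction = if (is.null(extinction)) -1 else extinction,
                         n_monitor = if (is.null(extinction)) 0 else structure$n_strains,
                         ramp = rampc)
  times <- seq(0, t_end, by = dt_out)
  out <- try(.integrate(parms, unname(state0), times, atol, rtol,
                        use_root = !is.null(extinction)), silent = TRUE)
  .as_trajectory(out, times, .state_names(structure), structure$n_strains,
                 extinction)
}

#' Simulate a gLV community
#'
#' @param params a `glv_params`.
#' @param state0 initial abundances.
#' @param t_end,dt_out horizon and output spacing (time units).
#' @param atol,rtol integration tolerances.
#' @param extinction optional abundance threshold terminating the run
#'   (`NULL`, the default: gLV runs are not stopped early).
#' @return a `chaoscope_trajectory`.
#' @export
simulate_glv <- function(params, state0, t_end = 5000, dt_out = 1,
                         atol = 1e-9, rtol = 1e-4, extinction = NULL) {
  parms <- .parms_vector(1, .pack_glv(params), params$n,
                         extinction = if (is.null(extinction)) -1 else extinction,
                         n_monitor = if (is.null(extinction)) 0 else params$n)
  times <- seq(0, t_end, by = dt_out)
  out <- try(.integrate(parms, unname(state0), times, atol, rtol,
                        use_root = !is.null(extinction)), silent = TRUE)
  nm <- if (!is.null(names(state0))) names(state0) else
    paste0("N", seq_len(params$n))
  .as_trajectory(out, times, nm, if (is.null(extinction)) 0 else params$n,
                 extinction)
}

.as_trajectory <- function(out, times, state_names, n_strains, extinction) {
  if (inherits(out, "try-error")) {
    return(structure(list(times = numeric(), states = NULL,
                          termination = list(status = "error")),
                     class = "chaoscope_trajectory"))
  }
  states <- out[, -1, drop = FALSE]
  colnames(states) <- state_names
  tt <- out[, 1]
  term <- list(status = "completed")
  if (!is.null(extinction) && n_strains > 0 &&
      (nrow(states) < length(times) ||
       min(states[nrow(states), seq_len(n_strains)]) <= extinction * 1.0001)) {
    strains <- states[nrow(states), seq_len(n_strains)]
    term <- list(status = "extinction", time = tt[length(tt)],
                 strain = which.min(strains))
  }
  structure(list(times = tt, states = states, termination = term),
            class = "chaoscope_trajectory")
}

#' @export
print.chaoscope_trajectory <- function(x, ...) {
  cat("<chaoscope_trajectory> ", nrow(x$states), " samples, ",
      ncol(x$states), " state variables, termination: ",
      x$termination$status, "\n", sep = "")
  invisible(x)
}

#' Piecewise-linear parameter ramp schedule
#'
#' @param param community parameter name (e.g. `"D"`, `"kA1"`).
#' @param times increasing knot times (h).
#' @param values parameter value at each knot; linearly interpolated and
#'   held constant outside the knot range.
#' @return a `ramp_schedule`.
#' @export
ramp_schedule <- function(param, times, values) {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (is.unsorted(times, strictly = TRUE)) stop("knot times must increase")
  structure(list(param = param, times = times, values = values),
            class = "ramp_schedule")
}
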