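## Maximal Lyapunov exponent by the dual-orbit renormalisation method:
## after a transient, a companion orbit displaced by delta0 is co-integrated
## with the reference orbit; at every renormalisation step the separation is
## logged (base 2) and the companion is pulled back to distance delta0 along
## the current separation direction. lambda1 = S / n in bits per step.

#' Dual-orbit estimator configuration
#'
#' @param delta0 initial (and renormalised) orbit separation.
#' @param transient_fraction fraction of the horizon discarded as transient.
#' @param dt renormalisation step (h); with `dt = 1` the exponent in bits
#'   per step equals bits per hour.
#' @param perturb_component index of the state component displaced by
#'   `delta0` (a strain density by default).
#' @return a `lyapunov_config` list.
#' @export
lyapunov_config <- function(delta0 = 1e-10, transient_fraction = 0.1,
                            dt = 1, perturb_component = 1L) {
  if (delta0 <= 0) stop("delta0 must be positive")
  if (transient_fraction < 0 || transient_fraction >= 1)
    stop("transient_fraction must be in [0, 1)")
  if (dt <= 0) stop("dt must be positive")
  structure(list(delta0 = delta0, transient_fraction = transient_fraction,
                 dt = dt, perturb_component = as.integer(perturb_component)),
            class = "lyapunov_config")
}

.lyap_run <- function(family, block, m, state0, t_end, config,
                      extinction, n_monitor, atol, rtol) {
  tt <- config$transient_fraction * t_end
  use_root <- !is.null(extinction)
  parms <- .parms_vector(family, block, m,
                         extinction = if (use_root) extinction else -1,
                         n_monitor = if (use_root) n_monitor else 0)
  a <- unname(state0)
  if (tt > 0) {
    out <- try(.integrate(parms, a, c(0, tt), atol, rtol, use_root = use_root),
               silent = TRUE)
    if (inherits(out, "try-error"))
      return(list(status = "error"))
    if (out[nrow(out), 1] < tt)
      return(list(status = "extinction", time = out[nrow(out), 1]))
    a <- as.numeric(out[nrow(out), -1])
  }
  b <- a
  b[config$perturb_component] <- b[config$perturb_component] + config$delta0
  n <- round((t_end - tt) / config$dt)
  ## integrate half a step beyond the last renormalisation time so the
  ## final event reliably fires before the run ends
  times <- c(seq(0, n * config$dt, by = config$dt),
             (n + 0.5) * config$dt)
  parms2 <- .parms_vector(family, block, m, dual = TRUE,
                          delta0 = config$delta0,
                          extinction = if (use_root) extinction else -1,
                          n_monitor = if (use_root) n_monitor else 0)
  out2 <- try(.integrate(parms2, c(a, b, 0), times, atol, rtol,
                         use_root = use_root,
                         events_times = seq(config$dt, n * config$dt,
                                            by = config$dt)),
              silent = TRUE)
  if (inherits(out2, "try-error"))
    return(list(status = "error"))
  if (out2[nrow(out2), 1] < n * config$dt)
    return(list(status = "extinction", time = tt + out2[nrow(out2), 1]))
  S <- unname(out2[nrow(out2), 2 * m + 2])
  list(status = "ok", S = S, n = n, lambda1 = S / n)
}

#' Maximal Lyapunov exponent of a community model
#'
#' @param structure a `community_structure`.
#' @param params a `community_params`.
#' @param state0 initial state.
#' @param t_end horizon (h); the first `transient_fraction` is discarded.
#' @param config a [lyapunov_config()].
#' @param extinction strain-density threshold aborting the estimate (the
#'   result is then flagged, not numeric).
#' @param atol,rtol integration tolerances.
#' @return a `lyapunov_result`: list with `lambda1` (bits/step), running
#'   sum `S`, step count `n`, and `status` (`"ok"`, `"extinction"`,
#'   `"error"`).
#' @export
max_lyapunov <- function(structure, params, state0, t_end = 5000,
                         config = lyapunov_config(), extinction = 1e-5,
                         atol = 1e-9, rtol = 1e-4) {
  m <- structure$n_strains + 1L + structure$n_bact + structure$n_qs
  res <- .lyap_run(0, .pack_community(structure, params), m, state0, t_end,
                   config, extinction, structure$n_strains, atol, rtol)
  res$config <- config
  class(res) <- "lyapunov_result"
  res
}

#' Maximal Lyapunov exponent of a gLV system
#'
#' @param params a `glv_params`.
#' @param state0 initial abundances.
#' @inheritParams max_lyapunov
#' @return a `lyapunov_result`.
#' @export
max_lyapunov_glv <- function(params, state0, t_end = 5000,
                             config = lyapunov_config(), extinction = NULL,
                             atol = 1e-9, rtol = 1e-4) {
  res <- .lyap_run(1, .pack_glv(params), params$n, state0, t_end, config,
                   extinction, params$n, atol, rtol)
  res$config <- config
  class(res) <- "lyapunov_result"
  res
}

#' Maximal Lyapunov exponent of the Lorenz system
#'
#' Mainly used as a fixture with a well-known positive exponent.
#'
#' @param sigma,rho,beta Lorenz parameters.
#' @param state0 initial state.
#' @inheritParams max_lyapunov
#' @return a `lyapunov_result`.
#' @export
max_lyapunov_lorenz <- function(sigma = 10, rho = 28, beta = 8 / 3,
                                state0 = c(1, 1, 1), t_end = 1000,
                                config = lyapunov_config(),
                                atol = 1e-9, rtol = 1e-6) {
  res <- .lyap_run(2, c(sigma, rho, beta), 3L, state0, t_end, config,
                   NULL, 0, atol, rtol)
  res$config <- config
  class(res) <- "lyapunov_result"
  res
}

#' Maximal Lyapunov exponent of a uniform linear decay flow
#'
#' Calibration fixture: for `dx_i/dt = -rate * x_i` the exact exponent is
#' `-rate * log2(e)` bits per unit time, so the estimator can be checked
#' against a closed form.
#'
#' @param rate decay rate.
#' @param state0 initial state.
#' @inheritParams max_lyapunov
#' @return a `lyapunov_result`.
#' @export
max_lyapunov_decay <- function(rate = 1, state0 = c(1, 1), t_end = 200,
                               config = lyapunov_config(),
                               atol = 1e-12, rtol = 1e-10) {
  res <- .lyap_run(3, rate, length(state0), state0, t_end, config,
                   NULL, 0, atol, rtol)
  res$config <- config
  class(res) <- "lyapunov_result"
  res
}

#' @export
print.lyapunov_result <- function(x, ...) {
  if (x$status == "ok")
    cat("<lyapunov_result> lambda1 =", signif(x$lambda1, 4), "bits/step (n =",
        x$n, ")\n")
  else cat("<lyapunov_result> status:", x$status, "\n")
  invisible(x)
}

#' Classify dynamical behaviour
#'
#' Combines extinction status, the maximal Lyapunov exponent and the
#' sustained-oscillation prescreen into one of four labels.
#'
#' @param lyap a `lyapunov_result` (or `NULL` when extinct).
#' @param trajectory the matching `chaoscope_trajectory`.
#' @param chaos_threshold lambda1 classification boundary (bits/step);
#'   0.003 for the community model, 0.015 for the gLV validation system.
#' @param K amplitude threshold of the oscillation prescreen (OD).
#' @return one of `"extinct"`, `"chaotic"`, `"oscillatory"`, `"stable"`.
#' @export
classify_behaviour <- function(lyap, trajectory, chaos_threshold = 0.003,
                               K = 0.05) {
  if (trajectory$termination$status != "completed") return("extinct")
  if (!is.null(lyap) && identical(lyap$status, "extinction")) return("extinct")
  if (!is.null(lyap) && identical(lyap$status, "ok") &&
      lyap$lambda1 > chaos_threshold) return("chaotic")
  if (chaos_prescreen(trajectory, K = K)) "oscillatory" else "stable"
}
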