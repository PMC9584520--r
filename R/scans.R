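## Parameter-plane classification maps, initial-condition sensitivity scans,
## bifurcation diagrams and real-time parameter ramps around a base input
## vector (parameters + initial state) of a community model.

.scan_cell <- function(structure, params, state0, t_end, chaos_threshold, K) {
  tr <- simulate_community(structure, params, state0, t_end = t_end)
  if (tr$termination$status == "error")
    return(list(lambda1 = NA_real_, label = "error"))
  if (tr$termination$status == "extinction")
    return(list(lambda1 = NA_real_, label = "extinct"))
  ly <- max_lyapunov(structure, params, state0, t_end = t_end)
  l1 <- if (ly$status == "ok") ly$lambda1 else NA_real_
  list(lambda1 = l1,
       label = classify_behaviour(ly, tr, chaos_threshold, K))
}

.override_param <- function(params, name, value) {
  m <- regmatches(name, regexec("^(mu_max|kA|KBmax|K_AB|n_z)([0-9]+)$", name))[[1]]
  if (length(m) == 3) {
    params[[m[2]]][as.integer(m[3])] <- value
  } else if (name %in% names(params)) {
    params[[name]] <- value
  } else stop("unknown parameter: ", name)
  params
}

#' Two-parameter classification map
#'
#' Overrides two parameters of a base input vector on a grid; each cell is
#' simulated, its maximal Lyapunov exponent estimated, and the behaviour
#' classified (`stable` / `oscillatory` / `chaotic` / `extinct`).
#'
#' @param structure a `community_structure`.
#' @param params base `community_params` (e.g. the chaotic reference).
#' @param state0 base initial state.
#' @param param_x,param_y parameter names (e.g. `"kA1"`, `"D"`).
#' @param grid_x,grid_y parameter values.
#' @param t_end horizon per cell (h).
#' @param chaos_threshold,K classification settings.
#' @return data frame (long format) with the grid values, `lambda1`, `label`.
#' @export
grid_scan <- function(structure, params, state0, param_x, param_y,
                      grid_x, grid_y, t_end = 5000,
                      chaos_threshold = 0.003, K = 0.05) {
  out <- expand.grid(x = grid_x, y = grid_y)
  names(out) <- c(param_x, param_y)
  out$lambda1 <- NA_real_; out$label <- NA_character_
  for (i in seq_len(nrow(out))) {
    p <- .override_param(params, param_x, out[i, 1])
    p <- .override_param(p, param_y, out[i, 2])
    cell <- .scan_cell(structure, p, state0, t_end, chaos_threshold, K)
    out$lambda1[i] <- cell$lambda1
    out$label[i] <- cell$label
  }
  out
}

#' Initial-condition sensitivity scan
#'
#' Varies the initial value of one state variable and classifies the
#' resulting behaviour, revealing coexisting attractors reachable by
#' changing the starting state alone.
#'
#' @param structure a `community_structure`.
#' @param params base `community_params`.
#' @param state0 base initial state (named).
#' @param species state-variable name (e.g. `"N1"`, `"B1"`).
#' @param value_grid initial values to scan.
#' @inheritParams grid_scan
#' @return data frame with `value`, `lambda1`, `label`.
#' @export
sensitivity_scan <- function(structure, params, state0, species, value_grid,
                             t_end = 5000, chaos_threshold = 0.003, K = 0.05) {
  if (!species %in% names(state0)) stop("unknown state variable: ", species)
  out <- data.frame(value = value_grid, lambda1 = NA_real_,
                    label = NA_character_)
  for (i in seq_along(value_grid)) {
    s0 <- state0; s0[species] <- value_grid[i]
    cell <- .scan_cell(structure, params, s0, t_end, chaos_threshold, K)
    out$lambda1[i] <- cell$lambda1
    out$label[i] <- cell$label
  }
  out
}

#' Bifurcation scan along one parameter
#'
#' For every parameter value the system is simulated and the post-transient
#' local maxima of one species collected (deduplicated at an absolute
#' tolerance), giving the attractor summary plotted in bifurcation
#' diagrams, together with the behaviour classification.
#'
#' @param structure a `community_structure`.
#' @param params base `community_params`.
#' @param state0 base initial state.
#' @param param parameter name.
#' @param value_grid parameter values.
#' @param species index of the species whose peaks are recorded.
#' @param transient_fraction fraction of the horizon discarded.
#' @param peak_tol dedup tolerance for peak heights.
#' @inheritParams grid_scan
#' @return list with `summary` (per-value label and lambda1) and `extrema`
#'   (long data frame of peak heights per parameter value).
#' @export
bifurcation_scan <- function(structure, params, state0, param, value_grid,
                             species = 1, t_end = 5000,
                             transient_fraction = 0.1, peak_tol = 1e-4,
                             chaos_threshold = 0.003, K = 0.05) {
  summ <- data.frame(value = value_grid, lambda1 = NA_real_,
                     label = NA_character_, n_extrema = NA_integer_)
  ext <- list()
  for (i in seq_along(value_grid)) {
    p <- .override_param(params, param, value_grid[i])
    tr <- simulate_community(structure, p, state0, t_end = t_end)
    if (tr$termination$status != "completed") {
      summ$label[i] <- if (tr$termination$status == "extinction")
        "extinct" else "error"
      summ$n_extrema[i] <- 0L
      next
    }
    ly <- max_lyapunov(structure, p, state0, t_end = t_end)
    summ$lambda1[i] <- if (ly$status == "ok") ly$lambda1 else NA_real_
    summ$label[i] <- classify_behaviour(ly, tr, chaos_threshold, K)
    post <- tr$states[tr$times >= transient_fraction * t_end, species]
    pk <- peak_amplitudes(post)
    heights <- post[pk$peaks]
    if (!length(heights)) heights <- post[length(post)]  # fixed point level
    heights <- sort(heights)
    keep <- c(TRUE, diff(heights) > peak_tol)
    heights <- heights[keep]
    summ$n_extrema[i] <- length(heights)
    ext[[i]] <- data.frame(value = value_grid[i], peak = heights)
  }
  list(summary = summ, extrema = do.call(rbind, ext))
}

#' Real-time parameter-ramp simulation
#'
#' Integrates the community with one parameter following a piecewise-linear
#' schedule inside the right-hand side (a single continuous integration,
#' not segment-wise restarts), emulating live tuning of a chemostat.
#'
#' @param structure a `community_structure`.
#' @param params base `community_params`.
#' @param state0 initial state.
#' @param schedule a [ramp_schedule()].
#' @param t_end horizon (h).
#' @param ... passed to [simulate_community()].
#' @return a `chaoscope_trajectory`.
#' @export
ramp_simulation <- function(structure, params, state0, schedule,
                            t_end = 5000, ...) {
  simulate_community(structure, params, state0, t_end = t_end,
                     ramp = schedule, ...)
}

#' Terminal-window coexistence check
#'
#' Utility used to verify that a ramp ended in stable three-strain
#' coexistence: over the final `window` hours all strains stay above the
#' extinction threshold and every strain's peak-to-trough range is below
#' `amplitude_tol`.
#'
#' @param trajectory a `chaoscope_trajectory`.
#' @param window length of the terminal window (h).
#' @param extinction strain-density floor.
#' @param amplitude_tol maximum allowed range per strain.
#' @param n_strains number of strain columns.
#' @return logical.
#' @export
stable_coexistence <- function(trajectory, window = 500, extinction = 1e-5,
                               amplitude_tol = 0.05, n_strains = 3) {
  if (trajectory$termination$status != "completed") return(FALSE)
  tt <- trajectory$times
  sel <- tt >= (tt[length(tt)] - window)
  st <- trajectory$states[sel, seq_len(n_strains), drop = FALSE]
  all(st > extinction) &&
    all(apply(st, 2, function(x) diff(range(x))) < amplitude_tol)
}
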