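## Distance functions used by ABC SMC: the oscillatory objective
## (d_o1, d_o2, d_o3) built from the dominant period, expected peak count
## and peak-to-trough amplitudes, and the chaos objective d_C1 = 1/(1+lambda1)
## with its sustained-oscillation prescreen.

#' Sentinel distance assigned to rejected simulations
#' @export
DIST_SENTINEL <- 1e6

#' Final oscillatory-objective thresholds (d_o1, d_o2, d_o3)
#' @export
EPS_OSCILLATION <- c(2.0, 2.5, 20.0)

#' Final chaos-objective threshold (d_C1)
#' @export
EPS_CHAOS <- 0.997

#' Dominant period of a uniformly sampled signal
#'
#' The mean is removed, the discrete Fourier transform taken, and the
#' positive frequency with maximal magnitude converted to a period
#' `T = 1/f`. A constant (or numerically flat) signal returns `Inf`.
#'
#' @param signal numeric vector on a uniform grid.
#' @param dt grid spacing (h).
#' @return dominant period (h), or `Inf`.
#' @export
dominant_period <- function(signal, dt = 1) {
  n <- length(signal)
  if (n < 4) stop("need at least 4 samples")
  x <- signal - mean(signal)
  mag <- Mod(stats::fft(x))[2:(n %/% 2 + 1)]
  if (!any(mag > n * max(1e-12, 1e-12 * max(abs(signal))))) return(Inf)
  k <- which.max(mag)
  (n * dt) / k
}

#' Peaks, troughs and peak-to-trough amplitudes
#'
#' Peaks are discrete gradient sign changes from positive to negative,
#' troughs the reverse; amplitudes are absolute differences between
#' consecutive extrema.
#'
#' @param signal numeric vector on a uniform grid.
#' @return list with `peaks`, `troughs` (indices), `amplitudes`, and the
#'   final amplitude `A_F` (0 when fewer than two extrema exist).
#' @export
peak_amplitudes <- function(signal) {
  d <- sign(diff(signal))
  ## collapse flat segments so plateaus count once
  nz <- which(d != 0)
  ext_idx <- integer(); ext_val <- numeric(); kind <- integer()
  if (length(nz) >= 2) {
    dn <- d[nz]
    ch <- which(dn[-length(dn)] != dn[-1])
    for (j in ch) {
      i <- nz[j + 1]                       # last index of the run boundary
      ext_idx <- c(ext_idx, i)
      ext_val <- c(ext_val, signal[i])
      kind <- c(kind, if (dn[j] > 0) 1L else -1L)  # 1 peak, -1 trough
    }
  }
  ## one amplitude per oscillation: successive non-overlapping
  ## peak/trough pairs, so a sustained oscillator has about t/T of them
  n_pair <- length(ext_val) %/% 2
  amps <- if (n_pair >= 1)
    abs(ext_val[2 * seq_len(n_pair)] - ext_val[2 * seq_len(n_pair) - 1L])
  else numeric()
  list(peaks = ext_idx[kind == 1L], troughs = ext_idx[kind == -1L],
       amplitudes = amps,
       A_F = if (length(amps)) amps[length(amps)] else 0)
}

#' Oscillation summary statistics of one signal
#'
#' @param signal numeric vector on a uniform grid.
#' @param dt grid spacing (h).
#' @param K amplitude threshold.
#' @return list with dominant period `T`, expected peak count `p = t/T`,
#'   `amplitudes`, above-threshold count `A_K`, final amplitude `A_F`.
#' @export
oscillation_stats <- function(signal, dt = 1, K = 0.05) {
  t_total <- (length(signal) - 1) * dt
  Tdom <- dominant_period(signal, dt)
  pk <- peak_amplitudes(signal)
  list(T = Tdom, p = if (is.finite(Tdom)) t_total / Tdom else 0,
       amplitudes = pk$amplitudes, A_K = sum(pk$amplitudes > K),
       A_F = pk$A_F, K = K)
}

.osc_distance_one <- function(signal, dt, t_total, K) {
  s <- oscillation_stats(signal, dt, K)
  d1 <- if (is.finite(s$T) && s$T < t_total / 2) 0 else
    if (is.finite(s$T)) abs(s$T - t_total / 2) else DIST_SENTINEL
  d2 <- abs(s$A_K - s$p)
  d3 <- abs(s$A_F - K)
  if (d3 > K) d3 <- 0
  c(d1, d2, d3)
}

#' Oscillatory-objective distances of a community trajectory
#'
#' Computes `(d_o1, d_o2, d_o3)` per strain and combines strains by the
#' componentwise maximum, so acceptance requires every strain to show
#' sustained oscillations. `d_o1` is zero when the dominant period is below
#' half the horizon and `|T - t/2|` otherwise; `d_o3` is zeroed when the
#' final amplitude differs from the threshold `K` by more than `K`.
#' Extinct or failed trajectories receive the sentinel vector.
#'
#' @param trajectory a `chaoscope_trajectory`.
#' @param K amplitude threshold.
#' @param n_strains number of leading state columns that are strains
#'   (defaults to all columns named `N*`).
#' @return numeric length-3 distance vector.
#' @export
oscillation_distances <- function(trajectory, K = 0.05, n_strains = NULL) {
  if (trajectory$termination$status != "completed")
    return(rep(DIST_SENTINEL, 3))
  states <- trajectory$states
  if (is.null(n_strains))
    n_strains <- sum(startsWith(colnames(states), "N"))
  dt <- diff(trajectory$times[1:2])
  t_total <- trajectory$times[length(trajectory$times)]
  d <- vapply(seq_len(n_strains), function(k)
    .osc_distance_one(states[, k], dt, t_total, K), numeric(3))
  apply(d, 1, max)
}

#' Chaos-objective distance
#'
#' `d_C1 = 1/(1 + lambda1)`; thresholding at 0.997 is equivalent to
#' requiring `lambda1 > 0.003`. Estimates with `lambda1 <= -1` are
#' rejected (the distance is not defined there).
#'
#' @param lambda1 maximal Lyapunov exponent (bits/step).
#' @return list with `d` (numeric) and `reject` (logical).
#' @export
chaos_distance <- function(lambda1) {
  if (!is.finite(lambda1) || lambda1 <= -1)
    return(list(d = DIST_SENTINEL, reject = TRUE))
  d <- 1 / (1 + lambda1)
  list(d = d, reject = d < 0)
}

#' Sustained-oscillation prescreen of the chaos objective
#'
#' A trajectory proceeds to the (costly) Lyapunov stage only if it
#' completed without extinction and every strain shows at least
#' `min_oscillations` peak-to-trough amplitudes above `K`.
#'
#' @param trajectory a `chaoscope_trajectory`.
#' @param K amplitude threshold.
#' @param min_oscillations minimum above-threshold amplitude count.
#' @param n_strains number of strain columns (default: all `N*` columns).
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
chaos_prescreen <- function(trajectory, K = 0.05, min_oscillations = 2,
                            n_strains = NULL) {
  if (trajectory$termination$status != "completed") return(FALSE)
  states <- trajectory$states
  if (is.null(n_strains))
    n_strains <- sum(startsWith(colnames(states), "N"))
  for (k in seq_len(n_strains)) {
    if (sum(peak_amplitudes(states[, k])$amplitudes > K) < min_oscillations)
      return(FALSE)
  }
  TRUE
}
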