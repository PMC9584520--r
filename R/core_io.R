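## Configuration files, trajectory serialisation, fixtures and manifests.

#' Load the prior configuration table
#'
#' Reads a YAML prior table (the packaged default holds the community model's
#' priors: uniform between min and max, with wide rate/affinity parameters
#' sampled on a log10 scale, constants with equal bounds).
#'
#' @param path YAML file; defaults to the packaged configuration.
#' @return a `prior_spec` data frame (`name`, `min`, `max`, `scale`).
#' @export
load_prior_config <- function(path = system.file("extdata",
                                                 "priors_community.yaml",
                                                 package = "chaoscope")) {
  y <- yaml::read_yaml(path)
  rows <- lapply(names(y$parameters), function(nm) {
    e <- y$parameters[[nm]]
    if (is.null(e$min) || is.null(e$max)) stop("prior row ", nm, " incomplete")
    data.frame(name = nm, min = as.numeric(e$min), max = as.numeric(e$max),
               scale = if (is.null(e$scale)) "linear" else e$scale,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  prior_spec(df$name, df$min, df$max, df$scale)
}

#' Load a fixed parameter vector and initial state
#'
#' @param path YAML file with `parameters` (scalars plus vector entries
#'   `mu_max`, `kA`, `KBmax`, `K_AB`, `n_z`) and `initial_state` blocks;
#'   defaults to the packaged chaotic reference vector of the focal
#'   topology.
#' @return list with `params` (a `community_params`) and `state0`.
#' @export
load_fixed_params <- function(path = system.file("extdata",
                                                 "chaotic_reference.yaml",
                                                 package = "chaoscope")) {
  y <- yaml::read_yaml(path)
  p <- y$parameters
  num <- function(x) as.numeric(unlist(x))
  params <- community_params(
    D = num(p$D), S0 = num(p$S0), K = num(p$K), gamma = num(p$gamma),
    C_N = num(p$C_N), C_B = num(p$C_B), C_A = num(p$C_A),
    K_omega = num(p$K_omega), n_omega = num(p$n_omega),
    omega_max = num(p$omega_max),
    mu_max = num(p$mu_max), kA = num(p$kA), KBmax = num(p$KBmax),
    K_AB = num(p$K_AB), n_z = num(p$n_z))
  state0 <- vapply(y$initial_state, function(x) as.numeric(x), numeric(1))
  list(params = params, state0 = state0)
}

#' Save a fixed parameter vector to YAML
#'
#' Round-trip counterpart of [load_fixed_params()].
#'
#' @param params a `community_params`.
#' @param state0 named initial state.
#' @param path output YAML file.
#' @export
save_fixed_params <- function(params, state0, path) {
  y <- list(parameters = unclass(params),
            initial_state = as.list(state0))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Generate a synthetic test signal
#'
#' Uniform-grid fixtures with known analytic properties, used to validate
#' the oscillation statistics and the Lyapunov estimator.
#'
#' @param name one of `"sine"`, `"damped_sine"`, `"multi_tone"`,
#'   `"lorenz"`, `"constant"`.
#' @param t_end,dt grid definition.
#' @param period,amplitude,offset sine parameters (`multi_tone` accepts
#'   vectors).
#' @param decay exponential amplitude decay rate of `damped_sine` (1/h).
#' @param value constant level for `"constant"`.
#' @param sigma,rho,beta,state0 Lorenz settings.
#' @return a `chaoscope_trajectory` (single column `X`, or the three
#'   Lorenz coordinates).
#' @export
make_fixture <- function(name = c("sine", "damped_sine", "multi_tone",
                                  "lorenz", "constant"),
                         t_end = 5000, dt = 1, period = 100, amplitude = 0.2,
                         offset = 0.5, decay = 1e-3, value = 1,
                         sigma = 10, rho = 28, beta = 8 / 3,
                         state0 = c(1, 1, 1)) {
  name <- match.arg(name)
  times <- seq(0, t_end, by = dt)
  states <- switch(name,
    sine = cbind(X = offset + amplitude * sin(2 * pi * times / period)),
    damped_sine = cbind(X = offset + amplitude * exp(-decay * times) *
                          sin(2 * pi * times / period)),
    multi_tone = cbind(X = offset + as.numeric(
      vapply(seq_along(period), function(i)
        amplitude[i] * sin(2 * pi * times / period[i]), numeric(length(times)))
      %*% rep(1, length(period)))),
    constant = cbind(X = rep(value, length(times))),
    lorenz = {
      parms <- .parms_vector(2, c(sigma, rho, beta), 3L)
      out <- .integrate(parms, unname(state0), times, 1e-9, 1e-6)
      m <- out[, -1, drop = FALSE]; colnames(m) <- c("X", "Y", "Z"); m
    })
  structure(list(times = times, states = states,
                 termination = list(status = "completed")),
            class = "chaoscope_trajectory")
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' @param trajectory a `chaoscope_trajectory`.
#' @param file CSV path (`time` column plus one column per state variable);
#'   metadata (termination, optional settings) goes to `<file>.json`.
#' @param metadata optional list stored in the sidecar.
#' @export
write_trajectory <- function(trajectory, file, metadata = list()) {
  df <- data.frame(time = trajectory$times, trajectory$states,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(c(list(termination = trajectory$termination),
                         metadata),
                       paste0(file, ".json"), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param file CSV path.
#' @return a `chaoscope_trajectory`.
#' @export
read_trajectory <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  structure(list(times = df$time,
                 states = as.matrix(df[, -1, drop = FALSE]),
                 termination = as.list(meta$termination)),
            class = "chaoscope_trajectory")
}

#' Write a run manifest
#'
#' Records the package version, master seed, settings and the MD5 hash of
#' every listed output file, sufficient to re-run a pipeline
#' bit-compatibly (up to floating-point solver determinism).
#'
#' @param path output JSON file.
#' @param seed master seed.
#' @param settings named list of run settings.
#' @param files character vector of output files to inventory.
#' @export
write_manifest <- function(path, seed, settings = list(), files = character()) {
  inv <- lapply(files, function(f)
    list(file = f, md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(
    list(package = "chaoscope",
         version = as.character(utils::packageVersion("chaoscope")),
         seed = seed, settings = settings, files = inv),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
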