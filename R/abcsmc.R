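## Approximate Bayesian Computation with Sequential Monte Carlo over
## (model, parameter) particles. The generic engine is problem-agnostic:
## it needs a prior specification per model and a simulate-and-distance
## function. Community wrappers attach the oscillatory / chaos objectives.

#' Prior specification table
#'
#' @param name parameter names.
#' @param min,max prior bounds (uniform between them; equal bounds mark a
#'   constant).
#' @param scale `"linear"` or `"log10"` sampling scale per parameter.
#' @return a `prior_spec` data frame.
#' @export
prior_spec <- function(name, min, max, scale = "linear") {
  if (any(min > max)) stop("prior min exceeds max")
  scale <- rep(scale, length.out = length(name))
  if (!all(scale %in% c("linear", "log10"))) stop("unknown scale")
  if (any(scale == "log10" & min <= 0))
    stop("log10-scaled priors need positive bounds")
  structure(data.frame(name = name, min = min, max = max, scale = scale,
                       stringsAsFactors = FALSE),
            class = c("prior_spec", "data.frame"))
}

.prior_sample <- function(prior) {
  u <- runif(nrow(prior))
  lo <- ifelse(prior$scale == "log10", log10(prior$min), prior$min)
  hi <- ifelse(prior$scale == "log10", log10(prior$max), prior$max)
  v <- lo + u * (hi - lo)
  v <- ifelse(prior$scale == "log10", 10^v, v)
  stats::setNames(v, prior$name)
}

## value on the sampling scale (kernel and support arithmetic happen there)
.to_scale <- function(prior, theta) {
  ifelse(prior$scale == "log10", log10(theta), theta)
}
.from_scale <- function(prior, x) {
  ifelse(prior$scale == "log10", 10^x, x)
}
.scale_bounds <- function(prior) {
  list(lo = ifelse(prior$scale == "log10", log10(prior$min), prior$min),
       hi = ifelse(prior$scale == "log10", log10(prior$max), prior$max))
}

#' Sample one particle from the prior
#'
#' @param priors named list of `prior_spec`, one per model id.
#' @param model_ids candidate model ids (uniform model prior).
#' @return list with `model_id` and named parameter vector `theta`.
#' @export
sample_prior <- function(priors, model_ids = names(priors)) {
  mid <- if (length(model_ids) == 1) model_ids else sample(model_ids, 1)
  list(model_id = mid, theta = .prior_sample(priors[[mid]]))
}

#' Perturb a particle with a uniform component-wise kernel
#'
#' Parameters move by at most `kernel_frac` of the prior range on the
#' sampling scale; proposals outside the prior support are redrawn
#' (up to `max_tries`, then clipped to the support). With probability
#' `p_model` the model switches to a uniformly chosen other candidate and
#' the parameters are redrawn from that model's prior.
#'
#' @param particle list with `model_id`, `theta`.
#' @param priors named list of `prior_spec`.
#' @param model_ids candidate models.
#' @param kernel_frac kernel half-width as a fraction of the prior range.
#' @param p_model model-switch probability.
#' @param max_tries resampling attempts before clipping.
#' @return perturbed particle.
#' @export
perturb_particle <- function(particle, priors, model_ids = names(priors),
                             kernel_frac = 0.1, p_model = 0,
                             max_tries = 100) {
  if (length(model_ids) > 1 && p_model > 0 && runif(1) < p_model) {
    others <- setdiff(model_ids, particle$model_id)
    mid <- if (length(others) == 1) others else sample(others, 1)
    return(list(model_id = mid, theta = .prior_sample(priors[[mid]])))
  }
  prior <- priors[[particle$model_id]]
  b <- .scale_bounds(prior)
  h <- kernel_frac * (b$hi - b$lo)
  x <- .to_scale(prior, particle$theta)
  for (i in seq_len(max_tries)) {
    xp <- x + runif(length(x), -h, h)
    if (all(xp >= b$lo & xp <= b$hi)) {
      return(list(model_id = particle$model_id,
                  theta = stats::setNames(.from_scale(prior, xp), prior$name)))
    }
  }
  xp <- pmin(pmax(x + runif(length(x), -h, h), b$lo), b$hi)
  list(model_id = particle$model_id,
       theta = stats::setNames(.from_scale(prior, xp), prior$name))
}

#' Importance weight of an accepted particle
#'
#' Generation 0 particles have weight 1. Later generations use the ratio of
#' the prior density to the kernel-smoothed previous population:
#' `w = pi(theta) / sum_j w_j K(theta | theta_j)`, with the sum over the
#' previous generation's particles of the same model.
#'
#' @param particle accepted particle (`model_id`, `theta`).
#' @param prev_particles previous generation (list of particles), or `NULL`
#'   for generation 0.
#' @param prev_weights normalised previous weights.
#' @param priors named list of `prior_spec`.
#' @param kernel_frac kernel half-width fraction (must match the perturbation).
#' @return unnormalised weight.
#' @export
compute_weight <- function(particle, prev_particles, prev_weights, priors,
                           kernel_frac = 0.1) {
  if (is.null(prev_particles)) return(1)
  prior <- priors[[particle$model_id]]
  b <- .scale_bounds(prior)
  h <- kernel_frac * (b$hi - b$lo)
  x <- .to_scale(prior, particle$theta)
  if (any(x < b$lo - 1e-12) || any(x > b$hi + 1e-12)) return(0)
  rng <- b$hi - b$lo
  pi_theta <- prod(ifelse(rng > 0, 1 / rng, 1))
  kdens <- prod(ifelse(h > 0, 1 / (2 * h), 1))
  denom <- 0
  for (j in seq_along(prev_particles)) {
    pj <- prev_particles[[j]]
    if (!identical(pj$model_id, particle$model_id)) next
    xj <- .to_scale(prior, pj$theta)
    free <- h > 0
    if (all(abs(x[free] - xj[free]) <= h[free] + 1e-12))
      denom <- denom + prev_weights[j] * kdens
  }
  if (denom == 0) stop("zero kernel denominator: perturbation out of reach")
  pi_theta / denom
}

#' Update the acceptance threshold from a population's distances
#'
#' Distances are sorted in ascending order per component and the value at
#' quantile `alpha` (lower / type-1 convention) becomes the next threshold,
#' floored at the final threshold `eps_final`.
#'
#' @param distances matrix (particles x components) of accepted distances.
#' @param alpha quantile in (0, 1].
#' @param eps_final final threshold vector.
#' @return list with `eps` (next threshold) and `final` (logical: floor
#'   reached in every component).
#' @export
update_epsilon <- function(distances, alpha, eps_final) {
  distances <- rbind(distances)
  eps <- vapply(seq_len(ncol(distances)), function(j)
    stats::quantile(distances[, j], alpha, type = 1, names = FALSE),
    numeric(1))
  hit <- eps <= eps_final
  eps <- pmax(eps, eps_final)
  list(eps = eps, final = all(hit))
}

#' Generic ABC SMC engine
#'
#' Algorithm: generation 0 accepts everything (`eps = Inf`); each later
#' generation resamples the previous population by weight, perturbs,
#' simulates, and accepts particles whose distance vector is below the
#' current threshold; the threshold shrinks to the `alpha` quantile of the
#' accepted distances until it reaches `eps_final`, which marks the final
#' generation.
#'
#' @param priors named list of `prior_spec` (one per candidate model).
#' @param distance_fn `function(model_id, theta)` returning a numeric
#'   distance vector (use `DIST_SENTINEL` components for rejected runs).
#' @param n_particles population size per generation.
#' @param eps_final final acceptance threshold (vector).
#' @param alpha threshold-shrink quantile.
#' @param kernel_frac perturbation kernel half-width fraction.
#' @param p_model model-switch probability of the perturbation.
#' @param max_generations safety cap on generations.
#' @param max_sims safety cap on simulations per generation.
#' @param eps_init initial threshold; `Inf` accepts everything in
#'   generation 0, while setting it to the rejection sentinel makes
#'   generation 0 sample the prior until it finds particles that actually
#'   reach the distance stage (useful when most prior draws are rejected
#'   outright and would otherwise leave the first population uninformative).
#' @return list with `populations` (per generation: particles, weights,
#'   distances, eps), `final` (the last population) and `n_sims`.
#' @export
abc_smc <- function(priors, distance_fn, n_particles = 100,
                    eps_final, alpha = 0.5, kernel_frac = 0.1,
                    p_model = 0.1, max_generations = 20,
                    max_sims = 1e5, eps_init = Inf) {
  model_ids <- names(priors)
  eps <- rep(eps_init, length.out = length(eps_final))
  populations <- list()
  prev_particles <- NULL; prev_weights <- NULL
  total_sims <- 0
  for (gen in seq_len(max_generations)) {
    particles <- vector("list", n_particles)
    weights <- numeric(n_particles)
    dists <- matrix(NA_real_, n_particles, length(eps_final))
    accepted <- 0; sims <- 0
    while (accepted < n_particles && sims < max_sims) {
      if (is.null(prev_particles)) {
        cand <- sample_prior(priors, model_ids)
      } else {
        j <- sample.int(length(prev_particles), 1, prob = prev_weights)
        cand <- perturb_particle(prev_particles[[j]], priors, model_ids,
                                 kernel_frac, p_model)
      }
      d <- distance_fn(cand$model_id, cand$theta)
      sims <- sims + 1
      if (all(d < eps)) {
        accepted <- accepted + 1
        particles[[accepted]] <- cand
        dists[accepted, ] <- d
        weights[accepted] <- compute_weight(cand, prev_particles,
                                            prev_weights, priors, kernel_frac)
      }
    }
    total_sims <- total_sims + sims
    if (accepted < n_particles) {
      warning("ABC SMC stalled in generation ", gen, " (", accepted, "/",
              n_particles, " accepted)")
      particles <- particles[seq_len(accepted)]
      dists <- dists[seq_len(accepted), , drop = FALSE]
      weights <- weights[seq_len(accepted)]
      if (!accepted) break
    }
    weights <- weights / sum(weights)
    is_final <- all(eps <= eps_final)
    populations[[gen]] <- list(particles = particles, weights = weights,
                               distances = dists, eps = eps,
                               final = is_final, n_sims = sims)
    if (is_final) break
    up <- update_epsilon(dists, alpha, eps_final)
    eps <- up$eps
    prev_particles <- particles
    prev_weights <- weights
  }
  list(populations = populations,
       final = populations[[length(populations)]],
       n_sims = total_sims)
}

#' Model posterior from one or more final populations
#'
#' @param finals list of final populations (one per independent repeat).
#' @param model_ids the candidate model ids.
#' @return data frame with per-model mean posterior probability and the
#'   standard deviation across repeats.
#' @export
model_posterior <- function(finals, model_ids) {
  probs <- vapply(finals, function(f) {
    w <- f$weights
    ids <- vapply(f$particles, function(p) as.character(p$model_id), "")
    vapply(as.character(model_ids),
           function(m) sum(w[ids == m]), numeric(1))
  }, numeric(length(model_ids)))
  probs <- rbind(probs)
  data.frame(model_id = model_ids,
             posterior = rowMeans(probs),
             sd = apply(probs, 1, stats::sd))
}

## ---- community wrappers ----

#' Default priors for a community model structure
#'
#' Instantiates the shipped prior table for every free parameter and
#' initial condition of a given structure: one `mu_max` per strain, one
#' `kA` per QS, and `KBmax`, `K_AB`, `n_z` per bacteriocin, plus initial
#' strain densities. Wide-ranged rate/affinity parameters are sampled on a
#' log10 scale; constants (equal bounds) are kept fixed.
#'
#' @param structure a `community_structure`.
#' @param config prior table from [load_prior_config()]; defaults to the
#'   packaged configuration.
#' @return a `prior_spec`.
#' @export
community_priors <- function(structure, config = load_prior_config()) {
  st <- structure
  row <- function(nm) config[config$name == nm, ]
  entry <- function(nm, base) {
    r <- row(base)
    data.frame(name = nm, min = r$min, max = r$max, scale = r$scale,
               stringsAsFactors = FALSE)
  }
  rows <- list(entry("D", "D"), entry("S0", "S0"), entry("K", "K"),
               entry("gamma", "gamma"), entry("C_N", "C_N"),
               entry("C_B", "C_B"), entry("C_A", "C_A"),
               entry("K_omega", "K_omega"), entry("n_omega", "n_omega"),
               entry("omega_max", "omega_max"))
  for (x in seq_len(st$n_strains)) rows <- c(rows, list(
    entry(paste0("mu_max", x), "mu_max")))
  for (a in seq_len(st$n_qs)) rows <- c(rows, list(
    entry(paste0("kA", a), "kA")))
  for (z in seq_len(st$n_bact)) rows <- c(rows, list(
    entry(paste0("KBmax", z), "KBmax"),
    entry(paste0("K_AB", z), "K_AB"),
    entry(paste0("n_z", z), "n_z")))
  for (x in seq_len(st$n_strains)) rows <- c(rows, list(
    entry(paste0("N", x, "_0"), "N0")))
  df <- do.call(rbind, rows)
  prior_spec(df$name, df$min, df$max, df$scale)
}

#' Assemble community parameters and initial state from a particle
#'
#' @param structure a `community_structure`.
#' @param theta named vector drawn from [community_priors()].
#' @return list with `params` (a `community_params`) and `state0`.
#' @export
particle_to_params <- function(structure, theta) {
  st <- structure
  g <- function(nm) unname(theta[nm])
  params <- community_params(
    D = g("D"), S0 = g("S0"), K = g("K"), gamma = g("gamma"),
    C_N = g("C_N"), C_B = g("C_B"), C_A = g("C_A"),
    K_omega = g("K_omega"), n_omega = g("n_omega"),
    omega_max = g("omega_max"),
    mu_max = g(paste0("mu_max", seq_len(st$n_strains))),
    kA = if (st$n_qs) g(paste0("kA", seq_len(st$n_qs))) else numeric(),
    KBmax = if (st$n_bact) g(paste0("KBmax", seq_len(st$n_bact))) else numeric(),
    K_AB = if (st$n_bact) g(paste0("K_AB", seq_len(st$n_bact))) else numeric(),
    n_z = if (st$n_bact) g(paste0("n_z", seq_len(st$n_bact))) else numeric())
  state0 <- c(g(paste0("N", seq_len(st$n_strains), "_0")), g("S0"),
              rep(1e-81, st$n_bact), rep(1e-10, st$n_qs))
  names(state0) <- .state_names(st)
  list(params = params, state0 = state0)
}

#' ABC SMC model selection over community models
#'
#' Runs the generic engine with either the oscillatory objective
#' (`eps_F = (2, 2.5, 20)`) or the chaos objective (`eps_F = 0.997`,
#' with the sustained-oscillation prescreen ahead of the Lyapunov stage),
#' repeated independently with derived seeds; the final populations are
#' combined into a model posterior.
#'
#' @param space a pruned `model_space`.
#' @param model_ids candidate model ids (uniform model prior).
#' @param objective `"oscillation"` or `"chaos"`.
#' @param n_particles population size per generation (the chaos search
#'   uses small populations of 10, repeated independently).
#' @param repeats number of independent runs.
#' @param t_end simulation horizon (h).
#' @param alpha,kernel_frac,p_model,max_generations,max_sims engine settings.
#' @param seed master seed; per-repeat seeds are derived deterministically.
#' @param prior_config prior table (see [load_prior_config()]).
#' @param verbose print per-repeat progress.
#' @return list with `posterior` (data frame), `finals`, `runs` and the
#'   settings used.
#' @export
run_smc <- function(space, model_ids, objective = c("oscillation", "chaos"),
                    n_particles = 10, repeats = 1, t_end = 5000,
                    alpha = 0.5, kernel_frac = 0.1, p_model = 0.1,
                    max_generations = 12, max_sims = 2000, seed = 1,
                    prior_config = load_prior_config(), verbose = FALSE) {
  objective <- match.arg(objective)
  structures <- lapply(model_ids, function(id)
    build_equation_structure(get_model(space, id)))
  names(structures) <- as.character(model_ids)
  priors <- lapply(structures, community_priors, config = prior_config)
  eps_final <- if (objective == "oscillation") EPS_OSCILLATION else EPS_CHAOS

  distance_fn <- function(model_id, theta) {
    st <- structures[[as.character(model_id)]]
    pp <- particle_to_params(st, theta)
    tr <- simulate_community(st, pp$params, pp$state0, t_end = t_end)
    if (objective == "oscillation")
      return(oscillation_distances(tr))
    if (!chaos_prescreen(tr)) return(DIST_SENTINEL)
    ly <- max_lyapunov(st, pp$params, pp$state0, t_end = t_end)
    if (ly$status != "ok") return(DIST_SENTINEL)
    cd <- chaos_distance(ly$lambda1)
    if (cd$reject) return(DIST_SENTINEL)
    cd$d
  }

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, repeats)
  runs <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(rep_seeds[r])
    runs[[r]] <- abc_smc(priors, distance_fn, n_particles = n_particles,
                         eps_final = eps_final, alpha = alpha,
                         kernel_frac = kernel_frac, p_model = p_model,
                         max_generations = max_generations,
                         max_sims = max_sims, eps_init = DIST_SENTINEL)
    if (verbose)
      message("repeat ", r, "/", repeats, ": ",
              length(runs[[r]]$populations), " generations, ",
              runs[[r]]$n_sims, " simulations")
  }
  finals <- lapply(runs, `[[`, "final")
  finals <- finals[!vapply(finals, is.null, logical(1))]
  list(posterior = model_posterior(finals, model_ids),
       finals = finals, runs = runs,
       settings = list(objective = objective, n_particles = n_particles,
                       repeats = repeats, alpha = alpha,
                       kernel_frac = kernel_frac, p_model = p_model,
                       seed = seed, rep_seeds = rep_seeds, t_end = t_end))
}
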