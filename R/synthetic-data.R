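# Synthetic metacommunity generator: sites, correlated environmental
# batteries with spatial structure, and communities assembled from Gaussian
# niche responses with lognormal maximum abundances — a ground-truth test
# bed for every stage of the partitioning chain. Defaults emulate a stream
# metacommunity survey: ~100-150 sites, dozens of species with strongly
# right-skewed abundances, and a large battery of partially correlated
# habitat variables.

#' Generate site coordinates
#'
#' Uniform positions in the unit square, or a clustered (Thomas-process-like)
#' pattern of Gaussian offspring around uniformly placed parents.
#'
#' @param n_sites number of sites (at least 10).
#' @param seed integer seed.
#' @param clustered draw clustered positions (default `FALSE`).
#' @param n_parents,cluster_sd cluster parents and offspring spread for the
#'   clustered mode.
#' @return a [site_coords] object (planar, unit square).
#' @export
generate_sites <- function(n_sites, seed = 1L, clustered = FALSE,
                           n_parents = 8L, cluster_sd = 0.04) {
  if (n_sites < 10) stop("n_sites must be at least 10")
  set.seed(as.integer(seed))
  if (clustered) {
    px <- stats::runif(n_parents); py <- stats::runif(n_parents)
    pid <- sample.int(n_parents, n_sites, replace = TRUE)
    # reflect at the unit-square boundary (no atoms at the edges, so no
    # coincident sites from clamping)
    reflect <- function(v) { v <- abs(v); 1 - abs(1 - (v %% 2)) }
    x <- reflect(stats::rnorm(n_sites, px[pid], cluster_sd))
    y <- reflect(stats::rnorm(n_sites, py[pid], cluster_sd))
  } else {
    x <- stats::runif(n_sites)
    y <- stats::runif(n_sites)
  }
  site_coords(sprintf("s%03d", seq_len(n_sites)), x, y, "planar")
}

# One realization of a spatially autocorrelated Gaussian field (squared-
# exponential covariance with the given range), unit variance up to nugget.
.gauss_field <- function(coords, range, nugget = 1e-6) {
  D <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
  K <- exp(-D^2 / (2 * range^2))
  diag(K) <- diag(K) + nugget
  U <- chol(K)
  drop(crossprod(U, stats::rnorm(nrow(K))))
}

#' Generate a correlated environmental battery
#'
#' `n_latent` latent gradients, each a mixture of a spatially autocorrelated
#' Gaussian field and white noise in proportion `spatial_share`; observed
#' variables are random linear mixtures of the gradients plus independent
#' noise, rescaled to heterogeneous means and spreads so that CV screening
#' has real work to do (realized CVs span well below 40% and well above
#' 80%). The standardized latent gradients are attached as attribute
#' `"latent"` and drive the community generator's niches.
#'
#' @param coords a [site_coords] object.
#' @param n_vars number of observed variables (>= `n_latent`).
#' @param n_latent number of latent gradients.
#' @param spatial_share proportion of latent variance that is spatially
#'   structured, in `[0, 1]`.
#' @param range autocorrelation range of the spatial fields (coordinate
#'   units).
#' @param seed integer seed.
#' @return an [env_matrix] with attribute `latent`.
#' @export
generate_env <- function(coords, n_vars = 120L, n_latent = 6L,
                         spatial_share = 0.5, range = 0.2, seed = 1L) {
  if (n_vars < n_latent || n_latent < 1)
    stop("require n_vars >= n_latent >= 1")
  set.seed(as.integer(seed))
  n <- nrow(coords)
  lat <- vapply(seq_len(n_latent), function(i) {
    f <- if (spatial_share > 0) {
      g <- .gauss_field(coords, range)
      (g - mean(g)) / stats::sd(g)
    } else numeric(n)
    z <- sqrt(spatial_share) * f + sqrt(1 - spatial_share) * stats::rnorm(n)
    (z - mean(z)) / stats::sd(z)
  }, numeric(n))
  L <- matrix(stats::rnorm(n_latent * n_vars), n_latent, n_vars)
  obs <- lat %*% L + 0.5 * matrix(stats::rnorm(n * n_vars), n, n_vars)
  obs <- scale(obs)  # unit sd before imposing heterogeneous units
  target_mean <- exp(stats::rnorm(n_vars, 1.5, 1.2))
  target_cv <- exp(stats::rnorm(n_vars, log(60), 0.9))  # percent
  vals <- sweep(obs, 2, target_cv * target_mean / 100, "*")
  vals <- sweep(vals, 2, target_mean, "+")
  env <- env_matrix(vals, coords$site, sprintf("env%03d", seq_len(n_vars)))
  attr(env, "latent") <- structure(lat, dimnames = list(coords$site,
                                   paste0("G", seq_len(n_latent))))
  env
}

#' Define the ground truth of a simulated metacommunity
#'
#' Species are split into environment-driven (Gaussian niche responses on
#' the latent gradients), space-driven (log-intensity from an independent
#' spatially autocorrelated field) and pure-noise groups. Maximum abundances
#' are lognormal across species — the strongly right-skewed
#' abundance distribution characteristic of stream communities.
#'
#' @param n_species number of species.
#' @param n_gradients number of latent gradients the niches respond to.
#' @param prop_env,prop_space proportions of env- and space-driven species
#'   (sum <= 1; remainder are noise species).
#' @param sigma_logN,mu_logN lognormal parameters of maximum abundances
#'   (defaults `sigma = 1.5`, `mu = 3`, i.e. median ~20 individuals with a
#'   heavy right tail).
#' @param breadth_range uniform range of niche breadths, in gradient
#'   standard deviations.
#' @param noise_model `"poisson"` or `"negbin"`; stream counts are
#'   overdispersed, so a negative-binomial option with dispersion
#'   `negbin_k` is provided (Poisson default keeps simulations fast).
#' @param spatial_range autocorrelation range of the space-driven species'
#'   intensity fields.
#' @param seed integer seed.
#' @return a list of class `"simulation_truth"`.
#' @export
simulation_truth <- function(n_species, n_gradients = 2L,
                             prop_env = 0.7, prop_space = 0.15,
                             sigma_logN = 1.5, mu_logN = 3,
                             breadth_range = c(0.8, 1.6),
                             noise_model = c("poisson", "negbin"),
                             negbin_k = 1, spatial_range = 0.2,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (prop_env < 0 || prop_space < 0 || prop_env + prop_space > 1)
    stop("prop_env and prop_space must be non-negative and sum to <= 1")
  set.seed(as.integer(seed))
  S <- as.integer(n_species)
  n_env <- round(prop_env * S)
  n_sp <- round(prop_space * S)
  if (n_env + n_sp > S) n_sp <- S - n_env
  roles <- c(rep("env", n_env), rep("space", n_sp),
             rep("noise", S - n_env - n_sp))
  structure(list(
    n_species = S, n_gradients = as.integer(n_gradients),
    roles = roles,
    species_optima = matrix(stats::rnorm(S * n_gradients), S, n_gradients),
    niche_breadths = matrix(stats::runif(S * n_gradients,
                                         breadth_range[1], breadth_range[2]),
                            S, n_gradients),
    max_abundances = stats::rlnorm(S, mu_logN, sigma_logN),
    noise_model = noise_model, negbin_k = negbin_k,
    spatial_range = spatial_range,
    sigma_logN = sigma_logN, mu_logN = mu_logN
  ), class = "simulation_truth")
}

#' Generate a community matrix from a simulation truth
#'
#' Expected abundance of an environment-driven species `i` at site `s` is
#' `max_abundance[i] * exp(-sum_g (G_g(s) - optimum_ig)^2 / (2 breadth_ig^2))`
#' over the standardized latent gradients `G` of `env`; space-driven species
#' use an independent spatially autocorrelated log-intensity field peaking
#' at the maximum abundance; noise species have a flat expectation at 30% of
#' their maximum. Counts are Poisson or negative-binomial draws. Sites that
#' come up empty are redrawn (zero-truncation at the site level) so the
#' result is a valid community matrix.
#'
#' @param coords a [site_coords] object.
#' @param env an [env_matrix] from [generate_env()] (its `latent` attribute
#'   supplies the gradients; standardized leading principal components are
#'   used as a fallback).
#' @param truth a [simulation_truth()].
#' @param seed integer seed.
#' @return a [community_matrix].
#' @export
generate_community <- function(coords, env, truth, seed = 1L) {
  if (!inherits(truth, "simulation_truth")) stop("truth must be a simulation_truth")
  n <- nrow(coords)
  if (nrow(env) != n || !identical(rownames(env), coords$site))
    stop("env and coords are not aligned")
  G <- attr(env, "latent")
  if (is.null(G))
    G <- stats::prcomp(unclass(env), center = TRUE, scale. = TRUE)$x
  if (ncol(G) < truth$n_gradients)
    stop("truth expects ", truth$n_gradients, " gradients; env provides ",
         ncol(G))
  G <- scale(G[, seq_len(truth$n_gradients), drop = FALSE])
  set.seed(as.integer(seed))
  S <- truth$n_species
  mu <- matrix(0, n, S)
  for (i in seq_len(S)) {
    mu[, i] <- switch(truth$roles[i],
      env = {
        dev <- sweep(G, 2, truth$species_optima[i, ], "-")
        q <- rowSums(sweep(dev^2, 2, 2 * truth$niche_breadths[i, ]^2, "/"))
        truth$max_abundances[i] * exp(-q)
      },
      space = {
        f <- .gauss_field(coords, truth$spatial_range)
        f <- (f - mean(f)) / stats::sd(f)
        truth$max_abundances[i] * exp(f - max(f))
      },
      noise = rep(0.3 * truth$max_abundances[i], n))
  }
  draw <- function(m) {
    if (truth$noise_model == "poisson") stats::rpois(length(m), m)
    else stats::rnbinom(length(m), mu = m, size = truth$negbin_k)
  }
  counts <- matrix(draw(mu), n, S)
  for (try in seq_len(50)) {
    empty <- rowSums(counts) == 0
    if (!any(empty)) break
    counts[empty, ] <- matrix(draw(mu[empty, , drop = FALSE]), sum(empty), S)
  }
  if (any(rowSums(counts) == 0))
    stop("could not produce a non-empty row for every site; ",
         "expected abundances too low")
  community_matrix(counts, coords$site, sprintf("sp%03d", seq_len(S)))
}

#' Simulate a full metacommunity data set
#'
#' Convenience wrapper producing aligned community, environment and
#' coordinate tables plus the generating truth. Per-component seeds are
#' derived from the master seed by fixed offsets, so each piece can be
#' regenerated independently. Scenarios:
#' \describe{
#'   \item{`"mixed"`}{60% env-driven, 20% space-driven species, lognormal
#'     abundances (`sigma = 1.5`), spatially structured environment.}
#'   \item{`"env_only"`}{all species environment-driven; the environment has
#'     no spatial structure (`spatial_share = 0`).}
#'   \item{`"space_only"`}{all species space-driven.}
#'   \item{`"exchangeable"`}{species i.i.d. pure noise with equal expected
#'     abundance (`sigma = 0`) — the null test bed.}
#' }
#'
#' @param n_sites,n_species,n_vars,n_latent problem sizes (defaults 120
#'   sites, 60 species, 120 variables, 6 gradients).
#' @param scenario see above.
#' @param seed master seed.
#' @param ... further arguments passed to [simulation_truth()].
#' @return a list with `community`, `env`, `coords`, `truth`, `scenario`,
#'   `seed`.
#' @export
simulate_metacommunity <- function(n_sites = 120L, n_species = 60L,
                                   n_vars = 120L, n_latent = 6L,
                                   scenario = c("mixed", "env_only",
                                                "space_only", "exchangeable"),
                                   seed = 1L, ...) {
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  coords <- generate_sites(n_sites, seed = seed + 11L)
  spatial_share <- switch(scenario, env_only = 0, 0.5)
  env <- generate_env(coords, n_vars = n_vars, n_latent = n_latent,
                      spatial_share = spatial_share, seed = seed + 23L)
  args <- switch(scenario,
    mixed = list(prop_env = 0.6, prop_space = 0.2, sigma_logN = 1.5),
    env_only = list(prop_env = 1, prop_space = 0, sigma_logN = 1.5),
    space_only = list(prop_env = 0, prop_space = 1, sigma_logN = 1.5),
    exchangeable = list(prop_env = 0, prop_space = 0, sigma_logN = 0))
  args <- utils::modifyList(args, list(...))
  truth <- do.call(simulation_truth,
                   c(list(n_species = n_species, n_gradients = min(2L, n_latent),
                          seed = seed + 37L), args))
  community <- generate_community(coords, env, truth, seed = seed + 53L)
  list(community = community, env = env, coords = coords, truth = truth,
       scenario = scenario, seed = seed)
}
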