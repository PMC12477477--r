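#' Configuration for the synthetic community generator
#'
#' Bundles and validates all parameters of [simulate_community()].  The
#' defaults emulate the survey design the package targets: 6 soil samples,
#' a genus-level community of 300 taxa, sequencing depth of 60,000 reads
#' per sample, six soil environmental factors with pH the strongest driver,
#' and 3 taxa whose relative abundance tracks a compound concentration.
#'
#' @param n_samples Number of samples.
#' @param n_taxa Number of taxa (>= 2).
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @param base_concentration Dirichlet concentration of the baseline
#'   community profile; smaller values give more uneven communities.
#' @param env_effect_sizes Named vector of per-factor effect sizes on the
#'   latent log-abundances (units: log-abundance shift per SD of the
#'   factor).
#' @param n_tracking_taxa Number of taxa whose relative abundance the
#'   compound concentration follows.
#' @param tracking_strength Fraction in \[0, 1\] of the compound signal
#'   carried by the tracking taxa (1 = fully determined by them).
#' @param noise_sd SD of the Gaussian noise added to the standardized
#'   compound signal.
#' @param depth Multinomial read depth per sample.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 6, n_taxa = 300, seed = 1,
                       base_concentration = 0.3,
                       env_effect_sizes = c(pH = 1.0, SP = 0.6, ORM = 0.4,
                                            HT = 0.3, CP = 0.3, SSG = 0.2),
                       n_tracking_taxa = 3, tracking_strength = 0.9,
                       noise_sd = 0.05, depth = 60000) {
  if (n_samples < 2) stop("'n_samples' must be at least 2")
  if (n_taxa < 2) stop("'n_taxa' must be at least 2")
  if (depth <= 0) stop("'depth' must be positive")
  if (base_concentration <= 0) stop("'base_concentration' must be positive")
  if (n_tracking_taxa < 1 || n_tracking_taxa > n_taxa)
    stop("'n_tracking_taxa' must be in [1, n_taxa]")
  if (tracking_strength < 0 || tracking_strength > 1)
    stop("'tracking_strength' must be in [0, 1]")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (is.null(names(env_effect_sizes)) && length(env_effect_sizes))
    stop("'env_effect_sizes' must be a named vector (factor -> effect size)")
  structure(list(n_samples = as.integer(n_samples),
                 n_taxa = as.integer(n_taxa),
                 seed = as.integer(seed),
                 base_concentration = base_concentration,
                 env_effect_sizes = env_effect_sizes,
                 n_tracking_taxa = as.integer(n_tracking_taxa),
                 tracking_strength = tracking_strength,
                 noise_sd = noise_sd,
                 depth = as.integer(depth)), class = "sim_config")
}

# realistic units for the canonical soil factors (mean, sd); factors not
# listed here are generated as standard normals
.factor_units <- list(pH = c(5.5, 1.2), ORM = c(34, 14), HT = c(110, 120),
                      CP = c(450, 100), SP = c(340, 110), SSG = c(210, 9))

#' Simulate a community count table with planted structure
#'
#' Generative model: a baseline taxon profile is drawn from a Dirichlet
#' distribution with concentration `base_concentration`; each environmental
#' factor shifts the latent log-abundances by
#' `effect_size x standardized factor x per-taxon loading` (loadings are
#' standard normal); small log-normal idiosyncratic noise (sd 0.2) is
#' added; per-sample counts are multinomial draws of `depth` reads from the
#' softmax of the latent log-abundances.  The compound concentration is a
#' positively weighted sum of the tracking taxa's realized relative
#' abundances, blended with Gaussian noise according to
#' `tracking_strength`/`noise_sd` and rescaled linearly into a positive
#' percent range (0.2-0.9%).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `community_sim` with elements `counts` (a
#'   [count_table()] of unit counts), `env` (an [env_table()] in natural
#'   units), `compound` (named vector, percent), and `truth` (tracking taxon
#'   ids and weights, per-factor loadings, effect sizes, seed).
#' @export
simulate_community <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("'cfg' must be a sim_config")
  withr::with_seed(cfg$seed, {
    samples <- sprintf("S%02d", seq_len(cfg$n_samples))
    taxa <- sprintf("taxon%03d", seq_len(cfg$n_taxa))
    factors <- names(cfg$env_effect_sizes)

    # environmental factors: latent standard normal, reported in natural units
    z <- matrix(stats::rnorm(cfg$n_samples * length(factors)),
                cfg$n_samples, length(factors),
                dimnames = list(samples, factors))
    env_nat <- z
    for (f in factors) {
      u <- .factor_units[[f]]
      if (!is.null(u)) env_nat[, f] <- u[1] + u[2] * z[, f]
    }

    # baseline profile: symmetric Dirichlet via gamma draws
    g <- stats::rgamma(cfg$n_taxa, shape = cfg$base_concentration)
    g[g <= 0] <- min(g[g > 0], 1e-12)
    base_p <- g / sum(g)

    # latent log-abundance with environmental shifts and biological noise
    loadings <- matrix(stats::rnorm(length(factors) * cfg$n_taxa),
                       length(factors), cfg$n_taxa,
                       dimnames = list(factors, taxa))
    shift <- z %*% (cfg$env_effect_sizes * loadings)
    # tracking taxa co-vary through a shared latent driver, the abundance
    # signal the compound concentration follows
    tracking_idx <- sample.int(cfg$n_taxa, cfg$n_tracking_taxa)
    driver <- stats::rnorm(cfg$n_samples)
    driver_load <- rep(0, cfg$n_taxa)
    driver_load[tracking_idx] <- 1.5
    log_lambda <- matrix(log(base_p), cfg$n_samples, cfg$n_taxa,
                         byrow = TRUE) + shift + outer(driver, driver_load) +
      matrix(stats::rnorm(cfg$n_samples * cfg$n_taxa, sd = 0.2),
             cfg$n_samples, cfg$n_taxa)

    probs <- exp(log_lambda - apply(log_lambda, 1, max))
    probs <- probs / rowSums(probs)
    counts <- t(apply(probs, 1, function(p)
      stats::rmultinom(1, size = cfg$depth, prob = p)[, 1]))
    dimnames(counts) <- list(samples, taxa)

    # compound tracks the realized relative abundance of the tracking taxa
    tracking <- taxa[tracking_idx]
    weights <- stats::runif(cfg$n_tracking_taxa, 0.5, 1)
    names(weights) <- tracking
    rel <- counts / rowSums(counts)
    signal <- as.numeric(rel[, tracking, drop = FALSE] %*% weights)
    # shape-preserving blend: tracking_strength interpolates between the
    # tracking taxa's profile (normalized to mean 1) and a flat profile, so
    # at strength 1 / zero noise the compound is exactly proportional to the
    # weighted tracking abundance; the final rescale is multiplicative
    # (shape-preserving), landing in a realistic percent range
    shape <- if (mean(signal) > 0) signal / mean(signal) else rep(1, cfg$n_samples)
    compound <- cfg$tracking_strength * shape + (1 - cfg$tracking_strength) +
      stats::rnorm(cfg$n_samples, sd = cfg$noise_sd)
    compound <- pmax(compound, 1e-3) * 0.4
    names(compound) <- samples

    structure(list(
      counts = count_table(counts, unit = "counts"),
      env = env_table(env_nat),
      compound = compound,
      truth = list(tracking_taxa = tracking, tracking_weights = weights,
                   env_loadings = loadings,
                   effect_sizes = cfg$env_effect_sizes,
                   base_profile = stats::setNames(base_p, taxa),
                   seed = cfg$seed)), class = "community_sim")
  })
}

#' Simulate a random coalescent tree over given taxa
#'
#' A rooted, binary, ultrametric coalescent topology
#' (via [ape::rcoal()]) with positive branch lengths, for exercising the
#' UniFrac path without real sequence data.
#'
#' @param taxon_ids Character vector of at least 2 leaf names.
#' @param seed Integer seed.
#' @return An [ape::phylo] tree with `length(taxon_ids)` leaves.
#' @export
simulate_tree <- function(taxon_ids, seed = 1) {
  if (length(taxon_ids) < 2) stop("at least 2 taxa are required")
  if (anyDuplicated(taxon_ids)) stop("taxon ids must be unique")
  withr::with_seed(as.integer(seed),
                   ape::rcoal(length(taxon_ids), tip.label = taxon_ids))
}

#' Simulate a community along an explicit ecological gradient
#'
#' Samples are placed evenly along a one-dimensional gradient and taxa
#' respond unimodally (Gaussian response curves with optima spread along
#' the gradient).  `turnover` controls beta diversity: it is the gradient
#' length in units of the species' tolerance, so small values give nearly
#' linear (short-gradient) responses and large values give complete species
#' turnover (long gradient).  Useful for exercising the DCA gradient-length
#' gate.
#'
#' @param n_samples,n_taxa Community dimensions.
#' @param turnover Gradient length in tolerance units (e.g. 1 = short
#'   gradient, 10 = long gradient with full turnover).
#' @param depth Reads per sample.
#' @param seed Integer seed.
#' @return A [count_table()] of counts.
#' @export
simulate_gradient <- function(n_samples = 12, n_taxa = 30, turnover = 10,
                              depth = 5000, seed = 1) {
  if (n_samples < 3 || n_taxa < 3) stop("need at least 3 samples and 3 taxa")
  if (turnover <= 0) stop("'turnover' must be positive")
  withr::with_seed(as.integer(seed), {
    grad <- seq(0, turnover, length.out = n_samples)
    optima <- stats::runif(n_taxa, 0, turnover)
    mu <- outer(grad, optima, function(g, o) exp(-(g - o)^2 / 2))
    mu <- mu + 1e-6  # keep every taxon observable
    counts <- t(apply(mu, 1, function(p)
      stats::rmultinom(1, size = depth, prob = p)[, 1]))
    dimnames(counts) <- list(sprintf("S%02d", seq_len(n_samples)),
                             sprintf("taxon%03d", seq_len(n_taxa)))
    # drop taxa never observed so downstream CA preconditions hold
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    count_table(counts, unit = "counts")
  })
}
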