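# Shared fixtures, built in code.

trait_set <- c("height", "leaf_area", "sla")

# noise-free generator: plastic signal only, everything else switched off
noise_free_params <- function(plastic = c(low = 2, mid = 1, high = 0),
                              seed = 1) {
  sim_params(
    trait_names = "height",
    transforms = c(height = "sqrt"),
    grand_mean = c(height = 8),
    plastic_effect = list(height = plastic),
    genetic_effect = zero_effects("height"),
    transect_effect = c(height = 0),
    block_sd = c(height = 0),
    residual_sd = c(height = 0),
    covariate_slope = c(height = 0),
    init_biomass_sd = 0.1,
    fitness_noise_sd = 0,
    seed = seed
  )
}

# the hand-computed two-site toy community (fixed means declared as (10, 20))
toy_community <- function() {
  community_dataset(
    sites = data.frame(site = c("s1", "s2"), gradient = c(0, 1)),
    abundance = rbind(c(0.8, 0.2), c(0.2, 0.8)),
    traits = list(trait = rbind(c(10, 18), c(12, 20)))
  )
}
toy_fixed_means <- c(10, 20)

# small random community for property checks
random_community <- function(seed, n_sites = 8, n_species = 4) {
  set.seed(seed)
  sites <- data.frame(site = sprintf("s%02d", 1:n_sites),
                      gradient = sort(runif(n_sites, 0, 100)))
  p <- matrix(runif(n_sites * n_species, 0.05, 1), n_sites, n_species)
  x <- matrix(rnorm(n_sites * n_species, 20, 4), n_sites, n_species)
  suppressWarnings(community_dataset(sites, p, list(trait = x)))
}

# six-site dataset whose fitness peaks at a CWM displaced from the
# population mean; used for the optimality consistency checks
optimality_study <- function(noise_sd, seed = 7, n_per_site = 100) {
  set.seed(seed)
  traits <- c("t1", "t2", "t3")
  offsets <- c(1.5, -1.5, 2)           # CWM minus population mean
  records <- NULL
  cwm <- NULL
  for (s in paste0("site", 1:6)) {
    X <- sapply(1:3, function(j) rnorm(n_per_site, mean = 10 * j, sd = 2))
    colnames(X) <- traits
    cw <- 10 * (1:3) + offsets
    W <- exp(-rowSums(sweep(X, 2, cw)^2) / 18) * exp(rnorm(n_per_site, 0, noise_sd))
    records <- rbind(records, data.frame(X, final_biomass = W, transect = s,
                                         elevation_transplant = "low"))
    cwm <- rbind(cwm, data.frame(site = paste0(s, ":low"), trait = traits,
                                 cwm = cw))
  }
  list(records = records, cwm = cwm, traits = traits)
}
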