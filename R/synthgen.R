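# Synthetic reciprocal-transplant and community generators.
#
# The transplant generator mirrors the two-transect x three-elevation design
# in which individuals from every origin elevation are planted back at all
# three elevations of their own transect, split over four blocks per site
# with seven individuals per origin per block (504 records in total).
# Traits are generated additively on the transformed analysis scale
# (sqrt for height, log for leaf area and SLA) and back-transformed, so a
# linear model on the transformed scale sees an exactly additive signal and
# parameter recovery is well-posed.

#' Reciprocal transplant design specification
#'
#' Describes the crossed transplant grid: a set of transects, an ordered set
#' of elevations (each with a nominal altitude in metres), the number of
#' blocks at each transplant site and the number of individuals per origin
#' within each block. Individuals are only moved within their transect of
#' origin, so the design has one site per (transect, transplant elevation)
#' pair and every block contains individuals from all origins.
#'
#' @param transects Character vector of transect labels.
#' @param elevations Named numeric vector of elevations; names are the factor
#'   labels (in gradient order) and values the altitudes in metres a.s.l.
#' @param blocks_per_site Number of blocks at each transplant site.
#' @param individuals_per_origin_per_block Individuals from each origin
#'   elevation planted in each block.
#' @return An object of class `design_spec` with an `n_total` element giving
#'   the implied number of experimental individuals.
#' @examples
#' d <- design_spec()
#' d$n_total  # 2 transects x 3 origins x 3 transplants x 4 blocks x 7 = 504
#' @export
design_spec <- function(transects = c("south", "north"),
                        elevations = c(low = 715, mid = 870, high = 1040),
                        blocks_per_site = 4,
                        individuals_per_origin_per_block = 7) {
  if (length(transects) < 1 || anyDuplicated(transects))
    .stopf("`transects` must be a non-empty set of unique labels")
  if (is.null(names(elevations)) || any(!nzchar(names(elevations))) ||
      anyDuplicated(names(elevations)) || length(elevations) < 2)
    .stopf("`elevations` must be a named numeric vector of >= 2 unique labels")
  if (blocks_per_site < 1 || individuals_per_origin_per_block < 1)
    .stopf("block and individual counts must be positive")
  k <- length(elevations)
  out <- list(
    transects = as.character(transects),
    elevations = elevations,
    blocks_per_site = as.integer(blocks_per_site),
    individuals_per_origin_per_block = as.integer(individuals_per_origin_per_block),
    n_total = length(transects) * k * k * as.integer(blocks_per_site) *
      as.integer(individuals_per_origin_per_block)
  )
  class(out) <- "design_spec"
  out
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Reciprocal transplant design\n")
  cat("  transects:  ", paste(x$transects, collapse = ", "), "\n")
  cat("  elevations: ",
      paste(sprintf("%s (%g m)", names(x$elevations), x$elevations),
            collapse = ", "), "\n")
  cat("  blocks/site:", x$blocks_per_site,
      " individuals/origin/block:", x$individuals_per_origin_per_block, "\n")
  cat("  total individuals:", x$n_total, "\n")
  invisible(x)
}

#' Zero effect tables for a set of traits
#'
#' Convenience constructor for all-zero per-elevation effect tables, used to
#' switch off the plastic or genetic component of the generator.
#'
#' @param trait_names Character vector of trait names.
#' @param levels Elevation labels (default low/mid/high).
#' @return Named list, one zero vector per trait.
#' @export
zero_effects <- function(trait_names, levels = .elev_levels) {
  stats::setNames(
    lapply(trait_names, function(t) stats::setNames(rep(0, length(levels)), levels)),
    trait_names
  )
}

.default_plastic <- function(levels, residual_sd) {
  # low -> high decline spanning one residual SD (traits shrink upslope)
  lapply(residual_sd, function(s) {
    stats::setNames(0.5 * s * seq(1, -1, length.out = length(levels)), levels)
  })
}

.default_genetic <- function(levels, residual_sd) {
  lapply(residual_sd, function(s) {
    stats::setNames(0.3 * s * seq(1, -1, length.out = length(levels)), levels)
  })
}

#' Simulation parameters for the synthetic transplant study
#'
#' Bundles the design grid with every generative effect size. Traits are
#' built on the transformed analysis scale as
#' grand mean + plastic effect (transplant elevation) + genetic effect
#' (origin elevation) + GxE + transect deviation + block deviate +
#' covariate slope x (initial biomass - mean) + residual noise,
#' then back-transformed to the raw measurement scale. Survival is Bernoulli
#' on a logistic scale; final dry biomass of survivors is lognormal in the
#' within-site standardized traits, so the true directional selection
#' gradients are known by construction.
#'
#' Default magnitudes: residual SDs are realistic for a small understory herb
#' measured on sqrt-mm (height) and log (leaf area mm^2, SLA mm^2/mg) scales;
#' the plastic low-to-high span is one residual SD and the genetic span 0.6
#' residual SD, so plasticity dominates the elevation signal (expected
#' plasticity share around 73%) without drowning the genetic component.
#'
#' @param design A [design_spec()].
#' @param trait_names Traits to generate.
#' @param transforms Named map trait -> one of `"sqrt"`, `"log"`,
#'   `"identity"`; the generator builds traits on this transformed scale and
#'   returns raw values through the inverse transform.
#' @param grand_mean Named per-trait grand means on the transformed scale.
#' @param plastic_effect,genetic_effect Named list per trait of per-elevation
#'   effects (transformed-trait units); `plastic_effect` is indexed by the
#'   elevation of transplant, `genetic_effect` by the elevation of origin.
#' @param gxe_effect Optional named list per trait of origin x transplant
#'   matrices (default all zero).
#' @param transect_effect Named per-trait transect contrast; the first
#'   transect gets +effect/2, the second -effect/2.
#' @param block_sd,residual_sd Named per-trait standard deviations of the
#'   block deviates and residual noise (transformed scale); non-negative,
#'   `residual_sd` strictly positive unless you want a noise-free limit.
#' @param init_biomass_mean,init_biomass_sd Initial dry biomass distribution
#'   (grams); values are truncated to stay positive.
#' @param covariate_slope Named per-trait slope of the transformed trait on
#'   centred initial biomass.
#' @param survival_logit List with `intercept` plus optional named
#'   per-elevation offsets `transplant` and `origin` and an
#'   origin x transplant `interaction` matrix, all on the logit scale.
#' @param fitness_beta Named per-trait true selection gradients on the
#'   within-site standardized transformed traits.
#' @param fitness_mean_biomass Median final dry biomass of survivors (g).
#' @param fitness_noise_sd SD of lognormal fitness noise.
#' @param transplant_shock Fraction of individuals lost to transplant shock
#'   and removed before any records are returned (default 0).
#' @param missing_rate Named per-trait probability that a trait measurement
#'   is missing completely at random (default 0), to exercise
#'   unbalanced-design code paths.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(design = design_spec(),
                       trait_names = c("height", "leaf_area", "sla"),
                       transforms = c(height = "sqrt", leaf_area = "log",
                                      sla = "log"),
                       grand_mean = c(height = 7.7, leaf_area = 5.7, sla = 3.2),
                       residual_sd = c(height = 1.0, leaf_area = 0.52,
                                       sla = 0.19),
                       plastic_effect = NULL,
                       genetic_effect = NULL,
                       gxe_effect = NULL,
                       transect_effect = c(height = 0.35, leaf_area = 0,
                                           sla = 0),
                       block_sd = c(height = 0.25, leaf_area = 0.12,
                                    sla = 0.05),
                       init_biomass_mean = 0.4,
                       init_biomass_sd = 0.1,
                       covariate_slope = c(height = 0.2, leaf_area = 0.15,
                                           sla = 0.05),
                       survival_logit = list(
                         intercept = 1.4,
                         transplant = c(low = -0.3, mid = 0.5, high = -0.3)
                       ),
                       fitness_beta = c(height = 0.15, leaf_area = 0.45,
                                        sla = -0.15),
                       fitness_mean_biomass = 0.5,
                       fitness_noise_sd = 0.4,
                       transplant_shock = 0,
                       missing_rate = NULL,
                       seed = 1L) {
  levels <- names(design$elevations)
  trait_names <- as.character(trait_names)

  # per-trait defaults are written for the standard trait set; restrict them
  # to the requested traits so custom trait lists inherit sensible values
  sub <- function(x) x[intersect(names(x), trait_names)]
  if (missing(grand_mean)) grand_mean <- sub(grand_mean)
  if (missing(residual_sd)) residual_sd <- sub(residual_sd)
  if (missing(transforms)) transforms <- sub(transforms)
  if (missing(transect_effect)) transect_effect <- sub(transect_effect)
  if (missing(block_sd)) block_sd <- sub(block_sd)
  if (missing(covariate_slope)) covariate_slope <- sub(covariate_slope)
  if (missing(fitness_beta)) fitness_beta <- sub(fitness_beta)

  grand_mean <- .complete_named(grand_mean, trait_names, "grand_mean")
  residual_sd <- .complete_named(residual_sd, trait_names, "residual_sd")
  transect_effect <- .complete_named(transect_effect, trait_names,
                                     "transect_effect", default = 0)
  block_sd <- .complete_named(block_sd, trait_names, "block_sd", default = 0)
  covariate_slope <- .complete_named(covariate_slope, trait_names,
                                     "covariate_slope", default = 0)
  fitness_beta <- .complete_named(fitness_beta, trait_names, "fitness_beta",
                                  default = 0)
  transforms <- .complete_named(transforms, trait_names, "transforms",
                                default = "identity", numeric = FALSE)
  if (!all(transforms %in% c("sqrt", "log", "identity")))
    .stopf("transforms must be 'sqrt', 'log' or 'identity'")

  plastic_effect <- .complete_effects(
    plastic_effect %||% .default_plastic(levels, residual_sd)[trait_names],
    trait_names, levels, "plastic_effect")
  genetic_effect <- .complete_effects(
    genetic_effect %||% .default_genetic(levels, residual_sd)[trait_names],
    trait_names, levels, "genetic_effect")
  gxe_effect <- .complete_gxe(gxe_effect, trait_names, levels)

  if (any(residual_sd < 0) || any(block_sd < 0))
    .stopf("standard deviations must be non-negative")
  if (!all(is.finite(c(unlist(plastic_effect), unlist(genetic_effect),
                       unlist(gxe_effect), grand_mean, residual_sd, block_sd,
                       transect_effect, covariate_slope, fitness_beta))))
    .stopf("all effect parameters must be finite")
  if (init_biomass_mean <= 0 || init_biomass_sd < 0)
    .stopf("initial biomass parameters must be positive")
  if (fitness_noise_sd < 0) .stopf("fitness_noise_sd must be non-negative")
  if (transplant_shock < 0 || transplant_shock >= 1)
    .stopf("transplant_shock must be in [0, 1)")

  missing_rate <- .complete_named(missing_rate %||% numeric(0), trait_names,
                                  "missing_rate", default = 0)
  if (any(missing_rate < 0 | missing_rate >= 1))
    .stopf("missing_rate must be in [0, 1)")

  sl <- survival_logit
  if (is.null(sl$intercept) || !is.finite(sl$intercept))
    .stopf("survival_logit$intercept is required and must be finite")
  sl$transplant <- .complete_named(sl$transplant %||% numeric(0), levels,
                                   "survival_logit$transplant", default = 0)
  sl$origin <- .complete_named(sl$origin %||% numeric(0), levels,
                               "survival_logit$origin", default = 0)
  if (is.null(sl$interaction)) {
    sl$interaction <- matrix(0, length(levels), length(levels),
                             dimnames = list(levels, levels))
  }

  out <- list(design = design, trait_names = trait_names,
              transforms = transforms, grand_mean = grand_mean,
              plastic_effect = plastic_effect, genetic_effect = genetic_effect,
              gxe_effect = gxe_effect, transect_effect = transect_effect,
              block_sd = block_sd, residual_sd = residual_sd,
              init_biomass_mean = init_biomass_mean,
              init_biomass_sd = init_biomass_sd,
              covariate_slope = covariate_slope, survival_logit = sl,
              fitness_beta = fitness_beta,
              fitness_mean_biomass = fitness_mean_biomass,
              fitness_noise_sd = fitness_noise_sd,
              transplant_shock = transplant_shock,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(out) <- "sim_params"
  out
}

.complete_named <- function(x, nms, what, default = NULL, numeric = TRUE) {
  if (is.list(x)) x <- unlist(x)
  out <- stats::setNames(rep(if (is.null(default)) NA else default,
                             length(nms)), nms)
  if (length(x)) {
    if (is.null(names(x))) {
      if (length(x) == 1) x <- stats::setNames(rep(x, length(nms)), nms)
      else if (length(x) == length(nms)) names(x) <- nms
      else .stopf("`%s` must be named or match the trait set", what)
    }
    bad <- setdiff(names(x), nms)
    if (length(bad)) .stopf("`%s` has unknown entries: %s", what,
                            paste(bad, collapse = ", "))
    out[names(x)] <- x
  }
  if (anyNA(out) && is.null(default))
    .stopf("`%s` is incomplete: missing %s", what,
           paste(nms[is.na(out)], collapse = ", "))
  if (numeric) storage.mode(out) <- "double"
  out
}

.complete_effects <- function(x, traits, levels, what) {
  if (!is.list(x)) .stopf("`%s` must be a list of per-trait effect vectors", what)
  miss <- setdiff(traits, names(x))
  if (length(miss)) .stopf("`%s` missing traits: %s", what,
                           paste(miss, collapse = ", "))
  out <- lapply(traits, function(tr) {
    v <- .complete_named(x[[tr]], levels, paste0(what, "$", tr))
    v
  })
  stats::setNames(out, traits)
}

.complete_gxe <- function(x, traits, levels) {
  k <- length(levels)
  zero <- matrix(0, k, k, dimnames = list(levels, levels))
  if (is.null(x)) return(stats::setNames(rep(list(zero), length(traits)), traits))
  out <- stats::setNames(rep(list(zero), length(traits)), traits)
  for (tr in names(x)) {
    if (!tr %in% traits) .stopf("gxe_effect has unknown trait '%s'", tr)
    m <- x[[tr]]
    if (!is.matrix(m) || !identical(dim(m), c(k, k)))
      .stopf("gxe_effect$%s must be a %d x %d origin x transplant matrix",
             tr, k, k)
    dimnames(m) <- list(levels, levels)
    out[[tr]] <- m
  }
  out
}

.fwd_transform <- function(x, how) {
  switch(how, sqrt = sqrt(x), log = log(x), identity = x)
}

.inv_transform <- function(x, how) {
  switch(how, sqrt = x^2, log = exp(x), identity = x)
}

#' Simulate a reciprocal transplant experiment
#'
#' Draws one full synthetic transplant study under a [sim_params()]
#' specification: one row per planted individual, with design factors,
#' initial-biomass covariate, raw-scale trait measurements, summer survival
#' and final dry biomass (present only for survivors).
#'
#' @param params A [sim_params()] object.
#' @return A data.frame of transplant records with columns `individual_id`,
#'   `transect`, `elevation_origin`, `elevation_transplant`, `block`,
#'   `init_biomass`, `survived`, `final_biomass` and one column per trait.
#'   The generating parameters are attached as attribute `"params"`.
#' @examples
#' rec <- simulate_transplant(sim_params(seed = 42))
#' nrow(rec)  # 504
#' @export
simulate_transplant <- function(params) {
  if (!inherits(params, "sim_params")) .stopf("`params` must be a sim_params object")
  d <- params$design
  levels <- names(d$elevations)
  set.seed(params$seed)

  grid <- expand.grid(
    ind = seq_len(d$individuals_per_origin_per_block),
    elevation_origin = factor(levels, levels = levels),
    block = seq_len(d$blocks_per_site),
    elevation_transplant = factor(levels, levels = levels),
    transect = factor(d$transects, levels = d$transects),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  stopifnot(n == d$n_total)

  rec <- data.frame(
    individual_id = sprintf("ind%04d", seq_len(n)),
    transect = grid$transect,
    elevation_origin = grid$elevation_origin,
    elevation_transplant = grid$elevation_transplant,
    block = as.integer(grid$block),
    stringsAsFactors = FALSE
  )

  ib <- rnorm(n, params$init_biomass_mean, params$init_biomass_sd)
  ib <- pmax(ib, 0.05 * params$init_biomass_mean)  # keep biomass positive
  rec$init_biomass <- ib

  # block deviates, one per (transect, transplant site, block, trait)
  blocks <- unique(rec[c("transect", "elevation_transplant", "block")])
  blocks$key <- do.call(paste, c(blocks, sep = "."))
  reckey <- paste(rec$transect, rec$elevation_transplant, rec$block, sep = ".")

  tvals <- matrix(NA_real_, n, length(params$trait_names),
                  dimnames = list(NULL, params$trait_names))
  for (tr in params$trait_names) {
    bdev <- stats::setNames(rnorm(nrow(blocks), 0, params$block_sd[[tr]]),
                            blocks$key)
    tdev <- ifelse(rec$transect == d$transects[1], 0.5, -0.5) *
      params$transect_effect[[tr]]
    mu <- params$grand_mean[[tr]] +
      params$plastic_effect[[tr]][as.character(rec$elevation_transplant)] +
      params$genetic_effect[[tr]][as.character(rec$elevation_origin)] +
      params$gxe_effect[[tr]][cbind(as.character(rec$elevation_origin),
                                    as.character(rec$elevation_transplant))] +
      tdev + bdev[reckey] +
      params$covariate_slope[[tr]] * (ib - params$init_biomass_mean)
    tvals[, tr] <- mu + rnorm(n, 0, params$residual_sd[[tr]])
  }

  # survival on the logit scale
  sl <- params$survival_logit
  eta <- sl$intercept +
    sl$transplant[as.character(rec$elevation_transplant)] +
    sl$origin[as.character(rec$elevation_origin)] +
    sl$interaction[cbind(as.character(rec$elevation_origin),
                         as.character(rec$elevation_transplant))]
  rec$survived <- rbinom(n, 1, plogis(eta)) == 1

  # lognormal fitness of survivors: true selection gradients on within-site
  # standardized transformed traits are fitness_beta by construction
  site <- interaction(rec$transect, rec$elevation_transplant, drop = TRUE)
  z <- tvals
  for (s in levels(site)) {
    i <- site == s
    for (tr in params$trait_names) {
      sdv <- sd(tvals[i, tr])
      z[i, tr] <- if (is.na(sdv) || sdv == 0) 0 else
        (tvals[i, tr] - mean(tvals[i, tr])) / sdv
    }
  }
  logw <- log(params$fitness_mean_biomass) +
    drop(z %*% params$fitness_beta[params$trait_names]) +
    rnorm(n, 0, params$fitness_noise_sd)
  rec$final_biomass <- ifelse(rec$survived, exp(logw), NA_real_)

  # raw-scale traits, with optional MCAR missingness per trait
  for (tr in params$trait_names) {
    raw <- .inv_transform(tvals[, tr], params$transforms[[tr]])
    mr <- params$missing_rate[[tr]]
    if (mr > 0) raw[stats::runif(n) < mr] <- NA_real_
    rec[[tr]] <- raw
  }

  if (params$transplant_shock > 0) {
    keep <- stats::runif(n) >= params$transplant_shock
    rec <- rec[keep, , drop = FALSE]
    rownames(rec) <- NULL
  }

  attr(rec, "params") <- params
  rec
}

#' Simulate a community dataset along a gradient
#'
#' Builds site-by-species relative abundances from Gaussian niche responses
#' to a numeric gradient (or a user abundance model) and site-specific
#' species trait values with linear intraspecific trends, so that the
#' community-weighted-mean decomposition downstream has a known ground
#' truth: with `itv_slopes = 0` and `noise_sd = 0` all intraspecific
#' variation vanishes.
#'
#' @param n_sites Number of sites (>= 3 for downstream regression).
#' @param species_pool Character vector of species names, or a species count.
#' @param gradient Numeric gradient positions of the sites (default evenly
#'   spaced elevations 715..1040 m).
#' @param species_means Per-species gradient-wide mean trait values.
#' @param itv_slopes Per-species linear trait response to the centred
#'   gradient (trait units per gradient unit).
#' @param abundance_model Either `"gaussian"` (niche optima spread along the
#'   gradient, common breadth `niche_breadth`) or a function
#'   `f(gradient, species)` returning a sites x species non-negative weight
#'   matrix.
#' @param niche_breadth Niche width (gradient units) for the Gaussian model.
#' @param noise_sd SD of site-level trait noise around the intraspecific
#'   trend.
#' @param trait_name Name of the generated trait.
#' @param seed Integer seed.
#' @return A [community_dataset()]; generating species means are attached as
#'   attribute `"true_means"`.
#' @export
simulate_community <- function(n_sites = 10,
                               species_pool = 5,
                               gradient = seq(715, 1040, length.out = n_sites),
                               species_means = NULL,
                               itv_slopes = 0,
                               abundance_model = "gaussian",
                               niche_breadth = NULL,
                               noise_sd = 0.5,
                               trait_name = "trait",
                               seed = 1L) {
  if (n_sites < 3) .stopf("`n_sites` must be >= 3")
  if (is.numeric(species_pool) && length(species_pool) == 1)
    species_pool <- sprintf("sp%02d", seq_len(species_pool))
  if (!length(species_pool)) .stopf("`species_pool` must be non-empty")
  ns <- length(species_pool)
  if (length(gradient) != n_sites) .stopf("`gradient` must have one value per site")
  set.seed(as.integer(seed))

  rng <- range(gradient)
  species_means <- species_means %||% seq(10, 30, length.out = ns)
  species_means <- rep_len(species_means, ns)
  itv_slopes <- rep_len(itv_slopes, ns)

  if (is.function(abundance_model)) {
    w <- abundance_model(gradient, species_pool)
    w <- as.matrix(w)
    if (!all(dim(w) == c(n_sites, ns)))
      .stopf("abundance_model must return a %d x %d matrix", n_sites, ns)
  } else if (identical(abundance_model, "gaussian")) {
    breadth <- niche_breadth %||% (diff(rng) / 2)
    optima <- if (ns == 1) mean(rng) else seq(rng[1], rng[2], length.out = ns)
    w <- outer(gradient, optima, function(g, o) exp(-(g - o)^2 / (2 * breadth^2)))
  } else .stopf("unknown abundance model")
  if (any(w < 0)) .stopf("abundance model produced negative weights")
  rs <- rowSums(w)
  if (any(rs == 0))
    .stopf("all-zero abundance row at site(s) %s: cannot renormalize",
           paste(which(rs == 0), collapse = ", "))
  p <- sweep(w, 1, rs, "/")

  gc <- gradient - mean(gradient)
  x <- outer(rep(1, n_sites), species_means) +
    outer(gc, itv_slopes) +
    matrix(rnorm(n_sites * ns, 0, noise_sd), n_sites, ns)

  sites <- data.frame(site = sprintf("site%02d", seq_len(n_sites)),
                      gradient = gradient, stringsAsFactors = FALSE)
  dimnames(p) <- dimnames(x) <- list(sites$site, species_pool)
  out <- community_dataset(sites, p, stats::setNames(list(x), trait_name))
  attr(out, "true_means") <- stats::setNames(species_means, species_pool)
  out
}
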