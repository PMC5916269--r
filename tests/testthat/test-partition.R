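test_that("trait transforms are applied and domain violations are named", {
  d <- data.frame(individual_id = c("a", "b", "c"),
                  height = c(16, 4, 0), sla = c(1, 2, 4))
  out <- apply_transform(d, c(height = "sqrt", sla = "log"))
  expect_equal(out$height_t, c(4, 2, 0))
  expect_equal(out$sla_t, log(c(1, 2, 4)))
  expect_equal(out$height, d$height)  # originals untouched

  d$leaf_area <- c(3, 0, 5)
  expect_error(apply_transform(d, c(leaf_area = "log")), "b")
  d$height[1] <- -1
  expect_error(apply_transform(d, c(height = "sqrt")), "a")
})

test_that("noise-free plastic-only data is fitted exactly", {
  rec <- apply_transform(simulate_transplant(noise_free_params()))
  fit <- fit_trait_model(rec, "height_t")
  tab <- type3_anova(fit)
  expect_lt(tab$ss[tab$term == "Residuals"], 1e-20)
  expect_lt(tab$ss[tab$term == "elevation_origin"], 1e-20)
  # sum-to-zero EL_T coefficients reproduce the centred plastic effects
  cf <- coef(fit$lm)
  centred <- c(low = 2, mid = 1, high = 0) - 1
  expect_equal(unname(cf[["elevation_transplant1"]]), centred[["low"]],
               tolerance = 1e-10)
  expect_equal(unname(cf[["elevation_transplant2"]]), centred[["mid"]],
               tolerance = 1e-10)
})

test_that("constant response gives zero effects and zero residual SS", {
  rec <- simulate_transplant(noise_free_params())
  rec$flat <- 3
  fit <- fit_trait_model(rec, "flat", covariate = NULL)
  cf <- coef(fit$lm)
  expect_equal(unname(cf[1]), 3)
  expect_true(all(abs(cf[-1]) < 1e-12))
  expect_lt(sum(resid(fit$lm)^2), 1e-20)
})

test_that("single-transect data drops the transect term with a warning", {
  rec <- apply_transform(simulate_transplant(sim_params(seed = 8)))
  rec <- rec[rec$transect == "south", ]
  expect_warning(fit <- fit_trait_model(rec, "height_t"), "transect")
  expect_false("transect" %in% fit$terms)
  expect_s3_class(type3_anova(fit), "anova_table")
})

test_that("type III equals sequential SS on balanced designs", {
  # factorial part only: a sampled covariate is never orthogonal
  rec <- apply_transform(simulate_transplant(sim_params(seed = 21)))
  fit <- fit_trait_model(rec, "leaf_area_t", covariate = NULL)
  t3 <- type3_anova(fit)
  seq_tab <- anova(fit$lm)  # sequential (type I) oracle
  for (term in setdiff(t3$term, "Residuals")) {
    expect_equal(t3$ss[t3$term == term],
                 seq_tab[term, "Sum Sq"], tolerance = 1e-8,
                 label = paste("type III SS for", term))
  }
})

test_that("type III matches the car::Anova oracle on unbalanced data", {
  skip_if_not_installed("car")
  rec <- apply_transform(simulate_transplant(
    sim_params(missing_rate = c(height = 0.15), seed = 33)))
  fit <- fit_trait_model(rec, "height_t")
  t3 <- type3_anova(fit)
  oracle <- car::Anova(fit$lm, type = 3)
  for (term in setdiff(t3$term, "Residuals")) {
    expect_equal(t3$ss[t3$term == term], oracle[term, "Sum Sq"],
                 tolerance = 1e-8, label = paste("marginal SS for", term))
  }
  # sequential conservation: type I SS + residual = total SS
  seq_tab <- anova(fit$lm)
  y <- rec$height_t[!is.na(rec$height_t) & !is.na(rec$init_biomass)]
  expect_equal(sum(seq_tab[, "Sum Sq"]), sum((y - mean(y))^2),
               tolerance = 1e-8)
})

test_that("single-factor model reduces to one-way ANOVA", {
  set.seed(14)
  d <- expand.grid(elevation_origin = c("low", "mid", "high"),
                   elevation_transplant = c("low", "mid", "high"),
                   rep = 1:7, stringsAsFactors = FALSE)
  d$transect <- "south"; d$block <- 1
  d$y <- rnorm(nrow(d)) + as.numeric(factor(d$elevation_origin))
  suppressWarnings(fit <- fit_trait_model(d, "y", covariate = NULL,
                                          include_interaction = FALSE))
  t3 <- type3_anova(fit)
  # balanced, so the marginal SS is the classical one-way between-group SS
  ow <- anova(lm(y ~ elevation_origin, data = d))
  expect_equal(t3$ss[t3$term == "elevation_origin"],
               ow["elevation_origin", "Sum Sq"], tolerance = 1e-8)
})

test_that("plasticity share behaves at the boundaries and under rescaling", {
  expect_equal(plasticity_share(3, 1), 75)
  expect_true(is.na(plasticity_share(0, 0)))
  expect_error(plasticity_share(-1, 2), "non-negative")
  # ratio invariant to response rescaling (SS scale cancels)
  rec <- apply_transform(simulate_transplant(sim_params(seed = 3)))
  f1 <- percent_plasticity(type3_anova(fit_trait_model(rec, "height_t")))
  rec$height_s <- rec$height_t * 10
  f2 <- percent_plasticity(type3_anova(fit_trait_model(rec, "height_s")))
  expect_equal(f1$percent_e, f2$percent_e, tolerance = 1e-9)
  expect_equal(f1$percent_e + f1$percent_g, 100)
})

test_that("null-term F tests hold their type I error rate", {
  # genetic effect truly zero; EL_O term should reject at ~5%
  rejections <- vapply(1:200, function(s) {
    rec <- simulate_transplant(sim_params(
      trait_names = "height", transforms = c(height = "identity"),
      grand_mean = c(height = 5),
      plastic_effect = list(height = c(low = 0.5, mid = 0, high = -0.5)),
      genetic_effect = zero_effects("height"),
      transect_effect = c(height = 0.2), block_sd = c(height = 0.2),
      residual_sd = c(height = 1), covariate_slope = c(height = 0.1),
      seed = 1000 + s))
    rec <- apply_transform(rec, c(height = "identity"))
    tab <- type3_anova(fit_trait_model(rec, "height_t"))
    tab$p_value[tab$term == "elevation_origin"] < 0.05
  }, logical(1))
  rate <- mean(rejections)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("survival model recovers a known transplant-elevation effect", {
  p <- sim_params(
    design = design_spec(individuals_per_origin_per_block = 30),  # n = 2160
    survival_logit = list(intercept = 0.5,
                          transplant = c(low = 0.5, mid = 0, high = -0.5)),
    seed = 17)
  rec <- simulate_transplant(p)
  fit <- fit_survival_model(rec)
  tab <- type3_anova(fit)
  expect_equal(attr(tab, "family"), "binomial")
  # sum-to-zero EL_T coefficient estimates the +0.5 low offset
  cf <- summary(fit$lm)$coefficients
  est <- cf["elevation_transplant1", 1]
  se <- cf["elevation_transplant1", 2]
  expect_lt(abs(est - 0.5), 3 * se)
  # the true-null origin term is quiet
  expect_gt(tab$p_value[tab$term == "elevation_origin"], 0.01)
})

test_that("survival separation and degenerate outcomes are flagged", {
  rec <- simulate_transplant(sim_params(seed = 19))
  rec$survived[rec$transect == "south" & rec$elevation_origin == "low" &
                 rec$elevation_transplant == "low"] <- TRUE
  expect_warning(fit_survival_model(rec), "south.low.low")

  rec$survived <- TRUE
  expect_error(fit_survival_model(rec), "same outcome")
})

test_that("lsmeans reproduce noise-free plastic effects and cell structure", {
  rec <- apply_transform(simulate_transplant(noise_free_params()))
  fit <- fit_trait_model(rec, "height_t")
  # zero-residual fit: "essentially perfect fit" warnings are expected
  res <- suppressWarnings(lsmeans_pairwise(fit))
  m <- res$means
  mean_at <- function(elt) mean(m$emmean[m$elevation_transplant == elt])
  expect_equal(mean_at("low") - mean_at("mid"), 1, tolerance = 1e-8)
  expect_equal(mean_at("low") - mean_at("high"), 2, tolerance = 1e-8)
  # no origin differences within any transplant elevation
  for (elt in c("low", "mid", "high")) {
    expect_lt(diff(range(m$emmean[m$elevation_transplant == elt])), 1e-8)
  }
  # contrast estimates are consistent with the cell means (antisymmetric
  # under order swap by construction: estimate(A-B) = mean(A) - mean(B))
  ct <- res$contrasts
  lab <- paste(m$elevation_origin, m$elevation_transplant)
  for (i in seq_len(nrow(ct))) {
    ab <- strsplit(as.character(ct$contrast[i]), " - ")[[1]]
    ab <- gsub("[()]", "", ab)
    expect_equal(ct$estimate[i],
                 m$emmean[lab == ab[1]] - m$emmean[lab == ab[2]],
                 tolerance = 1e-8)
  }
})

test_that("lsmeans equal raw cell means in a balanced design without covariate", {
  rec <- apply_transform(simulate_transplant(sim_params(seed = 23)))
  fit <- fit_trait_model(rec, "sla_t", covariate = NULL)
  m <- lsmeans_pairwise(fit)$means
  raw <- aggregate(sla_t ~ elevation_origin + elevation_transplant, rec, mean)
  mg <- merge(m, raw, by = c("elevation_origin", "elevation_transplant"))
  expect_equal(mg$emmean, mg$sla_t, tolerance = 1e-8)
})

test_that("stepwise initial-biomass selection finds the generating subset", {
  set.seed(5)
  n <- 200
  d <- data.frame(c1 = rnorm(n), c2 = rnorm(n), c3 = rnorm(n),
                  c4 = rnorm(n), c5 = rnorm(n))
  d$final_biomass <- 2 + 1.5 * d$c2 - 0.8 * d$c4 + rnorm(n, 0, 0.05)
  fit <- fit_initial_biomass(d, candidates = paste0("c", 1:5),
                             criterion = "BIC")
  expect_setequal(fit$selected, c("c2", "c4"))
  expect_gt(fit$r_squared, 0.99)
  expect_length(fit$predictions, n)
  # AIC search always keeps the generating pair too
  fit_aic <- fit_initial_biomass(d, candidates = paste0("c", 1:5))
  expect_true(all(c("c2", "c4") %in% fit_aic$selected))

  # a single candidate perfectly collinear with the response
  # ("essentially perfect fit" warnings from the underlying lm are expected)
  d2 <- data.frame(final_biomass = 1:20, x = (1:20) * 2)
  fit2 <- suppressWarnings(fit_initial_biomass(d2, candidates = "x"))
  expect_equal(fit2$selected, "x")
  expect_equal(fit2$r_squared, 1)

  # collinear candidates are reported
  d$c6 <- d$c1
  expect_warning(fit_initial_biomass(d, candidates = paste0("c", 1:6)),
                 "collinear")
})
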