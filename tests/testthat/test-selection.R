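test_that("relative fitness and trait standardization satisfy their identities", {
  expect_equal(relative_fitness(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(relative_fitness(rep(3, 5)), rep(1, 5))
  for (seed in 1:5) {
    set.seed(seed)
    W <- rexp(20)
    expect_equal(mean(relative_fitness(W)), 1, tolerance = 1e-12)
  }
  expect_error(relative_fitness(c(0, 0, 0)), "positive")

  expect_equal(drop(standardize_traits(c(1, 2, 3))), c(-1, 0, 1))
  set.seed(2)
  Z <- standardize_traits(matrix(rnorm(60), 20, 3))
  expect_equal(unname(colMeans(Z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_error(standardize_traits(cbind(a = rep(1, 5), b = 1:5)), "a")
})

test_that("within-site standardization differs from global standardization", {
  x <- c(1, 2, 3, 11, 12, 13)  # two sites with different means
  site1 <- drop(standardize_traits(x[1:3]))
  glob <- drop(standardize_traits(x))[1:3]
  expect_false(isTRUE(all.equal(site1, glob)))
})

test_that("selection differentials match hand-computed covariances", {
  # w = 1 + z: S = var(z) = 1
  set.seed(3)
  z <- drop(standardize_traits(rnorm(30)))
  expect_equal(selection_differential(1 + z, z)$S, 1, tolerance = 1e-12)
  # constant w: S = 0 and the correlation p-value is undefined
  res <- selection_differential(rep(1, 10), z[1:10])
  expect_equal(res$S, 0)
  expect_true(is.na(res$p))
  # frozen hand computation: x = (1,2,3,4), W = (1,1,2,4)
  zh <- drop(standardize_traits(c(1, 2, 3, 4)))
  wh <- relative_fitness(c(1, 1, 2, 4))
  expect_equal(selection_differential(wh, zh)$S, 0.6455, tolerance = 1e-4)
  expect_error(selection_differential(wh[1:2], zh[1:2]), "3 complete pairs")
})

test_that("selection gradients equal the normal-equations solution", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 5 + sample(10, 1)
    Z <- matrix(rnorm(n * 3), n, 3)
    w <- rnorm(n, 1, 0.5)
    g <- selection_gradients(w, Z)
    X <- cbind(1, Z)
    beta_oracle <- solve(t(X) %*% X, t(X) %*% w)  # brute-force oracle
    expect_equal(unname(g$beta), drop(beta_oracle)[-1], tolerance = 1e-10)
  }
})

test_that("orthogonal standardized traits make gradients equal differentials", {
  set.seed(8)
  raw <- qr.Q(qr(matrix(rnorm(80 * 3), 80, 3)))  # exactly orthogonal columns
  Z <- standardize_traits(raw)
  # residual correlation after standardizing is negligible but not exactly 0;
  # orthogonalize once more on the standardized scale
  Z <- standardize_traits(qr.Q(qr(scale(raw, scale = FALSE))))
  w <- relative_fitness(exp(0.3 * Z[, 1] - 0.2 * Z[, 2] + rnorm(80, 0, 0.2)))
  g <- selection_gradients(w, Z)
  S <- apply(Z, 2, function(z) cov(w, z))
  expect_equal(unname(g$beta), unname(S), tolerance = 1e-8)
})

test_that("the identity S = R beta links differentials and gradients", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 50
    Z <- standardize_traits(matrix(rnorm(n * 3), n, 3) %*%
                              matrix(c(1, .4, .2, 0, 1, .3, 0, 0, 1), 3))
    w <- relative_fitness(exp(0.4 * Z[, 1] - 0.2 * Z[, 3] + rnorm(n, 0, 0.3)))
    g <- selection_gradients(w, Z)
    S <- apply(Z, 2, function(z) cov(w, z))
    expect_equal(unname(S), unname(drop(cor(Z) %*% g$beta)), tolerance = 1e-8)
  }
})

test_that("collinear traits are rejected with the offending pair named", {
  set.seed(4)
  z1 <- rnorm(30)
  Z <- cbind(a = z1, b = 2 * z1, c = rnorm(30))
  expect_error(selection_gradients(rnorm(30, 1), Z), "a ~ b")
})

test_that("p-values are uniform under the no-selection null", {
  set.seed(123)
  pvals <- vapply(1:500, function(i) {
    z <- drop(standardize_traits(rnorm(20)))
    w <- relative_fitness(rexp(20))
    selection_differential(w, z)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the site-wise pipeline equals the stage operations composed", {
  rec <- simulate_transplant(sim_params(seed = 13))
  traits <- c("height", "leaf_area", "sla")
  res <- lande_arnold(rec, traits)
  expect_s3_class(res, "selection_result")
  expect_equal(sort(unique(res$site)),
               sort(paste(rep(c("south", "north"), each = 3),
                          c("low", "mid", "high"), sep = ":")))

  # recompute one site by hand
  s <- res$site[1]
  parts <- strsplit(s, ":")[[1]]
  d <- rec[rec$transect == parts[1] & rec$elevation_transplant == parts[2],
           c(traits, "final_biomass")]
  d <- d[complete.cases(d), ]
  w <- relative_fitness(d$final_biomass)
  Z <- standardize_traits(d[traits])
  g <- selection_gradients(w, Z)
  sub <- res[res$site == s, ]
  for (tr in traits) {
    expect_equal(sub$S[sub$trait == tr],
                 selection_differential(w, Z[, tr])$S, tolerance = 1e-12)
    expect_equal(sub$beta[sub$trait == tr], unname(g$beta[tr]),
                 tolerance = 1e-12)
  }
  # survivors-only contract: n equals complete survivor rows
  expect_equal(unique(sub$n), nrow(d))
})

test_that("six synthetic sites recover a common true selection gradient", {
  set.seed(77)
  hits <- 0
  for (s in paste0("st", 1:6)) {
    Z <- standardize_traits(matrix(rnorm(300 * 3), 300, 3))
    w <- 1 + 0.5 * Z[, 1] - 0.3 * Z[, 3] + rnorm(300, 0, 0.1)
    g <- selection_gradients(w, Z)
    hits <- hits + all(abs(g$beta - c(0.5, 0, -0.3)) <= 3 * g$se)
  }
  expect_equal(hits, 6)
})

test_that("the optimality check scores signs and rejects scale mismatches", {
  sel <- data.frame(site = "s1", trait = c("a", "b", "c"),
                    S = c(0.5, -0.2, 0.1))
  class(sel) <- c("selection_result", "data.frame")
  cwm <- data.frame(site = "s1", trait = c("a", "b", "c"),
                    cwm = c(12, 8, 10))
  pm <- data.frame(site = "s1", trait = c("a", "b", "c"),
                   mean = c(10, 10, 10))
  chk <- cwm_optimality(sel, cwm, pm)
  expect_equal(chk$consistent[chk$trait == "a"], TRUE)   # S>0, CWM above
  expect_equal(chk$consistent[chk$trait == "b"], TRUE)   # S<0, CWM below
  expect_true(is.na(chk$consistent[chk$trait == "c"]))   # exact tie
  expect_equal(attr(chk, "consistency"), 1)

  sel$S[1] <- -0.5
  chk2 <- cwm_optimality(sel, cwm, pm)
  expect_equal(attr(chk2, "consistency"), 0.5)

  expect_error(cwm_optimality(sel, cwm, pm, scale_selection = "raw",
                              scale_cwm = "transformed"), "mismatch")
})
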