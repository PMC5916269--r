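test_that("community-weighted means follow the abundance-weighted formula", {
  toy <- toy_community()
  expect_equal(unname(compute_cwm(toy, mode = "specific")), c(11.6, 18.4))
  expect_equal(unname(compute_cwm(toy, mode = "fixed",
                                  fixed_means = toy_fixed_means)), c(12, 18))

  # equal split of traits (2, 4) -> 3
  cd <- community_dataset(data.frame(site = "s", gradient = 0),
                          matrix(c(0.5, 0.5), 1), list(x = matrix(c(2, 4), 1)))
  expect_equal(unname(compute_cwm(cd, "x")), 3)

  # single species: CWM equals that species' local trait value
  one <- simulate_community(n_sites = 4, species_pool = "only",
                            itv_slopes = 0.05, noise_sd = 0.2, seed = 3)
  expect_equal(compute_cwm(one, mode = "specific"),
               setNames(one$traits$trait[, 1], rownames(one$abundance)))
})

test_that("missing trait values follow the declared policy", {
  toy <- toy_community()
  toy$traits$trait[1, 1] <- NA
  expect_error(compute_cwm(toy, mode = "specific"), "s1/sp01")
  expect_warning(v <- compute_cwm(toy, mode = "specific",
                                  fixed_means = toy_fixed_means,
                                  missing = "substitute"), "substituting")
  expect_equal(unname(v[1]), 0.8 * 10 + 0.2 * 18)
})

test_that("the two-site toy decomposition matches the hand computation", {
  dec <- cwm_decompose(toy_community(), fixed_means = toy_fixed_means)
  expect_equal(dec$ss_specific, 23.12, tolerance = 1e-12)
  expect_equal(dec$ss_fixed, 18, tolerance = 1e-12)
  expect_equal(dec$ss_intra, 0.32, tolerance = 1e-12)
  expect_equal(dec$ss_cov, 4.8, tolerance = 1e-12)
  expect_equal(dec$itv_share, 100 * 0.32 / 18.32, tolerance = 1e-9)
  # with two sites the gradient model saturates: explained = total
  expect_equal(dec$ss_specific, dec$ss_specific_total)
})

test_that("the decomposition is additive, shift-invariant and scales correctly", {
  for (seed in 1:5) {
    cd <- random_community(seed)
    dec <- cwm_decompose(cd)
    expect_equal(dec$ss_specific, dec$ss_fixed + dec$ss_intra + dec$ss_cov,
                 tolerance = 1e-9)
    expect_equal(dec$ss_specific_total,
                 dec$ss_fixed_total + dec$ss_intra_total + dec$ss_cov_total,
                 tolerance = 1e-9)

    # adding a constant to every trait value changes nothing
    cd2 <- cd
    cd2$traits$trait <- cd$traits$trait + 7
    expect_equal(as.data.frame(cwm_decompose(cd2))[-1],
                 as.data.frame(dec)[-1], tolerance = 1e-8)

    # rescaling traits scales every SS by the square
    cd3 <- cd
    cd3$traits$trait <- cd$traits$trait * 3
    dec3 <- cwm_decompose(cd3)
    expect_equal(dec3$ss_specific, 9 * dec$ss_specific, tolerance = 1e-8)
    expect_equal(dec3$itv_share, dec$itv_share, tolerance = 1e-8)

    # permuting species labels leaves every output unchanged
    perm <- sample(ncol(cd$abundance))
    cd4 <- community_dataset(cd$sites, cd$abundance[, perm],
                             list(trait = cd$traits$trait[, perm]))
    expect_equal(as.data.frame(cwm_decompose(cd4)), as.data.frame(dec),
                 tolerance = 1e-9)
  }
})

test_that("zero ITV gives a zero intraspecific component and share", {
  cd <- simulate_community(n_sites = 10, species_pool = 5, itv_slopes = 0,
                           noise_sd = 0, seed = 6)
  dec <- cwm_decompose(cd)
  expect_lt(dec$ss_intra, 1e-18)
  expect_equal(dec$itv_share, 0, tolerance = 1e-9)
  expect_equal(dec$spt_share, 100, tolerance = 1e-9)
})

test_that("identical composition everywhere puts all signal in ITV", {
  sites <- data.frame(site = c("a", "b", "c"), gradient = 1:3)
  p <- matrix(1 / 3, 3, 3)
  x <- matrix(5, 3, 3) + (1:3)  # same everywhere except a site-level trend
  cd <- community_dataset(sites, p, list(trait = x))
  dec <- cwm_decompose(cd)
  expect_lt(dec$ss_fixed, 1e-18)
  expect_equal(dec$itv_share, 100, tolerance = 1e-9)
})

test_that("undefined shares are reported as missing, never coerced", {
  sites <- data.frame(site = c("a", "b", "c"), gradient = 1:3)
  p <- matrix(1 / 2, 3, 2)
  x <- matrix(4, 3, 2)  # no variance anywhere
  dec <- cwm_decompose(community_dataset(sites, p, list(trait = x)))
  expect_true(is.na(dec$itv_share))
  expect_true(is.na(dec$spt_share))
})

test_that("the ITV share rises monotonically with the intraspecific slope", {
  shares <- vapply(c(0, 0.01, 0.03, 0.06, 0.12), function(slope) {
    cd <- simulate_community(n_sites = 12, species_pool = 5,
                             itv_slopes = slope, noise_sd = 0, seed = 11)
    cwm_decompose(cd)$itv_share
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
  expect_equal(shares[1], 0, tolerance = 1e-9)
})

test_that("factor-coded gradient model preserves additivity", {
  cd <- random_community(9, n_sites = 9)
  cd$sites$gradient <- rep(c(10, 20, 30), each = 3)
  dec <- cwm_decompose(cd, model = "factor")
  expect_equal(dec$ss_specific, dec$ss_fixed + dec$ss_intra + dec$ss_cov,
               tolerance = 1e-9)
  expect_gte(dec$ss_fixed, 0)
  expect_gte(dec$ss_intra, 0)
})
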