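test_that("heritability reproduces the worked-example table cells", {
  # sire model: 4 * sigma2s / sigma2p
  expect_equal(round(heritability(c(sigma2s = 1.069, sigma2v = 0.681,
                                    sigma2w = 0.999, sigma2p = 6.049),
                                  "sire")$h2, 2), 0.71)
  # sire-and-dam model with maternal environment fitted
  hd <- heritability(c(sigma2s = 1.100, sigma2d = 0.664, sigma2v = 0.681,
                       sigma2w = 0.437, sigma2p = 6.182), "sire_dam")
  expect_equal(round(hd$h2, 2), 0.57)
  expect_equal(round(hd$ratio_v, 2), 0.11)
  expect_equal(round(hd$ratio_w, 2), 0.07)
  # sire-and-dam model without maternal environment
  h0 <- heritability(c(sigma2s = 1.087, sigma2d = 1.110, sigma2v = 0.769,
                       sigma2p = 6.267), "sire_dam")
  expect_equal(round(h0$h2, 2), 0.70)
  expect_equal(round(h0$ratio_v, 2), 0.12)
  # remaining printed ratios of the sire column
  hs <- heritability(c(sigma2s = 1.069, sigma2v = 0.681, sigma2w = 0.999,
                       sigma2p = 6.049), "sire")
  expect_equal(round(hs$ratio_v, 2), 0.11)
  expect_equal(round(hs$ratio_w, 2), 0.17)
})

test_that("heritability flags h2 > 1 and validates inputs", {
  out <- heritability(c(sigma2s = 2, sigma2p = 6), "sire")
  expect_true(out$flag_h2_gt_1)
  expect_equal(out$h2, 8 / 6)
  expect_error(heritability(c(sigma2s = 1, sigma2p = 0), "sire"),
               "positive")
  expect_error(heritability(c(sigma2s = 1), "sire"), "sigma2p")
  expect_error(heritability(c(sigma2s = -1, sigma2p = 2), "sire"),
               "non-negative")
})

test_that("liability transform: closed forms and monotonicity", {
  expect_equal(liabilityTransform(1, 0.5), pi / 2, tolerance = 1e-12)
  expect_equal(liabilityTransform(0, 0.2), 0)
  # frozen numeric oracle at the 6.3% prevalence of the worked example
  expect_equal(liabilityTransform(1, 0.063), 3.854693, tolerance = 1e-6)
  expect_error(liabilityTransform(0.5, 0), "prevalence")
  expect_error(liabilityTransform(0.5, 1), "prevalence")
  # linear (hence monotone increasing) in h2_obs
  expect_lt(liabilityTransform(0.2, 0.1), liabilityTransform(0.4, 0.1))
  # for p < 0.5 the multiplier decreases as prevalence rises
  ps <- c(0.02, 0.063, 0.15, 0.3, 0.45)
  mult <- liabilityTransform(1, ps)
  expect_true(all(diff(mult) < 0))
})

test_that("gibbsVarComp recovers half-sib components and matches the
           ANOVA expectation for the sire variance", {
  hs <- simulateHalfSib(n_sires = 40, dams_per_sire = 4,
                        litters_per_dam = 1, n_per_litter = 8,
                        sigma2s = 1, sigma2v = 0.5, sigma2w = 0,
                        sigma2e = 4, seed = 13)
  fit <- gibbsVarComp(hs, response = "y", genetic = "sire",
                      environmental = "litter", n_iter = 3000,
                      burn_in = 800, thin = 2, seed = 7)
  sm <- fit$summary
  expect_lt(abs(sm["sigma2_sire", "mean"] - 1), 3 * sm["sigma2_sire", "sd"])
  expect_lt(abs(sm["sigma2_litter", "mean"] - 0.5),
            3 * sm["sigma2_litter", "sd"])
  expect_lt(abs(sm["sigma2_e", "mean"] - 4), 3 * sm["sigma2_e", "sd"])
  # method-of-moments sire component from the balanced one-way ANOVA
  k <- 32  # offspring per sire
  ms <- anova(lm(y ~ sire, hs))
  s2s_anova <- (ms$`Mean Sq`[1] - ms$`Mean Sq`[2]) / k
  expect_lt(abs(sm["sigma2_sire", "mean"] - s2s_anova),
            3 * sm["sigma2_sire", "sd"])
})

test_that("constant response drives all non-residual components to zero", {
  hs <- simulateHalfSib(n_sires = 15, dams_per_sire = 2,
                        litters_per_dam = 1, n_per_litter = 4, seed = 2)
  hs$y <- 3.7
  fit <- gibbsVarComp(hs, response = "y", genetic = "sire",
                      environmental = "litter", n_iter = 600,
                      burn_in = 200, seed = 3)
  expect_lt(fit$summary["sigma2_sire", "mean"], 1e-6)
  expect_lt(fit$summary["sigma2_litter", "mean"], 1e-6)
})

test_that("permuting litter labels destroys the litter variance", {
  hs <- simulateHalfSib(n_sires = 30, dams_per_sire = 3,
                        litters_per_dam = 1, n_per_litter = 8,
                        sigma2s = 0.5, sigma2v = 1.5, sigma2w = 0,
                        sigma2e = 3, seed = 21)
  orig <- gibbsVarComp(hs, response = "y", genetic = "sire",
                       environmental = "litter", n_iter = 1500,
                       burn_in = 500, seed = 4)
  hs_perm <- hs
  set.seed(9)
  hs_perm$litter <- sample(hs_perm$litter)
  perm <- gibbsVarComp(hs_perm, response = "y", genetic = "sire",
                       environmental = "litter", n_iter = 1500,
                       burn_in = 500, seed = 4)
  expect_gt(orig$summary["sigma2_litter", "mean"], 0.8)
  expect_lt(perm$summary["sigma2_litter", "mean"],
            0.25 * orig$summary["sigma2_litter", "mean"])
})

test_that("confounded fixed effects are rejected with the aliased column
           named", {
  hs <- simulateHalfSib(n_sires = 6, dams_per_sire = 2,
                        litters_per_dam = 1, n_per_litter = 3, seed = 5)
  hs$dup <- 1  # aliased with the intercept
  expect_error(gibbsVarComp(hs, response = "y", fixed = ~ dup,
                            genetic = "sire", environmental = "litter",
                            seed = 1),
               "aliased.*dup")
})

test_that("A-structured sire effects accept a pedigree", {
  hs <- simulateHalfSib(n_sires = 8, dams_per_sire = 2,
                        litters_per_dam = 1, n_per_litter = 4, seed = 6)
  # sires are full sibs in pairs
  sires <- unique(hs$sire)
  ped <- validatePedigree(data.frame(
    id = c("GS", "GD", sires),
    sire = c(NA, NA, rep("GS", 8)),
    dam = c(NA, NA, rep("GD", 8)),
    sex = c("M", "F", rep("M", 8))))
  fit <- gibbsVarComp(hs, response = "y", genetic = "sire",
                      environmental = "litter", ped = ped,
                      n_iter = 600, burn_in = 200, seed = 7)
  expect_true(all(is.finite(as.matrix(fit$summary))))
  expect_true(all(fit$draws$sigma2_sire >= 0))
})

test_that("sire-and-dam model reports the 2(s+d)/p heritability", {
  hs <- simulateHalfSib(n_sires = 20, dams_per_sire = 3,
                        litters_per_dam = 1, n_per_litter = 6,
                        sigma2s = 1, sigma2v = 0.3, sigma2w = 0.5,
                        sigma2e = 3, seed = 30)
  fit <- gibbsVarComp(hs, response = "y", genetic = c("sire", "dam"),
                      environmental = "litter", n_iter = 1200,
                      burn_in = 400, seed = 8)
  h2_manual <- mean(2 * (fit$draws$sigma2_sire + fit$draws$sigma2_dam) /
                      fit$draws$sigma2_p)
  expect_equal(unname(fit$h2["mean"]), h2_manual, tolerance = 1e-10)
  expect_equal(fit$model, "sire_dam")
})
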