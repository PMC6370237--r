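test_that("litterRatioTest pools affected litters against the 1/4
           expectation", {
  one <- litterRatioTest(data.frame(litter = "L1", n_offspring = 4,
                                    n_affected = 1))
  expect_equal(one$p_hat, 0.25)
  expect_equal(one$chi2, 0)
  three <- litterRatioTest(data.frame(litter = c("a", "b", "c"),
                                      n_offspring = c(8, 8, 8),
                                      n_affected = c(2, 3, 1)))
  expect_equal(three$p_hat, 0.25)
  expect_equal(three$chi2, 0)
  expect_equal(three$n_pooled, 24)
  # litters without affected offspring are excluded from the pool
  mix <- litterRatioTest(data.frame(litter = c("a", "b"),
                                    n_offspring = c(8, 8),
                                    n_affected = c(2, 0)))
  expect_equal(mix$n_pooled, 8)
  expect_error(litterRatioTest(data.frame(litter = "a", n_offspring = 6,
                                          n_affected = 0)), "no affected")
  expect_error(litterRatioTest(data.frame(litter = "a", n_offspring = 2,
                                          n_affected = 3)), "exceeds")
})

test_that("litterSummary aggregates offspring by litter", {
  ph <- data.frame(id = c("p1", "o1", "o2", "o3"),
                   litter = c(NA, "L1", "L1", "L2"),
                   affected = c(0, 1, 0, 1))
  ls <- litterSummary(ph)
  expect_equal(ls$n_offspring[ls$litter == "L1"], 2)
  expect_equal(ls$n_affected[ls$litter == "L1"], 1)
})

test_that("exact enumeration reduces to the HWE prior and to logical
           necessity", {
  ped1 <- validatePedigree(data.frame(id = "x", sire = NA, dam = NA))
  ex <- exactSegregationPosterior(ped1, data.frame(id = "x", y = NA),
                                  q = 0.3, mu = 0, a = 1, d = 0,
                                  sigma2e = 1)
  expect_equal(unname(ex$genotypeProb[1, ]), c(0.49, 0.42, 0.09))
  # trio with an affected (TT) offspring: both parents must carry T
  trio <- validatePedigree(data.frame(id = c("s", "d", "o"),
                                      sire = c(NA, NA, "s"),
                                      dam = c(NA, NA, "d")))
  ex2 <- exactSegregationPosterior(
    trio, data.frame(id = c("s", "d", "o"), y = c(0, 0, 1)),
    q = 0.25, mu = 0.5, a = 0.5, d = -0.5, sigma2e = 1e-4)
  carrier_or_tt <- rowSums(ex2$genotypeProb[c("s", "d"), c("GT", "TT")])
  expect_equal(unname(carrier_or_tt), c(1, 1), tolerance = 1e-10)
  expect_gt(ex2$genotypeProb["o", "TT"], 1 - 1e-10)
  expect_error(exactSegregationPosterior(
    validatePedigree(random_pedigree(12)), data.frame(id = "x", y = 1),
    q = 0.2, mu = 0, a = 1, d = 0, sigma2e = 1), "too large")
})

test_that("exact marginal likelihood matches an independent enumeration", {
  set.seed(6)
  raw <- random_pedigree(6, n_founders = 3, seed = 7)
  ped <- validatePedigree(raw)
  y <- rnorm(6, 0.3, 0.6); y[2] <- NA
  ph <- data.frame(id = pedIds(ped), y = y)
  ex <- exactSegregationPosterior(ped, ph, q = 0.35, mu = 0.4, a = 0.45,
                                  d = -0.3, sigma2e = 0.2)
  want <- oracle_marginal_lik(ped, y, q = 0.35, mu = 0.4, a = 0.45,
                              d = -0.3, s2e = 0.2)
  expect_equal(ex$log_marginal, want, tolerance = 1e-10)
  expect_equal(unname(rowSums(ex$genotypeProb)), rep(1, 6),
               tolerance = 1e-12)
})

test_that("Gibbs genotype posteriors agree with exact enumeration at
           fixed parameters", {
  # 8-individual two-generation pedigree with a mix of phenotypes
  raw <- data.frame(id = c("s1", "d1", "d2", "o1", "o2", "o3", "o4", "o5"),
                    sire = c(NA, NA, NA, "s1", "s1", "s1", "s1", "s1"),
                    dam = c(NA, NA, NA, "d1", "d1", "d2", "d2", "d2"),
                    sex = c("M", "F", "F", NA, NA, NA, NA, NA))
  ped <- validatePedigree(raw)
  ph <- data.frame(id = raw$id,
                   y = c(0.1, -0.05, NA, 0.95, 0.02, 1.05, 0.01, NA))
  fx <- list(q = 0.3, mu = 0.5, a = 0.5, d = -0.5, sigma2e = 0.05)
  ex <- exactSegregationPosterior(ped, ph, q = fx$q, mu = fx$mu, a = fx$a,
                                  d = fx$d, sigma2e = fx$sigma2e)
  gs <- gibbsSegregation(ped, ph, n_iter = 24000, burn_in = 4000,
                         thin = 2, seed = 17, fix_params = fx)
  # 10,000 retained sweeps: Monte-Carlo error ~ 3*sqrt(0.25/10000) < 0.016
  expect_lt(max(abs(ex$genotypeProb - genotypeProbabilities(gs))), 0.02)
})

test_that("the sampler recovers a fully penetrant recessive on carrier
           litters", {
  sim <- simulateCarrierLitters(150, litter_mean = 6, residual_sd = 0.1,
                                seed = 3)
  gs <- gibbsSegregation(sim$pedigree, sim$phenotypes, "y",
                         n_iter = 6000, burn_in = 2000, thin = 2, seed = 8)
  sm <- posteriorSummary(gs)
  expect_lt(abs(sm["a", "mean"] - 0.5), 0.05)
  expect_lt(abs(sm["d", "mean"] - (-0.5)), 0.05)
  # genotype posteriors identify affected offspring as TT
  aff <- sim$phenotypes$id[sim$phenotypes$affected == 1]
  expect_gt(mean(genotypeProbabilities(gs)[aff, "TT"]), 0.98)
  expect_gt(min(genotypeProbabilities(gs)[aff, "TT"]), 0.8)
})

test_that("pure-noise phenotypes attribute almost no variance to the
           locus", {
  sim <- simulateCarrierLitters(150, litter_mean = 6, seed = 3)
  ph <- sim$phenotypes
  set.seed(4)
  ph$y <- rnorm(nrow(ph))
  gs <- gibbsSegregation(sim$pedigree, ph, "y", n_iter = 4000,
                         burn_in = 1000, thin = 2, seed = 5)
  sm <- posteriorSummary(gs)
  expect_lt(sm["locus_var_share", "mean"], 0.1)
  # dominance credible interval covers zero
  expect_lt(sm["d", "ci_2.5"], 0)
  expect_gt(sm["d", "ci_97.5"], 0)
})

test_that("allele relabelling mirrors the posterior (a fixed, d and q
           flipped)", {
  sim <- simulateCarrierLitters(120, litter_mean = 6, seed = 9)
  ph_up <- sim$phenotypes                      # trait increases with TT
  ph_dn <- sim$phenotypes
  set.seed(10)
  noise <- rnorm(nrow(ph_dn), 0, 0.1)
  ph_up$y <- ph_up$affected + noise
  ph_dn$y <- 1 - ph_dn$affected + noise        # same noise, flipped signal
  up <- posteriorSummary(gibbsSegregation(sim$pedigree, ph_up, "y",
                                          n_iter = 5000, burn_in = 1500,
                                          thin = 2, seed = 11))
  dn <- posteriorSummary(gibbsSegregation(sim$pedigree, ph_dn, "y",
                                          n_iter = 5000, burn_in = 1500,
                                          thin = 2, seed = 12))
  expect_lt(abs(up["a", "mean"] - dn["a", "mean"]), 0.02)
  expect_lt(abs(up["d", "mean"] + dn["d", "mean"]), 0.05)
  expect_lt(abs(up["q", "mean"] - (1 - dn["q", "mean"])), 0.05)
})

test_that("chain and input validation", {
  sim <- simulateCarrierLitters(5, seed = 1)
  expect_error(gibbsSegregation(sim$pedigree, sim$phenotypes, "y",
                                n_iter = 100, burn_in = 200, seed = 1),
               "burn-in")
  expect_error(gibbsSegregation(sim$pedigree, sim$phenotypes, "y"),
               "seed")
  bad <- sim$phenotypes
  bad$y[1] <- Inf
  expect_error(gibbsSegregation(sim$pedigree, bad, "y", seed = 1),
               "non-finite")
})
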