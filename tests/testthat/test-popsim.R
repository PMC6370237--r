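small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_founders = 40, n_generations = 4, n_sires = 8, n_dams = 16,
         litter_mean = 6, chrom_lengths = c(`15` = 140e6), n_snps = 60),
    list(...))
  do.call(simConfig, args)
}

test_that("simConfig rejects invalid study conditions", {
  expect_error(simConfig(q0 = 1.2), "q0")
  expect_error(simConfig(litter_mean = 0), "litter_mean")
  expect_error(simConfig(survival_40 = c(GG = 1.2, GT = 1, TT = 0)),
               "survival")
  expect_error(simConfig(causal_chrom = "7"), "not in chrom_lengths")
  expect_error(simConfig(causal_pos = 1e9), "outside")
  expect_error(simConfig(n_founders = 7), "even")
})

test_that("q0 = 0 gives a population with no T alleles and no affected", {
  pop <- simulatePopulation(small_cfg(q0 = 0), seed = 3)
  expect_true(all(causalGenotypes(pop) == 0))
  expect_equal(sum(phenotypes(pop)$affected), 0)
})

test_that("zero TT survival to 110 kg leaves no TT finisher", {
  pop <- simulatePopulation(small_cfg(), seed = 5)
  g <- causalGenotypes(pop)
  expect_equal(sum(g == 2 & stageFlags(pop)[, "wt110"]), 0)
  expect_gt(sum(g == 2), 0)  # but TT zygotes are born
})

test_that("all TT individuals are homozygous across the IBD window", {
  pop <- simulatePopulation(small_cfg(n_generations = 6), seed = 8)
  g <- causalGenotypes(pop)
  map <- snpMap(pop)
  win <- which(map$chrom == "15" & abs(map$pos - 94.62e6) <= 8.3e6 / 2)
  expect_gt(length(win), 3)
  gw <- genotypeMatrix(pop)[g == 2, win, drop = FALSE]
  expect_true(all(apply(gw, 2, function(x)
    all(x %in% c(0, 2)) && length(unique(x)) == 1)))
})

test_that("birth-cohort genotype frequencies are at Hardy-Weinberg", {
  # one round of random mating from founders at q0 = 0.22, with many
  # small litters so the zygotes are close to independent draws; the HWE
  # chi-square should exceed its 5% critical value in about 1 in 20 seeds
  exceed <- 0L
  for (seed in 1:10) {
    pop <- simulatePopulation(
      simConfig(n_founders = 220, n_generations = 2, n_sires = 100,
                n_dams = 100, litter_mean = 5, selection = "random",
                chrom_lengths = c(`15` = 140e6), n_snps = 10),
      seed = seed)
    g <- causalGenotypes(pop)[as.data.frame(pop@pedigree)$generation == 1]
    s <- cohortStats(sum(g == 0), sum(g == 1), sum(g == 2))
    expect_gt(s$n, 400)
    if (!is.na(s$chi2) && s$chi2 > qchisq(0.95, 1)) exceed <- exceed + 1L
  }
  expect_lte(exceed, 2L)
})

test_that("stochastic allele-frequency trajectories track the
           deterministic recursion", {
  s1 <- 0.282; s2 <- 1
  n_gen <- 4
  reps <- 50
  qmat <- matrix(NA_real_, reps, n_gen + 1)
  for (r in seq_len(reps)) {
    pop <- simulatePopulation(
      simConfig(n_founders = 50, n_generations = n_gen + 1, n_sires = 12,
                n_dams = 24, litter_mean = 8, selection = "random",
                survival_40 = c(GG = 1 - s1, GT = 1, TT = 1 - s2),
                survival_110 = c(GG = 1, GT = 1, TT = 1),
                chrom_lengths = c(`15` = 140e6), n_snps = 8),
      seed = 1000 + r)
    g <- causalGenotypes(pop)
    gen <- as.data.frame(pop@pedigree)$generation
    qmat[r, ] <- vapply(0:n_gen, function(t) mean(g[gen == t]) / 2,
                        numeric(1))
  }
  traj <- deterministicRecursion(s1, s2, q0 = 0.22, n_gen)$trajectory
  for (t in seq_len(n_gen + 1)) {
    mc_se <- sd(qmat[, t]) / sqrt(reps)
    expect_lt(abs(mean(qmat[, t]) - traj[t]), max(3 * mc_se, 1e-3))
  }
})

test_that("with all variances zero phenotypes are deterministic in
           genotype", {
  pop <- simulatePopulation(small_cfg(), seed = 2)
  qt <- defaultQuantTraits()
  qt[, c("sigma2a", "sigma2v", "sigma2w", "sigma2e")] <- 0
  tm <- traitModel(leg_penetrance = 1, quant = qt)
  ph <- assignPhenotypes(pop, tm, seed = 4)
  g <- causalGenotypes(pop)
  expect_equal(ph$affected, unname(as.integer(g == 2)))
  expect_equal(ph$leg_score, unname(as.numeric(g == 2)))
  expect_equal(ph$muscle,
               qt$mean_GG[1] * (g == 0) + qt$mean_GT[1] * (g == 1) +
                 qt$mean_TT[1] * (g == 2),
               ignore_attr = TRUE)
})

test_that("the simulated carrier effect is recovered within 3 SE", {
  pop <- simulatePopulation(small_cfg(n_generations = 5, n_dams = 24),
                            seed = 6)
  ph <- assignPhenotypes(pop, traitModel(), seed = 9)
  g <- causalGenotypes(pop)
  keep <- g <= 1
  delta <- diff(tapply(ph$muscle[keep], g[keep], mean))
  n0 <- sum(g == 0); n1 <- sum(g == 1)
  se <- sd(ph$muscle[keep]) * sqrt(1 / n0 + 1 / n1)
  truth <- defaultQuantTraits()$mean_GT[1] - defaultQuantTraits()$mean_GG[1]
  expect_lt(abs(delta - truth), 3 * se)
})

test_that("litter-only variance produces the expected intraclass
           correlation", {
  skip_if_not_installed("lme4")
  pop <- simulatePopulation(small_cfg(n_generations = 5, n_dams = 30,
                                      litter_mean = 8), seed = 10)
  qt <- defaultQuantTraits()
  qt[, c("sigma2a", "sigma2w")] <- 0
  qt$sigma2v <- 4; qt$sigma2e <- 12
  ph <- assignPhenotypes(pop, traitModel(quant = qt), seed = 11)
  d <- ph[!is.na(ph$litter), ]
  fit <- lme4::lmer(muscle ~ 1 + (1 | litter), data = d)
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc <- vc$vcov[1] / sum(vc$vcov)
  expect_lt(abs(icc - 4 / 16), 0.06)
})

test_that("carrier-by-carrier litters segregate 1:2:1 and score 25%
           affected", {
  sim <- simulateCarrierLitters(400, litter_mean = 8, seed = 12)
  df <- as.data.frame(sim$pedigree)
  parents <- is.na(df$litter)
  expect_true(all(sim$genotype[parents] == 1))
  off <- sim$genotype[!parents]
  expect_lt(abs(mean(off == 2) - 0.25), 3 * sqrt(0.25 * 0.75 / length(off)))
  expect_equal(sim$phenotypes$affected[!parents],
               unname(as.integer(off == 2)))
})

test_that("deterministic recursion: equilibria and monotone decline", {
  expect_equal(deterministicRecursion(0.25, 1, 0.22, 10)$equilibrium, 0.2)
  tr <- deterministicRecursion(0.25, 1, 0.05, 400)$trajectory
  expect_equal(tail(tr, 1), 0.2, tolerance = 1e-6)
  # pure lethal without carrier advantage: q declines monotonically to 0
  dec <- deterministicRecursion(0, 1, 0.22, 100)$trajectory
  expect_true(all(diff(dec) < 0))
  expect_lt(tail(dec, 1), 0.01)
  # neutral case: constant trajectory, flagged
  neu <- deterministicRecursion(0, 0, 0.22, 5)
  expect_true(neu$neutral)
  expect_equal(neu$trajectory, rep(0.22, 6))
  # inverting the closed form: q* = 0.22 for a lethal needs s1 = q/(1-q)
  s1 <- 0.22 / (1 - 0.22)
  expect_equal(deterministicRecursion(s1, 1, 0.5, 10)$equilibrium, 0.22)
  expect_error(deterministicRecursion(-0.1, 1, 0.2, 5), "coefficients")
})

test_that("emitted artifacts round-trip and contain the planted truth", {
  pop <- simulatePopulation(small_cfg(n_generations = 5), seed = 14)
  out <- tempfile("artifacts")
  paths <- emitArtifacts(pop, out, seed = 2)
  expect_true(all(file.exists(paths)))
  # genotype round trips, both formats
  gm <- genotypeMatrix(pop); storage.mode(gm) <- "integer"
  rt <- readGenotypes(paths[["ped"]], paths[["map"]])
  expect_identical(rt$genotypes, gm)
  expect_identical(readGenotypesTsv(paths[["tsv"]]), gm)
  expect_equal(rt$map$pos, snpMap(pop)$pos)
  # one cohort row per stage
  cc <- readCohortCounts(paths[["cohorts"]])
  expect_equal(cc$stage, c("birth", "wt40", "wt110"))
  expect_equal(cc$n_TT[3], 0)
  # the VCF holds exactly one variant passing hard + strict candidate
  vv <- readVcfVariants(paths[["vcf"]])
  grp <- list(
    cases = grep("^case_", colnames(vv$genotypes), value = TRUE),
    carriers = grep("^carrier_", colnames(vv$genotypes), value = TRUE),
    controls = grep("^control_", colnames(vv$genotypes), value = TRUE))
  hf <- siteHardFilter(vv$sites)
  cand <- candidateFilter(hf[hf$pass, ], vv$genotypes[hf$pass, ], grp)
  expect_equal(nrow(cand), 1)
  ann <- annotateConsequence(cand$chrom, cand$pos, cand$ref, cand$alt,
                             syntheticMstnModel())
  expect_equal(ann$consequence, "stop_gained")
  expect_equal(ann$hgvs_p, "p.E274*")
})

test_that("simulation is reproducible from the master seed", {
  p1 <- simulatePopulation(small_cfg(), seed = 21)
  p2 <- simulatePopulation(small_cfg(), seed = 21)
  expect_identical(causalGenotypes(p1), causalGenotypes(p2))
  expect_identical(phenotypes(p1), phenotypes(p2))
  p3 <- simulatePopulation(small_cfg(), seed = 22)
  expect_false(identical(causalGenotypes(p1), causalGenotypes(p3)))
})
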