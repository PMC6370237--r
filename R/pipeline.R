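#' Run the full discovery pipeline on a simulated population
#'
#' Sequences the whole inference chain on one simulated population:
#' simulate and write artifacts, within-litter segregation ratio and
#' Bayesian segregation analysis, observed-scale variance components for
#' the binary trait, case/control homozygosity mapping, candidate-variant
#' filtering with consequence annotation, Hardy-Weinberg distortion across
#' life stages, and the carrier-effect association for the quantitative
#' traits. Per-stage outputs and a machine-readable JSON summary are
#' written under `outdir`; any stage failure aborts with the stage name
#' while retaining earlier outputs. Reruns with the same seed and
#' configuration are byte-identical.
#'
#' @param config `NULL` for defaults, a nested list, or the path to a YAML
#'   file with any of the blocks `simulate` (arguments of [simConfig()]),
#'   `segregation` (`n_iter`, `burn_in`, `thin`), `varcomp` (`n_iter`,
#'   `burn_in`, `thin`), `rohmap` (`n_cases`, `n_controls`,
#'   `allow_case_het`), `varfilter` (`max_het_cases`,
#'   `max_homref_carriers`) and `assoc` (`traits`). Unknown keys are
#'   rejected.
#' @param outdir run directory (created)
#' @param seed master seed; every stochastic stage derives its stream from
#'   it
#' @param verbose print stage progress
#' @return invisibly, the summary list (also written as `summary.json`)
#' @export
runPipeline <- function(config = NULL, outdir, seed = 1L,
                        verbose = TRUE) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  config <- config %||% list()
  known <- c("simulate", "segregation", "varcomp", "rohmap", "varfilter",
             "assoc", "seed", "outdir")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logfile, append = TRUE)
    if (verbose) message(msg)
  }
  stage <- function(name, expr) {
    say("stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  getcfg <- function(block, defaults) {
    ov <- config[[block]] %||% list()
    bad <- setdiff(names(ov), names(defaults))
    if (length(bad))
      stop("unknown keys in config$", block, ": ",
           paste(bad, collapse = ", "))
    utils::modifyList(defaults, ov)
  }
  cat("", file = logfile)
  say("pipeline start, seed = ", seed)
  summary <- list(seed = seed)

  sim_args <- config$simulate %||% list()
  # YAML delivers named numeric vectors as lists of strings; coerce back
  for (k in c("chrom_lengths", "survival_40", "survival_110",
              "index_weights")) {
    if (!is.null(sim_args[[k]])) {
      u <- unlist(sim_args[[k]])
      sim_args[[k]] <- setNames(as.numeric(u), names(u))
    }
  }
  scfg <- stage("simulate", do.call(simConfig, sim_args))
  pop <- stage("simulate", simulatePopulation(scfg, seed = seed))
  datadir <- file.path(outdir, "data")
  paths <- stage("emit", emitArtifacts(pop, datadir, seed = seed))
  ph <- phenotypes(pop)
  g <- causalGenotypes(pop)
  summary$simulate <- list(n_individuals = length(pop@pedigree),
                           n_markers = nrow(snpMap(pop)),
                           q_birth = mean(g) / 2,
                           n_affected = sum(ph$affected))

  seg_cfg <- getcfg("segregation",
                    list(n_iter = 3000, burn_in = 1000, thin = 2))
  summary$segregation <- stage("segregation", {
    lits <- litterSummary(ph)
    lr <- if (any(lits$n_affected > 0)) litterRatioTest(lits) else NULL
    gs <- gibbsSegregation(pop@pedigree, ph, trait = "leg_score",
                           n_iter = seg_cfg$n_iter,
                           burn_in = seg_cfg$burn_in, thin = seg_cfg$thin,
                           seed = .streamSeed(seed, "pipe_seg"))
    sm <- posteriorSummary(gs)
    write.table(cbind(parameter = rownames(sm), round(sm, 6)),
                file.path(outdir, "segregation_posterior.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(litter_ratio = lr,
         posterior_mean = as.list(setNames(sm$mean, rownames(sm))))
  })

  vc_cfg <- getcfg("varcomp", list(n_iter = 2000, burn_in = 500, thin = 2))
  summary$varcomp <- stage("varcomp", {
    df <- as.data.frame(pop@pedigree)
    dat <- data.frame(y = ph$affected, sire = df$sire, dam = df$dam,
                      litter = df$litter, sex = ph$sex)
    dat <- dat[complete.cases(dat), ]
    fit <- gibbsVarComp(dat, response = "y", fixed = ~ sex,
                        genetic = "sire", environmental = "litter",
                        ped = pop@pedigree, n_iter = vc_cfg$n_iter,
                        burn_in = vc_cfg$burn_in, thin = vc_cfg$thin,
                        seed = .streamSeed(seed, "pipe_vc"))
    h2_obs <- unname(fit$h2["mean"])
    prev <- mean(dat$y)
    list(components = as.list(setNames(fit$summary$mean,
                                       rownames(fit$summary))),
         h2_observed = h2_obs,
         h2_liability = if (prev > 0 && prev < 1)
           liabilityTransform(h2_obs, prev) else NA)
  })

  roh_cfg <- getcfg("rohmap",
                    list(n_cases = 10, n_controls = 10, allow_case_het = 0))
  summary$rohmap <- stage("rohmap", {
    cases <- names(g)[g == 2 & ph$affected == 1]
    if (length(cases) < 2) list(top_segment = NULL, n_cases = length(cases))
    else {
      cases <- head(cases, roh_cfg$n_cases)
      controls <- head(names(g)[g == 0 & ph$affected == 0],
                       roh_cfg$n_controls)
      gm <- genotypeMatrix(pop)[c(cases, controls), , drop = FALSE]
      fi <- filterInformative(gm, snpMap(pop))
      segs <- longestSharedSegment(fi$genotypes, fi$map, cases,
                                   allow_case_het = roh_cfg$allow_case_het)
      write.table(segs, file.path(outdir, "roh_segments.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_informative = fi$n_retained,
           top_segment = if (nrow(segs)) as.list(segs[1, ]) else NULL)
    }
  })

  vf_cfg <- getcfg("varfilter",
                   list(max_het_cases = 0, max_homref_carriers = 0))
  summary$varfilter <- stage("varfilter", {
    vv <- readVcfVariants(paths[["vcf"]])
    grp <- list(
      cases = grep("^case_", colnames(vv$genotypes), value = TRUE),
      carriers = grep("^carrier_", colnames(vv$genotypes), value = TRUE),
      controls = grep("^control_", colnames(vv$genotypes), value = TRUE))
    hf <- siteHardFilter(vv$sites)
    if (!length(grp$cases) || !length(grp$carriers))
      list(n_sites = nrow(vv$sites), n_pass_hard = sum(hf$pass),
           candidates = NULL)
    else {
      cand <- candidateFilter(hf[hf$pass, , drop = FALSE],
                              vv$genotypes[hf$pass, , drop = FALSE], grp,
                              max_het_cases = vf_cfg$max_het_cases,
                              max_homref_carriers = vf_cfg$max_homref_carriers)
      gm_model <- readGeneModel(paths[["gene_exons"]], paths[["gene_fasta"]])
      ann <- if (nrow(cand))
        annotateConsequence(cand$chrom, cand$pos, cand$ref, cand$alt,
                            gm_model)
      else data.frame()
      out <- cbind(cand, ann)
      write.table(out, file.path(outdir, "candidates.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(n_sites = nrow(vv$sites), n_pass_hard = sum(hf$pass),
           n_candidates = nrow(cand),
           classes = as.list(tabulateCandidates(ann)),
           candidates = if (nrow(cand))
             paste0(cand$chrom, ":", cand$pos, cand$ref, ">", cand$alt,
                    ifelse(is.na(ann$hgvs_p), "", paste0(" (", ann$hgvs_p, ")")))
           else character(0))
    }
  })

  summary$hwe <- stage("hwe", {
    cc <- readCohortCounts(paths[["cohorts"]])
    if (all(cc$n_GT + cc$n_TT == 0))
      list(note = "locus monomorphic; no HWE analysis")
    else {
      sc <- stageComparison(cc)
      write.table(sc$stats, file.path(outdir, "hwe_stages.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      gc <- genotypeChangeTest(cc)
      list(stages = lapply(seq_len(nrow(sc$stats)), function(i)
             as.list(sc$stats[i, c("stage", "n", "q", "alpha", "chi2",
                                   "p_value")])),
           genotype_change = gc[c("chi2", "df", "p_value")])
    }
  })

  as_cfg <- getcfg("assoc", list(traits = c("muscle", "fat", "weight")))
  summary$assoc <- stage("assoc", {
    df <- as.data.frame(pop@pedigree)
    keep <- stageFlags(pop)[, "wt110"] & g <= 1
    res <- lapply(as_cfg$traits, function(tr) {
      dat <- data.frame(id = df$id, y = ph[[tr]], geno = g,
                        sex = ph$sex)[keep, ]
      dat <- dat[complete.cases(dat), ]
      if (length(unique(dat$geno)) < 2) return(NULL)
      fit <- fitAssociation(dat, "y", "geno", ~ sex, pop@pedigree)
      fit[c("b", "se_b", "b_std", "sigmaP", "wald", "p_value", "n")]
    })
    names(res) <- as_cfg$traits
    res[!vapply(res, is.null, TRUE)]
  })

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(outdir, "summary.json"))
  say("pipeline done")
  invisible(summary)
}
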