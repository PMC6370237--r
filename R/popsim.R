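#' Trait model for the forward simulator
#'
#' Parameters of the simulated phenotypes. The binary leg-weakness trait is
#' monogenic: an individual is affected with probability `leg_penetrance`
#' iff it is TT at the causal locus; optional polygenic, litter, maternal
#' and residual components act additively on the observed 0/1 scale.
#' Quantitative traits (muscle depth, fat depth, live weight; trait units
#' mm, mm, kg) have genotype-specific means plus polygenic, litter,
#' maternal-environment and residual components. Default genotype means
#' are the carrier-advantage pattern of the motivating study (GT about
#' +4.8 mm muscle, -1.8 mm fat relative to GG); default variance
#' partitions give phenotypic SDs near 5.95, 2.72 and 7.96 with
#' heritability ~0.35.
#'
#' @param leg_penetrance probability a TT individual is affected
#' @param leg_sigma2a,leg_sigma2v,leg_sigma2w,leg_sigma2e observed-scale
#'   variance components added to the 0/1 leg record
#' @param quant data.frame with one row per quantitative trait and columns
#'   `trait, mean_GG, mean_GT, mean_TT, sigma2a, sigma2v, sigma2w, sigma2e`
#' @return object of class `TraitModel`
#' @export
traitModel <- function(leg_penetrance = 1,
                       leg_sigma2a = 0, leg_sigma2v = 0,
                       leg_sigma2w = 0, leg_sigma2e = 0,
                       quant = defaultQuantTraits()) {
  stopifnot(leg_penetrance >= 0, leg_penetrance <= 1,
            leg_sigma2a >= 0, leg_sigma2v >= 0, leg_sigma2w >= 0,
            leg_sigma2e >= 0)
  need <- c("trait", "mean_GG", "mean_GT", "mean_TT",
            "sigma2a", "sigma2v", "sigma2w", "sigma2e")
  if (!all(need %in% names(quant)))
    stop("quant needs columns: ", paste(need, collapse = ", "))
  if (any(quant[, c("sigma2a", "sigma2v", "sigma2w", "sigma2e")] < 0))
    stop("variances must be non-negative")
  structure(list(leg_penetrance = leg_penetrance,
                 leg_sigma2a = leg_sigma2a, leg_sigma2v = leg_sigma2v,
                 leg_sigma2w = leg_sigma2w, leg_sigma2e = leg_sigma2e,
                 quant = as.data.frame(quant)),
            class = "TraitModel")
}

#' @rdname traitModel
#' @export
defaultQuantTraits <- function() {
  data.frame(
    trait = c("muscle", "fat", "weight"),
    mean_GG = c(48.38, 10.19, 87.13),
    mean_GT = c(53.21, 8.42, 84.89),
    mean_TT = c(58.04, 6.65, 82.65),  # additive extrapolation, rarely used
    sigma2a = c(12.4, 2.59, 22.2),
    sigma2v = c(3.5, 0.74, 6.3),
    sigma2w = c(1.8, 0.37, 3.2),
    sigma2e = c(17.7, 3.70, 31.7),
    stringsAsFactors = FALSE)
}

#' Configuration of the forward population simulator
#'
#' Defines the study conditions the simulator emulates: a closed nucleus
#' herd bred for a fixed number of generations with truncation selection on
#' a muscle/fat index, segregating a recessive lethal T allele at founder
#' frequency `q0` whose carriers enjoy an index advantage and whose
#' homozygotes rarely survive to the 40 kg stage and never to 110 kg.
#'
#' @param n_founders founder count (even; half of each sex)
#' @param n_generations total generations including founders
#' @param n_sires,n_dams breeding animals selected per generation
#' @param litter_mean mean litter size (Poisson, truncated at 1)
#' @param q0 founder frequency of the lethal T allele, in `[0, 1)`
#' @param selection `"index"` (truncation on `w_muscle*muscle -
#'   w_fat*fat`) or `"random"`
#' @param index_weights named numeric `c(muscle=, fat=)`
#' @param survival_40,survival_110 length-3 survival probabilities to
#'   40 kg (from birth) and to 110 kg (from 40 kg) for GG, GT, TT
#' @param chrom_lengths named numeric, chromosome lengths in bp
#' @param n_snps total marker count (allocated proportionally to length)
#' @param cM_per_Mbp genetic map density (uniform, Haldane mapping)
#' @param causal_chrom,causal_pos location of the causal locus
#' @param ibd_window_bp width of the identical-by-descent marker window
#'   shared by all founder copies of the T allele, centred on the locus
#' @param traits a [traitModel()]
#' @return object of class `SimConfig`
#' @export
simConfig <- function(n_founders = 80, n_generations = 9,
                      n_sires = 15, n_dams = 35, litter_mean = 8,
                      q0 = 0.22, selection = c("index", "random"),
                      index_weights = c(muscle = 1, fat = 1),
                      survival_40 = c(GG = 0.95, GT = 0.95, TT = 0.02),
                      survival_110 = c(GG = 0.92, GT = 0.92, TT = 0),
                      chrom_lengths = c(`1` = 100e6, `15` = 140e6),
                      n_snps = 700, cM_per_Mbp = 1,
                      causal_chrom = "15", causal_pos = 94.62e6,
                      ibd_window_bp = 8.3e6,
                      traits = traitModel()) {
  selection <- match.arg(selection)
  if (q0 < 0 || q0 >= 1) stop("q0 must be in [0, 1)")
  if (litter_mean <= 0) stop("litter_mean must be positive")
  if (any(c(survival_40, survival_110) < 0) ||
      any(c(survival_40, survival_110) > 1))
    stop("survival probabilities must be in [0, 1]")
  if (!causal_chrom %in% names(chrom_lengths))
    stop("causal chromosome not in chrom_lengths")
  if (causal_pos < 1 || causal_pos > chrom_lengths[[causal_chrom]])
    stop("causal locus outside its chromosome")
  if (n_founders < 4 || n_founders %% 2 != 0)
    stop("n_founders must be an even number >= 4")
  structure(list(n_founders = n_founders, n_generations = n_generations,
                 n_sires = n_sires, n_dams = n_dams,
                 litter_mean = litter_mean, q0 = q0, selection = selection,
                 index_weights = index_weights,
                 survival_40 = survival_40, survival_110 = survival_110,
                 chrom_lengths = chrom_lengths, n_snps = n_snps,
                 cM_per_Mbp = cM_per_Mbp, causal_chrom = causal_chrom,
                 causal_pos = causal_pos, ibd_window_bp = ibd_window_bp,
                 traits = traits),
            class = "SimConfig")
}

# deterministic per-stage seed derived from one master seed
.streamSeed <- function(seed, name) {
  u <- utf8ToInt(name)
  h <- sum(u * (seq_along(u) * 131)) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483599) + 1L
}

# Haldane recombination fractions between adjacent loci
.recFrac <- function(pos_bp, cM_per_Mbp) {
  d_morgan <- diff(pos_bp) * cM_per_Mbp / 1e8
  0.5 * (1 - exp(-2 * d_morgan))
}

# one gamete from a pair of haplotype vectors; loci grouped by chromosome
.gamete <- function(h1, h2, chrom_index, rfrac) {
  out <- integer(length(h1))
  for (ci in seq_along(chrom_index)) {
    idx <- chrom_index[[ci]]
    x <- c(runif(1) < 0.5, runif(length(idx) - 1) < rfrac[[ci]])
    phase <- cumsum(x) %% 2
    out[idx] <- ifelse(phase == 0, h1[idx], h2[idx])
  }
  out
}

#' Simulate a closed breeding population with a recessive lethal
#'
#' Forward simulation at the individual level: founder marker haplotypes
#' with the lethal T allele embedded in a shared founder haplotype segment
#' (so every TT individual is homozygous across the configured IBD window),
#' gamete formation with Haldane recombination on a uniform genetic map,
#' genotype-dependent survival through the 40 kg and 110 kg stages,
#' polygenic trait values bred down the pedigree by the midparent +
#' Mendelian-sampling rule (with the inbreeding correction), and truncation
#' selection of breeding animals on a muscle/fat phenotype index.
#'
#' @param config a [simConfig()]
#' @param seed integer master seed; all stage-level randomness is derived
#'   from it through named streams
#' @return a [Population-class]
#' @export
simulatePopulation <- function(config, seed = 1L) {
  stopifnot(inherits(config, "SimConfig"))
  tm <- config$traits
  qt <- tm$quant
  ntr <- nrow(qt)

  ## marker map (+ causal locus as an internal pseudo-marker)
  set.seed(.streamSeed(seed, "map"))
  chroms <- names(config$chrom_lengths)
  per <- setNames(pmax(2L, round(config$n_snps * config$chrom_lengths /
                                   sum(config$chrom_lengths))), chroms)
  map <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chrom_lengths[[ch]], per[[ch]]))
    data.frame(snp = sprintf("chr%s_snp%04d", ch, seq_along(pos)),
               chrom = ch, pos = pos, a1 = "A", a2 = "B",
               stringsAsFactors = FALSE)
  }))
  causal_row <- data.frame(snp = ".causal", chrom = config$causal_chrom,
                           pos = config$causal_pos, a1 = "G", a2 = "T",
                           stringsAsFactors = FALSE)
  full <- rbind(map, causal_row)
  full <- full[order(match(full$chrom, chroms), full$pos), ]
  rownames(full) <- NULL
  causal_col <- which(full$snp == ".causal")
  m <- nrow(full)
  chrom_index <- lapply(chroms, function(ch) which(full$chrom == ch))
  rfrac <- lapply(chrom_index, function(idx)
    .recFrac(full$pos[idx], config$cM_per_Mbp))

  ## founders
  set.seed(.streamSeed(seed, "founders"))
  nF <- config$n_founders
  freq <- runif(m, 0.15, 0.85)
  freq[causal_col] <- 0
  Nmax <- nF + (config$n_generations - 1) *
    ceiling(config$n_dams * (config$litter_mean + 6 * sqrt(config$litter_mean)))
  H1 <- matrix(0L, Nmax, m); H2 <- matrix(0L, Nmax, m)
  H1[1:nF, ] <- matrix(rbinom(nF * m, 1, rep(freq, each = nF)), nF, m)
  H2[1:nF, ] <- matrix(rbinom(nF * m, 1, rep(freq, each = nF)), nF, m)
  # single-origin IBD template across the window around the causal locus
  win <- which(full$chrom == config$causal_chrom &
                 abs(full$pos - config$causal_pos) <=
                   config$ibd_window_bp / 2)
  n_t <- round(2 * nF * config$q0)
  if (n_t > nF)
    stop("q0 too high: founder carriers are heterozygous, need q0 <= 0.5")
  if (n_t > 0) {
    carriers0 <- sample.int(nF, n_t)       # distinct het founder carriers
    template <- rbinom(length(win), 1, 0.5)
    template[match(causal_col, win)] <- 1L
    for (ind in carriers0) {
      if (runif(1) < 0.5) H1[ind, win] <- template else H2[ind, win] <- template
    }
  }
  # the IBD window is a single-origin young haplotype: model it as fully
  # linked so every TT individual is homozygous across the whole window
  ci_causal <- match(config$causal_chrom, chroms)
  widx <- match(win, chrom_index[[ci_causal]])
  if (length(widx) > 1)
    rfrac[[ci_causal]][widx[-length(widx)]] <- 0

  id <- character(Nmax); sire <- character(Nmax); dam <- character(Nmax)
  sex <- character(Nmax); litter <- character(Nmax); gen <- integer(Nmax)
  id[1:nF] <- sprintf("F%03d", 1:nF)
  sire[1:nF] <- NA; dam[1:nF] <- NA
  sex[1:nF] <- rep(c("M", "F"), length.out = nF)
  litter[1:nF] <- NA; gen[1:nF] <- 0L

  A <- matrix(0, Nmax, Nmax)
  diag(A)[1:nF] <- 1
  Fcoef <- numeric(Nmax)
  u <- matrix(0, Nmax, ntr)          # polygenic values per quant trait
  set.seed(.streamSeed(seed, "founder_effects"))
  for (t in seq_len(ntr))
    u[1:nF, t] <- rnorm(nF, 0, sqrt(qt$sigma2a[t]))
  uleg <- rnorm(nF, 0, sqrt(tm$leg_sigma2a))

  alive40 <- logical(Nmax); alive110 <- logical(Nmax)
  alive40[1:nF] <- TRUE; alive110[1:nF] <- TRUE
  pheno <- matrix(NA_real_, Nmax, ntr)
  affected <- integer(Nmax)
  yleg <- numeric(Nmax)

  .quantPheno <- function(rows, lit_eff, mat_eff) {
    g <- H1[rows, causal_col] + H2[rows, causal_col]
    for (t in seq_len(ntr)) {
      mu <- c(qt$mean_GG[t], qt$mean_GT[t], qt$mean_TT[t])[g + 1]
      pheno[rows, t] <<- mu + u[rows, t] + lit_eff[, t] + mat_eff[, t] +
        rnorm(length(rows), 0, sqrt(qt$sigma2e[t]))
    }
  }
  # founder phenotypes (no litter/maternal structure recorded for founders)
  set.seed(.streamSeed(seed, "founder_pheno"))
  .quantPheno(1:nF, matrix(0, nF, ntr), matrix(0, nF, ntr))
  yleg[1:nF] <- 0

  n_cur <- nF
  for (g in seq_len(config$n_generations - 1)) {
    set.seed(.streamSeed(seed, paste0("gen", g)))
    prev <- which(gen[1:n_cur] == g - 1L & alive110[1:n_cur])
    males <- prev[sex[prev] == "M"]; females <- prev[sex[prev] == "F"]
    if (length(males) < 2 || length(females) < 2)
      stop("generation ", g, ": too few surviving breeding candidates")
    if (config$selection == "index") {
      wm <- config$index_weights[["muscle"]]
      wf <- config$index_weights[["fat"]]
      im <- which(qt$trait == "muscle"); jf <- which(qt$trait == "fat")
      idx <- wm * pheno[, im] - wf * pheno[, jf]
      males <- males[order(-idx[males])]
      females <- females[order(-idx[females])]
      sires_g <- males[seq_len(min(config$n_sires, length(males)))]
      dams_g <- females[seq_len(min(config$n_dams, length(females)))]
    } else {
      sires_g <- sample(males, min(config$n_sires, length(males)))
      dams_g <- sample(females, min(config$n_dams, length(females)))
    }
    mate <- sample(sires_g, length(dams_g), replace = TRUE)
    sizes <- pmax(1L, rpois(length(dams_g), config$litter_mean))
    for (L in seq_along(dams_g)) {
      dm <- dams_g[L]; sr <- mate[L]
      lit_id <- sprintf("G%d_L%03d", g, L)
      lit_eff <- rnorm(ntr, 0, sqrt(qt$sigma2v))
      mat_eff <- rnorm(ntr, 0, sqrt(qt$sigma2w))
      leg_lit <- rnorm(1, 0, sqrt(tm$leg_sigma2v))
      leg_mat <- rnorm(1, 0, sqrt(tm$leg_sigma2w))
      rows <- n_cur + seq_len(sizes[L])
      for (k in seq_along(rows)) {
        i <- rows[k]
        H1[i, ] <- .gamete(H1[sr, ], H2[sr, ], chrom_index, rfrac)
        H2[i, ] <- .gamete(H1[dm, ], H2[dm, ], chrom_index, rfrac)
        id[i] <- sprintf("G%d_%05d", g, i)
        sire[i] <- id[sr]; dam[i] <- id[dm]
        sex[i] <- sample(c("M", "F"), 1)
        litter[i] <- lit_id; gen[i] <- g
        j <- seq_len(i - 1L)
        aij <- 0.5 * (A[j, sr] + A[j, dm])
        A[j, i] <- aij; A[i, j] <- aij
        A[i, i] <- 1 + 0.5 * A[sr, dm]
        Fcoef[i] <- 0.5 * A[sr, dm]
        msd <- 0.5 * (1 - (Fcoef[sr] + Fcoef[dm]) / 2)
        for (t in seq_len(ntr))
          u[i, t] <- 0.5 * (u[sr, t] + u[dm, t]) +
            rnorm(1, 0, sqrt(qt$sigma2a[t] * msd))
        uleg[i] <- 0.5 * (uleg[sr] + uleg[dm]) +
          rnorm(1, 0, sqrt(tm$leg_sigma2a * msd))
        gcaus <- H1[i, causal_col] + H2[i, causal_col]
        affected[i] <- rbinom(1, 1, if (gcaus == 2L) tm$leg_penetrance else 0)
        yleg[i] <- affected[i] + uleg[i] + leg_lit + leg_mat +
          rnorm(1, 0, sqrt(tm$leg_sigma2e))
        alive40[i] <- runif(1) < config$survival_40[[gcaus + 1L]]
        alive110[i] <- alive40[i] &&
          runif(1) < config$survival_110[[gcaus + 1L]]
      }
      lit_mat <- matrix(rep(lit_eff, each = length(rows)), ncol = ntr)
      mat_mat <- matrix(rep(mat_eff, each = length(rows)), ncol = ntr)
      .quantPheno(rows, lit_mat, mat_mat)
      n_cur <- n_cur + sizes[L]
    }
  }

  keep <- seq_len(n_cur)
  ped <- validatePedigree(data.frame(
    id = id[keep], sire = sire[keep], dam = dam[keep], sex = sex[keep],
    litter = litter[keep], generation = gen[keep],
    stringsAsFactors = FALSE))
  # simulator emits in topological order already; align all per-id data
  ord <- match(pedIds(ped), id[keep])
  marker_cols <- setdiff(seq_len(m), causal_col)
  ph <- data.frame(id = id[keep][ord],
                   litter = litter[keep][ord],
                   sex = sex[keep][ord],
                   generation = gen[keep][ord],
                   affected = affected[keep][ord],
                   leg_score = yleg[keep][ord],
                   stringsAsFactors = FALSE)
  for (t in seq_len(ntr)) ph[[qt$trait[t]]] <- pheno[keep, t][ord]
  # quantitative records only exist for animals completing the test
  surv110 <- alive110[keep][ord]
  for (t in seq_len(ntr)) ph[[qt$trait[t]]][!surv110] <- NA_real_
  flags <- cbind(birth = TRUE, wt40 = alive40[keep][ord],
                 wt110 = alive110[keep][ord])
  rownames(flags) <- ph$id
  new("Population", pedigree = ped,
      map = { mm <- full[marker_cols, ]; rownames(mm) <- NULL; mm },
      hap1 = H1[keep, marker_cols, drop = FALSE][ord, , drop = FALSE],
      hap2 = H2[keep, marker_cols, drop = FALSE][ord, , drop = FALSE],
      causalGenotype = as.integer(H1[keep, causal_col] +
                                    H2[keep, causal_col])[ord],
      causalLocus = list(chrom = config$causal_chrom,
                         pos = config$causal_pos,
                         ibd_window_bp = config$ibd_window_bp),
      phenotypes = ph, stageFlags = flags)
}

#' Re-draw phenotypes for a simulated population
#'
#' Draws a fresh phenotype realisation for an existing population under a
#' given trait model: leg weakness as a penetrance draw on TT individuals,
#' and quantitative traits as genotype mean + polygenic value (bred down
#' the pedigree by midparent + Mendelian sampling, with the inbreeding
#' correction) + litter + maternal + residual. No selection feedback:
#' the pedigree is taken as fixed. With all variances zero and penetrance
#' one, every phenotype is an exact deterministic function of genotype.
#'
#' @param pop a [Population-class]
#' @param model a [traitModel()]
#' @param seed integer seed
#' @return phenotype data.frame in pedigree order (columns as in
#'   `phenotypes(pop)`)
#' @export
assignPhenotypes <- function(pop, model, seed = 1L) {
  stopifnot(inherits(model, "TraitModel"))
  set.seed(.streamSeed(seed, "assign_pheno"))
  ped <- pop@pedigree
  df <- as.data.frame(ped)
  n <- nrow(df)
  p <- .parentIndex(ped)
  g <- pop@causalGenotype
  qt <- model$quant; ntr <- nrow(qt)
  Fc <- inbreeding(ped)

  drawU <- function(sigma2a) {
    uu <- numeric(n)
    for (i in seq_len(n)) {
      s <- p$sire[i]; d <- p$dam[i]
      if (s == 0L && d == 0L) uu[i] <- rnorm(1, 0, sqrt(sigma2a))
      else {
        us <- if (s > 0L) uu[s] else 0; ud <- if (d > 0L) uu[d] else 0
        fs <- if (s > 0L) Fc[s] else 0; fd <- if (d > 0L) Fc[d] else 0
        msd <- if (s > 0L && d > 0L) 0.5 * (1 - (fs + fd) / 2) else 0.75
        uu[i] <- 0.5 * (us + ud) + rnorm(1, 0, sqrt(sigma2a * msd))
      }
    }
    uu
  }
  lit <- df$litter
  lit_key <- ifelse(is.na(lit), paste0(".solo", seq_len(n)), lit)
  dam_key <- ifelse(is.na(df$dam), paste0(".nodam", seq_len(n)), df$dam)
  randEff <- function(keys, sigma2) {
    e <- rnorm(length(unique(keys)), 0, sqrt(sigma2))
    e[match(keys, unique(keys))]
  }
  out <- data.frame(id = df$id, litter = lit, sex = df$sex,
                    generation = df$generation, stringsAsFactors = FALSE)
  out$affected <- ifelse(g == 2L, rbinom(n, 1, model$leg_penetrance), 0L)
  out$leg_score <- out$affected + drawU(model$leg_sigma2a) +
    randEff(lit_key, model$leg_sigma2v) + randEff(dam_key, model$leg_sigma2w) +
    rnorm(n, 0, sqrt(model$leg_sigma2e))
  for (t in seq_len(ntr)) {
    mu <- c(qt$mean_GG[t], qt$mean_GT[t], qt$mean_TT[t])[g + 1L]
    out[[qt$trait[t]]] <- mu + drawU(qt$sigma2a[t]) +
      randEff(lit_key, qt$sigma2v[t]) + randEff(dam_key, qt$sigma2w[t]) +
      rnorm(n, 0, sqrt(qt$sigma2e[t]))
  }
  out
}

#' Simulate carrier-by-carrier litters segregating a recessive trait
#'
#' The mating design behind the within-litter segregation ratio: every
#' litter is produced by two heterozygous carriers, so offspring are
#' GG:GT:TT in expectation 1:2:1 and, under full penetrance, one quarter
#' are affected. The binary record is returned both as the exact affected
#' indicator and as a Gaussian-penetrance score `y = affected + N(0,
#' residual_sd^2)` suitable for the segregation sampler.
#'
#' @param n_litters number of litters
#' @param litter_mean mean litter size (Poisson truncated at 1)
#' @param penetrance probability a TT offspring is affected
#' @param residual_sd residual SD of the score
#' @param seed integer seed
#' @return list: `pedigree` ([Pedigree-class]), `phenotypes` (data.frame
#'   `id, litter, y, affected`; parents scored unaffected), `genotype`
#'   (named true T-dosage 0/1/2 per individual)
#' @export
simulateCarrierLitters <- function(n_litters, litter_mean = 8,
                                   penetrance = 1, residual_sd = 0.1,
                                   seed = 1L) {
  set.seed(.streamSeed(seed, "carrier_litters"))
  sizes <- pmax(1L, rpois(n_litters, litter_mean))
  ids <- list(); sires <- list(); dams <- list(); lits <- list()
  gts <- list()
  for (L in seq_len(n_litters)) {
    s <- sprintf("S%04d", L); d <- sprintf("D%04d", L)
    off <- sprintf("L%04d_%02d", L, seq_len(sizes[L]))
    ids[[L]] <- c(s, d, off)
    sires[[L]] <- c(NA, NA, rep(s, sizes[L]))
    dams[[L]] <- c(NA, NA, rep(d, sizes[L]))
    lits[[L]] <- c(NA, NA, rep(sprintf("LIT%04d", L), sizes[L]))
    goff <- rbinom(sizes[L], 1, 0.5) + rbinom(sizes[L], 1, 0.5)
    gts[[L]] <- c(1L, 1L, goff)
  }
  ped <- validatePedigree(data.frame(
    id = unlist(ids), sire = unlist(sires), dam = unlist(dams),
    sex = NA, litter = unlist(lits), generation = NA,
    stringsAsFactors = FALSE))
  gt <- setNames(unlist(gts), unlist(ids))[pedIds(ped)]
  aff <- ifelse(gt == 2L, rbinom(length(gt), 1, penetrance), 0L)
  y <- aff + rnorm(length(gt), 0, residual_sd)
  list(pedigree = ped,
       phenotypes = data.frame(
         id = pedIds(ped),
         litter = as.data.frame(ped)$litter,
         y = y, affected = aff, stringsAsFactors = FALSE),
       genotype = gt)
}

#' Deterministic one-locus viability selection recursion
#'
#' Iterates allele frequency under constant viability selection with
#' heterozygote-referenced fitnesses `w_GG = 1 - s1`, `w_GT = 1`,
#' `w_TT = 1 - s2`: `s1` is the carrier advantage over wildtype and `s2`
#' the homozygote disadvantage (`s2 = 1` for a lethal). With both selection
#' coefficients positive this is the classical overdominance regime, with
#' stable internal equilibrium `q* = s1 / (s1 + s2)`; a frequency of 0.22
#' for a lethal therefore implies `s1 = q*/(1 - q*) ~ 0.28`.
#'
#' @param s1 carrier advantage, in `[0, 1]`
#' @param s2 homozygote disadvantage, in `[0, 1]`
#' @param q0 initial T frequency
#' @param n_gen number of generations to iterate
#' @return list: `trajectory` (numeric, `q` at generations `0..n_gen`),
#'   `equilibrium` (`q*`; when s1 = s2 = 0 the starting frequency is
#'   returned), `neutral` flag (TRUE when s1 = s2 = 0, where the
#'   trajectory is constant and no selective equilibrium exists)
#' @examples
#' deterministicRecursion(0.25, 1, 0.22, 50)$equilibrium  # 0.2
#' @export
deterministicRecursion <- function(s1, s2, q0, n_gen) {
  if (s1 < 0 || s1 > 1 || s2 < 0 || s2 > 1)
    stop("selection coefficients must be in [0, 1]")
  if (q0 < 0 || q0 > 1) stop("q0 must be in [0, 1]")
  w <- c(GG = 1 - s1, GT = 1, TT = 1 - s2)
  q <- numeric(n_gen + 1); q[1] <- q0
  for (t in seq_len(n_gen)) {
    p <- 1 - q[t]
    wbar <- p^2 * w[["GG"]] + 2 * p * q[t] * w[["GT"]] + q[t]^2 * w[["TT"]]
    q[t + 1] <- if (wbar > 0)
      q[t] * (p * w[["GT"]] + q[t] * w[["TT"]]) / wbar else q[t]
  }
  neutral <- s1 == 0 && s2 == 0
  eq <- if (neutral) q0  # no selection: any frequency is an equilibrium
  else if (s1 == 0) 0
  else if (s2 == 0) 1
  else s1 / (s1 + s2)
  list(trajectory = q, equilibrium = eq, neutral = neutral)
}

#' Simulate a balanced half-sib design with litter structure
#'
#' Gaussian records under the sire + litter (+ maternal) linear model used
#' for binary-trait variance components on the observed scale:
#' `y = mu + sire + litter + maternal + residual`, each dam nested in one
#' sire, one litter per dam-parity, maternal effects shared across a dam's
#' litters. Used for parameter-recovery checks of the variance-component
#' sampler; truth is known by construction.
#'
#' @param n_sires,dams_per_sire,litters_per_dam,n_per_litter design sizes
#' @param mu intercept
#' @param sigma2s,sigma2v,sigma2w,sigma2e sire, litter, maternal-environment
#'   and residual variances
#' @param seed integer seed
#' @return data.frame `id, sire, dam, litter, y` plus the realised effects
#' @export
simulateHalfSib <- function(n_sires = 30, dams_per_sire = 4,
                            litters_per_dam = 2, n_per_litter = 6,
                            mu = 0, sigma2s = 1, sigma2v = 0.5,
                            sigma2w = 0.25, sigma2e = 4, seed = 1L) {
  set.seed(.streamSeed(seed, "half_sib"))
  rows <- list()
  k <- 0L
  for (s in seq_len(n_sires)) {
    es <- rnorm(1, 0, sqrt(sigma2s))
    for (d in seq_len(dams_per_sire)) {
      ew <- rnorm(1, 0, sqrt(sigma2w))
      dam_id <- sprintf("S%02dD%02d", s, d)
      for (l in seq_len(litters_per_dam)) {
        ev <- rnorm(1, 0, sqrt(sigma2v))
        lit_id <- sprintf("%sL%d", dam_id, l)
        for (o in seq_len(n_per_litter)) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            id = sprintf("O%05d", k), sire = sprintf("S%02d", s),
            dam = dam_id, litter = lit_id,
            sire_eff = es, maternal_eff = ew, litter_eff = ev,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  df$y <- mu + df$sire_eff + df$litter_eff + df$maternal_eff +
    rnorm(nrow(df), 0, sqrt(sigma2e))
  df
}
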