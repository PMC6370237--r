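#' Summarise litters for the segregation-ratio test
#'
#' @param phenotypes data.frame with columns `id`, `litter` and `affected`
#'   (0/1); rows with missing litter (e.g. founders) are ignored
#' @return data.frame `litter, n_offspring, n_affected`
#' @export
litterSummary <- function(phenotypes) {
  df <- phenotypes[!is.na(phenotypes$litter), , drop = FALSE]
  if (!nrow(df)) stop("no littered individuals")
  agg <- aggregate(df$affected, by = list(litter = df$litter),
                   FUN = function(x) c(n = length(x), aff = sum(x)))
  data.frame(litter = agg$litter,
             n_offspring = agg$x[, "n"], n_affected = agg$x[, "aff"],
             stringsAsFactors = FALSE)
}

#' Pooled within-litter segregation-ratio test
#'
#' Pools the offspring of all litters containing at least one affected
#' individual and tests the pooled affected proportion against the
#' Mendelian expectation for a fully penetrant recessive from
#' carrier-by-carrier matings (`expected_p = 0.25`) with a 1-df
#' chi-square. Conditioning on litters with at least one affected case
#' slightly inflates the crude mean of within-litter proportions (litters
#' with no affected by chance are excluded), which is why the pooled
#' proportion, not the mean proportion, is tested.
#'
#' @param litters data.frame from [litterSummary()] (`litter, n_offspring,
#'   n_affected`)
#' @param expected_p expected affected probability under the null
#' @return list: `p_hat` (pooled proportion), `chi2`, `p_value`,
#'   `n_pooled`, `n_litters_affected`, `mean_within_litter` and
#'   `se_within_litter` (mean and SE of per-litter proportions)
#' @examples
#' litterRatioTest(data.frame(litter = 1:3, n_offspring = 8,
#'                            n_affected = c(2, 3, 1)))$p_hat  # 0.25
#' @export
litterRatioTest <- function(litters, expected_p = 0.25) {
  aff <- litters[litters$n_affected >= 1, , drop = FALSE]
  if (!nrow(aff)) stop("no affected litters")
  if (any(aff$n_affected > aff$n_offspring))
    stop("n_affected exceeds n_offspring")
  N <- sum(aff$n_offspring)
  X <- sum(aff$n_affected)
  p_hat <- X / N
  chi2 <- (X - N * expected_p)^2 / (N * expected_p * (1 - expected_p))
  props <- aff$n_affected / aff$n_offspring
  list(p_hat = p_hat, chi2 = chi2,
       p_value = pchisq(chi2, 1, lower.tail = FALSE),
       n_pooled = N, n_litters_affected = nrow(aff),
       mean_within_litter = mean(props),
       se_within_litter = sd(props) / sqrt(length(props)))
}

# genotype-class means under the (mu, a, d) parameterisation:
# GG -> mu - a, GT -> mu + d, TT -> mu + a (T-dosage 0/1/2)
.classMeans <- function(mu, a, d) c(mu - a, mu + d, mu + a)

# Likelihood-aware, Mendelian-consistent initial genotype configuration.
# Single-site updates cannot escape a state where both parents of a
# clearly-affected offspring are homozygous wildtype (the offspring's full
# conditional is then degenerate), so the chain must start near the
# phenotype-supported configuration: read a provisional 3-class split off
# the phenotype, then repair it to positive transmission probability
# (parents of carriers/homozygotes made carriers, impossible children
# resampled from their parents).
.initGenotypes <- function(y, pa, q) {
  n <- length(pa$sire)
  geno <- integer(n)
  obs <- which(!is.na(y))
  yr <- range(y[obs])
  if (diff(yr) > sqrt(.Machine$double.eps)) {
    cuts <- yr[1] + diff(yr) * c(1, 2) / 3
    geno[obs] <- as.integer(cut(y[obs], c(-Inf, cuts, Inf))) - 1L
  }
  for (i in seq_len(n)) {       # unphenotyped: draw from parents / HWE
    if (!is.na(y[i])) next
    s <- pa$sire[i]; d <- pa$dam[i]
    gs <- if (s > 0L) rbinom(1, 1, geno[s] / 2) else rbinom(1, 1, q)
    gd <- if (d > 0L) rbinom(1, 1, geno[d] / 2) else rbinom(1, 1, q)
    geno[i] <- gs + gd
  }
  for (i in rev(seq_len(n))) {  # upward repair: parents must carry T
    s <- pa$sire[i]; d <- pa$dam[i]
    if (geno[i] == 2L) {
      if (s > 0L && geno[s] == 0L) geno[s] <- 1L
      if (d > 0L && geno[d] == 0L) geno[d] <- 1L
    } else if (geno[i] == 1L && s > 0L && d > 0L &&
               geno[s] == 0L && geno[d] == 0L) {
      geno[s] <- 1L
    }
  }
  for (i in seq_len(n)) {       # downward repair: children must be legal
    s <- pa$sire[i]; d <- pa$dam[i]
    if (s == 0L && d == 0L) next
    gs <- if (s > 0L) geno[s] else 1L   # unknown parent can transmit both
    gd <- if (d > 0L) geno[d] else 1L
    lo <- (gs == 2L) + (gd == 2L)       # forced minimum T copies
    hi <- 2L - (gs == 0L) - (gd == 0L)  # available T copies
    geno[i] <- min(max(geno[i], lo), hi)
  }
  geno
}

.prepPedArrays <- function(ped) {
  p <- .parentIndex(ped)
  n <- length(p$id)
  children <- vector("list", n)
  childMate <- vector("list", n)
  for (i in seq_len(n)) {
    children[[i]] <- integer(0); childMate[[i]] <- integer(0)
  }
  for (c in seq_len(n)) {
    s <- p$sire[c]; d <- p$dam[c]
    if (s > 0L) {
      children[[s]] <- c(children[[s]], c)
      childMate[[s]] <- c(childMate[[s]], d)
    }
    if (d > 0L) {
      children[[d]] <- c(children[[d]], c)
      childMate[[d]] <- c(childMate[[d]], s)
    }
  }
  list(sire = p$sire, dam = p$dam, children = children,
       childMate = childMate, ids = p$id,
       founder = p$sire == 0L & p$dam == 0L)
}

#' Bayesian monogenic segregation analysis by Gibbs sampling
#'
#' Fits a single biallelic major locus with environmental variation to
#' pedigree phenotypes: founders drawn from Hardy-Weinberg proportions at
#' frequency `q`, Mendelian transmission down the pedigree, and a Gaussian
#' penetrance on the observed scale with genotype means `mu - a` (GG),
#' `mu + d` (GT) and `mu + a` (TT) and residual variance `sigma2e`. For a
#' fully penetrant recessive scored 0/1 the expectation is `a = 0.5` and
#' `d = -0.5`. The sampler alternates (i) single-site genotype updates
#' from each individual's full conditional (parent transmission x
#' transmission to offspring with current mates x phenotype likelihood),
#' (ii) a conjugate Beta update of `q` from founder allele counts, (iii) a
#' joint conjugate normal update of `(mu, a, d)` via the saturated
#' genotype-class means, and (iv) a scaled inverse-chi-square update of
#' `sigma2e`. Draws are relabelled to the `a >= 0` orientation (allele
#' labels are not identified by the likelihood).
#'
#' @param ped a [Pedigree-class]
#' @param phenotypes data.frame with `id` and the trait column; individuals
#'   absent from it get a missing phenotype
#' @param trait name of the phenotype column (numeric; 0/1 allowed)
#' @param n_iter,burn_in,thin chain control (defaults 20000 / 5000 / 5)
#' @param seed integer seed (mandatory for reproducibility)
#' @param priors list; `q_beta = c(1, 1)` are the Beta prior counts for
#'   `q`. `(mu, a, d)` carry improper flat priors and `sigma2e` the flat
#'   scaled-inverse-chi-square with nu = -2
#' @param fix_params optional list `q, mu, a, d, sigma2e`: hold all model
#'   parameters fixed and sample genotypes only, so the genotype
#'   posteriors are directly comparable with
#'   [exactSegregationPosterior()] at the same values
#' @return a [MonogenicPosterior-class]
#' @export
gibbsSegregation <- function(ped, phenotypes, trait = "y",
                             n_iter = 20000, burn_in = 5000, thin = 5,
                             seed, priors = list(q_beta = c(1, 1)),
                             fix_params = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (burn_in >= n_iter) stop("chain shorter than burn-in")
  pa <- .prepPedArrays(ped)
  n <- length(pa$ids)
  y <- rep(NA_real_, n)
  hit <- match(pa$ids, phenotypes$id)
  y[!is.na(hit)] <- phenotypes[[trait]][hit[!is.na(hit)]]
  if (any(is.nan(y) | is.infinite(y)))
    stop("non-finite phenotype values")
  n_obs <- sum(!is.na(y))
  if (n_obs < 4) stop("too few phenotyped individuals")
  qb <- priors$q_beta %||% c(1, 1)

  set.seed(.streamSeed(seed, "gibbs_segregation"))
  q <- 0.25
  geno <- .initGenotypes(y, pa, q)
  mu <- mean(y, na.rm = TRUE); a <- sd(y, na.rm = TRUE); d_dev <- 0
  s2e <- max(var(y, na.rm = TRUE) / 2, 1e-4)
  fixed <- !is.null(fix_params)
  if (fixed) {
    need <- c("q", "mu", "a", "d", "sigma2e")
    if (!all(need %in% names(fix_params)))
      stop("fix_params needs all of: ", paste(need, collapse = ", "))
    q <- fix_params$q; mu <- fix_params$mu; a <- fix_params$a
    d_dev <- fix_params$d; s2e <- fix_params$sigma2e
  }
  nf <- sum(pa$founder)
  obs <- which(!is.na(y))

  keep_at <- seq(burn_in + thin, n_iter, by = thin)
  draws <- matrix(NA_real_, length(keep_at), 6,
                  dimnames = list(NULL, c("q", "mu", "a", "d", "sigma2e",
                                          "locus_var_share")))
  gprob <- matrix(0, n, 3)
  ki <- 0L
  cm <- .classMeans(mu, a, d_dev)
  for (it in seq_len(n_iter)) {
    gibbs_genotype_sweep(geno, pa$sire, pa$dam, pa$children, pa$childMate,
                         y, cm, s2e, q)
    if (!fixed) {
      tf <- sum(geno[pa$founder])
      q <- rbeta(1, qb[1] + tf, qb[2] + 2 * nf - tf)
      # joint (mu, a, d) via independent class means (saturated design)
      m <- cm
      for (g in 0:2) {
        sel <- obs[geno[obs] == g]
        if (length(sel))
          m[g + 1] <- rnorm(1, mean(y[sel]), sqrt(s2e / length(sel)))
        # empty class: flat full conditional, retain current value
      }
      mu <- (m[1] + m[3]) / 2; a <- (m[3] - m[1]) / 2; d_dev <- m[2] - mu
      cm <- .classMeans(mu, a, d_dev)
      sse <- sum((y[obs] - cm[geno[obs] + 1])^2)
      s2e <- max(sse / rchisq(1, max(n_obs - 2, 3)), 1e-10)
    }
    if (ki < length(keep_at) && it == keep_at[ki + 1L]) {
      ki <- ki + 1L
      flip <- !fixed && a < 0
      qs <- if (flip) 1 - q else q
      as <- abs(a)
      pg <- tabulate(geno[obs] + 1L, 3L) / n_obs
      mbar <- sum(pg * cm)
      vloc <- sum(pg * (cm - mbar)^2)
      draws[ki, ] <- c(qs, mu, as, d_dev, s2e, vloc / (vloc + s2e))
      idx <- if (flip) 3L - geno else geno + 1L
      gprob[cbind(seq_len(n), idx)] <- gprob[cbind(seq_len(n), idx)] + 1
    }
  }
  gprob <- gprob / length(keep_at)
  dimnames(gprob) <- list(pa$ids, c("GG", "GT", "TT"))
  dd <- as.data.frame(draws)
  summ <- data.frame(
    mean = colMeans(dd), sd = apply(dd, 2, sd),
    ci_2.5 = apply(dd, 2, quantile, 0.025),
    ci_97.5 = apply(dd, 2, quantile, 0.975))
  new("MonogenicPosterior", draws = dd, summary = summ,
      genotypeProb = gprob)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact genotype posteriors by pedigree enumeration
#'
#' Brute-force oracle for small pedigrees: sums over every genotype
#' configuration (3^n, so at most 10 individuals), with founder
#' Hardy-Weinberg priors at fixed `q`, Mendelian transmission (unknown
#' single parents integrated over HWE) and the same Gaussian penetrance as
#' [gibbsSegregation()] at fixed parameter values.
#'
#' @param ped a [Pedigree-class] with at most 10 individuals
#' @param phenotypes data.frame with `id` and the trait column (`NA` =
#'   unobserved)
#' @param trait phenotype column name
#' @param q,mu,a,d,sigma2e fixed model parameters
#' @return list: `genotypeProb` (n x 3 matrix `GG, GT, TT`),
#'   `log_marginal` (log marginal likelihood of the observed phenotypes)
#' @export
exactSegregationPosterior <- function(ped, phenotypes, trait = "y",
                                      q, mu, a, d, sigma2e) {
  pa <- .prepPedArrays(ped)
  n <- length(pa$ids)
  if (n > 10) stop("pedigree too large for exact enumeration (max 10)")
  y <- rep(NA_real_, n)
  hit <- match(pa$ids, phenotypes$id)
  y[!is.na(hit)] <- phenotypes[[trait]][hit[!is.na(hit)]]
  cm <- .classMeans(mu, a, d)
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  tr <- array(0, c(3, 3, 3))   # P(child | sire, dam), dosage+1 indexing
  for (gs in 0:2) for (gd in 0:2) {
    ps <- gs / 2; pd <- gd / 2
    tr[1, gs + 1, gd + 1] <- (1 - ps) * (1 - pd)
    tr[2, gs + 1, gd + 1] <- ps * (1 - pd) + (1 - ps) * pd
    tr[3, gs + 1, gd + 1] <- ps * pd
  }
  trU <- matrix(0, 3, 3)       # P(child | one parent), mate ~ HWE(q)
  for (gp in 0:2) for (gc in 0:2)
    trU[gc + 1, gp + 1] <- sum(hw * tr[gc + 1, gp + 1, ])
  configs <- as.matrix(expand.grid(rep(list(0:2), n)))
  logp <- numeric(nrow(configs))
  for (i in seq_len(n)) {
    s <- pa$sire[i]; d_ <- pa$dam[i]
    gi <- configs[, i] + 1L
    pri <- if (s > 0L && d_ > 0L)
      tr[cbind(gi, configs[, s] + 1L, configs[, d_] + 1L)]
    else if (s > 0L) trU[cbind(gi, configs[, s] + 1L)]
    else if (d_ > 0L) trU[cbind(gi, configs[, d_] + 1L)]
    else hw[gi]
    logp <- logp + log(pri)
    if (!is.na(y[i]))
      logp <- logp + dnorm(y[i], cm[gi], sqrt(sigma2e), log = TRUE)
  }
  mx <- max(logp)
  w <- exp(logp - mx)
  post <- w / sum(w)
  gp <- matrix(0, n, 3, dimnames = list(pa$ids, c("GG", "GT", "TT")))
  for (i in seq_len(n))
    for (g in 0:2) gp[i, g + 1] <- sum(post[configs[, i] == g])
  list(genotypeProb = gp, log_marginal = mx + log(sum(w)))
}
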