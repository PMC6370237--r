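#' Pedigree mixed-model genotype association
#'
#' Estimates the carrier effect (GT vs GG; a single degree of freedom when
#' no mutant homozygote survives to measurement) on a quantitative trait
#' under the animal model `y = X beta + g b + Z u + e`, with polygenic
#' effects `u ~ MVN(0, A sigma2a)` structured by the pedigree numerator
#' relationship matrix. The variance ratio `lambda = sigma2e / sigma2a` is
#' profiled out of the residual (REML) likelihood on a 50-point log-spaced
#' grid over `[1e-3, 1e3]` with local refinement at the maximiser, unless
#' supplied. The genotype effect is tested with a 1-df Wald test.
#'
#' @param data data.frame with columns `id`, the response, the genotype
#'   indicator and any fixed covariates
#' @param response trait column name
#' @param genotype name of the 0/1 genotype column (0 = GG, 1 = GT)
#' @param fixed one-sided formula of nuisance fixed effects
#' @param ped a [Pedigree-class] covering all ids (ancestry may extend
#'   beyond the phenotyped animals)
#' @param lambda optional fixed variance ratio `sigma2e / sigma2a`;
#'   `NULL` profiles it
#' @return list: `b` (GT - GG, trait units), `se_b`, `wald`, `p_value`,
#'   `b_std` (`b / sigmaP`), `sigmaP` (phenotypic SD,
#'   `sqrt(sigma2a + sigma2e)`), `sigma2a`, `sigma2e`, `lambda`,
#'   `lsmeans` (adjusted GG and GT means at covariate means), `n`
#' @export
fitAssociation <- function(data, response = "y", genotype = "geno",
                           fixed = ~ 1, ped, lambda = NULL) {
  y <- data[[response]]
  g <- data[[genotype]]
  if (anyNA(y) || anyNA(g)) stop("missing response or genotype values")
  if (length(unique(g)) < 2) stop("genotype column is constant")
  X <- model.matrix(fixed, data)
  W <- cbind(X, geno = g)
  if (qr(W)$rank < ncol(W)) stop("singular fixed-effect design")
  n <- nrow(W); p <- ncol(W)
  A <- aMatrix(ped, as.character(data$id))
  eg <- eigen(A, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  yt <- drop(crossprod(eg$vectors, y))
  Wt <- crossprod(eg$vectors, W)

  gls <- function(lam) {
    wts <- 1 / (d + lam)
    WtW <- crossprod(Wt * wts, Wt)
    Rc <- chol(WtW)
    bhat <- backsolve(Rc, forwardsolve(t(Rc), crossprod(Wt * wts, yt)))
    r <- yt - drop(Wt %*% bhat)
    rss <- sum(r^2 * wts)
    s2a <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(s2a) + sum(log(d + lam)) +
                    2 * sum(log(diag(Rc))) + (n - p))
    list(ll = ll, bhat = drop(bhat), s2a = s2a, Rc = Rc)
  }
  if (is.null(lambda)) {
    grid <- exp(seq(log(1e-3), log(1e3), length.out = 50))
    lls <- vapply(grid, function(l) gls(l)$ll, numeric(1))
    i <- which.max(lls)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(function(l) gls(exp(l))$ll, c(log(lo), log(hi)),
                    maximum = TRUE, tol = 1e-6)
    lambda <- exp(opt$maximum)
  }
  fit <- gls(lambda)
  covb <- chol2inv(fit$Rc) * fit$s2a
  b <- fit$bhat[p]
  se <- sqrt(covb[p, p])
  wald <- (b / se)^2
  s2a <- fit$s2a; s2e <- lambda * s2a
  sigmaP <- sqrt(s2a + s2e)
  xbar <- colMeans(X)
  mu_GG <- sum(c(xbar, 0) * fit$bhat)
  list(b = b, se_b = se, wald = wald,
       p_value = pchisq(wald, 1, lower.tail = FALSE),
       b_std = standardizeEffect(b, sigmaP), sigmaP = sigmaP,
       sigma2a = s2a, sigma2e = s2e, lambda = lambda,
       lsmeans = c(GG = mu_GG, GT = mu_GG + b), n = n)
}

#' Standardise a genotype effect by the phenotypic SD
#'
#' @param b effect in trait units
#' @param sigmaP phenotypic standard deviation (> 0)
#' @param digits optional rounding
#' @return `b / sigmaP`, unitless
#' @examples
#' standardizeEffect(4.83, 5.95, digits = 2)   #  0.81
#' standardizeEffect(-1.76, 2.72, digits = 2)  # -0.65
#' @export
standardizeEffect <- function(b, sigmaP, digits = NULL) {
  if (any(sigmaP <= 0)) stop("sigmaP must be positive")
  out <- b / sigmaP
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Share of additive genetic variance explained by one locus
#'
#' The locus variance is the genotype-frequency-weighted variance of the
#' genotype means; the share is taken relative to the total
#' `locus variance + background polygenic variance`.
#'
#' @param freqs genotype frequencies (must be non-negative, sum to 1)
#' @param means genotype means, same length
#' @param sigma2a_background residual polygenic variance (> 0)
#' @return fraction in `[0, 1]`
#' @examples
#' locusVarianceShare(c(0.5, 0.5), c(0, 2), 1)  # 0.5: g^2/4 vs sigma2a 1
#' @export
locusVarianceShare <- function(freqs, means, sigma2a_background) {
  if (length(freqs) != length(means)) stop("freqs/means length mismatch")
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("degenerate genotype frequencies")
  if (sigma2a_background <= 0) stop("background variance must be positive")
  mbar <- sum(freqs * means)
  vloc <- sum(freqs * (means - mbar)^2)
  vloc / (vloc + sigma2a_background)
}
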