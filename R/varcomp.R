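#' Variance components for a binary trait by Gibbs sampling
#'
#' Linear mixed model on the observed 0/1 scale, fitted with a conjugate
#' blocked Gibbs sampler: fixed effects and each random term are drawn
#' from their multivariate-normal full conditionals via the mixed-model
#' equations, and each variance from its scaled inverse-chi-square full
#' conditional (flat prior, nu = -2). Genetic terms (`sire`, `dam`,
#' `animal`) carry the pedigree numerator-relationship covariance
#' `A * sigma2`; `litter` and `maternal` (dam environment across litters)
#' are identity-structured.
#'
#' @param data data.frame with the response, the random-term id columns
#'   (`sire`, `dam`, `litter`, `id` as applicable) and any fixed-effect
#'   columns
#' @param response name of the 0/1 (or continuous) response column
#' @param fixed one-sided formula of fixed effects (default intercept only)
#' @param genetic character: `"sire"`, c(`"sire"`, `"dam"`) or `"animal"`
#' @param environmental character subset of `c("litter", "maternal")`
#' @param ped optional [Pedigree-class] for the A-structure of genetic
#'   terms; when `NULL` genetic levels are treated as unrelated
#' @param n_iter,burn_in,thin chain control
#' @param seed integer seed
#' @return list: `draws` (data.frame of variance-component draws,
#'   including the derived `sigma2p` = sum of fitted components),
#'   `summary` (posterior mean/sd/95% interval), `h2` (posterior
#'   mean/sd of the model's heritability, see [heritability()])
#' @export
gibbsVarComp <- function(data, response = "y", fixed = ~ 1,
                         genetic = "sire",
                         environmental = c("litter", "maternal"),
                         ped = NULL, n_iter = 4000, burn_in = 1000,
                         thin = 2, seed = 1L) {
  if (burn_in >= n_iter) stop("chain shorter than burn-in")
  y <- data[[response]]
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite response values")
  n <- length(y)
  X <- model.matrix(fixed, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("confounded fixed effects, aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  genetic <- match.arg(genetic, c("sire", "dam", "animal"),
                       several.ok = TRUE)
  if ("animal" %in% genetic && length(genetic) > 1)
    stop("animal model cannot be combined with sire/dam terms")
  terms <- list()
  addTerm <- function(key, col, structured) {
    f <- factor(data[[col]])
    Ainv <- if (structured && !is.null(ped)) solve(aMatrix(ped, levels(f)))
    else NULL  # identity structure: diagonal normal equations
    terms[[key]] <<- list(fidx = as.integer(f), counts = tabulate(f),
                          Ainv = Ainv, q = nlevels(f))
  }
  for (g in genetic)
    addTerm(g, if (g == "animal") "id" else g, structured = TRUE)
  for (e in environmental)
    addTerm(e, if (e == "maternal") "dam" else e, structured = FALSE)
  if (!length(terms)) stop("no random terms specified")

  set.seed(.streamSeed(seed, "gibbs_varcomp"))
  p <- ncol(X)
  XtX <- crossprod(X)
  RX <- chol(XtX)
  beta <- qr.coef(qrX, y)
  u <- lapply(terms, function(tm) numeric(tm$q))
  s2 <- setNames(rep(var(y) / (length(terms) + 1), length(terms)),
                 names(terms))
  s2e <- var(y) / 2
  floor_v <- 1e-8 * max(var(y), 1e-8)

  keep_at <- seq(burn_in + thin, n_iter, by = thin)
  cols <- c(paste0("sigma2_", names(terms)), "sigma2_e", "sigma2_p")
  draws <- matrix(NA_real_, length(keep_at), length(cols),
                  dimnames = list(NULL, cols))
  ki <- 0L
  fitted_random <- function() {
    out <- numeric(n)
    for (k in names(terms)) out <- out + u[[k]][terms[[k]]$fidx]
    out
  }
  for (it in seq_len(n_iter)) {
    r <- y - fitted_random()
    bhat <- backsolve(RX, forwardsolve(t(RX), crossprod(X, r)))
    beta <- drop(bhat + backsolve(RX, rnorm(p)) * sqrt(s2e))
    xb <- drop(X %*% beta)
    for (k in names(terms)) {
      tm <- terms[[k]]
      rk <- y - xb
      for (j in names(terms)) if (j != k)
        rk <- rk - u[[j]][terms[[j]]$fidx]
      lam <- s2e / max(s2[k], floor_v)
      Ztr <- drop(rowsum(rk, tm$fidx, reorder = TRUE))
      zr <- numeric(tm$q)
      zr[sort(unique(tm$fidx))] <- Ztr
      if (is.null(tm$Ainv)) {     # identity: diagonal full conditional
        dC <- tm$counts + lam
        u[[k]] <- zr / dC + rnorm(tm$q) * sqrt(s2e / dC)
        ss <- sum(u[[k]]^2)
      } else {
        C <- diag(tm$counts, tm$q) + lam * tm$Ainv
        Rc <- chol(C)
        mean_u <- backsolve(Rc, forwardsolve(t(Rc), zr))
        u[[k]] <- drop(mean_u + backsolve(Rc, rnorm(tm$q)) * sqrt(s2e))
        ss <- drop(crossprod(u[[k]], tm$Ainv %*% u[[k]]))
      }
      s2[k] <- max(ss / rchisq(1, max(tm$q - 2, 1)), floor_v)
    }
    res <- y - xb - fitted_random()
    s2e <- sum(res^2) / rchisq(1, max(n - 2, 1))
    if (ki < length(keep_at) && it == keep_at[ki + 1L]) {
      ki <- ki + 1L
      draws[ki, ] <- c(s2, s2e, sum(s2) + s2e)
    }
  }
  dd <- as.data.frame(draws)
  summ <- data.frame(mean = colMeans(dd), sd = apply(dd, 2, sd),
                     ci_2.5 = apply(dd, 2, quantile, 0.025),
                     ci_97.5 = apply(dd, 2, quantile, 0.975))
  model <- if ("animal" %in% genetic) "animal"
  else if (all(c("sire", "dam") %in% genetic)) "sire_dam" else "sire"
  h2d <- apply(dd, 1, function(z) {
    vc <- c(sigma2s = unname(z["sigma2_sire"]),
            sigma2d = unname(z["sigma2_dam"]),
            sigma2a = unname(z["sigma2_animal"]),
            sigma2p = unname(z["sigma2_p"]))
    heritability(vc[!is.na(vc)], model = model)$h2
  })
  list(draws = dd, summary = summ,
       h2 = c(mean = mean(h2d), sd = sd(h2d)), model = model)
}

#' Heritability and variance ratios from fitted components
#'
#' Applies the model-specific heritability formula: `4 * sigma2s / sigma2p`
#' for a sire model, `2 * (sigma2s + sigma2d) / sigma2p` for a sire-and-dam
#' model, and `sigma2a / sigma2p` for an animal model, plus the litter and
#' maternal-environment variance ratios when those components are given.
#' Sire-model estimates can exceed 1 in small samples; values above 1 are
#' flagged rather than truncated.
#'
#' @param components named numeric vector with the applicable entries of
#'   `sigma2s, sigma2d, sigma2a, sigma2v, sigma2w, sigma2p` (squared trait
#'   units); `sigma2p` is required
#' @param model `"sire"`, `"sire_dam"` or `"animal"`
#' @return list: `h2`, `ratio_v`, `ratio_w` (NA when the component is
#'   absent), `scale = "observed"`, `flag_h2_gt_1`
#' @examples
#' heritability(c(sigma2s = 1.100, sigma2d = 0.664, sigma2p = 6.182),
#'              model = "sire_dam")$h2  # 0.57
#' @export
heritability <- function(components, model = c("sire", "sire_dam",
                                               "animal")) {
  model <- match.arg(model)
  cmp <- function(nm) if (nm %in% names(components))
    unname(components[[nm]]) else NA_real_
  if (any(components < 0, na.rm = TRUE))
    stop("variance components must be non-negative")
  s2p <- cmp("sigma2p")
  if (is.na(s2p)) stop("sigma2p is required")
  if (s2p <= 0) stop("sigma2p must be positive")
  h2 <- switch(model,
    sire = 4 * cmp("sigma2s") / s2p,
    sire_dam = 2 * (cmp("sigma2s") + cmp("sigma2d")) / s2p,
    animal = cmp("sigma2a") / s2p)
  list(h2 = h2,
       ratio_v = cmp("sigma2v") / s2p,
       ratio_w = cmp("sigma2w") / s2p,
       scale = "observed",
       flag_h2_gt_1 = isTRUE(h2 > 1))
}

#' Dempster-Lerner liability transformation
#'
#' Converts an observed-scale (0/1) heritability to the underlying
#' liability scale: `h2_liab = h2_obs * p * (1 - p) / z^2`, where `p` is
#' the trait prevalence and `z` the standard normal density at the
#' liability threshold `qnorm(1 - p)`. At `p = 0.5` the multiplier is
#' `pi / 2`.
#'
#' @param h2_obs observed-scale heritability
#' @param prevalence trait prevalence `p`, strictly inside (0, 1)
#' @return heritability on the liability scale
#' @examples
#' liabilityTransform(1, 0.5)           # pi/2
#' liabilityTransform(0.28, 0.063)      # the 6.3%-prevalence multiplier
#' @export
liabilityTransform <- function(h2_obs, prevalence) {
  if (any(prevalence <= 0) || any(prevalence >= 1))
    stop("prevalence must be strictly inside (0, 1)")
  z <- dnorm(qnorm(1 - prevalence))
  h2_obs * prevalence * (1 - prevalence) / z^2
}
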