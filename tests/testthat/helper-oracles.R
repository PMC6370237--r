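# Independent brute-force oracles used across the suite. Each reimplements
# the quantity it checks by a different route than the package code.

# kinship coefficient by the top-down recursion f(i,j); F_i = f(sire,dam)
oracle_kinship <- function(ped_df) {
  ids <- ped_df$id
  si <- match(ped_df$sire, ids)
  di <- match(ped_df$dam, ids)
  memo <- new.env()
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + f(si[i], di[i]))
    } else {
      # j is never an ancestor of i when j appears later in the table
      0.5 * (f(i, si[j]) + f(i, di[j]))
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- f(i, j)
  dimnames(K) <- list(ids, ids)
  K
}

# random valid pedigree: each non-founder picks parents among earlier ids
random_pedigree <- function(n, n_founders = 5, seed = 1) {
  set.seed(seed)
  id <- sprintf("i%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  for (i in (n_founders + 1):n) {
    males <- which(sex[1:(i - 1)] == "M")
    females <- which(sex[1:(i - 1)] == "F")
    if (length(males)) sire[i] <- id[males[sample.int(length(males), 1)]]
    if (length(females)) dam[i] <- id[females[sample.int(length(females), 1)]]
  }
  data.frame(id = id, sire = sire, dam = dam, sex = sex,
             stringsAsFactors = FALSE)
}

# brute-force longest shared case-homozygous interval: scan all O(m^2)
# intervals on one chromosome
oracle_longest_run <- function(cases, allow_case_het = 0) {
  m <- ncol(cases)
  qualifies <- function(j) {
    g <- cases[, j]; g <- g[!is.na(g)]
    if (!length(g)) return(FALSE)
    any(vapply(c(0, 2), function(h)
      sum(g != h) <= allow_case_het && any(g == h), TRUE))
  }
  ok <- vapply(seq_len(m), qualifies, TRUE)
  best <- 0
  for (a in seq_len(m)) for (b in a:m) {
    if (all(ok[a:b])) best <- max(best, b - a + 1)
  }
  best
}

# brute-force recessive-candidate predicate for one variant
oracle_candidate <- function(gc, gk, gn, max_het = 0, max_homref = 0) {
  gc <- gc[!is.na(gc)]; gk <- gk[!is.na(gk)]; gn <- gn[!is.na(gn)]
  for (h in c(0, 2)) {
    cases_ok <- !any(gc == 2 - h) && sum(gc == 1) <= max_het
    carr_ok <- !any(gk == h) && sum(gk == 2 - h) <= max_homref
    ctrl_ok <- all(gn == 2 - h)
    if (cases_ok && carr_ok && ctrl_ok) return(TRUE)
  }
  FALSE
}

# second, independent enumeration of the monogenic-model marginal
# likelihood: loops configurations one at a time with its own
# transmission arithmetic
oracle_marginal_lik <- function(ped, y, q, mu, a, d, s2e) {
  df <- as.data.frame(ped)
  n <- nrow(df)
  si <- match(df$sire, df$id); di <- match(df$dam, df$id)
  means <- c(mu - a, mu + d, mu + a)
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  gam <- function(g) c(1 - g / 2, g / 2)  # P(transmit G), P(transmit T)
  tot <- 0
  for (code in 0:(3^n - 1)) {
    cfg <- (code %/% 3^(seq_len(n) - 1)) %% 3
    pr <- 1
    for (i in seq_len(n)) {
      pi_ <- if (is.na(si[i]) && is.na(di[i])) hw[cfg[i] + 1]
      else {
        ps <- if (is.na(si[i])) {
          c(sum(hw * c(1, 0.5, 0)), sum(hw * c(0, 0.5, 1)))
        } else gam(cfg[si[i]])
        pd <- if (is.na(di[i])) {
          c(sum(hw * c(1, 0.5, 0)), sum(hw * c(0, 0.5, 1)))
        } else gam(cfg[di[i]])
        pp <- c(ps[1] * pd[1], ps[1] * pd[2] + ps[2] * pd[1], ps[2] * pd[2])
        pp[cfg[i] + 1]
      }
      pr <- pr * pi_
      if (!is.na(y[i]))
        pr <- pr * dnorm(y[i], means[cfg[i] + 1], sqrt(s2e))
    }
    tot <- tot + pr
  }
  log(tot)
}
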