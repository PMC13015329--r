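# Independent oracles, deliberately written with different algorithms than
# the package implementations they check.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ranked[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exact conditional HWE by direct enumeration over every heterozygote count
# compatible with the allele counts, probabilities from products of ratios.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((na - h) / 2) + h * log(2) +
          lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Joint multiple regression oracle: coefficient of g in lm on [1, X, g]
ols_oracle <- function(y, g, X = NULL) {
  Z <- cbind(1, X, g)
  fit <- stats::lm.fit(Z, y)
  cf <- fit$coefficients
  slope <- unname(cf[length(cf)])
  res <- fit$residuals
  dof <- length(y) - ncol(Z)
  s2 <- sum(res^2) / dof
  XtXi <- solve(crossprod(Z))
  se <- sqrt(s2 * XtXi[ncol(Z), ncol(Z)])
  list(slope = slope, se = se, t = slope / se,
       p = 2 * stats::pt(-abs(slope / se), dof))
}

# 2-D grid-search maximum likelihood for the beta-binomial, refined in three
# zoom stages; returns the ML imbalance beta/(alpha+beta) with y = ALT reads.
betabinom_grid_oracle <- function(y, n) {
  ll <- function(mu, conc) {
    a <- conc * (1 - mu)  # REF shape
    b <- conc * mu        # ALT shape
    sum(lchoose(n, y) + lbeta((n - y) + a, y + b) - lbeta(a, b))
  }
  mu_lo <- 0.01; mu_hi <- 0.99
  lc_lo <- log(0.5); lc_hi <- log(1e6)
  best <- c(mu = 0.5, lc = log(10))
  for (stage in 1:4) {
    mus <- seq(mu_lo, mu_hi, length.out = 61)
    lcs <- seq(lc_lo, lc_hi, length.out = 41)
    vals <- outer(mus, lcs, Vectorize(function(m, l) ll(m, exp(l))))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    best <- c(mu = mus[ix[1]], lc = lcs[ix[2]])
    dmu <- (mu_hi - mu_lo) / 60; dlc <- (lc_hi - lc_lo) / 40
    mu_lo <- max(1e-4, best["mu"] - 2 * dmu)
    mu_hi <- min(1 - 1e-4, best["mu"] + 2 * dmu)
    lc_lo <- best["lc"] - 2 * dlc
    lc_hi <- best["lc"] + 2 * dlc
  }
  list(imbalance = unname(best["mu"]), loglik = ll(best["mu"], exp(best["lc"])))
}

# Direct analytic evaluation of the toy PWM model: naive per-position loops.
toy_model_oracle <- function(model, seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  out <- numeric(length(model$cell_types))
  names(out) <- model$cell_types
  for (ct in model$cell_types) {
    s <- 0
    for (pwm in model$pwms[[ct]]) {
      w <- ncol(pwm)
      bestv <- -Inf
      for (pos in seq_len(length(ch) - w + 1)) {
        sc <- 0
        for (j in seq_len(w)) {
          base <- ch[pos + j - 1]
          sc <- sc + if (base %in% rownames(pwm)) pwm[base, j] else 0
        }
        if (sc > bestv) bestv <- sc
      }
      s <- s + bestv
    }
    x <- model$weight * s + model$intercept
    out[ct] <- if (x > 30) x else log1p(exp(x))
  }
  out
}

# null beta-binomial sampler for calibration checks
rbetabinom <- function(nrep, n, mu, conc) {
  p <- stats::rbeta(nrep, conc * mu, conc * (1 - mu))
  stats::rbinom(nrep, n, p)
}
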