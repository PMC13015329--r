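#' Beta-binomial log-likelihood
#'
#' `log BetaBinomial(y | n, alpha, beta)` computed with log-beta functions,
#' stable for counts up to ~1e6.
#'
#' @param y successes (ALT-haplotype reads), vectorised.
#' @param n totals.
#' @param alpha,beta positive shape parameters.
#' @return vector of log-likelihood contributions.
#' @export
#' @examples
#' betabinom_loglik(3, 10, 1, 1)   # uniform compound: -log(11)
betabinom_loglik <- function(y, n, alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) stop("alpha and beta must be positive")
  if (any(y < 0) || any(y > n)) stop("y must lie in [0, n]")
  lchoose(n, y) + lbeta(y + alpha, n - y + beta) - lbeta(alpha, beta)
}

# shared optimizer bounds: concentrations above this behave binomially
.MAX_CONC <- 1e7

# beta-binomial log-likelihood parameterised by the ALT-share mean mu and a
# fixed concentration: shapes (alpha, beta) = (conc*(1-mu), conc*mu)
ll_mu_conc <- function(y, n, mu, conc) {
  sum(betabinom_loglik(n - y, n, conc * (1 - mu), conc * mu))
}

# maximise over mu at fixed concentration; mirror-canonicalised so the
# result is exactly symmetric under y <-> n - y
fit_mu_given_conc <- function(y, n, conc, tol = 1e-10) {
  mirrored <- sum(y) > sum(n - y)
  yy <- if (mirrored) n - y else y
  o <- optimize(function(m) -ll_mu_conc(yy, n, m, conc),
                interval = c(1e-4, 1 - 1e-4), tol = tol)
  mu <- if (mirrored) 1 - o$minimum else o$minimum
  list(mu = mu, loglik = -o$objective)
}

# maximise the summed beta-binomial log-likelihood; parameterised on
# log(alpha), log(beta) (H1) or log(concentration) with alpha = beta (H0)
fit_betabinom <- function(y, n, null = FALSE, tol = 1e-8) {
  nll1 <- function(par) {
    a <- min(exp(par[1]), .MAX_CONC); b <- min(exp(par[2]), .MAX_CONC)
    -sum(betabinom_loglik(y, n, a, b))
  }
  nll0 <- function(par) {
    c2 <- min(exp(par[1]), .MAX_CONC)
    -sum(betabinom_loglik(y, n, c2 / 2, c2 / 2))
  }
  # method-of-moments initialisation (deterministic, no random starts)
  ybar <- sum(y) / sum(n)
  ybar <- min(max(ybar, 1e-3), 1 - 1e-3)
  v <- var(y / pmax(n, 1))
  if (is.na(v) || v < 1e-6) v <- 1e-6  # single-donor or degenerate spread
  conc <- max(ybar * (1 - ybar) / v - 1, 2)
  conc <- min(conc, .MAX_CONC / 2)
  if (null) {
    fit <- optim(log(conc), nll0, method = "Brent",
                 lower = log(1e-4), upper = log(.MAX_CONC),
                 control = list(reltol = tol))
    a <- b <- min(exp(fit$par[1]), .MAX_CONC) / 2
  } else {
    fit <- optim(log(c(conc * ybar, conc * (1 - ybar))), nll1,
                 method = "Nelder-Mead",
                 control = list(reltol = tol, maxit = 2000))
    a <- min(exp(fit$par[1]), .MAX_CONC)
    b <- min(exp(fit$par[2]), .MAX_CONC)
  }
  list(alpha = a, beta = b, loglik = -fit$value,
       converged = fit$convergence == 0L)
}

#' Allele-specific beta-binomial imbalance test (AS-CHT)
#'
#' Models per-donor ALT-haplotype read counts `y_d` out of `n_d` as
#' beta-binomial with shape parameters `(alpha, beta)` shared across donors.
#' The alternative fits both shapes freely; the null constrains
#' `alpha = beta` (balanced alleles); the likelihood-ratio statistic is
#' referred to chi-squared with 1 degree of freedom. The imbalance metric is
#' `beta / (alpha + beta)`: with `y` oriented to the ALT-carrying haplotype,
#' values above 0.5 mean the ALT haplotype is the more accessible one.
#'
#' Tests with fewer than `min_het_donors` heterozygous donors or fewer than
#' `min_total_reads` allele-informative reads are returned untestable rather
#' than fitted.
#'
#' With `conc = NULL` the overdispersion is estimated inside the test, which
#' inflates the type-I error when only a handful of donors is available.
#' Supplying a shared concentration `conc` (estimated across all tests, as
#' [asca_map()] does) reduces the alternative to a single free mean and
#' yields a calibrated 1-df likelihood-ratio test; the reported shape
#' parameters and imbalance always come from the free two-parameter fit.
#'
#' @param rows `data.table` with columns `y` and `n` (one row per
#'   heterozygous donor) for a single (variant, peak, cell type).
#' @param min_het_donors minimum heterozygous donors.
#' @param min_total_reads minimum total allele-specific reads.
#' @param conc optional shared beta-binomial concentration (`alpha + beta`)
#'   used for the likelihood-ratio test.
#' @return object of class `ascht`: `alpha`, `beta`, `imbalance`, `lrt`,
#'   `p`, `n_het_donors`, `total_reads`, `untestable`, `converged`.
#' @export
as_cht_test <- function(rows, min_het_donors = 5L, min_total_reads = 50L,
                        conc = NULL) {
  rows <- as.data.table(rows)
  if (!nrow(rows)) stop("empty allelic count table")
  y <- rows$y; n <- rows$n
  stopifnot(all(y >= 0), all(y <= n))
  out <- list(alpha = NA_real_, beta = NA_real_, imbalance = NA_real_,
              lrt = NA_real_, p = NA_real_,
              n_het_donors = nrow(rows), total_reads = sum(n),
              untestable = FALSE, converged = NA)
  class(out) <- "ascht"
  if (nrow(rows) < min_het_donors || sum(n) < min_total_reads) {
    out$untestable <- TRUE
    return(out)
  }
  # alpha is the REF-haplotype shape and beta the ALT-haplotype shape, so the
  # reported imbalance beta/(alpha+beta) is the expected ALT-haplotype read
  # share. The free fit is run on the minority side and mirrored back, which
  # makes the result exactly symmetric under swapping y and n - y.
  if (sum(y) <= sum(n - y)) {
    f1 <- fit_betabinom(y, n, null = FALSE)
    f1[c("alpha", "beta")] <- f1[c("beta", "alpha")]
  } else {
    f1 <- fit_betabinom(n - y, n, null = FALSE)
  }
  if (is.null(conc)) {
    f0 <- fit_betabinom(n - y, n, null = TRUE)
    if (!f0$converged || !f1$converged) {
      out$converged <- FALSE
      return(out)
    }
    lrt <- max(0, 2 * (f1$loglik - f0$loglik))
  } else {
    if (!f1$converged) {
      out$converged <- FALSE
      return(out)
    }
    h1 <- fit_mu_given_conc(y, n, conc)
    lrt <- max(0, 2 * (h1$loglik - ll_mu_conc(y, n, 0.5, conc)))
  }
  out$alpha <- f1$alpha
  out$beta <- f1$beta
  out$imbalance <- f1$beta / (f1$alpha + f1$beta)
  out$lrt <- lrt
  out$p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  out$converged <- TRUE
  out
}

#' @export
print.ascht <- function(x, ...) {
  cat("Allele-specific chromatin accessibility test (beta-binomial LRT)\n")
  if (x$untestable) {
    cat(sprintf("  untestable: %d het donors, %d reads\n",
                x$n_het_donors, x$total_reads))
  } else {
    cat(sprintf("  alpha = %.3f, beta = %.3f, imbalance = %.4f\n",
                x$alpha, x$beta, x$imbalance))
    cat(sprintf("  LRT = %.3f, p = %.3g (%d donors, %d reads)\n",
                x$lrt, x$p, x$n_het_donors, x$total_reads))
  }
  invisible(x)
}

#' @export
coef.ascht <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, imbalance = object$imbalance)
}

#' Run the ASCA test over all (variant, peak, cell type) groups
#'
#' Two-pass procedure: first every group is fitted freely, giving the
#' reported shape parameters and imbalance; the per-group concentrations
#' `alpha + beta` are then pooled into a genome-wide median, and the
#' likelihood-ratio p-values are computed against that shared
#' overdispersion (see [as_cht_test()]). Sharing the dispersion across
#' tests keeps the test calibrated with as few as 5 heterozygous donors;
#' `shared_dispersion = FALSE` falls back to fully per-test estimation.
#'
#' @param counts `AllelicCountTable`-style table from
#'   [aggregate_allelic_counts()].
#' @param min_het_donors,min_total_reads thresholds passed to
#'   [as_cht_test()].
#' @param shared_dispersion estimate one concentration across all testable
#'   groups (default) instead of per test.
#' @return `data.table` with one row per (variant, peak, cell type):
#'   `alpha`, `beta`, `imbalance`, `lrt`, `p`, `n_het`, `n_reads`,
#'   `untestable` (no `q`: apply [fdr_correct()] over the combined set).
#'   The shared concentration is attached as attribute `concentration`.
#' @export
asca_map <- function(counts, min_het_donors = 5L, min_total_reads = 50L,
                     shared_dispersion = TRUE) {
  counts <- as.data.table(counts)
  if (!nrow(counts)) {
    return(data.table(variant_id = character(), peak_id = character(),
                      cell_type = character(), alpha = numeric(),
                      beta = numeric(), imbalance = numeric(),
                      lrt = numeric(), p = numeric(), n_het = integer(),
                      n_reads = integer(), untestable = logical()))
  }
  conc <- NULL
  if (shared_dispersion) {
    # pool per-group concentrations from the balanced (alpha = beta) fit:
    # with the mean pinned there is no incidental mean parameter to overfit,
    # and the median is robust to the minority of truly imbalanced groups
    # (which can only pull the estimate conservative)
    h0 <- counts[, {
      ok <- .N >= min_het_donors && sum(n) >= min_total_reads
      f <- if (ok) fit_betabinom(n - y, n, null = TRUE) else NULL
      list(conc_g = if (ok) f$alpha + f$beta else NA_real_)
    }, by = .(variant_id, peak_id, cell_type)]
    pool <- h0[is.finite(conc_g) & conc_g < .MAX_CONC / 2, conc_g]
    if (length(pool) >= 5L) conc <- median(pool)
  }
  res <- counts[, {
    fit <- as_cht_test(.SD, min_het_donors, min_total_reads, conc = conc)
    list(alpha = fit$alpha, beta = fit$beta, imbalance = fit$imbalance,
         lrt = fit$lrt, p = fit$p, n_het = fit$n_het_donors,
         n_reads = fit$total_reads, untestable = fit$untestable)
  }, by = .(variant_id, peak_id, cell_type)]
  setorder(res, peak_id, variant_id, cell_type)
  setattr(res, "concentration", conc)
  res[]
}
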