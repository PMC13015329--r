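#' Assemble the covariate matrix for cis-QTL regression
#'
#' Numeric covariates are kept as-is; categorical covariates are one-hot
#' encoded dropping the first level; genotype and phenotype principal
#' components are appended. The phenotype-PC block is capped upstream (see
#' [phenotype_pcs()]); here the assembled matrix must be full column rank
#' and leave at least 3 residual degrees of freedom.
#'
#' @param covars `data.table` with a `donor` column plus covariates (e.g.
#'   `age`, `sex`, `batch`, `modality`).
#' @param donors donor IDs defining row order.
#' @param geno_pcs optional donors x k matrix from [genotype_pcs()].
#' @param pheno_pcs optional donors x k matrix from [phenotype_pcs()].
#' @return donors x p numeric matrix (no intercept column).
#' @export
build_covariates <- function(covars, donors, geno_pcs = NULL,
                             pheno_pcs = NULL) {
  covars <- as.data.table(covars)
  stopifnot("donor" %in% names(covars))
  idx <- match(donors, covars$donor)
  if (anyNA(idx)) stop("covariate table is missing donors")
  covars <- covars[idx]
  blocks <- list()
  for (nm in setdiff(names(covars), "donor")) {
    x <- covars[[nm]]
    if (is.numeric(x)) {
      blocks[[nm]] <- matrix(x, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(x)
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, levels(f)[-1])
        blocks[[nm]] <- mm
      }
    }
  }
  add_pcs <- function(m, prefix) {
    if (is.null(m)) return(NULL)
    m <- m[donors, , drop = FALSE]
    colnames(m) <- paste0(prefix, seq_len(ncol(m)))
    m
  }
  blocks$geno_pc <- add_pcs(geno_pcs, "gPC")
  blocks$pheno_pc <- add_pcs(pheno_pcs, "phPC")
  X <- do.call(cbind, blocks[!vapply(blocks, is.null, TRUE)])
  rownames(X) <- donors
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("covariate matrix is rank deficient after encoding")
  }
  if (length(donors) <= ncol(X) + 2L) {
    stop("too few donors for the covariate matrix (need n > p + 2)")
  }
  X
}

#' Single-variant OLS slope test with covariate residualisation
#'
#' Residualises both phenotype and dosage on `[1, X]` (Frisch-Waugh), then
#' regresses the residualised phenotype on the residualised dosage. The
#' standard error uses `dof = n - rank([1, X]) - 1`, matching the joint
#' multiple regression on `[1, X, g]`; the p-value is two-sided from the t
#' distribution.
#'
#' @param y phenotype vector.
#' @param g dosage vector (0/1/2).
#' @param X covariate matrix (no intercept) or `NULL`.
#' @return list with `slope`, `se`, `t`, `p`, `dof`, and `untestable = TRUE`
#'   when the dosage is constant within the covariate space.
#' @export
ols_slope_test <- function(y, g, X = NULL) {
  n <- length(y)
  stopifnot(length(g) == n, is.null(X) || nrow(X) == n)
  Q <- qr.Q(qr(cbind(rep(1, n), X)))
  rank <- ncol(Q)
  yt <- y - Q %*% crossprod(Q, y)
  gt <- g - Q %*% crossprod(Q, g)
  gg <- sum(gt^2)
  if (gg < 1e-12) {
    return(list(slope = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                dof = n - rank - 1L, untestable = TRUE))
  }
  slope <- sum(yt * gt) / gg
  dof <- n - rank - 1L
  rss <- sum(yt^2) - slope^2 * gg
  se <- sqrt(max(rss, 0) / dof / gg)
  tstat <- slope / se
  list(slope = slope, se = se, t = tstat,
       p = 2 * pt(-abs(tstat), dof), dof = dof, untestable = FALSE)
}

# cis-window margins per feature kind: SNPs must fall inside a peak while
# indels get a 200 bp margin; genes use +/- 1 Mb from the gene body; CpG
# methylation bins use a 10 kb window.
default_window_spec <- function(kind) {
  switch(kind,
         peak = list(snp = 0L, indel = 200L),
         gene = list(snp = 1e6, indel = 1e6),
         methylation = list(snp = 1e4, indel = 1e4),
         stop(sprintf("unknown feature kind '%s'", kind)))
}

#' Nominal cis-QTL mapping
#'
#' Tests every (variant, feature) pair whose distance satisfies the
#' feature-kind-specific cis window, using [ols_slope_test()] for each pair.
#' Pairs whose dosage is constant within the covariate space are flagged
#' `untestable` and carry `NA` statistics.
#'
#' @param phenotypes a normalised `pseudobulk_matrix`.
#' @param G a filtered `phased_genotypes` object containing (at least) the
#'   phenotype donors.
#' @param X covariate matrix from [build_covariates()] (rows = phenotype
#'   donors) or `NULL`.
#' @param window_spec optional list with `snp` and `indel` margins in bp;
#'   defaults depend on the feature kind.
#' @return `data.table` with `variant_id`, `feature_id`, `cell_type`,
#'   `slope`, `se`, `t`, `p`, `untestable` (no `q` column: apply [bh_fdr()]
#'   over the full combined test set).
#' @export
map_cis_qtl <- function(phenotypes, G, X = NULL, window_spec = NULL) {
  stopifnot(inherits(phenotypes, "pseudobulk_matrix"),
            inherits(G, "phased_genotypes"))
  kind <- phenotypes$features$kind[1]
  if (is.null(kind) || is.na(kind)) stop("features must declare their kind")
  ws <- window_spec %||% default_window_spec(kind)
  donors <- phenotypes$donors
  Gd <- subset_genotypes(G, donors = donors)

  feats <- phenotypes$features
  vv <- Gd$variants[, .(variant_id, chrom, pos0, is_indel)]
  pairs <- merge(vv, feats[, .(feature_id, chrom, start, end)],
                 by = "chrom", allow.cartesian = TRUE)
  pairs[, dist := interval_distance(pos0, start, end)]
  pairs <- pairs[dist <= ifelse(is_indel, ws$indel, ws$snp)]
  if (!nrow(pairs)) {
    return(data.table(variant_id = character(), feature_id = character(),
                      cell_type = character(), slope = numeric(),
                      se = numeric(), t = numeric(), p = numeric(),
                      untestable = logical()))
  }

  n <- length(donors)
  Q <- qr.Q(qr(cbind(rep(1, n), X)))
  rank <- ncol(Q)
  dof <- n - rank - 1L
  Yt <- phenotypes$values - Q %*% crossprod(Q, phenotypes$values)
  Dt <- Gd$dosage - Q %*% crossprod(Q, Gd$dosage)

  vi <- match(pairs$variant_id, Gd$variants$variant_id)
  fi <- match(pairs$feature_id, feats$feature_id)
  gg <- colSums(Dt^2)[vi]
  yy <- colSums(Yt^2)[fi]
  gy <- colSums(Dt[, vi, drop = FALSE] * Yt[, fi, drop = FALSE])
  untestable <- gg < 1e-12
  slope <- ifelse(untestable, NA_real_, gy / gg)
  rss <- pmax(yy - slope^2 * gg, 0)
  se <- sqrt(rss / dof / gg)
  tstat <- slope / se
  res <- data.table(variant_id = pairs$variant_id,
                    feature_id = pairs$feature_id,
                    cell_type = phenotypes$cell_type,
                    slope = slope, se = se, t = tstat,
                    p = 2 * pt(-abs(tstat), dof),
                    untestable = untestable)
  setorder(res, feature_id, variant_id)
  res[]
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' Thin wrapper around `p.adjust(method = "BH")`; exposed as its own
#' operation because the correction is applied once over the full combined
#' set of tests (all cell types, all assay runs pooled), never per stratum.
#'
#' @param p vector of p-values (NAs allowed, left NA).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Apply combined-set FDR correction to QTL/ASCA tables
#'
#' Concatenates the tables, computes BH q-values over all non-missing
#' p-values jointly, and returns the tables with a `q` column added.
#'
#' @param tables list of `data.table`s each containing a `p` column.
#' @return the list with `q` columns added.
#' @export
fdr_correct <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  sizes <- vapply(tables, nrow, 0L)
  allp <- unlist(lapply(tables, function(x) x$p), use.names = FALSE)
  q <- bh_fdr(allp)
  offs <- cumsum(c(0L, sizes))
  out <- lapply(seq_along(tables), function(i) {
    x <- copy(as.data.table(tables[[i]]))
    x[, q := if (sizes[i]) ..q[(offs[i] + 1L):offs[i + 1L]] else numeric()]
    x
  })
  names(out) <- names(tables)
  if (length(out) == 1L && is.null(names(out))) out[[1]] else out
}
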