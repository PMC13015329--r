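#' @import data.table
#' @importFrom stats complete.cases cor dbinom median optim p.adjust pbinom
#'   plogis pnorm prcomp pt qlogis quantile rbeta rbinom rlnorm rnbinom rnorm
#'   rpois runif sd setNames var wilcox.test rexp lm coef
#' @importFrom utils head tail
NULL

# Internal coordinate convention: 0-based half-open [start, end) everywhere.
# VCF positions are converted to 0-based on read and back to 1-based on write.

#' Distance from a position to an interval
#'
#' Zero when the position lies inside the half-open interval, otherwise the
#' number of bases to the nearest retained base.
#' @param pos integer vector, 0-based positions
#' @param start,end interval bounds, 0-based half-open
#' @return integer vector of distances
#' @keywords internal
interval_distance <- function(pos, start, end) {
  pmax(start - pos, pos - (end - 1L), 0L)
}

# PCA scores with a deterministic sign convention: for each component the
# loading with the largest absolute value is made positive.
pca_scores <- function(mat, k) {
  if (k >= nrow(mat)) stop("k must be smaller than the number of rows")
  keep <- which(apply(mat, 2L, sd) > 0)
  if (length(keep) < 1L) stop("no variable columns for PCA")
  p <- prcomp(mat[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(k, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(mat)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

# Derive a child RNG seed from a base seed and a stream label, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + sum(utf8ToInt(stream)) * 7L) %% 214748329L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
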