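#' Filter lowly expressed genes
#'
#' A gene is kept when, in at least \code{min_samples} samples, it has
#' strictly more than \code{min_reads} raw counts AND strictly more than
#' \code{min_cpm} counts per million (CPM uses the input library sizes).
#' Both inequalities are strict, so a gene sitting exactly on a threshold is
#' excluded. The filter is idempotent: re-filtering can only raise CPM
#' (library sizes shrink), so every kept gene keeps passing.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @param min_reads,min_cpm,min_samples thresholds (defaults 6, 1, 10).
#' @return the filtered counts matrix.
#' @export
filterGenes <- function(counts, min_reads = 6, min_cpm = 1, min_samples = 10) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("all library sizes must be positive")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  keep <- rowSums(counts > min_reads & cpm > min_cpm) >= min_samples
  if (!any(keep)) warning("no genes pass the expression filter")
  counts[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' The reference sample is the one whose upper-quartile CPM is closest to the
#' mean upper-quartile. Each sample's factor is 2 to the precision-weighted
#' mean M-value against the reference after trimming 30% of M-values and 5%
#' of A-values from each tail (genes with a zero in either sample excluded);
#' factors are rescaled to geometric mean 1.
#'
#' @param counts genes x samples matrix.
#' @param lib.sizes optional per-sample library sizes (default column sums).
#' @return numeric vector of scaling factors, one per sample.
#' @export
tmmFactors <- function(counts, lib.sizes = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- lib.sizes %||% colSums(counts)
  if (any(colSums(counts) == 0)) stop("sample(s) with all-zero counts")
  f75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- if (median(f75) < 1e-20) which.max(colSums(sqrt(counts)))
         else which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(i)
    tmmPair(counts[, i], counts[, ref], lib[i], lib[ref]), numeric(1))
  f / exp(mean(log(f)))
}

## One sample's TMM factor against the reference column.
tmmPair <- function(obs, ref, nO, nR, logratioTrim = 0.3, sumTrim = 0.05) {
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratioTrim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sumTrim) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  fw <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(fw)) fw <- 0
  2^fw
}

#' voom-style log2 counts per million
#'
#' \code{log2((count + 0.5) / (libSize * factor + 1) * 1e6)}: the
#' variance-stabilized log-CPM transform. Precision weights are deliberately
#' not computed (downstream modeling uses unweighted regression).
#'
#' @param counts genes x samples matrix.
#' @param factors per-sample TMM factors (default all 1).
#' @param lib.sizes optional library sizes (default column sums).
#' @return genes x samples matrix of log2-CPM values.
#' @export
logCpm <- function(counts, factors = NULL, lib.sizes = NULL) {
  lib <- lib.sizes %||% colSums(counts)
  f <- factors %||% rep(1, ncol(counts))
  if (any(f <= 0)) stop("scaling factors must be positive")
  eff <- lib * f
  log2(sweep(counts + 0.5, 2, eff + 1, "/") * 1e6)
}

#' Remove known covariates and PCA-estimated hidden factors
#'
#' Expression is first residualized on the known covariates; the leading
#' principal components of that residual matrix estimate hidden systematic
#' variation (batch, technical factors) and are guaranteed orthogonal to the
#' covariate space by construction. The returned values are the residuals
#' after regressing each gene jointly on covariates and factors.
#'
#' @param logexpr genes x samples matrix (e.g. from \code{\link{logCpm}}).
#' @param covariates samples x covariates matrix/data.frame (may be NULL).
#' @param n_factors number of hidden factors to estimate and remove.
#' @return list with \code{values} (genes x samples residuals),
#'   \code{factors} (samples x n_factors PC scores) and
#'   \code{factors_removed}.
#' @export
removeHiddenFactors <- function(logexpr, covariates = NULL, n_factors = 5) {
  n <- ncol(logexpr)
  C <- if (is.null(covariates)) matrix(numeric(0), n, 0)
       else as.matrix(covariates)
  if (ncol(C)) {
    qrC <- qr(cbind(Intercept = 1, C))
    if (qrC$rank < ncol(C) + 1) {
      bad <- setdiff(colnames(cbind(Intercept = 1, C))[qrC$pivot[-seq_len(qrC$rank)]],
                     "Intercept")
      stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
    }
  }
  rankC <- if (ncol(C)) qr(cbind(1, C))$rank else 1L
  if (n_factors >= n - rankC - 1)
    stop("n_factors must be < n_samples - rank(covariates) - 1")
  resid1 <- residualizeRows(logexpr, C)
  factors <- NULL
  if (n_factors > 0) {
    pc <- prcomp(t(resid1), center = TRUE, scale. = FALSE)
    k <- min(n_factors, ncol(pc$x))
    factors <- pc$x[, seq_len(k), drop = FALSE]
  }
  design <- cbind(C, factors)
  values <- residualizeRows(logexpr, design)
  list(values = values, factors = factors,
       factors_removed = if (is.null(factors)) 0L else ncol(factors))
}

## Residualize each row of M (genes x samples) on [1, D] (samples x p).
residualizeRows <- function(M, D) {
  X <- cbind(1, D)
  Q <- qr.Q(qr(X))
  t(t(M) - Q %*% crossprod(Q, t(M)))
}
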