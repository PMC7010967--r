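#' Condition GWAS summary statistics on a set of SNPs
#'
#' Approximate joint/conditional estimation from summary statistics with
#' reference LD: for each remaining SNP j, the conditional effect is the
#' coefficient of j in the implied joint regression on \{j\} plus the
#' conditioning set S, reconstructed from marginal betas and the reference
#' dosage covariance. The phenotypic variance is inferred from
#' \code{median(se^2 * n * 2 * maf * (1 - maf))} across SNPs, and the
#' conditional standard error uses the joint-model residual variance, so
#' that with reference = GWAS cohort the conditional z reproduces the
#' joint individual-level OLS t-statistic.
#'
#' Conditioning SNPs are excluded from the output. A SNP with r2 > 0.99
#' against the conditioning set is reported with z = 0 and flagged
#' (collinearity guard); a singular conditioning covariance is
#' ridge-regularized with 1e-6 I (warning).
#'
#' @param gwas a harmonized \linkS4class{GwasSummary}.
#' @param ref an \code{LdReference} covering all involved SNPs (conditioning
#'   set and targets).
#' @param snps character: SNP ids to condition on (empty set = identity).
#' @param maf named minor allele frequencies (for the phenotypic-variance
#'   bookkeeping); defaults to implying variance from the reference.
#' @return data.frame with snp_id, beta_c, se_c, z_c, collinear flag, and a
#'   \code{conditioned_on} attribute.
#' @export
conditionSummary <- function(gwas, ref, snps, maf = NULL) {
  tb <- gwasTable(gwas)
  n <- gwas@nGwas
  snps <- intersect(snps, tb$snp_id)
  keepIds <- setdiff(intersect(tb$snp_id, names(ref$sd)), snps)
  v <- ref$sd[tb$snp_id]^2
  names(v) <- tb$snp_id
  vBook <- if (is.null(maf)) v else 2 * maf[tb$snp_id] * (1 - maf[tb$snp_id])
  sigma2y <- median(tb$se^2 * n * vBook, na.rm = TRUE)
  beta <- setNames(tb$beta, tb$snp_id)
  if (!length(snps)) {
    out <- data.frame(snp_id = keepIds, beta_c = beta[keepIds],
                      se_c = tb$se[match(keepIds, tb$snp_id)],
                      z_c = beta[keepIds] / tb$se[match(keepIds, tb$snp_id)],
                      collinear = FALSE, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "conditioned_on") <- character()
    return(out)
  }
  G_SS <- ref$cov[snps, snps, drop = FALSE]
  inv <- tryCatch(solve(G_SS), error = function(e) {
    warning("singular conditioning covariance; ridge-regularized with 1e-6 I")
    solve(G_SS + diag(1e-6, length(snps)))
  })
  vS <- v[snps]
  bS <- beta[snps]
  out <- lapply(keepIds, function(j) {
    gjS <- ref$cov[j, snps, drop = FALSE]
    r2 <- as.vector(gjS %*% inv %*% t(gjS)) / v[j]
    if (r2 > 0.99)
      return(data.frame(snp_id = j, beta_c = 0, se_c = NA_real_, z_c = 0,
                        collinear = TRUE, stringsAsFactors = FALSE))
    denom <- v[j] - as.vector(gjS %*% inv %*% t(gjS))
    num <- v[j] * beta[j] - as.vector(gjS %*% inv %*% (vS * bS))
    bc <- num / denom
    ## joint coefficients on A = S + j, for the residual-variance bookkeeping
    A <- c(snps, j)
    G_AA <- ref$cov[A, A, drop = FALSE]
    bJoint <- tryCatch(solve(G_AA, v[A] * beta[A]),
                       error = function(e) solve(G_AA + diag(1e-6, length(A)),
                                                 v[A] * beta[A]))
    explained <- sum(bJoint * v[A] * beta[A])
    s2r <- max(sigma2y - explained, 1e-12) * n / (n - length(A) - 1)
    sec <- sqrt(s2r / (n * denom))
    data.frame(snp_id = j, beta_c = bc, se_c = sec, z_c = bc / sec,
               collinear = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "conditioned_on") <- snps
  res
}

#' Re-run the TWAS after conditioning on each association's top SNP
#'
#' For every significant association, the GWAS is conditioned on the
#' association's top contributing SNP, the conditioned SNP is removed from
#' the gene's model, sigma_g is recomputed on the reduced SNP set, and the
#' association Z is recomputed from the conditioned per-SNP z-scores.
#' Models reduced to zero SNPs are reported as fully explained by the
#' conditioned SNP.
#'
#' @param mset an \linkS4class{ExpressionModelSet}.
#' @param scan data.frame from \code{\link{associationScan}} (rows to
#'   condition; typically the significant ones).
#' @param gwasList named list of harmonized \linkS4class{GwasSummary}.
#' @param ref an \code{LdReference} covering all model SNPs.
#' @param alpha caller-supplied significance threshold on the conditional
#'   p-value (e.g. a Bonferroni level over genes x tissues x phenotypes).
#' @param maf optional named MAFs passed to \code{\link{conditionSummary}}.
#' @param stepwise condition iteratively: while the association stays
#'   significant and model SNPs remain, add the conditioned result's new top
#'   contributing SNP to the conditioning set and re-condition. The default
#'   single round conditions on the lead SNP once.
#' @return data.frame with gene_id, phenotype_id, conditioned_snp
#'   (comma-separated set in stepwise mode), z_cond, p_cond,
#'   still_significant, fully_explained.
#' @export
conditionalTwas <- function(mset, scan, gwasList, ref, alpha, maf = NULL,
                            stepwise = FALSE) {
  stopifnot(length(models(mset)) >= 1)
  ms <- models(mset)
  rows <- list()
  for (i in seq_len(nrow(scan))) {
    g <- scan$gene_id[i]; ph <- scan$phenotype_id[i]
    top <- scan$top_snp[i]
    m <- ms[[g]]
    if (is.null(m) || is.na(top)) next
    S <- top
    repeat {
      res <- conditionOnce(m, gwasList[[ph]], ref, S, maf)
      if (!stepwise || res$fully_explained || res$p > alpha) break
      nxt <- tryCatch(
        topContributingSnp(res$contributions, res$z),
        error = function(e) NA_character_)
      if (is.na(nxt)) break
      S <- c(S, nxt)
    }
    rows[[i]] <- data.frame(gene_id = g, phenotype_id = ph,
                            dataset_id = scan$dataset_id[i],
                            conditioned_snp = paste(S, collapse = ","),
                            z_cond = res$z, p_cond = res$p,
                            still_significant = !res$fully_explained &&
                              res$p <= alpha,
                            fully_explained = res$fully_explained,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), phenotype_id = character(),
                      conditioned_snp = character(), z_cond = numeric(),
                      p_cond = numeric(), still_significant = logical(),
                      fully_explained = logical())
  rownames(out) <- NULL
  out
}

## One conditioning round for a single model: condition the GWAS on S,
## drop S (and collinear leftovers) from the model, recompute the
## association z on the reduced SNP set.
conditionOnce <- function(m, gwas, ref, S, maf) {
  cond <- conditionSummary(gwas, ref, S, maf = maf)
  w <- modelWeights(m)
  w <- w[setdiff(names(w), S)]
  if (length(w)) {
    have <- names(w) %in% cond$snp_id &
      !cond$collinear[match(names(w), cond$snp_id)]
    w <- w[have]
  }
  if (!length(w))
    return(list(z = 0, p = 1, fully_explained = TRUE,
                contributions = numeric()))
  sg <- sigmaG(w, ref)
  zc <- cond$z_c[match(names(w), cond$snp_id)]
  contrib <- w * ref$sd[names(w)] / sg * zc
  z <- sum(contrib)
  list(z = z, p = 2 * pnorm(-abs(z)), fully_explained = FALSE,
       contributions = contrib)
}
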