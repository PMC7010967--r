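#' Colocalization eligibility of a gene-phenotype association
#'
#' An association is amenable to colocalization testing when at least one
#' SNP in the gene's model is both a significant cis-eQTL (q below
#' \code{eqtl_fdr}) and a significant QTL for the phenotype (GWAS p at or
#' below \code{gwas_p}).
#'
#' @param model an \linkS4class{ExpressionModel}.
#' @param eqtlRecords cis-scan records for the model's gene (needs snp_id, q).
#' @param gwas a harmonized \linkS4class{GwasSummary}.
#' @param eqtl_fdr,gwas_p the two significance gates (defaults 0.01, 5e-8).
#' @return list with \code{eligible} (logical) and \code{snps} (the
#'   qualifying SNP ids).
#' @export
colocEligibility <- function(model, eqtlRecords, gwas, eqtl_fdr = 0.01,
                             gwas_p = 5e-8) {
  snps <- modelSnps(model)
  if (!length(snps)) return(list(eligible = FALSE, snps = character()))
  tb <- gwasTable(gwas)
  gp <- 2 * pnorm(-abs(tb$z[match(snps, tb$snp_id)]))
  eq <- eqtlRecords$q[match(snps, eqtlRecords$snp_id)]
  ok <- !is.na(gp) & !is.na(eq) & eq < eqtl_fdr & gp <= gwas_p
  list(eligible = any(ok), snps = snps[ok])
}

## Enumerate causal configurations of size <= max_causal as index lists.
causalConfigurations <- function(m, max_causal) {
  configs <- list(integer(0))
  for (k in seq_len(min(max_causal, m))) {
    configs <- c(configs,
                 if (k == 1) as.list(seq_len(m))
                 else apply(combn(m, k), 2, identity, simplify = FALSE))
  }
  configs
}

## Per-SNP causal posterior for one trait by configuration enumeration.
## The covariance is fixed across configurations, so its Cholesky factor is
## computed once and only the mean shifts per configuration.
causalPosterior <- function(z, ld, max_causal, prior, ncp) {
  m <- length(z)
  configs <- causalConfigurations(m, max_causal)
  ch <- tryCatch(chol(ld), error = function(e) chol(nearestPsd(ld)))
  logdet <- sum(log(diag(ch)))
  logpost <- vapply(configs, function(cf) {
    lam <- numeric(m)
    lam[cf] <- ncp * sign(z[cf])
    mu <- as.vector(ld %*% lam)
    u <- backsolve(ch, z - mu, transpose = TRUE)
    k <- length(cf)
    k * log(prior) + (m - k) * log(1 - prior) -
      0.5 * m * log(2 * pi) - logdet - 0.5 * sum(u^2)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  post <- numeric(m)
  for (i in seq_along(configs)) post[configs[[i]]] <- post[configs[[i]]] + w[i]
  post
}

#' Per-SNP colocalization posterior probabilities (CLPP)
#'
#' For each trait, causal configurations of size at most \code{max_causal}
#' are enumerated; a configuration's likelihood is the multivariate normal
#' density of the observed Z-vector with mean \code{ld \%*\% lambda}
#' (lambda = \code{ncp}, signed by the observed Z, at causal SNPs; 0
#' elsewhere) and covariance \code{ld}, under an independent Bernoulli
#' \code{prior} per SNP. The per-SNP causal posterior sums the posteriors of
#' configurations containing that SNP, and CLPP is the product of the two
#' traits' per-SNP posteriors.
#'
#' @param z_eqtl,z_gwas per-SNP Z-scores over the locus (same SNP order).
#' @param ld SNP correlation matrix (repaired to the nearest PSD matrix with
#'   a warning if needed).
#' @param max_causal maximum causal SNPs per trait (default 2).
#' @param prior per-SNP causal prior (default 0.01).
#' @param ncp assumed noncentrality of a causal SNP (default 5.2).
#' @return named list: \code{clpp} per SNP, \code{post_eqtl},
#'   \code{post_gwas}, \code{max_clpp}.
#' @export
clpp <- function(z_eqtl, z_gwas, ld, max_causal = 2, prior = 0.01,
                 ncp = 5.2) {
  stopifnot(length(z_eqtl) == length(z_gwas), nrow(ld) == length(z_eqtl))
  ev <- eigen((ld + t(ld)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    warning("LD matrix not positive definite; repaired to nearest PSD")
    ld <- nearestPsd(ld)
  }
  p1 <- causalPosterior(z_eqtl, ld, max_causal, prior, ncp)
  p2 <- causalPosterior(z_gwas, ld, max_causal, prior, ncp)
  cl <- p1 * p2
  names(cl) <- rownames(ld)
  list(clpp = cl, post_eqtl = p1, post_gwas = p2, max_clpp = max(cl))
}

#' Colocalization analysis of one gene-phenotype association
#'
#' Applies the eligibility gates, then computes CLPP over the locus SNPs
#' (capped at the \code{max_locus} largest |GWAS z|, keeping all model SNPs)
#' and extracts the per-model-SNP values.
#'
#' @param model an \linkS4class{ExpressionModel}.
#' @param eqtlRecords cis-scan records for this gene (snp_id, beta, se, q).
#' @param gwas a harmonized \linkS4class{GwasSummary}.
#' @param panel a \linkS4class{GenotypePanel} for the LD matrix.
#' @param eqtl_fdr,gwas_p eligibility gates.
#' @param threshold CLPP call threshold (strict >; default 0.01).
#' @param max_causal,prior,ncp passed to \code{\link{clpp}}.
#' @param max_locus locus size cap for enumeration (default 50).
#' @return data.frame with one row per model SNP: gene_id, snp_id, clpp,
#'   eligible, colocalized (logical; NA when ineligible), max_clpp.
#' @export
colocAnalysis <- function(model, eqtlRecords, gwas, panel, eqtl_fdr = 0.01,
                          gwas_p = 5e-8, threshold = 0.01, max_causal = 2,
                          prior = 0.01, ncp = 5.2, max_locus = 50) {
  elig <- colocEligibility(model, eqtlRecords, gwas, eqtl_fdr, gwas_p)
  snps <- modelSnps(model)
  base <- data.frame(gene_id = geneId(model), snp_id = snps,
                     clpp = NA_real_, eligible = elig$eligible,
                     colocalized = NA, max_clpp = NA_real_,
                     stringsAsFactors = FALSE)
  if (!elig$eligible || !length(snps)) return(base)
  tb <- gwasTable(gwas)
  rec <- eqtlRecords[!is.na(eqtlRecords$q), , drop = FALSE]
  locus <- intersect(rec$snp_id, tb$snp_id)
  if (!length(locus)) return(base)
  zg <- tb$z[match(locus, tb$snp_id)]
  if (length(locus) > max_locus) {
    ord <- order(-abs(zg))
    keep <- union(locus[ord][seq_len(max_locus)], intersect(snps, locus))
    zg <- zg[match(keep, locus)]
    locus <- keep
  }
  ze <- with(rec, (beta / se)[match(locus, snp_id)])
  ld <- ldMatrix(panel, locus)
  res <- clpp(ze, zg, ld, max_causal = max_causal, prior = prior, ncp = ncp)
  idx <- match(snps, locus)
  base$clpp <- res$clpp[idx]
  mx <- suppressWarnings(max(base$clpp, na.rm = TRUE))
  if (!is.finite(mx)) mx <- NA_real_
  base$max_clpp <- mx
  base$colocalized <- !is.na(mx) && mx > threshold
  base
}

#' Call colocalization across datasets
#'
#' A gene-phenotype pair is called colocalized when any model SNP in any
#' dataset has CLPP strictly above the threshold; pairs that were nowhere
#' eligible get NA (no call), distinct from an ineligible "not colocalized".
#'
#' @param results data.frame rbind of \code{\link{colocAnalysis}} outputs
#'   with added phenotype_id (and optionally dataset_id) columns.
#' @param threshold CLPP call threshold (strict >; default 0.01).
#' @return data.frame gene_id, phenotype_id, eligible, colocalized.
#' @export
callColocalization <- function(results, threshold = 0.01) {
  key <- paste(results$gene_id, results$phenotype_id, sep = "|")
  out <- lapply(split(results, key), function(d) {
    elig <- any(d$eligible)
    data.frame(gene_id = d$gene_id[1], phenotype_id = d$phenotype_id[1],
               eligible = elig,
               colocalized = if (!elig) NA
                             else any(!is.na(d$clpp) & d$clpp > threshold),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
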