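#' Harmonize GWAS summary statistics to panel allele coding
#'
#' SNPs whose effect allele equals the panel's counted allele pass through;
#' swapped coding flips the sign of beta (and z); strand-ambiguous SNPs
#' (A/T, C/G) and allele pairs that match neither orientation are dropped.
#' Drop counts are attached as the \code{"log"} attribute.
#'
#' @param gwas a \linkS4class{GwasSummary}.
#' @param panel a \linkS4class{GenotypePanel} supplying the allele coding.
#' @return a harmonized \linkS4class{GwasSummary} restricted to panel SNPs.
#' @export
harmonizeGwas <- function(gwas, panel) {
  tb <- gwasTable(gwas)
  info <- snpInfo(panel)
  idx <- match(tb$snp_id, info$snp_id)
  inPanel <- !is.na(idx)
  tb <- tb[inPanel, , drop = FALSE]
  idx <- idx[inPanel]
  ambig <- (tb$a1 == "A" & tb$a2 == "T") | (tb$a1 == "T" & tb$a2 == "A") |
           (tb$a1 == "C" & tb$a2 == "G") | (tb$a1 == "G" & tb$a2 == "C")
  same <- tb$a1 == info$eff[idx] & tb$a2 == info$ref[idx]
  swap <- tb$a1 == info$ref[idx] & tb$a2 == info$eff[idx]
  keep <- !ambig & (same | swap)
  nAmbig <- sum(ambig)
  nMismatch <- sum(!ambig & !same & !swap)
  if (nAmbig) message("dropped ", nAmbig, " strand-ambiguous SNP(s)")
  if (nMismatch) message("dropped ", nMismatch, " SNP(s) with unmatched alleles")
  tb2 <- tb[keep, , drop = FALSE]
  flip <- swap[keep]
  tb2$beta[flip] <- -tb2$beta[flip]
  a1 <- tb2$a1; a2 <- tb2$a2
  tb2$a1[flip] <- a2[flip]; tb2$a2[flip] <- a1[flip]
  out <- GwasSummary(tb2, gwas@nGwas)
  out@harmonized <- TRUE
  attr(out@table, "log") <- c(ambiguous = nAmbig, unmatched = nMismatch,
                              absent = sum(!inPanel))
  out
}

#' LD reference for a set of model SNPs
#'
#' Per-SNP dosage standard deviations and the pairwise dosage covariance,
#' computed from a reference panel (typically the expression-training panel,
#' which doubles as the LD reference; any cohort's dosage matrix works).
#'
#' @param x a \linkS4class{GenotypePanel} or a samples x SNPs dosage matrix
#'   with column names.
#' @param snps optional SNP ids to restrict to.
#' @return an object of class \code{LdReference}: list with \code{sd}
#'   (named) and \code{cov} (matrix).
#' @export
ldReference <- function(x, snps = NULL) {
  X <- if (is(x, "GenotypePanel")) dosageMatrix(x, snps)
       else if (is.null(snps)) as.matrix(x)
       else as.matrix(x)[, snps, drop = FALSE]
  V <- cov(X)
  structure(list(sd = setNames(sqrt(diag(V)), colnames(X)), cov = V),
            class = "LdReference")
}

#' Standard deviation of a gene's predicted expression
#'
#' \code{sigma_g = sqrt(w' Gamma w)} with Gamma the reference dosage
#' covariance of the model SNPs. (The normalizer in the association formula
#' is a standard deviation, dimensionally consistent with per-SNP sd terms.)
#'
#' @param model an \linkS4class{ExpressionModel} or a named weight vector.
#' @param ref an \code{LdReference} covering the model SNPs.
#' @return numeric sigma_g (0 is the caller's signal to skip the gene).
#' @export
sigmaG <- function(model, ref) {
  w <- if (is(model, "ExpressionModel")) modelWeights(model) else model
  snps <- names(w)
  miss <- setdiff(snps, names(ref$sd))
  if (length(miss))
    stop("model SNP(s) absent from LD reference: ", paste(miss, collapse = ", "))
  G <- ref$cov[snps, snps, drop = FALSE]
  sqrt(max(as.vector(t(w) %*% G %*% w), 0))
}

#' Summary-statistic TWAS association for one gene
#'
#' The gene-level Z is the weighted sum of per-SNP GWAS Z scores,
#' \code{z_g = sum_l w_lg (sigma_l / sigma_g) z_l}; each term is stored as
#' that SNP's contribution, so contributions add up to z_g exactly. Model
#' SNPs missing from the (harmonized) GWAS are dropped from the sum;
#' \code{coverage} records the fraction retained and \code{sigma_g} is
#' recomputed on the retained set.
#'
#' @param model an \linkS4class{ExpressionModel}.
#' @param gwas a harmonized \linkS4class{GwasSummary}.
#' @param ref an \code{LdReference} covering the model SNPs.
#' @return list with \code{gene_id}, \code{z}, \code{p}, \code{sigma_g},
#'   \code{coverage}, \code{n_model_snps}, \code{contributions} (named
#'   numeric), or NULL when coverage is zero or sigma_g degenerates.
#' @export
spredixcanZ <- function(model, gwas, ref) {
  if (!gwas@harmonized)
    warning("GWAS summary not harmonized; allele coding is trusted as-is")
  w <- modelWeights(model)
  tb <- gwasTable(gwas)
  have <- names(w) %in% tb$snp_id
  coverage <- mean(have)
  if (!any(have)) return(NULL)
  w <- w[have]
  sg <- sigmaG(w, ref)
  if (sg == 0) {
    message("sigma_g = 0 for ", geneId(model), "; gene skipped")
    return(NULL)
  }
  zl <- tb$z[match(names(w), tb$snp_id)]
  contrib <- w * ref$sd[names(w)] / sg * zl
  z <- sum(contrib)
  list(gene_id = geneId(model), z = z, p = 2 * pnorm(-abs(z)), sigma_g = sg,
       coverage = coverage, n_model_snps = length(modelWeights(model)),
       contributions = contrib)
}

#' Top contributing SNP of a TWAS association
#'
#' Among SNPs whose individual contribution shares the sign of the overall
#' Z, the one with the largest absolute contribution; exact ties go to the
#' smaller genomic position (then lexicographic id).
#'
#' @param contributions named numeric per-SNP contributions.
#' @param z the gene-level Z (sum of contributions).
#' @param positions optional named positions for tie-breaking.
#' @return SNP id (character).
#' @export
topContributingSnp <- function(contributions, z, positions = NULL) {
  same <- sign(contributions) == sign(z) & contributions != 0
  if (!any(same))
    stop("no contribution shares the sign of the overall Z; flagged for review")
  cand <- contributions[same]
  best <- abs(cand) == max(abs(cand))
  ids <- names(cand)[best]
  if (length(ids) > 1) {
    if (!is.null(positions)) ids <- ids[order(positions[ids], ids)]
    else ids <- sort(ids)
  }
  ids[1]
}

#' Transcriptome-wide association scan
#'
#' Runs \code{\link{spredixcanZ}} for every model x phenotype combination,
#' BH-adjusts p-values across the whole scan, and flags significance at the
#' requested FDR.
#'
#' @param mset an \linkS4class{ExpressionModelSet}.
#' @param gwasList named list of harmonized \linkS4class{GwasSummary}
#'   (names are phenotype ids).
#' @param ref an \code{LdReference} covering all model SNPs.
#' @param fdr significance threshold on BH q-values (default 0.01).
#' @param dataset dataset/tissue label recorded in the output.
#' @param positions optional named SNP positions for top-SNP tie-breaking.
#' @return data.frame with one row per gene-phenotype test: gene_id,
#'   phenotype_id, dataset_id, z, p, q, significant, sigma_g, coverage,
#'   n_model_snps, top_snp, plus a \code{contributions} list-column.
#' @export
associationScan <- function(mset, gwasList, ref, fdr = 0.01,
                            dataset = "ds1", positions = NULL) {
  stopifnot(length(gwasList) >= 1, length(models(mset)) >= 1)
  rows <- list()
  contribs <- list()
  for (ph in names(gwasList)) {
    for (m in models(mset)) {
      if (!length(m@weights)) next
      res <- spredixcanZ(m, gwasList[[ph]], ref)
      if (is.null(res)) next
      top <- tryCatch(
        topContributingSnp(res$contributions, res$z, positions),
        error = function(e) NA_character_)
      key <- paste(res$gene_id, ph, dataset, sep = "|")
      rows[[key]] <- data.frame(
        gene_id = res$gene_id, phenotype_id = ph, dataset_id = dataset,
        z = res$z, p = res$p, sigma_g = res$sigma_g,
        coverage = res$coverage, n_model_snps = res$n_model_snps,
        top_snp = top, stringsAsFactors = FALSE)
      contribs[[key]] <- res$contributions
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(), phenotype_id = character(),
                      dataset_id = character(), z = numeric(), p = numeric(),
                      q = numeric(), significant = logical()))
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out$contributions <- I(contribs[rownames(out)])
  rownames(out) <- NULL
  out
}
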