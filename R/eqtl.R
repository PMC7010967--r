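#' Cis windows around genes
#'
#' The cis window is the closed interval [TSS - cisDistance, TES +
#' cisDistance], clamped at position 1.
#'
#' @param genes gene annotation: list of \code{\link{geneArchitecture}} or a
#'   data.frame with gene_id, chrom, tss, tes.
#' @param cisDistance window half-width in bp (default 1 Mb).
#' @return data.frame gene_id, chrom, start, end.
#' @export
cisWindows <- function(genes, cisDistance = 1e6) {
  tb <- geneAnnotationTable(genes)
  data.frame(gene_id = tb$gene_id, chrom = tb$chrom,
             start = pmax(1, tb$tss - cisDistance),
             end = tb$tes + cisDistance, stringsAsFactors = FALSE)
}

#' Single-variant cis-eQTL scan
#'
#' Every SNP inside a gene's cis window is tested by simple linear regression
#' of residual expression on dosage (two-sided t-test); BH q-values are
#' computed across all gene-SNP tests in the dataset. Zero-variance dosages
#' are skipped with a message.
#'
#' @param residExpr genes x samples matrix of residual expression; rownames
#'   are gene ids, columns aligned with the panel's samples.
#' @param panel a \linkS4class{GenotypePanel}.
#' @param windows data.frame from \code{\link{cisWindows}}.
#' @return data.frame gene_id, snp_id, chrom, bp, beta, se, p, q.
#' @export
cisScan <- function(residExpr, panel, windows) {
  info <- snpInfo(panel)
  X <- dosageMatrix(panel)
  if (ncol(residExpr) != nrow(X))
    stop("expression samples and panel samples are not aligned")
  n <- nrow(X)
  sx <- apply(X, 2, sd)
  if (any(sx == 0))
    message("skipping ", sum(sx == 0), " zero-variance SNP(s)")
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    if (!w$gene_id %in% rownames(residExpr)) next
    sel <- which(info$chrom == w$chrom & info$bp >= w$start &
                   info$bp <= w$end & sx > 0)
    if (!length(sel)) next
    y <- residExpr[w$gene_id, ]
    ss <- marginalGwas(X[, sel, drop = FALSE], y)
    tstat <- ss$beta / ss$se
    out[[i]] <- data.frame(
      gene_id = w$gene_id, snp_id = info$snp_id[sel], chrom = info$chrom[sel],
      bp = info$bp[sel], beta = ss$beta, se = ss$se,
      p = 2 * pt(-abs(tstat), df = n - 2), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(gene_id = character(), snp_id = character(),
                      chrom = character(), bp = integer(), beta = numeric(),
                      se = numeric(), p = numeric(), q = numeric()))
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Top eQTL per gene
#'
#' The SNP with the lowest p-value for each gene; exact ties are broken by
#' smaller genomic position, then lexicographic SNP id, so the winner is
#' deterministic.
#'
#' @param records data.frame from \code{\link{cisScan}}.
#' @return one row per gene.
#' @export
topEqtl <- function(records) {
  if (!nrow(records)) return(records)
  ord <- order(records$gene_id, records$p, records$bp, records$snp_id)
  rec <- records[ord, , drop = FALSE]
  out <- rec[!duplicated(rec$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
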