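#' @rdname GenotypePanel-class
#' @param object,panel a \linkS4class{GenotypePanel}
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))
#' @rdname GenotypePanel-class
#' @export
setMethod("dosages", "GenotypePanel", function(object) object@dosages)

#' @rdname GenotypePanel-class
#' @export
setGeneric("snpInfo", function(object) standardGeneric("snpInfo"))
#' @rdname GenotypePanel-class
#' @export
setMethod("snpInfo", "GenotypePanel", function(object) object@snpInfo)

#' @rdname GenotypePanel-class
#' @export
nSamples <- function(panel) nrow(panel@dosages)

#' @rdname GenotypePanel-class
#' @export
nSnps <- function(panel) ncol(panel@dosages)

#' Pairwise dosage covariance / correlation for a SNP subset
#'
#' @param panel a \linkS4class{GenotypePanel}
#' @param snps character vector of SNP ids (default: all)
#' @return covariance (\code{ldCovariance}) or correlation (\code{ldMatrix})
#'   matrix of dosages, SNP ids on dimnames.
#' @export
ldCovariance <- function(panel, snps = NULL) {
  X <- dosageMatrix(panel, snps)
  cov(X)
}

#' @rdname ldCovariance
#' @export
ldMatrix <- function(panel, snps = NULL) {
  X <- dosageMatrix(panel, snps)
  s <- apply(X, 2, sd)
  if (any(s == 0))
    warning("zero-variance SNPs in LD computation: ",
            paste(colnames(X)[s == 0], collapse = ", "))
  suppressWarnings(cor(X))
}

#' Dosage submatrix by SNP id
#'
#' @param panel a \linkS4class{GenotypePanel}
#' @param snps SNP ids to extract (default all); unknown ids are an error.
#' @return samples x SNPs numeric matrix with SNP ids as column names.
#' @export
dosageMatrix <- function(panel, snps = NULL) {
  X <- panel@dosages
  colnames(X) <- panel@snpInfo$snp_id
  if (is.null(snps)) return(X)
  miss <- setdiff(snps, colnames(X))
  if (length(miss))
    stop("SNPs absent from panel: ", paste(miss, collapse = ", "))
  X[, snps, drop = FALSE]
}

#' @rdname GwasSummary-class
#' @param object a \linkS4class{GwasSummary}
#' @export
setGeneric("gwasTable", function(object) standardGeneric("gwasTable"))
#' @rdname GwasSummary-class
#' @export
setMethod("gwasTable", "GwasSummary", function(object) object@table)

#' Construct a GwasSummary from a summary-statistic table
#'
#' @param table data.frame with columns snp_id, a1 (effect allele), a2,
#'   beta, se and optionally chrom, bp.
#' @param nGwas GWAS sample size.
#' @return a \linkS4class{GwasSummary}; z is recomputed as beta/se.
#' @export
GwasSummary <- function(table, nGwas) {
  table$z <- table$beta / table$se
  if (is.null(table$chrom)) table$chrom <- NA_character_
  if (is.null(table$bp)) table$bp <- NA_integer_
  new("GwasSummary", table = as.data.frame(table), nGwas = as.numeric(nGwas))
}

#' @rdname ExpressionModel-class
#' @param object an \linkS4class{ExpressionModel} or
#'   \linkS4class{ExpressionModelSet}
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))
#' @rdname ExpressionModel-class
#' @export
setMethod("modelWeights", "ExpressionModel", function(object) object@weights)

#' @rdname ExpressionModel-class
#' @export
setGeneric("modelSnps", function(object) standardGeneric("modelSnps"))
#' @rdname ExpressionModel-class
#' @export
setMethod("modelSnps", "ExpressionModel", function(object) names(object@weights))

#' @rdname ExpressionModel-class
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))
#' @rdname ExpressionModel-class
#' @export
setMethod("geneId", "ExpressionModel", function(object) object@geneId)

#' @rdname ExpressionModelSet-class
#' @param object an \linkS4class{ExpressionModelSet}
#' @export
setGeneric("models", function(object) standardGeneric("models"))
#' @rdname ExpressionModelSet-class
#' @export
setMethod("models", "ExpressionModelSet", function(object) object@models)

#' Flatten an ExpressionModelSet to a one-row-per-gene-SNP table
#'
#' @param mset an \linkS4class{ExpressionModelSet}
#' @param panel optional \linkS4class{GenotypePanel} supplying allele columns.
#' @return data.frame with gene_id, snp_id, weight, lambda, alpha_ridge,
#'   r2_full, r2_filtered, fit_p, fit_q (+ ref/eff alleles when panel given).
#' @export
modelTable <- function(mset, panel = NULL) {
  rows <- lapply(models(mset), function(m) {
    if (!length(m@weights)) return(NULL)
    data.frame(
      gene_id = m@geneId, snp_id = names(m@weights), weight = unname(m@weights),
      lambda = m@lambdaLasso, alpha_ridge = m@alphaRidge,
      r2_full = m@r2Full, r2_filtered = m@r2Filtered,
      fit_p = m@fitP, fit_q = m@fitQ, stringsAsFactors = FALSE
    )
  })
  tb <- do.call(rbind, rows)
  if (is.null(tb))
    tb <- data.frame(gene_id = character(), snp_id = character(),
                     weight = numeric())
  if (!is.null(panel) && nrow(tb)) {
    si <- snpInfo(panel)
    idx <- match(tb$snp_id, si$snp_id)
    tb$ref_allele <- si$ref[idx]
    tb$eff_allele <- si$eff[idx]
  }
  rownames(tb) <- NULL
  tb
}
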