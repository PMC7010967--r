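#' GenotypePanel: a samples-by-SNPs dosage matrix with variant metadata
#'
#' Holds diploid dosages in \{0, 1, 2\} together with per-SNP metadata
#' (position, alleles, minor allele frequency, LD-block membership) and the
#' generative LD parameters needed to draw an independent cohort from the
#' same model (used when simulating an external GWAS).
#'
#' @slot dosages numeric matrix, samples x SNPs, entries in \{0, 1, 2\}.
#' @slot snpInfo data.frame with one row per SNP: \code{snp_id}, \code{chrom},
#'   \code{bp}, \code{ref} (other allele), \code{eff} (counted allele),
#'   \code{maf} (realized), \code{target_maf}, \code{block}, \code{rho}.
#' @slot sampleIds character vector of sample identifiers.
#'
#' @export
setClass("GenotypePanel",
  representation(
    dosages = "matrix",
    snpInfo = "data.frame",
    sampleIds = "character"
  )
)

setValidity("GenotypePanel", function(object) {
  msgs <- character()
  d <- object@dosages
  if (ncol(d) != nrow(object@snpInfo))
    msgs <- c(msgs, "ncol(dosages) must equal nrow(snpInfo)")
  if (nrow(d) != length(object@sampleIds))
    msgs <- c(msgs, "nrow(dosages) must equal length(sampleIds)")
  if (length(d) && !all(d %in% c(0, 1, 2)))
    msgs <- c(msgs, "dosages must be 0, 1 or 2")
  need <- c("snp_id", "chrom", "bp", "ref", "eff", "maf")
  miss <- setdiff(need, names(object@snpInfo))
  if (length(miss))
    msgs <- c(msgs, paste("snpInfo lacks columns:", paste(miss, collapse = ", ")))
  if (!length(miss) && anyDuplicated(object@snpInfo$snp_id))
    msgs <- c(msgs, "snp_id values must be unique")
  if (length(msgs)) msgs else TRUE
})

#' GwasSummary: per-SNP GWAS summary statistics
#'
#' A thin S4 wrapper around a summary-statistic table with columns
#' \code{snp_id}, \code{chrom}, \code{bp}, \code{a1} (effect allele),
#' \code{a2} (other allele), \code{beta}, \code{se}, \code{z}, plus the GWAS
#' sample size. \code{z} is always recomputed as \code{beta/se} on
#' construction (published p-values can round to zero; the ratio cannot).
#'
#' @slot table data.frame of summary statistics.
#' @slot nGwas integer GWAS sample size.
#' @slot harmonized logical; TRUE once alleles are aligned to a panel.
#'
#' @export
setClass("GwasSummary",
  representation(table = "data.frame", nGwas = "numeric", harmonized = "logical"),
  prototype(harmonized = FALSE)
)

setValidity("GwasSummary", function(object) {
  tb <- object@table
  need <- c("snp_id", "a1", "a2", "beta", "se")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    return(paste("table lacks columns:", paste(miss, collapse = ", ")))
  if (nrow(tb) && any(tb$se <= 0))
    return("all standard errors must be positive")
  TRUE
})

#' ExpressionModel: a sparse multi-SNP predictor of one gene's expression
#'
#' Final ridge-smoothed weights over the SNPs retained by LASSO selection and
#' forward R-squared filtering, with the model-level statistics used
#' downstream.
#'
#' @slot geneId character gene identifier.
#' @slot weights named numeric vector of per-SNP weights (expression units
#'   per counted allele).
#' @slot lambdaLasso numeric LASSO penalty selected by repeated CV.
#' @slot alphaRidge numeric ridge penalty selected by repeated CV.
#' @slot r2Full numeric R-squared of the post-LASSO full OLS model.
#' @slot r2Filtered numeric R-squared of the filtered OLS model.
#' @slot fitP,fitQ numeric pre-validated model-fit p and BH q.
#' @slot status character: "ok", "intercept_only", or a flag string.
#'
#' @export
setClass("ExpressionModel",
  representation(
    geneId = "character", weights = "numeric",
    lambdaLasso = "numeric", alphaRidge = "numeric",
    r2Full = "numeric", r2Filtered = "numeric",
    fitP = "numeric", fitQ = "numeric", status = "character"
  ),
  prototype(lambdaLasso = NA_real_, alphaRidge = NA_real_,
            r2Full = NA_real_, r2Filtered = NA_real_,
            fitP = NA_real_, fitQ = NA_real_, status = "ok")
)

setValidity("ExpressionModel", function(object) {
  if (length(object@weights) &&
      (is.null(names(object@weights)) || any(!nzchar(names(object@weights)))))
    return("weights must be named by snp_id")
  if (!is.na(object@r2Full) && !is.na(object@r2Filtered) &&
      object@r2Full > 0 &&
      object@r2Filtered < 0.95 * object@r2Full - 1e-8)
    return("r2Filtered violates the 95% forward-filter guarantee")
  TRUE
})

#' ExpressionModelSet: models for many genes
#'
#' @slot models named list of \linkS4class{ExpressionModel} (names = gene ids).
#'
#' @export
setClass("ExpressionModelSet", representation(models = "list"))

setValidity("ExpressionModelSet", function(object) {
  if (!all(vapply(object@models, is, TRUE, "ExpressionModel")))
    return("all elements must be ExpressionModel")
  TRUE
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object@dosages), "samples x",
      ncol(object@dosages), "SNPs\n")
  cat("  blocks:", length(unique(object@snpInfo$block)),
      " MAF range:", paste(signif(range(object@snpInfo$maf), 3), collapse = "-"),
      "\n")
})

setMethod("show", "GwasSummary", function(object) {
  cat("GwasSummary:", nrow(object@table), "SNPs, n =", object@nGwas,
      if (object@harmonized) "(harmonized)" else "(unharmonized)", "\n")
})

setMethod("show", "ExpressionModel", function(object) {
  cat("ExpressionModel", object@geneId, "-", length(object@weights), "SNPs,",
      "R2(full/filtered):", signif(object@r2Full, 3), "/",
      signif(object@r2Filtered, 3), "\n")
})

setMethod("show", "ExpressionModelSet", function(object) {
  k <- vapply(object@models, function(m) length(m@weights), 1L)
  cat("ExpressionModelSet:", length(object@models), "genes;",
      sum(k > 0), "with SNPs; median SNPs/model:", median(k[k > 0]), "\n")
})
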