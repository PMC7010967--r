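#' Specify one LD block of SNPs
#'
#' SNP dosages within a block are generated from two independent haplotypes
#' per sample; each haplotype is an order-1 autoregressive latent Gaussian
#' thresholded at the per-SNP minor-allele-frequency quantile, which gives
#' tunable adjacent-SNP LD (r grows with \code{rho}) while blocks remain
#' mutually independent.
#'
#' @param n_snps number of SNPs in the block.
#' @param rho adjacent-SNP latent correlation, in [0, 1).
#' @param maf_range minor allele frequency interval; lower bound must be
#'   >= 0.05 (variants rarer than that are excluded from the study design).
#' @param start_bp 1-based position of the first SNP.
#' @param spacing_bp distance between adjacent SNPs.
#' @param chrom chromosome label.
#' @return an object of class \code{LdBlockSpec} (a validated list).
#' @export
ldBlockSpec <- function(n_snps, rho = 0.8, maf_range = c(0.1, 0.5),
                        start_bp = 1e6, spacing_bp = 5000, chrom = "chr1") {
  if (n_snps < 1) stop("LdBlockSpec: n_snps must be >= 1")
  if (rho < 0 || rho >= 1) stop("LdBlockSpec: rho must be in [0, 1)")
  if (maf_range[1] < 0.05 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("LdBlockSpec: maf_range must be within [0.05, 0.5]")
  structure(list(n_snps = as.integer(n_snps), rho = rho,
                 maf_range = maf_range, start_bp = as.integer(start_bp),
                 spacing_bp = as.integer(spacing_bp), chrom = chrom),
            class = "LdBlockSpec")
}

#' Specify the cis-regulatory architecture of one gene
#'
#' @param gene_id gene identifier.
#' @param tss,tes 1-based transcription start/end positions (tes >= tss).
#' @param chrom chromosome label.
#' @param causal_snps named numeric vector: names are SNP ids, values the
#'   relative effect of each causal SNP on expression (per standardized
#'   dosage). The absolute scale is set by \code{h2}.
#' @param h2 cis-heritability of the latent expression, in [0, 1).
#' @return an object of class \code{GeneArchitecture}.
#' @export
geneArchitecture <- function(gene_id, tss, tes, chrom = "chr1",
                             causal_snps = numeric(), h2 = 0) {
  if (tes < tss) stop("GeneArchitecture: tes must be >= tss")
  if (h2 < 0 || h2 >= 1) stop("GeneArchitecture: h2 must be in [0, 1)")
  if (length(causal_snps) && is.null(names(causal_snps)))
    stop("GeneArchitecture: causal_snps must be named by snp_id")
  structure(list(gene_id = gene_id, tss = as.integer(tss),
                 tes = as.integer(tes), chrom = chrom,
                 causal_snps = causal_snps, h2 = h2),
            class = "GeneArchitecture")
}

#' Specify the genetic architecture of one (GWAS) phenotype
#'
#' Four causal configurations are supported, covering the arrangements a
#' TWAS must disentangle: variants shared with eQTLs, variants merely in LD
#' with eQTLs, variants distinct from any eQTL, and phenotypes driven by a
#' gene's genetic expression (true mediation).
#'
#' @param phenotype_id identifier.
#' @param mode one of "shared_with_eqtl", "ld_tagged", "distinct",
#'   "mediated_by_gene".
#' @param causal_snps named numeric vector of direct SNP effects (phenotype
#'   SD units per standardized dosage); ignored for mediated mode.
#' @param gene_id,gene_effect for mediated mode: the driving gene and its
#'   effect (phenotype SD per expression SD).
#' @return an object of class \code{PhenotypeArchitecture}.
#' @export
phenotypeArchitecture <- function(phenotype_id,
                                  mode = c("shared_with_eqtl", "ld_tagged",
                                           "distinct", "mediated_by_gene"),
                                  causal_snps = numeric(),
                                  gene_id = NULL, gene_effect = NULL) {
  mode <- match.arg(mode)
  if (mode == "mediated_by_gene" &&
      (is.null(gene_id) || is.null(gene_effect)))
    stop("PhenotypeArchitecture: mediated_by_gene requires gene_id and gene_effect")
  if (mode != "mediated_by_gene" && length(causal_snps) &&
      is.null(names(causal_snps)))
    stop("PhenotypeArchitecture: causal_snps must be named by snp_id")
  structure(list(phenotype_id = phenotype_id, mode = mode,
                 causal_snps = causal_snps, gene_id = gene_id,
                 gene_effect = gene_effect),
            class = "PhenotypeArchitecture")
}

#' Assemble a full simulation scenario
#'
#' @param n_samples expression-panel sample size (>= 50, the minimum tissue
#'   size analyzed).
#' @param n_gwas_samples GWAS cohort size (>= 100), drawn independently of
#'   the expression panel from the same LD model.
#' @param blocks list of \code{\link{ldBlockSpec}}.
#' @param genes list of \code{\link{geneArchitecture}}.
#' @param phenotypes list of \code{\link{phenotypeArchitecture}}.
#' @param seed integer master seed; all stages derive child seeds from it.
#' @return an object of class \code{ScenarioConfig}.
#' @export
scenarioConfig <- function(n_samples, n_gwas_samples, blocks, genes = list(),
                           phenotypes = list(), seed = 1L) {
  if (n_samples < 50)
    stop("ScenarioConfig: n_samples must be >= 50")
  if (n_gwas_samples < 100)
    stop("ScenarioConfig: n_gwas_samples must be >= 100")
  if (!length(blocks)) stop("ScenarioConfig: at least one LD block required")
  stopifnot(all(vapply(blocks, inherits, TRUE, "LdBlockSpec")))
  structure(list(n_samples = as.integer(n_samples),
                 n_gwas_samples = as.integer(n_gwas_samples),
                 blocks = blocks, genes = genes, phenotypes = phenotypes,
                 seed = as.integer(seed)),
            class = "ScenarioConfig")
}

## SNP metadata table for a block list (deterministic ids and alleles).
blockSnpInfo <- function(blocks, seed) {
  allelePairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                       c("C", "A"), c("G", "A"), c("T", "C"), c("T", "G"))
  withSeed(childSeed(seed, "snpinfo"), {
    rows <- lapply(seq_along(blocks), function(b) {
      blk <- blocks[[b]]
      m <- blk$n_snps
      ap <- allelePairs[sample.int(nrow(allelePairs), m, replace = TRUE), ,
                        drop = FALSE]
      data.frame(
        snp_id = sprintf("blk%d_snp%d", b, seq_len(m)),
        chrom = blk$chrom,
        bp = blk$start_bp + (seq_len(m) - 1L) * blk$spacing_bp,
        ref = ap[, 1], eff = ap[, 2],
        maf = NA_real_,
        target_maf = runif(m, blk$maf_range[1], blk$maf_range[2]),
        block = b, rho = blk$rho,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

## Draw an n x SNP dosage matrix from the AR(1)-threshold haplotype model
## encoded in a snpInfo table (needs target_maf, block, rho columns).
drawDosages <- function(info, n, seed) {
  withSeed(seed, {
    cols <- vector("list", nrow(info))
    for (b in unique(info$block)) {
      idx <- which(info$block == b)
      m <- length(idx)
      rho <- info$rho[idx[1]]
      thr <- qnorm(info$target_maf[idx])
      dose <- matrix(0L, n, m)
      for (h in 1:2) {
        Z <- matrix(rnorm(n * m), n, m)
        if (m > 1 && rho > 0) {
          for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
        }
        dose <- dose + (Z < rep(thr, each = n))
      }
      for (j in seq_len(m)) cols[[idx[j]]] <- dose[, j]
    }
    out <- do.call(cbind, cols)
    colnames(out) <- info$snp_id
    out
  })
}

#' Simulate a genotype panel with LD-block structure
#'
#' Draws diploid dosages (two independent haplotypes per sample) under the
#' AR(1)-threshold model of \code{\link{ldBlockSpec}}. SNPs whose realized
#' minor allele frequency falls below 0.05 are dropped with a warning;
#' remaining ids, positions and generative parameters are kept so an
#' independent cohort (e.g. a GWAS) can be drawn from the same model.
#'
#' @param config a \code{\link{scenarioConfig}} (its blocks and seed are used).
#' @return a \linkS4class{GenotypePanel}.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  info <- blockSnpInfo(config$blocks, config$seed)
  dose <- drawDosages(info, config$n_samples, childSeed(config$seed, "panel"))
  freq <- colMeans(dose) / 2
  maf <- pmin(freq, 1 - freq)
  keep <- maf >= 0.05
  if (!all(keep)) {
    warning(sum(!keep), " SNP(s) dropped: realized MAF < 0.05 (",
            paste(head(info$snp_id[!keep], 5), collapse = ", "), ")")
    causal <- unique(unlist(lapply(config$genes,
                                   function(g) names(g$causal_snps))))
    lost <- intersect(causal, info$snp_id[!keep])
    if (length(lost))
      stop("causal SNP(s) dropped by the MAF filter: ",
           paste(lost, collapse = ", "))
  }
  info <- info[keep, , drop = FALSE]
  info$maf <- maf[keep]
  rownames(info) <- NULL
  new("GenotypePanel",
      dosages = dose[, keep, drop = FALSE],
      snpInfo = info,
      sampleIds = sprintf("S%04d", seq_len(config$n_samples)))
}

## Latent genetic value of a gene on a dosage matrix; returns the value
## scaled so its variance equals h2 when total latent variance is 1.
geneticValue <- function(X, gene) {
  snps <- names(gene$causal_snps)
  if (!length(snps) || gene$h2 == 0) return(rep(0, nrow(X)))
  miss <- setdiff(snps, colnames(X))
  if (length(miss))
    stop("causal SNP(s) absent from panel: ", paste(miss, collapse = ", "))
  g <- as.vector(standardizeColumns(X[, snps, drop = FALSE]) %*%
                   gene$causal_snps)
  vg <- var(g)
  if (vg == 0) return(rep(0, nrow(X)))
  g / sqrt(vg) * sqrt(gene$h2)
}

#' Simulate one gene's expression: latent values and raw counts
#'
#' The latent expression is the sum of causal-SNP effects on standardized
#' dosages plus Gaussian noise, scaled so genotype explains \code{h2} of the
#' variance (total latent variance 1). Raw counts are negative-binomial
#' around \code{libFactor * baseMean * exp(latent)}, giving the count-level
#' filters and normalization something realistic to work on.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param gene a \code{\link{geneArchitecture}}.
#' @param seed integer seed.
#' @param libFactors per-sample relative library size factors (default all 1).
#' @param baseMean mean count at latent = 0 and libFactor = 1.
#' @param dispersion negative-binomial dispersion (variance = mu + disp*mu^2).
#' @return list with \code{latent} (numeric, one per sample) and
#'   \code{counts} (non-negative integers).
#' @export
simulateExpression <- function(panel, gene, seed, libFactors = NULL,
                               baseMean = 100, dispersion = 0.1) {
  X <- dosageMatrix(panel)
  n <- nrow(X)
  if (is.null(libFactors)) libFactors <- rep(1, n)
  g <- geneticValue(X, gene)
  withSeed(childSeed(seed, paste0("expr_", gene$gene_id)), {
    latent <- g + rnorm(n, 0, sqrt(max(1 - gene$h2, 0)))
    mu <- libFactors * baseMean * exp(latent)
    counts <- rnbinom(n, mu = mu, size = 1 / dispersion)
    list(latent = latent, counts = counts)
  })
}

## Phenotype vector for a cohort dosage matrix under an architecture.
phenotypeValues <- function(X, pheno, genes, seed) {
  n <- nrow(X)
  withSeed(seed, {
    if (pheno$mode == "mediated_by_gene") {
      gene <- NULL
      for (g in genes) if (g$gene_id == pheno$gene_id) gene <- g
      if (is.null(gene))
        stop("mediated phenotype references unknown gene: ", pheno$gene_id)
      gv <- geneticValue(X, gene)  # variance h2 on the expression SD scale
      y <- pheno$gene_effect * gv + rnorm(n)
    } else {
      snps <- names(pheno$causal_snps)
      if (length(snps)) {
        miss <- setdiff(snps, colnames(X))
        if (length(miss))
          stop("phenotype causal SNP(s) absent: ", paste(miss, collapse = ", "))
        y <- as.vector(standardizeColumns(X[, snps, drop = FALSE]) %*%
                         pheno$causal_snps) + rnorm(n)
      } else {
        y <- rnorm(n)
      }
    }
    y
  })
}

#' Simulate GWAS summary statistics from an independent cohort
#'
#' A cohort of \code{nGwas} individuals is drawn from the panel's LD model
#' (independent of the expression samples, mirroring the application of
#' expression models to an external GWAS). Per SNP, beta and se come from
#' simple linear regression of the phenotype on raw dosage; monomorphic SNPs
#' in the realized cohort are excluded with a message.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param pheno a \code{\link{phenotypeArchitecture}}.
#' @param nGwas cohort size (>= 100).
#' @param seed integer seed.
#' @param genes list of \code{\link{geneArchitecture}} (needed for mediated
#'   phenotypes).
#' @param swapAlleles optional character vector of SNP ids emitted with
#'   effect/other alleles swapped (beta negated accordingly) to exercise
#'   harmonization.
#' @param returnCohort also return the cohort dosages and phenotype (for
#'   individual-level cross-checks).
#' @return a \linkS4class{GwasSummary}; with \code{returnCohort=TRUE}, a list
#'   \code{(gwas, dosages, phenotype)}.
#' @export
simulateGwasSummary <- function(panel, pheno, nGwas, seed, genes = list(),
                                swapAlleles = character(),
                                returnCohort = FALSE) {
  if (nGwas < 100) stop("nGwas must be >= 100")
  info <- snpInfo(panel)
  X <- drawDosages(info, nGwas,
                   childSeed(seed, paste0("gwasgeno_", pheno$phenotype_id)))
  y <- phenotypeValues(X, pheno, genes,
                       childSeed(seed, paste0("gwaspheno_", pheno$phenotype_id)))
  ss <- marginalGwas(X, y)
  mono <- is.na(ss$beta)
  if (any(mono))
    message(sum(mono), " monomorphic SNP(s) excluded from GWAS summary: ",
            paste(head(colnames(X)[mono], 5), collapse = ", "))
  tb <- data.frame(snp_id = info$snp_id, chrom = info$chrom, bp = info$bp,
                   a1 = info$eff, a2 = info$ref,
                   beta = ss$beta, se = ss$se, stringsAsFactors = FALSE)
  tb <- tb[!mono, , drop = FALSE]
  if (length(swapAlleles)) {
    i <- tb$snp_id %in% swapAlleles
    tmp <- tb$a1[i]; tb$a1[i] <- tb$a2[i]; tb$a2[i] <- tmp
    tb$beta[i] <- -tb$beta[i]
  }
  gw <- GwasSummary(tb, nGwas)
  if (returnCohort) list(gwas = gw, dosages = X, phenotype = y) else gw
}

#' Vectorized per-SNP simple linear regression
#'
#' Marginal slope and standard error of \code{y} on each column of \code{X}
#' (the per-SNP summary statistics of a GWAS or eQTL scan); zero-variance
#' columns yield NA.
#'
#' @param X samples x SNPs dosage matrix.
#' @param y phenotype/expression vector.
#' @return list with \code{beta} and \code{se}, one entry per column.
#' @export
marginalGwas <- function(X, y) {
  n <- nrow(X)
  xc <- sweep(X, 2, colMeans(X), "-")
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- as.vector(crossprod(xc, yc))
  syy <- sum(yc^2)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- syy - ifelse(sxx > 0, sxy^2 / sxx, 0)
  se <- ifelse(sxx > 0, sqrt(pmax(rss, 0) / (n - 2) / sxx), NA_real_)
  se[is.finite(se) & se == 0] <- NA_real_
  list(beta = beta, se = se)
}
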