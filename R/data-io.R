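#' Write a genotype panel to disk
#'
#' \code{writeGenotypeTsv} writes a samples x SNPs dosage table with a SNP
#' metadata header block; \code{writeGenotypeVcf} writes a minimal VCF 4.2
#' with GT genotypes (dosage of the ALT = counted allele).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param path output file.
#' @export
writeGenotypeTsv <- function(panel, path) {
  X <- dosageMatrix(panel)
  out <- data.frame(sample_id = panel@sampleIds, X, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypeTsv
#' @export
writeGenotypeVcf <- function(panel, path) {
  info <- snpInfo(panel)
  X <- dosageMatrix(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel@sampleIds), collapse = "\t")),
             con)
  gtmap <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(info))) {
    gts <- gtmap[X[, j] + 1L]
    writeLines(paste(c(info$chrom[j], info$bp[j], info$snp_id[j], info$ref[j],
                       info$eff[j], ".", "PASS", ".", "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read a genes x samples expression table
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path file path.
#' @export
writeExpressionTsv <- function(counts, path) {
  out <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTsv
#' @export
readExpressionTsv <- function(path) {
  tb <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- tb[[1]]
  m
}

#' Write / read gene annotation as 4-column BED
#'
#' On disk the interval is half-open 0-based (BED convention); in memory
#' coordinates are 1-based closed (tss/tes).
#'
#' @param genes list of \code{\link{geneArchitecture}} or a data.frame with
#'   gene_id, chrom, tss, tes.
#' @param path file path.
#' @export
writeGeneAnnotationBed <- function(genes, path) {
  tb <- geneAnnotationTable(genes)
  bed <- data.frame(chrom = tb$chrom, start = tb$tss - 1L, end = tb$tes,
                    gene_id = tb$gene_id)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneAnnotationBed
#' @export
readGeneAnnotationBed <- function(path) {
  bed <- read.delim(path, header = FALSE,
                    col.names = c("chrom", "start", "end", "gene_id"))
  data.frame(gene_id = bed$gene_id, chrom = bed$chrom,
             tss = bed$start + 1L, tes = bed$end, stringsAsFactors = FALSE)
}

## Normalize gene annotation input to a data.frame.
geneAnnotationTable <- function(genes) {
  if (is.data.frame(genes)) return(genes)
  do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, chrom = g$chrom, tss = g$tss, tes = g$tes,
               stringsAsFactors = FALSE)))
}

#' Write / read GWAS summary statistics (SNP, CHR, BP, A1, A2, BETA, SE)
#'
#' @param gwas a \linkS4class{GwasSummary}.
#' @param path file path.
#' @param nGwas sample size to attach on read.
#' @export
writeGwasTsv <- function(gwas, path) {
  tb <- gwasTable(gwas)
  out <- data.frame(SNP = tb$snp_id, CHR = tb$chrom, BP = tb$bp,
                    A1 = tb$a1, A2 = tb$a2, BETA = tb$beta, SE = tb$se)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGwasTsv
#' @export
readGwasTsv <- function(path, nGwas) {
  tb <- read.delim(path)
  GwasSummary(data.frame(snp_id = tb$SNP, chrom = tb$CHR, bp = tb$BP,
                         a1 = tb$A1, a2 = tb$A2, beta = tb$BETA, se = tb$SE,
                         stringsAsFactors = FALSE),
              nGwas = nGwas)
}
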