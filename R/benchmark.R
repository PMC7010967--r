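#' Label significant TWAS calls against a truth set
#'
#' A significant gene-phenotype call is a \code{true_positive} when the pair
#' is in the truth set; a \code{bystander} when its gene body lies within
#' \code{window} (closed interval, minimal gene-body-to-gene-body distance)
#' of a truth gene for the same phenotype; \code{novel} otherwise. Calls for
#' unannotated genes are labeled novel with a warning. Calls are
#' deduplicated to unique gene-phenotype pairs (multi-dataset hits count
#' once).
#'
#' @param calls data.frame of significant calls (gene_id, phenotype_id,
#'   optionally colocalized).
#' @param truth data.frame of causal pairs (gene_id, phenotype_id).
#' @param annotation data.frame gene_id, chrom, tss, tes covering both call
#'   and truth genes.
#' @param window distance threshold in bp (default 1 Mb).
#' @return unique-pair data.frame with a \code{label} column.
#' @export
annotateBystanders <- function(calls, truth, annotation, window = 1e6) {
  ann <- geneAnnotationTable(annotation)
  pairs <- unique(calls[, intersect(c("gene_id", "phenotype_id", "colocalized"),
                                    names(calls)), drop = FALSE])
  if (!"colocalized" %in% names(pairs)) pairs$colocalized <- NA
  ## collapse multi-dataset duplicates: colocalized if colocalized anywhere
  key <- paste(pairs$gene_id, pairs$phenotype_id, sep = "|")
  pairs <- do.call(rbind, lapply(split(pairs, key), function(d)
    data.frame(gene_id = d$gene_id[1], phenotype_id = d$phenotype_id[1],
               colocalized = if (all(is.na(d$colocalized))) NA
                             else any(d$colocalized, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  truthKey <- paste(truth$gene_id, truth$phenotype_id, sep = "|")
  lab <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    k <- paste(pairs$gene_id[i], pairs$phenotype_id[i], sep = "|")
    if (k %in% truthKey) { lab[i] <- "true_positive"; next }
    gi <- ann[ann$gene_id == pairs$gene_id[i], , drop = FALSE]
    if (!nrow(gi)) {
      warning("gene not annotated, labeled novel: ", pairs$gene_id[i])
      lab[i] <- "novel"; next
    }
    tg <- truth$gene_id[truth$phenotype_id == pairs$phenotype_id[i]]
    ti <- ann[ann$gene_id %in% tg, , drop = FALSE]
    near <- FALSE
    for (j in seq_len(nrow(ti))) {
      if (ti$chrom[j] != gi$chrom[1]) next
      d <- max(0, max(ti$tss[j], gi$tss[1]) - min(ti$tes[j], gi$tes[1]))
      if (d <= window) { near <- TRUE; break }
    }
    lab[i] <- if (near) "bystander" else "novel"
  }
  pairs$label <- lab
  rownames(pairs) <- NULL
  pairs
}

#' Sensitivity against a truth set
#'
#' \code{|detected truth pairs| / |truth pairs|}.
#'
#' @param truth data.frame (gene_id, phenotype_id) of causal pairs.
#' @param detected data.frame (gene_id, phenotype_id) of detected pairs.
#' @export
sensitivityScore <- function(truth, detected) {
  stopifnot(nrow(truth) > 0)
  tk <- unique(paste(truth$gene_id, truth$phenotype_id, sep = "|"))
  dk <- unique(paste(detected$gene_id, detected$phenotype_id, sep = "|"))
  length(intersect(tk, dk)) / length(tk)
}

#' Positive predictive value at truth-set loci
#'
#' TP / (TP + bystanders), over unique gene-phenotype pairs at truth-set
#' loci; novel calls (outside truth loci) do not enter the denominator.
#' Returns NA when no call lands at a truth locus.
#'
#' @param labeled data.frame from \code{\link{annotateBystanders}}.
#' @param colocalizedOnly restrict to calls with evidence of colocalization.
#' @export
ppvScore <- function(labeled, colocalizedOnly = FALSE) {
  if (colocalizedOnly)
    labeled <- labeled[!is.na(labeled$colocalized) & labeled$colocalized, ,
                       drop = FALSE]
  tp <- sum(labeled$label == "true_positive")
  by <- sum(labeled$label == "bystander")
  if (tp + by == 0) return(NA_real_)
  tp / (tp + by)
}

#' Benchmark report: sensitivity, PPV and bystander accounting
#'
#' @param calls significant TWAS calls (gene_id, phenotype_id, optionally
#'   colocalized from \code{\link{callColocalization}}).
#' @param truth truth-set pairs (gene_id, phenotype_id).
#' @param annotation gene annotation (gene_id, chrom, tss, tes).
#' @param window bystander distance (default 1 Mb).
#' @return list with sensitivity, ppv, ppv_colocalized, the labeled call
#'   table and count breakdown.
#' @export
benchmarkReport <- function(calls, truth, annotation, window = 1e6) {
  labeled <- annotateBystanders(calls, truth, annotation, window)
  detected <- labeled[labeled$label == "true_positive", , drop = FALSE]
  colocDet <- detected[!is.na(detected$colocalized) & detected$colocalized, ,
                       drop = FALSE]
  list(
    sensitivity = sensitivityScore(truth, detected),
    sensitivity_colocalized = sensitivityScore(truth, colocDet),
    ppv = ppvScore(labeled),
    ppv_colocalized = ppvScore(labeled, colocalizedOnly = TRUE),
    counts = table(factor(labeled$label,
                          c("true_positive", "bystander", "novel"))),
    labeled = labeled,
    n_truth = nrow(unique(truth[, c("gene_id", "phenotype_id")]))
  )
}

#' Load the packaged truth-set detection table
#'
#' A curated table of 41 detected causal gene-metabolite pairs (metabolite
#' id/name, causal gene, number of tissue-level associations, most
#' significant tissue and its q-value), bundled as a fixture for
#' report-formatting examples and regression tests.
#'
#' @return data.frame with 41 rows.
#' @export
truthsetDetections <- function() {
  read.delim(system.file("extdata", "truthset_detected.tsv",
                         package = "twasBench"),
             stringsAsFactors = FALSE)
}
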