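#' A multi-locus benchmark scenario with pleiotropic bystander genes
#'
#' Each locus is one LD block on its own chromosome carrying one causal gene
#' and \code{genesPerLocus - 1} bystander genes. All genes at a locus share
#' the same causal regulatory SNP (a pleiotropic eQTL), and the locus
#' phenotype is mediated by the causal gene's genetic expression. This is
#' the arrangement in which colocalization cannot rescue bystanders: their
#' eQTL genuinely shares the phenotype's causal variant.
#'
#' @param nLoci number of loci/phenotypes (default 20).
#' @param genesPerLocus genes per locus (default 3: 1 causal + 2 bystanders).
#' @param nSamples expression panel size (default 300).
#' @param nGwas GWAS cohort size (default 3000).
#' @param snpsPerLocus SNPs per LD block (default 30).
#' @param h2 cis-heritability of each gene (default 0.6).
#' @param geneEffect mediation effect of the causal gene on the phenotype
#'   (phenotype SD per expression SD; default 0.3).
#' @param rho adjacent-SNP LD parameter (default 0.8).
#' @param seed master seed.
#' @return list with \code{config} (a \code{\link{scenarioConfig}}) and
#'   \code{truth} (data.frame gene_id, phenotype_id).
#' @export
bystanderScenario <- function(nLoci = 20, genesPerLocus = 3, nSamples = 300,
                              nGwas = 3000, snpsPerLocus = 30, h2 = 0.6,
                              geneEffect = 0.3, rho = 0.8, seed = 1L) {
  blocks <- list(); genes <- list(); phenos <- list()
  truth <- list()
  for (l in seq_len(nLoci)) {
    chrom <- sprintf("chr%d", l)
    blocks[[l]] <- ldBlockSpec(snpsPerLocus, rho = rho,
                               maf_range = c(0.1, 0.5), start_bp = 1e6,
                               spacing_bp = 5000, chrom = chrom)
    causalSnp <- sprintf("blk%d_snp%d", l, ceiling(snpsPerLocus / 2))
    ph <- sprintf("pheno%02d", l)
    for (g in seq_len(genesPerLocus)) {
      gid <- sprintf("gene%02d_%d", l, g)
      tss <- 1e6 + (g - 1L) * 2e4
      genes[[gid]] <- geneArchitecture(gid, tss = tss, tes = tss + 1e4,
                                       chrom = chrom,
                                       causal_snps = setNames(1, causalSnp),
                                       h2 = h2)
      if (g == 1) truth[[length(truth) + 1]] <-
          data.frame(gene_id = gid, phenotype_id = ph,
                     stringsAsFactors = FALSE)
    }
    phenos[[ph]] <- phenotypeArchitecture(
      ph, mode = "mediated_by_gene", gene_id = sprintf("gene%02d_1", l),
      gene_effect = geneEffect)
  }
  list(config = scenarioConfig(nSamples, nGwas, blocks, genes, phenos,
                               seed = seed),
       truth = do.call(rbind, truth))
}

#' Run the full analysis pipeline on a simulation scenario
#'
#' simulate genotypes and expression, preprocess (expression filter, TMM,
#' log-CPM, hidden-factor removal), cis-eQTL scan, multi-SNP model building
#' with pre-validated fit filtering, GWAS simulation and harmonization,
#' summary-statistic TWAS, conditional analysis of significant hits,
#' colocalization, and truth-set benchmarking. All stages derive their seeds
#' from the scenario seed, so a re-run with the same configuration is
#' bit-identical.
#'
#' @param scenario list with \code{config} and \code{truth} (e.g. from
#'   \code{\link{bystanderScenario}}).
#' @param params \code{\link{modelParams}} list (default
#'   \code{\link{testProfile}}).
#' @param n_hidden_factors hidden expression factors to remove. The default
#'   is 0: the generator plants no batch structure, and with few genes the
#'   leading expression PCs are the genetic signals themselves, so removing
#'   them would be destructive. Raise this when emulating confounded data.
#' @param twas_fdr,eqtl_fdr,fit_fdr,gwas_p,clpp_threshold stage thresholds.
#' @param cond_alpha conditional significance level; default Bonferroni
#'   0.05 / (number of TWAS tests).
#' @param out_dir optional directory for stage TSVs and a run manifest.
#' @return list with the panel, intermediate tables, and the
#'   \code{\link{benchmarkReport}}.
#' @export
runPipeline <- function(scenario, params = testProfile(),
                        n_hidden_factors = 0, twas_fdr = 0.01,
                        eqtl_fdr = 0.01, fit_fdr = 0.01, gwas_p = 5e-8,
                        clpp_threshold = 0.01, cond_alpha = NULL,
                        out_dir = NULL) {
  config <- scenario$config
  truth <- scenario$truth
  seed <- config$seed
  panel <- simulateGenotypes(config)
  n <- nSamples(panel)

  ## expression: shared library-size factors, per-gene counts + latent
  libFactors <- withSeed(childSeed(seed, "libsize"),
                         exp(rnorm(n, 0, 0.3)))
  counts <- matrix(0L, length(config$genes), n,
                   dimnames = list(names(config$genes), panel@sampleIds))
  for (g in names(config$genes)) {
    sim <- simulateExpression(panel, config$genes[[g]], seed = seed,
                              libFactors = libFactors)
    counts[g, ] <- sim$counts
  }

  filtered <- filterGenes(counts)
  tmm <- tmmFactors(filtered)
  le <- logCpm(filtered, tmm)
  resid <- removeHiddenFactors(le, covariates = NULL,
                               n_factors = n_hidden_factors)

  windows <- cisWindows(config$genes)
  eqtls <- cisScan(resid$values, panel, windows)
  topHits <- topEqtl(eqtls)

  mset <- buildModels(resid$values, panel, windows, params = params,
                      seed = seed)
  mset <- modelFitQvalues(mset, resid$values, panel, k = params$k,
                          seed = seed)
  retained <- significantModels(mset, fdr = fit_fdr)

  gwasList <- list()
  for (ph in names(config$phenotypes)) {
    gw <- simulateGwasSummary(panel, config$phenotypes[[ph]],
                              config$n_gwas_samples, seed = seed,
                              genes = config$genes)
    gwasList[[ph]] <- harmonizeGwas(gw, panel)
  }

  info <- snpInfo(panel)
  positions <- setNames(info$bp, info$snp_id)
  ref <- ldReference(panel)
  scan <- associationScan(retained, gwasList, ref, fdr = twas_fdr,
                          positions = positions)
  sig <- scan[scan$significant, , drop = FALSE]

  if (is.null(cond_alpha))
    cond_alpha <- if (nrow(scan)) 0.05 / nrow(scan) else 0.05
  maf <- setNames(info$maf, info$snp_id)
  cond <- conditionalTwas(retained, sig, gwasList, ref, alpha = cond_alpha,
                          maf = maf)

  colocRows <- list()
  for (i in seq_len(nrow(sig))) {
    g <- sig$gene_id[i]; ph <- sig$phenotype_id[i]
    rec <- eqtls[eqtls$gene_id == g, , drop = FALSE]
    ca <- colocAnalysis(models(retained)[[g]], rec, gwasList[[ph]], panel,
                        eqtl_fdr = eqtl_fdr, gwas_p = gwas_p,
                        threshold = clpp_threshold)
    ca$phenotype_id <- ph
    ca$dataset_id <- sig$dataset_id[i]
    colocRows[[i]] <- ca
  }
  colocTable <- if (length(colocRows)) do.call(rbind, colocRows)
                else data.frame()
  colocCalls <- if (nrow(colocTable))
    callColocalization(colocTable, threshold = clpp_threshold)
  else data.frame(gene_id = character(), phenotype_id = character(),
                  eligible = logical(), colocalized = logical())

  calls <- sig[, c("gene_id", "phenotype_id", "dataset_id", "z", "p", "q")]
  idx <- match(paste(calls$gene_id, calls$phenotype_id),
               paste(colocCalls$gene_id, colocCalls$phenotype_id))
  calls$colocalized <- colocCalls$colocalized[idx]
  report <- benchmarkReport(calls, truth, config$genes)

  out <- list(panel = panel, counts = counts, residual = resid$values,
              eqtls = eqtls, top_eqtls = topHits, models = mset,
              retained_models = retained, gwas = gwasList, scan = scan,
              significant = sig, conditional = cond, coloc = colocTable,
              coloc_calls = colocCalls, calls = calls, report = report,
              cond_alpha = cond_alpha)
  if (!is.null(out_dir)) writePipelineOutputs(out, scenario, out_dir)
  out
}

## Write stage tables and a manifest (seed, thresholds, package version);
## no timestamps, so identical runs produce identical files.
writePipelineOutputs <- function(out, scenario, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(out$eqtls, "eqtls.tsv")
  wt(modelTable(out$retained_models, out$panel), "models.tsv")
  scan <- out$scan
  scan$contributions <- NULL
  wt(scan, "twas.tsv")
  wt(out$conditional, "conditional.tsv")
  if (nrow(out$coloc)) wt(out$coloc, "coloc.tsv")
  wt(out$report$labeled, "benchmark_calls.tsv")
  manifest <- list(
    seed = scenario$config$seed,
    n_samples = scenario$config$n_samples,
    n_gwas_samples = scenario$config$n_gwas_samples,
    n_genes = length(scenario$config$genes),
    n_phenotypes = length(scenario$config$phenotypes),
    package_version = as.character(utils::packageVersion("twasBench")),
    sensitivity = out$report$sensitivity,
    ppv = out$report$ppv,
    ppv_colocalized = out$report$ppv_colocalized)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Build a benchmark scenario from a YAML configuration file
#'
#' Recognized keys (all optional, with \code{\link{bystanderScenario}}
#' defaults): n_loci, genes_per_locus, n_samples, n_gwas_samples,
#' snps_per_locus, h2, gene_effect, rho, seed.
#'
#' @param path YAML file path.
#' @return list with \code{config} and \code{truth}, as
#'   \code{\link{bystanderScenario}}.
#' @export
scenarioFromYaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  bystanderScenario(
    nLoci = y$n_loci %||% 20, genesPerLocus = y$genes_per_locus %||% 3,
    nSamples = y$n_samples %||% 300, nGwas = y$n_gwas_samples %||% 3000,
    snpsPerLocus = y$snps_per_locus %||% 30, h2 = y$h2 %||% 0.6,
    geneEffect = y$gene_effect %||% 0.3, rho = y$rho %||% 0.8,
    seed = y$seed %||% 1L)
}
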