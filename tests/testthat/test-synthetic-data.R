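test_that("seeded genotype simulation is bit-reproducible and respects the MAF floor", {
  cfg <- scenarioConfig(100, 500,
                        blocks = list(ldBlockSpec(15, rho = 0.9),
                                      ldBlockSpec(10, rho = 0, chrom = "chr2",
                                                  start_bp = 5e6)),
                        seed = 11)
  p1 <- simulateGenotypes(cfg)
  p2 <- simulateGenotypes(cfg)
  expect_identical(dosages(p1), dosages(p2))
  expect_identical(snpInfo(p1), snpInfo(p2))
  expect_true(all(snpInfo(p1)$maf >= 0.05))
  expect_true(all(dosages(p1) %in% 0:2))
})

test_that("LD structure follows the AR(1) haplotype model", {
  cfg <- scenarioConfig(2000, 500,
                        blocks = list(ldBlockSpec(10, rho = 0.95),
                                      ldBlockSpec(10, rho = 0, chrom = "chr2",
                                                  start_bp = 9e6)),
                        seed = 5)
  panel <- simulateGenotypes(cfg)
  info <- snpInfo(panel)
  R <- suppressWarnings(cor(dosages(panel)))
  cross <- abs(R[info$block == 1, info$block == 2])
  expect_lt(max(cross), 0.1)
  b1 <- which(info$block == 1)
  adj <- vapply(seq_len(length(b1) - 1),
                function(i) R[b1[i], b1[i + 1]]^2, numeric(1))
  expect_gt(max(adj), 0.5)
})

test_that("degenerate block configurations are rejected", {
  expect_error(ldBlockSpec(0, rho = 0.5), "n_snps")
  expect_error(ldBlockSpec(5, rho = 1), "rho")
  expect_error(ldBlockSpec(5, rho = 0.5, maf_range = c(0.01, 0.4)),
               "maf_range")
  expect_error(scenarioConfig(40, 500, list(ldBlockSpec(5))), "n_samples")
})

test_that("expression heritability is realized as specified", {
  # null gene: no slope on its nominal causal SNP
  tFail <- 0
  for (s in 1:20) {
    sc <- makeSingleEqtlScenario(n = 500, h2 = 0, seed = s)
    X <- dosageMatrix(sc$panel)
    fit <- summary(lm(sc$expr$latent ~ X[, sc$causal]))
    if (abs(fit$coefficients[2, 3]) >= 4) tFail <- tFail + 1
  }
  expect_lte(tFail, 1)

  # h2 = 0.5, single causal SNP: sample R2 concentrates around 0.5
  hits <- 0
  for (s in 1:50) {
    sc <- makeSingleEqtlScenario(n = 500, h2 = 0.5, seed = 100 + s)
    r2 <- cor(dosageMatrix(sc$panel)[, sc$causal], sc$expr$latent)^2
    if (r2 >= 0.35 && r2 <= 0.65) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("two uncorrelated causal SNPs split the heritability", {
  cfg <- scenarioConfig(
    3000, 500,
    blocks = list(ldBlockSpec(1, rho = 0, chrom = "chr1"),
                  ldBlockSpec(1, rho = 0, chrom = "chr1", start_bp = 1.5e6)),
    genes = list(g1 = geneArchitecture(
      "g1", 1e6, 1.01e6, "chr1",
      causal_snps = c(blk1_snp1 = 1, blk2_snp1 = 1), h2 = 0.5)),
    seed = 21)
  panel <- simulateGenotypes(cfg)
  expr <- simulateExpression(panel, cfg$genes$g1, seed = 21)
  X <- dosageMatrix(panel)
  r2a <- cor(X[, "blk1_snp1"], expr$latent)^2
  r2b <- cor(X[, "blk2_snp1"], expr$latent)^2
  expect_equal(r2a, 0.25, tolerance = 0.2)
  expect_equal(r2b, 0.25, tolerance = 0.2)
})

test_that("causal SNPs absent from the panel are an error", {
  sc <- makeSingleEqtlScenario(seed = 2)
  bad <- geneArchitecture("gX", 1e6, 1.01e6, "chr1",
                          causal_snps = c(nonexistent_snp = 1), h2 = 0.3)
  expect_error(simulateExpression(sc$panel, bad, seed = 1), "absent")
})

test_that("GWAS summary statistics equal the OLS oracle on the same cohort", {
  sc <- makeSingleEqtlScenario(seed = 3)
  ph <- phenotypeArchitecture("p1", mode = "shared_with_eqtl",
                              causal_snps = setNames(0.2, sc$causal))
  sim <- simulateGwasSummary(sc$panel, ph, 400, seed = 3,
                             returnCohort = TRUE)
  tb <- gwasTable(sim$gwas)
  for (i in sample(nrow(tb), 5)) {
    fit <- summary(lm(sim$phenotype ~ sim$dosages[, tb$snp_id[i]]))
    expect_equal(tb$beta[i], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(tb$se[i], fit$coefficients[2, 2], tolerance = 1e-10)
  }
})

test_that("null phenotypes give calibrated marginal p-values", {
  cfg <- scenarioConfig(
    100, 2000,
    blocks = lapply(1:40, function(b)
      ldBlockSpec(50, rho = 0, chrom = sprintf("chr%d", b))),
    seed = 9)
  panel <- simulateGenotypes(cfg)
  ph <- phenotypeArchitecture("null", mode = "distinct")
  gw <- simulateGwasSummary(panel, ph, 2000, seed = 9)
  tb <- gwasTable(gw)
  p <- 2 * pnorm(-abs(tb$z))
  expect_gt(nrow(tb), 1500)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("a causal SNP powered at noncentrality 8 reaches genome-wide significance", {
  # E[z] = sqrt(n) * b for unit-variance noise; b chosen for ncp 8,
  # so power at p <= 5e-8 is pnorm(8 - 5.45) ~ 0.99
  hits <- 0
  nseeds <- 20
  for (s in seq_len(nseeds)) {
    sc <- makeSingleEqtlScenario(n = 100, seed = 300 + s, rho = 0)
    n <- 2000
    b <- 8 / sqrt(n)
    ph <- phenotypeArchitecture("p", mode = "shared_with_eqtl",
                                causal_snps = setNames(b, sc$causal))
    gw <- simulateGwasSummary(sc$panel, ph, n, seed = 300 + s)
    tb <- gwasTable(gw)
    pz <- 2 * pnorm(-abs(tb$z[tb$snp_id == sc$causal]))
    if (length(pz) && pz <= 5e-8) hits <- hits + 1
  }
  expect_gte(hits / nseeds, 0.7)
})

test_that("file writers round-trip their formats", {
  sc <- makeSingleEqtlScenario(n = 60, nSnps = 5, seed = 4)
  td <- withr::local_tempdir()
  writeGenotypeVcf(sc$panel, file.path(td, "geno.vcf"))
  vcf <- readLines(file.path(td, "geno.vcf"))
  expect_match(vcf[1], "fileformat=VCFv4.2")
  expect_length(vcf, 3 + nSnps(sc$panel))

  ann <- file.path(td, "genes.bed")
  writeGeneAnnotationBed(sc$config$genes, ann)
  back <- readGeneAnnotationBed(ann)
  expect_equal(back$tss, 1e6)
  expect_equal(back$tes, 1.01e6)

  ph <- phenotypeArchitecture("p1", mode = "distinct")
  gw <- simulateGwasSummary(sc$panel, ph, 300, seed = 4)
  gf <- file.path(td, "gwas.tsv")
  writeGwasTsv(gw, gf)
  expect_identical(readLines(gf, n = 1), "SNP\tCHR\tBP\tA1\tA2\tBETA\tSE")
  back <- readGwasTsv(gf, nGwas = 300)
  expect_equal(gwasTable(back)$beta, gwasTable(gw)$beta, tolerance = 1e-6)
})
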