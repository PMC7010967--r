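# A tiny panel + handcrafted GWAS for the algebraic identities.
makeTwasFixture <- function(seed = 1L, n = 400, nSnps = 8, rho = 0.5) {
  sc <- makeSingleEqtlScenario(n = n, nSnps = nSnps, rho = rho, seed = seed)
  ph <- phenotypeArchitecture("p1", mode = "shared_with_eqtl",
                              causal_snps = setNames(0.15, sc$causal))
  gw <- simulateGwasSummary(sc$panel, ph, 2000, seed = seed)
  list(sc = sc, gwas = harmonizeGwas(gw, sc$panel),
       ref = ldReference(sc$panel))
}

test_that("harmonization passes matched alleles, flips swapped ones, drops ambiguous", {
  sc <- makeSingleEqtlScenario(n = 60, nSnps = 4, seed = 71, causalIdx = 2)
  info <- snpInfo(sc$panel)
  tb <- data.frame(snp_id = info$snp_id, chrom = info$chrom, bp = info$bp,
                   a1 = info$eff, a2 = info$ref,
                   beta = c(0.2, -0.1, 0.3, 0.05), se = 0.1)
  # snp2 swapped; snp3 strand-ambiguous; snp4 mismatched alleles
  tb$a1[2] <- info$ref[2]; tb$a2[2] <- info$eff[2]; tb$beta[2] <- -0.1
  tb$a1[3] <- "A"; tb$a2[3] <- "T"
  tb$a1[4] <- "G"; tb$a2[4] <- "G"
  h <- suppressMessages(harmonizeGwas(GwasSummary(tb, 500), sc$panel))
  ht <- gwasTable(h)
  expect_equal(ht$beta[ht$snp_id == info$snp_id[1]], 0.2)
  expect_equal(ht$beta[ht$snp_id == info$snp_id[2]], 0.1)  # sign restored
  expect_false(info$snp_id[3] %in% ht$snp_id)
  expect_false(info$snp_id[4] %in% ht$snp_id)
})

test_that("alleles emitted swapped by the generator flip z only", {
  sc <- makeSingleEqtlScenario(n = 100, nSnps = 5, seed = 72)
  ph <- phenotypeArchitecture("p", mode = "shared_with_eqtl",
                              causal_snps = setNames(0.3, sc$causal))
  straight <- simulateGwasSummary(sc$panel, ph, 800, seed = 72)
  swapped <- simulateGwasSummary(sc$panel, ph, 800, seed = 72,
                                 swapAlleles = sc$causal)
  hs <- harmonizeGwas(straight, sc$panel)
  hw <- harmonizeGwas(swapped, sc$panel)
  zs <- gwasTable(hs); zw <- gwasTable(hw)
  expect_equal(zs$z, zw$z[match(zs$snp_id, zw$snp_id)], tolerance = 1e-12)
  raw <- gwasTable(swapped)
  expect_equal(raw$z[raw$snp_id == sc$causal],
               -zs$z[zs$snp_id == sc$causal], tolerance = 1e-12)
})

test_that("sigma_g matches hand values and the direct-computation oracle", {
  ref1 <- structure(list(sd = c(s1 = 0.5), cov = matrix(0.25, 1, 1,
                    dimnames = list("s1", "s1"))), class = "LdReference")
  expect_equal(sigmaG(c(s1 = 2), ref1), 1.0)
  ref2 <- structure(list(sd = c(a = 1, b = 1),
                         cov = diag(2) |> `dimnames<-`(list(c("a", "b"),
                                                            c("a", "b")))),
                    class = "LdReference")
  expect_equal(sigmaG(c(a = 1, b = 1), ref2), sqrt(2))

  fx <- makeTwasFixture(seed = 73)
  snps <- snpInfo(fx$sc$panel)$snp_id[1:5]
  w <- setNames(rnorm(5, 0, 0.3), snps)
  direct <- sd(dosageMatrix(fx$sc$panel, snps) %*% w)
  expect_equal(sigmaG(w, fx$ref), direct, tolerance = 1e-8)
})

test_that("single-SNP models reduce to the GWAS z-score, with the weight's sign", {
  fx <- makeTwasFixture(seed = 74)
  snp <- fx$sc$causal
  tb <- gwasTable(fx$gwas)
  zl <- tb$z[tb$snp_id == snp]
  mPos <- new("ExpressionModel", geneId = "g", weights = setNames(0.7, snp))
  mNeg <- new("ExpressionModel", geneId = "g", weights = setNames(-0.7, snp))
  expect_equal(spredixcanZ(mPos, fx$gwas, fx$ref)$z, zl, tolerance = 1e-10)
  expect_equal(spredixcanZ(mNeg, fx$gwas, fx$ref)$z, -zl, tolerance = 1e-10)
})

test_that("per-SNP contributions sum exactly to the gene z-score", {
  fx <- makeTwasFixture(seed = 75)
  snps <- snpInfo(fx$sc$panel)$snp_id
  set.seed(75)
  w <- setNames(rnorm(length(snps), 0, 0.4), snps)
  m <- new("ExpressionModel", geneId = "g", weights = w)
  res <- spredixcanZ(m, fx$gwas, fx$ref)
  expect_equal(sum(res$contributions), res$z, tolerance = 1e-10)
  expect_equal(res$p, 2 * pnorm(-abs(res$z)))
})

test_that("flipping a SNP's allele coding everywhere leaves z_g unchanged", {
  fx <- makeTwasFixture(seed = 76)
  snp <- fx$sc$causal
  w <- setNames(c(0.5, -0.2), c(snp, snpInfo(fx$sc$panel)$snp_id[1]))
  m <- new("ExpressionModel", geneId = "g", weights = w)
  z0 <- spredixcanZ(m, fx$gwas, fx$ref)$z

  # recode: dosage -> 2 - dosage, weight and GWAS beta negate together
  panel2 <- fx$sc$panel
  j <- which(snpInfo(panel2)$snp_id == snp)
  panel2@dosages[, j] <- 2 - panel2@dosages[, j]
  tmp <- panel2@snpInfo$ref[j]
  panel2@snpInfo$ref[j] <- panel2@snpInfo$eff[j]
  panel2@snpInfo$eff[j] <- tmp
  tb <- gwasTable(fx$gwas)
  k <- tb$snp_id == snp
  tb$beta[k] <- -tb$beta[k]
  a1 <- tb$a1[k]; tb$a1[k] <- tb$a2[k]; tb$a2[k] <- a1
  gwas2 <- GwasSummary(tb, fx$gwas@nGwas); gwas2@harmonized <- TRUE
  w2 <- w; w2[snp] <- -w2[snp]
  m2 <- new("ExpressionModel", geneId = "g", weights = w2)
  z1 <- spredixcanZ(m2, gwas2, ldReference(panel2))$z
  expect_equal(z1, z0, tolerance = 1e-10)
})

test_that("the top contributing SNP follows the sign-and-magnitude rule", {
  expect_equal(topContributingSnp(c(a = 1.5, b = -0.4, c = 0.9), 2.0), "a")
  expect_equal(topContributingSnp(c(a = 1.0), 1.0), "a")
  expect_equal(topContributingSnp(c(a = 1.0, b = 1.0), 2.0,
                                  positions = c(a = 900, b = 100)), "b")
  expect_error(topContributingSnp(c(a = -1, b = -2), 3), "review")
})

test_that("summary-based z matches the individual-level regression oracle", {
  # phenotype mediated by the gene; LD reference = the GWAS cohort itself
  deltas <- numeric(10)
  for (s in 1:10) {
    sc <- makeSingleEqtlScenario(n = 300, nSnps = 10, h2 = 0.4,
                                 seed = 800 + s)
    m <- buildModel(sc$expr$latent, dosageMatrix(sc$panel), "g1",
                    params = testProfile(), seed = s)
    if (!length(modelWeights(m))) { deltas[s] <- NA; next }
    ph <- phenotypeArchitecture("p", mode = "mediated_by_gene",
                                gene_id = "g1", gene_effect = 0.2)
    sim <- simulateGwasSummary(sc$panel, ph, 5000, seed = 800 + s,
                               genes = sc$config$genes, returnCohort = TRUE)
    gwas <- harmonizeGwas(sim$gwas, sc$panel)
    ref <- ldReference(sim$dosages, modelSnps(m))
    zSummary <- spredixcanZ(m, gwas, ref)$z
    pred <- as.vector(sim$dosages[, modelSnps(m), drop = FALSE] %*%
                        modelWeights(m))
    zInd <- summary(lm(sim$phenotype ~ pred))$coefficients[2, 3]
    deltas[s] <- abs(zSummary - zInd)
  }
  expect_lte(median(deltas, na.rm = TRUE), 0.15)
})

test_that("the association scan is deterministic and BH-calibrated", {
  fx <- makeTwasFixture(seed = 77)
  snps <- snpInfo(fx$sc$panel)$snp_id
  m <- new("ExpressionModel", geneId = "g1",
           weights = setNames(c(0.6, 0.2), c(fx$sc$causal, snps[1])))
  mset <- new("ExpressionModelSet", models = list(g1 = m))
  scan1 <- associationScan(mset, list(p1 = fx$gwas, p1_again = fx$gwas),
                           fx$ref)
  expect_equal(scan1$z[1], scan1$z[2], tolerance = 1e-12)
  expect_true(all(scan1$q >= scan1$p - 1e-15))
})
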