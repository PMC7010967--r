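test_that("LASSO mostly leaves pure-noise genes as intercept-only models", {
  # Minimum-mean-MSE penalty selection admits a few noise variables in a
  # minority of datasets (the known behavior of the lambda-min rule); the
  # testable property is a majority of intercept-only models and very small
  # models otherwise.
  hits <- 0
  sizes <- integer()
  for (s in 1:15) {
    X <- makeDosageMatrix(200, 50, seed = 400 + s)
    set.seed(500 + s)
    y <- rnorm(200)
    sel <- lassoSelect(y, X, repeats = 5, seed = s)
    if (sel$status == "intercept_only") hits <- hits + 1
    sizes <- c(sizes, length(sel$snps))
  }
  expect_gte(hits / 15, 0.5)
  expect_lte(median(sizes), 1)
})

test_that("LASSO recovers a strong causal SNP essentially always", {
  hits <- 0
  for (s in 1:15) {
    sc <- makeSingleEqtlScenario(n = 500, h2 = 0.5, seed = 600 + s)
    sel <- lassoSelect(sc$expr$latent, dosageMatrix(sc$panel),
                       repeats = 5, seed = s)
    R <- suppressWarnings(cor(dosageMatrix(sc$panel)))
    tagged <- any(R[sel$snps, sc$causal]^2 > 0.8)
    if (tagged) hits <- hits + 1
  }
  expect_gte(hits / 15, 0.95)
})

test_that("more CV repeats stabilize the selected penalty", {
  X <- makeDosageMatrix(150, 30, seed = 3)
  set.seed(3)
  y <- 0.4 * scale(X[, 5]) + rnorm(150)
  lam1 <- vapply(1:25, function(s)
    lassoSelect(y, X, repeats = 1, seed = s)$lambda, numeric(1))
  lam20 <- vapply(1:25, function(s)
    lassoSelect(y, X, repeats = 20, seed = s)$lambda, numeric(1))
  expect_gt(var(log(lam1)), var(log(lam20)))
})

test_that("forward filter honors the 95% rule and the perfect-LD rule", {
  set.seed(41)
  n <- 300
  X <- makeDosageMatrix(n, 3, seed = 41)
  X <- cbind(X, snp3_dup = X[, 3])          # a perfect-LD duplicate
  y <- 0.5 * X[, 1] + 0.3 * X[, 2] + rnorm(n)

  ff <- forwardFilter(y, X, seed = 1)
  expect_gte(ff$r2_filtered, 0.95 * ff$r2_full - 1e-12)
  expect_equal(length(intersect(c("snp3", "snp3_dup"), ff$snps)) <= 1, TRUE)

  # single-SNP input: subset R2 equals full R2
  f1 <- forwardFilter(y, X[, 1, drop = FALSE], seed = 1)
  expect_equal(f1$r2_filtered, f1$r2_full)
  expect_equal(f1$snps, "snp1")

  # when the best single SNP already attains 95% of the full R2 it is alone
  yb <- X[, 1] + rnorm(n, 0, 2)
  fb <- forwardFilter(yb, X[, 1:3], seed = 1)
  r2top <- summary(lm(yb ~ X[, 1]))$r.squared
  if (r2top >= 0.95 * fb$r2_full) expect_length(fb$snps, 1)
})

test_that("perfect-LD retention is uniform but seeded", {
  set.seed(5)
  X <- makeDosageMatrix(100, 2, seed = 5)
  X <- cbind(X, dup = X[, 2])
  y <- X[, 2] + rnorm(100)
  picks <- vapply(1:30, function(s)
    intersect(forwardFilter(y, X, seed = s)$snps, c("snp2", "dup")),
    character(1))
  expect_identical(picks, vapply(1:30, function(s)
    intersect(forwardFilter(y, X, seed = s)$snps, c("snp2", "dup")),
    character(1)))
  expect_length(unique(picks), 2)  # both members get picked across seeds
})

test_that("ridge smoothing has the correct closed-form limits", {
  set.seed(6)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  qrX <- qr.Q(qr(X))            # orthonormal columns
  colnames(qrX) <- c("a", "b", "c")
  y <- qrX %*% c(1, -2, 0.5) + rnorm(n, 0, 0.1)
  ols <- lm.fit(cbind(1, qrX), y)$coefficients[-1]

  near0 <- fitRidge(qrX, y, 1e-10)$coef
  expect_equal(unname(near0), unname(ols), tolerance = 1e-6)

  big <- fitRidge(qrX, y, 1e12)$coef
  expect_lt(max(abs(big)), 1e-6)

  # centered orthonormal columns: weight = OLS / (1 + alpha)
  Xc <- sweep(qrX, 2, colMeans(qrX), "-")
  Xc <- qr.Q(qr(Xc)); colnames(Xc) <- c("a", "b", "c")
  y2 <- Xc %*% c(2, 1, -1) + rnorm(n, 0, 0.1)
  ols2 <- lm.fit(cbind(1, Xc), y2)$coefficients[-1]
  for (alpha in c(0.5, 2, 10))
    expect_equal(unname(fitRidge(Xc, y2, alpha)$coef),
                 unname(ols2) / (1 + alpha), tolerance = 1e-8)
})

test_that("BH adjustment matches the hand-computed example", {
  expect_equal(p.adjust(c(0.001, 0.02, 0.9), method = "BH"),
               c(0.003, 0.03, 0.9))
})

test_that("pre-validated fit q-values calibrate nulls and retain true signals", {
  # null genes: few survive q < 0.01
  cfg <- scenarioConfig(
    150, 500, blocks = list(ldBlockSpec(8, rho = 0.5)),
    genes = setNames(lapply(1:60, function(g)
      geneArchitecture(sprintf("g%d", g), 1e6, 1.01e6, "chr1", h2 = 0)),
      sprintf("g%d", 1:60)),
    seed = 31)
  panel <- simulateGenotypes(cfg)
  set.seed(31)
  Y <- matrix(rnorm(60 * nSamples(panel)), 60,
              dimnames = list(names(cfg$genes), NULL))
  # force a 1-SNP model per gene so the fit test is exercised on nulls
  ms <- lapply(names(cfg$genes), function(g)
    new("ExpressionModel", geneId = g,
        weights = c(blk1_snp1 = 0.5), alphaRidge = 1))
  names(ms) <- names(cfg$genes)
  mset <- modelFitQvalues(new("ExpressionModelSet", models = ms), Y, panel,
                          seed = 31)
  kept <- length(models(significantModels(mset, fdr = 0.01)))
  expect_lte(kept / 60, 0.02 + 1e-9)

  # strong genes survive
  hits <- 0
  for (s in 1:10) {
    sc <- makeSingleEqtlScenario(n = 500, h2 = 0.5, seed = 700 + s)
    Y <- matrix(sc$expr$latent, 1, dimnames = list("g1", NULL))
    m <- buildModel(sc$expr$latent, dosageMatrix(sc$panel), "g1",
                    params = testProfile(), seed = s)
    mset <- modelFitQvalues(
      new("ExpressionModelSet", models = list(g1 = m)), Y, sc$panel, seed = s)
    if (length(models(significantModels(mset, 0.01)))) hits <- hits + 1
  }
  expect_gte(hits / 10, 0.95)
})

test_that("strict pre-validation re-runs the builder per fold and stays deterministic", {
  sc <- makeSingleEqtlScenario(n = 200, h2 = 0.5, seed = 61, nSnps = 8)
  Y <- matrix(sc$expr$latent, 1, dimnames = list("g1", NULL))
  m <- buildModel(sc$expr$latent, dosageMatrix(sc$panel), "g1",
                  params = testProfile(), seed = 4)
  fast <- modelParams(lasso_repeats = 3, ridge_repeats = 2)
  s1 <- modelFitQvalues(new("ExpressionModelSet", models = list(g1 = m)),
                        Y, sc$panel, seed = 5, strict = TRUE, params = fast)
  s2 <- modelFitQvalues(new("ExpressionModelSet", models = list(g1 = m)),
                        Y, sc$panel, seed = 5, strict = TRUE, params = fast)
  expect_identical(models(s1)$g1@fitP, models(s2)$g1@fitP)
  expect_lt(models(s1)$g1@fitP, 0.01)  # a real signal survives strict mode
})

test_that("the whole builder is deterministic under seed and satisfies its invariants", {
  sc <- makeSingleEqtlScenario(n = 300, h2 = 0.4, seed = 55, nSnps = 20,
                               rho = 0.9)
  m1 <- buildModel(sc$expr$latent, dosageMatrix(sc$panel), "g1",
                   params = testProfile(), seed = 8)
  m2 <- buildModel(sc$expr$latent, dosageMatrix(sc$panel), "g1",
                   params = testProfile(), seed = 8)
  expect_identical(modelWeights(m1), modelWeights(m2))
  expect_gte(m1@r2Filtered, 0.95 * m1@r2Full - 1e-12)
  if (length(modelWeights(m1)) > 1) {
    R <- suppressWarnings(cor(dosageMatrix(sc$panel)[, modelSnps(m1)]))
    expect_lt(max(abs(R[upper.tri(R)])), 1 - 1e-10)
  }
})
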