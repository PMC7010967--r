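# Shared fixture builders: everything generated in code at test time.

# One-block panel with a planted single-eQTL gene.
makeSingleEqtlScenario <- function(n = 200, nSnps = 12, h2 = 0.5, rho = 0.6,
                                   seed = 1L, causalIdx = 5L) {
  cfg <- scenarioConfig(
    n_samples = n, n_gwas_samples = 1000,
    blocks = list(ldBlockSpec(nSnps, rho = rho, chrom = "chr1")),
    genes = list(g1 = geneArchitecture(
      "g1", tss = 1e6, tes = 1.01e6, chrom = "chr1",
      causal_snps = setNames(1, sprintf("blk1_snp%d", causalIdx)), h2 = h2)),
    seed = seed)
  panel <- simulateGenotypes(cfg)
  expr <- simulateExpression(panel, cfg$genes$g1, seed = seed)
  list(config = cfg, panel = panel, expr = expr,
       causal = sprintf("blk1_snp%d", causalIdx))
}

# Dosage-like matrix with controllable correlation, for pure-regression tests.
makeDosageMatrix <- function(n, p, seed = 1L) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  colnames(X) <- sprintf("snp%d", seq_len(p))
  X
}

# Random count matrix for normalization tests.
makeCountMatrix <- function(nGenes = 20, nSamples = 6, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnbinom(nGenes * nSamples, mu = 200, size = 3),
              nGenes, nSamples,
              dimnames = list(sprintf("gene%d", seq_len(nGenes)),
                              sprintf("s%d", seq_len(nSamples))))
  m
}

# Independent brute-force CLPP oracle: full subset enumeration with MVN
# density computed from scratch via solve() and determinant.
bruteForceClpp <- function(z1, z2, ld, max_causal = 2, prior = 0.01,
                           ncp = 5.2) {
  m <- length(z1)
  dmvn <- function(x, mu) {
    S <- ld
    as.numeric(exp(-0.5 * t(x - mu) %*% solve(S) %*% (x - mu)) /
                 sqrt((2 * pi)^m * det(S)))
  }
  postFor <- function(z) {
    like <- c(); inConfig <- list()
    id <- 0
    for (bits in 0:(2^m - 1)) {
      cf <- which(bitwAnd(bits, 2^(seq_len(m) - 1)) > 0)
      if (length(cf) > max_causal) next
      id <- id + 1
      lam <- numeric(m); lam[cf] <- ncp * sign(z[cf])
      like[id] <- prior^length(cf) * (1 - prior)^(m - length(cf)) *
        dmvn(z, as.vector(ld %*% lam))
      inConfig[[id]] <- cf
    }
    w <- like / sum(like)
    post <- numeric(m)
    for (i in seq_along(w)) post[inConfig[[i]]] <- post[inConfig[[i]]] + w[i]
    post
  }
  postFor(z1) * postFor(z2)
}
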