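#' @import methods
#' @importFrom stats coef cor cov lm lm.fit median pnorm pt qnorm quantile
#'   rnbinom rnorm runif sd var setNames p.adjust prcomp
#' @importFrom utils combn read.delim write.table head
NULL

## Run code under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards. All exported stochastic operations funnel through
## this so that seeded runs are bit-reproducible and never perturb the
## session RNG.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Derive a child seed from a parent seed and a stream label, keeping the
## result inside the 32-bit integer range.
childSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}

## Column-standardize a matrix; zero-variance columns become all-zero.
standardizeColumns <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- Inf
  sweep(sweep(X, 2, mu, "-"), 2, s, "/")
}

## Multivariate normal log-density with covariance `sigma` via Cholesky.
mvnLogDensity <- function(x, mean, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(nearestPsd(sigma))
  }
  d <- length(x)
  u <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(u^2)
}

## Clip negative eigenvalues to restore positive semidefiniteness, then add a
## small ridge so Cholesky succeeds.
nearestPsd <- function(sigma, eps = 1e-8) {
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  v <- pmax(e$values, eps)
  e$vectors %*% (v * t(e$vectors))
}

## R-squared of an OLS fit of y on the columns of X (with intercept).
olsR2 <- function(y, X) {
  X <- as.matrix(X)
  fit <- lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
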