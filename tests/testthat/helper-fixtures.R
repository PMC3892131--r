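## Shared fixture builders. Everything is generated in code; no data files.

## small uniform descending grid, n points ending at `to`
testGrid <- function(n = 51, from = 1800, by = 4) {
  seq(from, by = -by, length.out = n)
}

## SpectraSet of smooth random spectra (sum of a few Gaussians), seeded
testSpectra <- function(nSamples = 5, grid = testGrid(), seed = 1,
                        reference = NULL) {
  withr::with_seed(seed, {
    mat <- t(vapply(seq_len(nSamples), function(i) {
      ctr <- runif(4, min(grid), max(grid))
      ht <- runif(4, 0.1, 0.5)
      wd <- runif(4, 15, 60)
      rowSums(vapply(1:4, function(k)
        ht[k] * exp(-(grid - ctr[k])^2 / (2 * wd[k]^2)),
        numeric(length(grid))))
    }, numeric(length(grid))))
    SpectraSet(grid, mat, reference = reference)
  })
}

## random regression instance with exact low-rank-free X (full column rank)
testInstance <- function(n, p, m = 1, seed = 1, noise = 0.1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    B <- matrix(rnorm(p * m), p, m)
    Y <- X %*% B + matrix(rnorm(n * m, 0, noise), n, m)
    colnames(Y) <- paste0("y", seq_len(m))
    list(X = X, Y = Y)
  })
}

## closed-form least-squares predictions on centered data (oracle)
lsOracle <- function(X, Y, Xnew = X) {
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  B <- solve(crossprod(Xc), crossprod(Xc, Yc))
  sweep(sweep(Xnew, 2, xm) %*% B, 2, ym, "+")
}
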