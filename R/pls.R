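## PLS regression core: NIPALS and wide-kernel algorithms.
##
## Both fit the same bilinear model on mean-centered data
##   X = T P' + E,  Y = T Q' + F,  B = W (P'W)^-1 Q'
## and must agree in their predictions; the wide-kernel route works on the
## n x n association matrices XX' and YY' and is preferred when p >> n
## (hundreds of wavenumbers, tens of samples).

.PLS_TOL <- 1e-12
.PLS_MAXIT <- 500L

.plsNipals <- function(Xc, Yc, nLv) {
  n <- nrow(Xc); p <- ncol(Xc); m <- ncol(Yc)
  W <- matrix(0, p, nLv); P <- matrix(0, p, nLv)
  Q <- matrix(0, m, nLv); TT <- matrix(0, n, nLv)
  scale0 <- NA_real_
  for (k in seq_len(nLv)) {
    u <- Yc[, which.max(apply(Yc, 2, stats::var))]
    if (all(abs(u) < 1e-14)) u <- Yc[, 1]
    w0 <- sqrt(sum(crossprod(Xc, u)^2))
    if (k == 1) scale0 <- w0
    if (w0 < 1e-12 * scale0)
      stop("n_lv exceeds the effective rank of the data")
    tOld <- rep(Inf, n)
    for (it in seq_len(.PLS_MAXIT)) {
      w <- crossprod(Xc, u)
      w <- w / sqrt(sum(w^2))
      tt <- Xc %*% w
      q <- crossprod(Yc, tt) / sum(tt^2)
      u <- Yc %*% q / sum(q^2)
      if (sqrt(sum((tt - tOld)^2)) <= .PLS_TOL * sqrt(sum(tt^2))) break
      if (it == .PLS_MAXIT) stop("NIPALS did not converge")
      tOld <- tt
      if (m == 1) break  # single response: one pass is exact
    }
    pp <- crossprod(Xc, tt) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, q)
    W[, k] <- w; P[, k] <- pp; Q[, k] <- q; TT[, k] <- tt
  }
  list(W = W, P = P, Q = Q, scores = TT)
}

.plsWideKernel <- function(Xc, Yc, nLv) {
  n <- nrow(Xc); m <- ncol(Yc)
  XXt <- tcrossprod(Xc)
  Ydef <- Yc                      # deflated response block
  TT <- matrix(0, n, nLv); U <- matrix(0, n, nLv)
  scale0 <- NA_real_
  for (k in seq_len(nLv)) {
    ## the dominant eigenvector of XX'YY' is XX'Y v1, where v1 is the top
    ## eigenvector of the small symmetric m x m matrix Y'XX'Y -- exact, no
    ## power iteration
    XY <- XXt %*% Ydef
    A <- crossprod(Ydef, XY)
    v1 <- eigen(A, symmetric = TRUE)$vectors[, 1]
    tt <- XY %*% v1
    nt <- sqrt(sum(tt^2))
    if (k == 1) scale0 <- nt
    if (nt < 1e-12 * scale0)
      stop("n_lv exceeds the effective rank of the data")
    tt <- tt / nt
    u <- Ydef %*% crossprod(Ydef, tt)
    TT[, k] <- tt; U[, k] <- u
    G <- diag(n) - tcrossprod(tt)
    XXt <- G %*% XXt %*% G
    Ydef <- Ydef - tt %*% crossprod(tt, Ydef)
  }
  W <- crossprod(Xc, U)
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  TtTinv <- solve(crossprod(TT))
  P <- crossprod(Xc, TT) %*% TtTinv
  Q <- crossprod(Yc, TT) %*% TtTinv
  list(W = W, P = P, Q = Q, scores = TT)
}

## coefficients using the first k components
.plsCoef <- function(core, k) {
  W <- core$W[, seq_len(k), drop = FALSE]
  P <- core$P[, seq_len(k), drop = FALSE]
  Q <- core$Q[, seq_len(k), drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Fit a PLS regression on preprocessed data
#'
#' Fits a partial least squares regression of `Y` on `X` by the NIPALS
#' algorithm (deflation-based, iterating scores to a 1e-12 tolerance) or the
#' wide-kernel algorithm (power iteration on the n x n association matrices
#' XX' and YY', suited to wide spectral matrices). Data are mean centered
#' internally; the two algorithms produce the same predictions.
#'
#' @param X numeric matrix, samples x variables (preprocessed spectra).
#' @param Y numeric matrix or vector of reference values, row-aligned with
#'   `X`.
#' @param nLv number of latent variables, `1 <= nLv <= min(n-1, p)`.
#' @param algorithm `"nipals"` or `"widekernel"`.
#' @return a `plsFit` list: weights `W`, loadings `P` and `Q`, `scores`,
#'   coefficient matrix `B` (on centered data), centering vectors `xMeans`,
#'   `yMeans`, and bookkeeping (`nLv`, `algorithm`, target names).
#' @seealso [plsPredict()], [crossValidate()], [jackknifeCiFilter()]
#' @export
fitPls <- function(X, Y, nLv, algorithm = c("nipals", "widekernel")) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  if (is.vector(Y) || is.data.frame(Y)) Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must be row-aligned")
  if (anyNA(X) || anyNA(Y)) stop("NaN/NA in inputs")
  n <- nrow(X); p <- ncol(X)
  if (nLv < 1 || nLv > min(n - 1, p)) stop("n_lv out of bounds")
  xMeans <- colMeans(X); yMeans <- colMeans(Y)
  Xc <- sweep(X, 2, xMeans); Yc <- sweep(Y, 2, yMeans)
  core <- if (algorithm == "nipals") .plsNipals(Xc, Yc, nLv)
          else .plsWideKernel(Xc, Yc, nLv)
  structure(list(W = core$W, P = core$P, Q = core$Q, scores = core$scores,
                 B = .plsCoef(core, nLv), xMeans = xMeans, yMeans = yMeans,
                 nLv = as.integer(nLv), algorithm = algorithm,
                 targets = colnames(Y)),
            class = "plsFit")
}

#' Predict from a plsFit
#'
#' @param fit a `plsFit` from [fitPls()].
#' @param X new data matrix on the same variables.
#' @param nLv optionally predict with fewer components than fitted.
#' @return matrix of predictions, samples x targets.
#' @export
plsPredict <- function(fit, X, nLv = fit$nLv) {
  X <- as.matrix(X)
  if (ncol(X) != length(fit$xMeans)) stop("variable count mismatch")
  B <- if (nLv == fit$nLv) fit$B else .plsCoef(fit, nLv)
  out <- sweep(sweep(X, 2, fit$xMeans) %*% B, 2, fit$yMeans, "+")
  dimnames(out) <- list(rownames(X), fit$targets)
  out
}

#' Leave-one-out cross-validation of a PLS calibration
#'
#' "Full" cross-validation: each sample is left out in turn, the model is
#' refitted on the remainder, and the held-out sample is predicted with
#' 1..`maxLv` components. RMSECV per component count is computed from the
#' pooled out-of-fold predictions, which are retained for offset/slope bias
#' calibration.
#'
#' @param X,Y as in [fitPls()]; at least 3 samples.
#' @param maxLv maximum number of latent variables to assess (the screening
#'   default is 15).
#' @param scheme only `"loo"` is implemented.
#' @param algorithm passed to [fitPls()].
#' @return list with `rmsecv` (matrix maxLv x targets), `oof` (array
#'   n x targets x maxLv of out-of-fold predictions) and `maxLv`.
#' @export
crossValidate <- function(X, Y, maxLv, scheme = "loo",
                          algorithm = "nipals") {
  scheme <- match.arg(scheme, "loo")
  X <- as.matrix(X)
  if (is.vector(Y) || is.data.frame(Y)) Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3) stop("too few samples for cross-validation")
  ## cap at the effective rank of the centered data: components beyond it
  ## are numerically arbitrary and cannot be fitted in every fold
  rk <- qr(sweep(X, 2, colMeans(X)))$rank
  maxLv <- min(maxLv, n - 2, ncol(X), rk)
  oof <- array(NA_real_, c(n, ncol(Y), maxLv))
  for (i in seq_len(n)) {
    fit <- fitPls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], maxLv,
                  algorithm)
    for (k in seq_len(maxLv))
      oof[i, , k] <- plsPredict(fit, X[i, , drop = FALSE], nLv = k)
  }
  rmsecv <- matrix(0, maxLv, ncol(Y),
                   dimnames = list(NULL, colnames(Y)))
  for (k in seq_len(maxLv))
    rmsecv[k, ] <- sqrt(colMeans((oof[, , k, drop = FALSE][, , 1] - Y)^2))
  list(rmsecv = rmsecv, oof = oof, maxLv = maxLv)
}

#' Choose the number of latent variables from an RMSECV profile
#'
#' Returns the smallest component count whose RMSECV is within `tol`
#' (default 1%) of the minimum — the parsimony rule; exact ties break toward
#' fewer components.
#'
#' @param rmsecv numeric vector of RMSECV values for 1..K components.
#' @param tol relative parsimony tolerance.
#' @return the selected component count (integer).
#' @export
selectNLv <- function(rmsecv, tol = 0.01) {
  stopifnot(length(rmsecv) >= 1)
  lo <- min(rmsecv)
  as.integer(which(rmsecv <= lo * (1 + tol))[1])
}

#' Jackknife confidence-interval variable filter
#'
#' Martens' jackknife over the leave-one-out refits: the variance of each
#' regression coefficient is `((n-1)/n) * sum((b_i - mean(b_i))^2)` across the
#' LOO coefficient vectors, giving a normal-approximation confidence interval
#' `b +/- z_(1-alpha/2) * se` around the full-data coefficient. Variables
#' whose interval spans 0 (insignificant at level `1 - alpha`) are dropped.
#' With several targets a variable is kept if significant for any of them.
#'
#' @param X,Y as in [fitPls()].
#' @param nLv components used for every refit.
#' @param alpha two-sided significance level; 0.10 gives the 90% CI filter.
#' @param algorithm passed to [fitPls()].
#' @return logical mask over the columns of `X` (`TRUE` = keep).
#' @export
jackknifeCiFilter <- function(X, Y, nLv, alpha = 0.10,
                              algorithm = "nipals") {
  X <- as.matrix(X)
  if (is.vector(Y) || is.data.frame(Y)) Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  bFull <- fitPls(X, Y, nLv, algorithm)$B
  bb <- array(0, c(p, m, n))
  for (i in seq_len(n))
    bb[, , i] <- fitPls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                        nLv, algorithm)$B
  bBar <- apply(bb, c(1, 2), mean)
  v <- apply(sweep(bb, c(1, 2), bBar)^2, c(1, 2), sum) * (n - 1) / n
  z <- stats::qnorm(1 - alpha / 2)
  keepMat <- abs(bFull) > z * sqrt(v)  # CI excludes zero
  keep <- apply(keepMat, 1, any)
  if (!any(keep)) stop("empty model: all variables removed by CI filter")
  keep
}

#' Offset/slope bias correction from cross-validation predictions
#'
#' Fits the ordinary least-squares line `pred = a + b * ref` on out-of-fold
#' prediction/reference pairs. The offset `a` (for juice models, effectively
#' the water background) is subtracted from raw predictions; a slope
#' adjustment factor `1/b` is applied only when the slope deviates from one by
#' more than `deadband` (default 1%). Corrected prediction =
#' `(raw - offset) * slopeFactor`.
#'
#' @param pred out-of-fold predictions (vector or matrix, one column per
#'   target).
#' @param ref reference values, same shape.
#' @param deadband relative slope dead-band within which no slope adjustment
#'   is made.
#' @return data.frame with one row per target: `offset`, `slopeFactor`.
#' @export
calibrateBias <- function(pred, ref, deadband = 0.01) {
  pred <- as.matrix(pred); ref <- as.matrix(ref)
  if (nrow(pred) < 3) stop("need at least 3 prediction/reference pairs")
  out <- data.frame(target = colnames(ref) %||% paste0("y", seq_len(ncol(ref))),
                    offset = 0, slopeFactor = 1)
  for (j in seq_len(ncol(ref))) {
    if (stats::sd(ref[, j]) == 0) stop("degenerate: constant reference")
    cf <- stats::coef(stats::lm(pred[, j] ~ ref[, j]))
    out$offset[j] <- cf[1]
    b <- cf[2]
    out$slopeFactor[j] <- if (abs(b - 1) > deadband) 1 / b else 1
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibration / validation error metrics
#'
#' RMSE is the root mean squared prediction error; the coefficient of
#' determination is `1 - SSE/SStot` about the reference mean, reported as R2
#' for calibration samples and Q2 for validation samples. Bias is the mean
#' signed error and slope the OLS slope of predicted on reference.
#'
#' @param pred,ref numeric vectors (or single-column matrices) of equal
#'   length >= 2.
#' @param context `"calibration"` or `"validation"`; labels the output.
#' @return list with `RMSE`, `R2` (or `Q2`), `bias`, `slope`, `n`, `context`.
#' @export
regressionMetrics <- function(pred, ref,
                              context = c("calibration", "validation")) {
  context <- match.arg(context)
  pred <- as.numeric(pred); ref <- as.numeric(ref)
  if (length(pred) != length(ref)) stop("length mismatch")
  if (length(pred) < 2) stop("need at least 2 pairs")
  sse <- sum((pred - ref)^2)
  sstot <- sum((ref - mean(ref))^2)
  r2 <- 1 - sse / sstot
  out <- list(RMSE = sqrt(mean((pred - ref)^2)),
              bias = mean(pred - ref),
              slope = unname(stats::coef(stats::lm(pred ~ ref))[2]),
              n = length(pred), context = context)
  if (context == "calibration") out$R2 <- r2 else out$Q2 <- r2
  out
}

#' Residual/leverage outlier report
#'
#' Flags calibration samples with large studentized y-residuals or high
#' leverage. Leverage uses the score-space hat matrix with the centering
#' (intercept) term, `h_i = 1/n + t_i' (T'T)^-1 t_i`, so leverages sum to
#' `nLv + 1`. This is a report only — mirroring manual examination before any
#' removal — samples are never dropped automatically.
#'
#' @param fit a `plsFit` from [fitPls()].
#' @param X,Y the calibration data the fit was made on.
#' @param residualZ flag when |studentized residual| exceeds this (default 3).
#' @param leverageMult flag when leverage exceeds
#'   `leverageMult * (nLv + 1) / n` (default 3).
#' @return data.frame per sample: `residual`, `studentized`, `leverage`,
#'   `flagged`, `reason`.
#' @export
detectOutliers <- function(fit, X, Y, residualZ = 3.0, leverageMult = 3.0) {
  X <- as.matrix(X)
  if (is.vector(Y) || is.data.frame(Y)) Y <- as.matrix(Y)
  n <- nrow(X)
  TT <- fit$scores
  h <- 1 / n + rowSums((TT %*% solve(crossprod(TT))) * TT)
  e <- Y - plsPredict(fit, X)
  ## worst studentized residual across targets
  stud <- apply(sweep(e, 2, apply(e, 2, stats::sd), "/"), 1,
                function(r) max(abs(r)))
  stud <- stud / sqrt(pmax(1 - h, .Machine$double.eps))
  hCut <- leverageMult * (fit$nLv + 1) / n
  flagRes <- stud > residualZ
  flagLev <- h > hCut
  reason <- rep("", n)
  reason[flagRes] <- "residual"
  reason[flagLev] <- paste0(reason[flagLev],
                            ifelse(nchar(reason[flagLev]), "+", ""), "leverage")
  data.frame(sample = seq_len(n),
             residual = apply(abs(e), 1, max),
             studentized = stud, leverage = h,
             flagged = flagRes | flagLev, reason = reason)
}
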