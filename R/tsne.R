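## Exact t-SNE (no Barnes-Hut), sufficient for the few hundred activation
## vectors visualised here.  Conditional-perplexity calibration by binary
## search on the Gaussian precision, symmetrised P, early exaggeration and
## momentum gradient descent; deterministic given `seed`.

tsnePerplexity <- function(D2, perplexity, tol = 1e-5, maxIter = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    Di <- D2[i, -i]
    for (iter in seq_len(maxIter)) {
      Pi <- exp(-Di * beta)
      sumPi <- sum(Pi)
      if (sumPi == 0) sumPi <- .Machine$double.eps
      H <- log(sumPi) + beta * sum(Di * Pi) / sumPi
      if (abs(H - logU) < tol) break
      if (H > logU) {
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumPi
  }
  P
}

#' 2-D t-SNE embedding of activation vectors
#'
#' Exact (dense) t-SNE used to visualise per-layer activations; suitable
#' for up to a few thousand samples.
#'
#' @param x numeric matrix, one row per sample.
#' @param perplexity Gaussian perplexity (reduced automatically when the
#'   sample count is small).
#' @param iters gradient-descent iterations.
#' @param seed integer seed for the random initialization.
#' @return n x 2 coordinate matrix (rownames preserved).
#' @export
tsneEmbed <- function(x, perplexity = 30, iters = 500L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 samples for t-SNE", call. = FALSE)
  perplexity <- min(perplexity, (n - 1) / 3)
  set.seed(seed)
  sq <- rowSums(x^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
  P <- tsnePerplexity(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  eta <- 200
  exag <- 12
  for (it in seq_len(iters)) {
    Pe <- if (it <= 100L) P * exag else P
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + outer(sqy, sqy, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250L) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8),
                  0.01)
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  rownames(Y) <- rownames(x)
  colnames(Y) <- c("x", "y")
  Y
}
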