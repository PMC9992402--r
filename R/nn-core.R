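## Internal neural-network engine: vectorised forward and backward passes
## for the two-branch architecture (embedding -> {Bi-LSTM + attention} ||
## {multi-scale 1-D CNN} -> dense 64/9/1 -> sigmoid), plus Adam.
## All matmuls go through BLAS; minibatch rows are samples.
##
## Layout convention: the embedded batch is kept as a (n*L) x d matrix
## `Emat` whose rows are ordered time-major with the sample index fastest,
## i.e. row (t-1)*n + b holds sample b at position t.

sigm <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

addBias <- function(M, b) M + rep(b, each = nrow(M))

featWidth <- function(cfg) {
  (if (cfg@useBiLSTM) 2L * cfg@lstmUnits else 0L) +
    length(cfg@activeScales) * cfg@cnnFilters
}

## fresh parameter list; consumes the RNG stream (caller seeds)
initParams <- function(cfg) {
  d <- cfg@embedDim; H <- cfg@lstmUnits; F <- cfg@cnnFilters
  p <- list(Wemb = matrix(stats::runif(cfg@vocabSize * d, -0.05, 0.05),
                          cfg@vocabSize, d))
  if (cfg@useBiLSTM) {
    mk <- function() {
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1          # forget-gate bias init
      list(Wx = glorot(d, 4L * H), Wh = glorot(H, 4L * H), b = b)
    }
    p$lstm_f <- mk(); p$lstm_b <- mk()
    if (cfg@useAttention)
      p$att <- list(w = glorot(2L * H, 1L), b = 0)
  }
  if (length(cfg@activeScales)) {
    p$conv <- lapply(stats::setNames(as.list(cfg@activeScales),
                                     cfg@activeScales), function(k)
      list(W = glorot(k * d, F), b = numeric(F)))
  }
  inDim <- featWidth(cfg)
  p$dense <- list(W1 = glorot(inDim, cfg@denseSizes[1]),
                  b1 = numeric(cfg@denseSizes[1]),
                  W2 = glorot(cfg@denseSizes[1], cfg@denseSizes[2]),
                  b2 = numeric(cfg@denseSizes[2]),
                  W3 = glorot(cfg@denseSizes[2], cfg@denseSizes[3]),
                  b3 = numeric(cfg@denseSizes[3]))
  p
}

countLeaves <- function(p)
  if (is.list(p)) sum(vapply(p, countLeaves, 0)) else length(p)

## 'same'-padding im2col row-source indices for kernel width k:
## for tap j (1..k) a length-(n*L) vector of source rows into Emat,
## with n*L+1 denoting the appended zero row.
convSrcIndex <- function(n, L, k) {
  padL <- (k - 1L) %/% 2L
  tvec <- rep(seq_len(L), each = n)
  bvec <- rep(seq_len(n), L)
  lapply(seq_len(k), function(j) {
    s <- tvec + j - 1L - padL
    ok <- s >= 1L & s <= L
    ifelse(ok, (s - 1L) * n + bvec, n * L + 1L)
  })
}

## Full forward pass.  Returns probabilities plus a cache sufficient for
## backprop and for layer taps.  Dropout is applied only when train = TRUE
## and cfg@dropoutRate > 0 (consumes RNG).
modelForward <- function(params, cfg, X, train = FALSE) {
  n <- nrow(X); L <- cfg@L; d <- cfg@embedDim; H <- cfg@lstmUnits
  stopifnot(ncol(X) == L)
  rowsT <- lapply(seq_len(L), function(t) ((t - 1L) * n + 1L):(t * n))
  idx <- as.vector(X) + 1L
  Emat <- params$Wemb[idx, , drop = FALSE]
  if (!all(is.finite(Emat))) stop("non-finite embedding activations")
  cache <- list(n = n, idx = idx, rowsT = rowsT, Emat = Emat)

  ## ---- recurrent branch -------------------------------------------------
  bilstmOut <- NULL
  if (cfg@useBiLSTM) {
    runDir <- function(W, ts) {
      Hs <- vector("list", L); Cs <- vector("list", L)
      I <- vector("list", L); Fg <- vector("list", L)
      G <- vector("list", L); O <- vector("list", L)
      TC <- vector("list", L); Cprev <- vector("list", L)
      h <- matrix(0, n, H); cc <- matrix(0, n, H)
      for (t in ts) {
        Z <- addBias(Emat[rowsT[[t]], , drop = FALSE] %*% W$Wx + h %*% W$Wh,
                     W$b)
        i <- sigm(Z[, 1:H, drop = FALSE])
        f <- sigm(Z[, (H + 1L):(2L * H), drop = FALSE])
        g <- tanh(Z[, (2L * H + 1L):(3L * H), drop = FALSE])
        o <- sigm(Z[, (3L * H + 1L):(4L * H), drop = FALSE])
        Cprev[[t]] <- cc
        cc <- f * cc + i * g
        tc <- tanh(cc)
        h <- o * tc
        Hs[[t]] <- h; Cs[[t]] <- cc
        I[[t]] <- i; Fg[[t]] <- f; G[[t]] <- g; O[[t]] <- o; TC[[t]] <- tc
      }
      list(H = Hs, I = I, Fg = Fg, G = G, O = O, TC = TC, Cprev = Cprev)
    }
    fwd <- runDir(params$lstm_f, seq_len(L))
    bwd <- runDir(params$lstm_b, rev(seq_len(L)))
    Hcat <- lapply(seq_len(L), function(t) cbind(fwd$H[[t]], bwd$H[[t]]))
    cache$fwd <- fwd; cache$bwd <- bwd; cache$Hcat <- Hcat

    if (cfg@useAttention) {
      S <- matrix(0, n, L)
      for (t in seq_len(L))
        S[, t] <- tanh(Hcat[[t]] %*% params$att$w + params$att$b)
      A <- exp(S - apply(S, 1L, max))
      A <- A / rowSums(A)
      ctx <- matrix(0, n, 2L * H)
      for (t in seq_len(L)) ctx <- ctx + A[, t] * Hcat[[t]]
      cache$attS <- S; cache$attA <- A
      bilstmOut <- ctx
    } else {
      bilstmOut <- cbind(fwd$H[[L]], bwd$H[[1L]])   # final fwd + final bwd state
    }
    cache$bilstmOut <- bilstmOut
  }

  ## ---- convolutional branch ---------------------------------------------
  pools <- list()
  if (length(cfg@activeScales)) {
    Epad <- rbind(Emat, 0)
    F <- cfg@cnnFilters
    cache$conv <- list()
    for (k in cfg@activeScales) {
      ck <- as.character(k)
      src <- convSrcIndex(n, L, k)
      M <- matrix(0, n * L, k * d)
      for (j in seq_len(k))
        M[, ((j - 1L) * d + 1L):(j * d)] <- Epad[src[[j]], , drop = FALSE]
      Y <- addBias(M %*% params$conv[[ck]]$W, params$conv[[ck]]$b)
      Arel <- Y * (Y > 0)
      pooled <- matrix(0, n, F); amax <- matrix(0L, n, F)
      for (f in seq_len(F)) {
        Yf <- matrix(Arel[, f], n, L)
        a <- max.col(Yf, ties.method = "first")
        amax[, f] <- a
        pooled[, f] <- Yf[cbind(seq_len(n), a)]
      }
      cache$conv[[ck]] <- list(src = src, M = M, relu = Arel, amax = amax,
                               pooled = pooled)
      pools[[ck]] <- pooled
    }
  }

  feat <- do.call(cbind, c(if (!is.null(bilstmOut)) list(bilstmOut), pools))
  cache$feat <- feat

  dropMask <- NULL
  if (train && cfg@dropoutRate > 0) {
    keep <- 1 - cfg@dropoutRate
    dropMask <- matrix((stats::runif(length(feat)) < keep) / keep,
                       nrow(feat), ncol(feat))
  }
  featD <- if (is.null(dropMask)) feat else feat * dropMask
  cache$dropMask <- dropMask; cache$featD <- featD

  dn <- params$dense
  A1 <- addBias(featD %*% dn$W1, dn$b1); A1 <- A1 * (A1 > 0)
  A2 <- addBias(A1 %*% dn$W2, dn$b2);    A2 <- A2 * (A2 > 0)
  logit <- addBias(A2 %*% dn$W3, dn$b3)
  probs <- as.vector(sigm(logit))
  if (!all(is.finite(probs))) stop("non-finite network output")
  cache$A1 <- A1; cache$A2 <- A2; cache$probs <- probs
  cache
}

bceLoss <- function(probs, y, eps = 1e-12) {
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Backward pass for mean binary cross-entropy; returns gradients
## mirroring the structure of `params`.
modelBackward <- function(params, cfg, cache, y) {
  n <- cache$n; L <- cfg@L; d <- cfg@embedDim; H <- cfg@lstmUnits
  rowsT <- cache$rowsT
  dn <- params$dense

  dlogit <- matrix((cache$probs - y) / n, ncol = 1L)
  g <- list()
  g$dense <- list(
    W3 = crossprod(cache$A2, dlogit), b3 = sum(dlogit))
  dA2 <- (dlogit %*% t(dn$W3)) * (cache$A2 > 0)
  g$dense$W2 <- crossprod(cache$A1, dA2); g$dense$b2 <- colSums(dA2)
  dA1 <- (dA2 %*% t(dn$W2)) * (cache$A1 > 0)
  g$dense$W1 <- crossprod(cache$featD, dA1); g$dense$b1 <- colSums(dA1)
  dfeat <- dA1 %*% t(dn$W1)
  if (!is.null(cache$dropMask)) dfeat <- dfeat * cache$dropMask

  dEmat <- matrix(0, n * L, d)
  off <- 0L

  ## ---- recurrent branch -------------------------------------------------
  if (cfg@useBiLSTM) {
    dctx <- dfeat[, 1:(2L * H), drop = FALSE]
    off <- 2L * H
    dHf <- vector("list", L); dHb <- vector("list", L)
    zero <- matrix(0, n, H)
    for (t in seq_len(L)) { dHf[[t]] <- zero; dHb[[t]] <- zero }

    if (cfg@useAttention) {
      A <- cache$attA; S <- cache$attS; Hcat <- cache$Hcat
      dAlpha <- matrix(0, n, L)
      for (t in seq_len(L)) dAlpha[, t] <- rowSums(dctx * Hcat[[t]])
      dS <- A * (dAlpha - rowSums(A * dAlpha))
      dpre <- dS * (1 - S^2)
      wa <- as.vector(params$att$w)
      dwa <- matrix(0, 2L * H, 1L)
      for (t in seq_len(L)) {
        dwa <- dwa + crossprod(Hcat[[t]], dpre[, t, drop = FALSE])
        dHcat_t <- A[, t] * dctx + dpre[, t, drop = FALSE] %*% t(params$att$w)
        dHf[[t]] <- dHf[[t]] + dHcat_t[, 1:H, drop = FALSE]
        dHb[[t]] <- dHb[[t]] + dHcat_t[, (H + 1L):(2L * H), drop = FALSE]
      }
      g$att <- list(w = dwa, b = sum(dpre))
    } else {
      dHf[[L]] <- dHf[[L]] + dctx[, 1:H, drop = FALSE]
      dHb[[1L]] <- dHb[[1L]] + dctx[, (H + 1L):(2L * H), drop = FALSE]
    }

    backDir <- function(W, st, dHext, ts) {
      dWx <- array(0, dim(W$Wx)); dWh <- array(0, dim(W$Wh))
      db <- numeric(length(W$b))
      dhnext <- matrix(0, n, H); dcnext <- matrix(0, n, H)
      for (s in rev(seq_along(ts))) {
        t <- ts[s]
        dh <- dHext[[t]] + dhnext
        tc <- st$TC[[t]]
        do_ <- dh * tc
        dc <- dcnext + dh * st$O[[t]] * (1 - tc^2)
        di <- dc * st$G[[t]]
        df <- dc * st$Cprev[[t]]
        dg <- dc * st$I[[t]]
        dcnext <- dc * st$Fg[[t]]
        dZ <- cbind(di * st$I[[t]] * (1 - st$I[[t]]),
                    df * st$Fg[[t]] * (1 - st$Fg[[t]]),
                    dg * (1 - st$G[[t]]^2),
                    do_ * st$O[[t]] * (1 - st$O[[t]]))
        Et <- cache$Emat[rowsT[[t]], , drop = FALSE]
        hprev <- if (s > 1L) st$H[[ts[s - 1L]]] else matrix(0, n, H)
        dWx <- dWx + crossprod(Et, dZ)
        dWh <- dWh + crossprod(hprev, dZ)
        db <- db + colSums(dZ)
        dEmat[rowsT[[t]], ] <<- dEmat[rowsT[[t]], , drop = FALSE] +
          dZ %*% t(W$Wx)
        dhnext <- dZ %*% t(W$Wh)
      }
      list(Wx = dWx, Wh = dWh, b = db)
    }
    g$lstm_f <- backDir(params$lstm_f, cache$fwd, dHf, seq_len(L))
    g$lstm_b <- backDir(params$lstm_b, cache$bwd, dHb, rev(seq_len(L)))
  }

  ## ---- convolutional branch ---------------------------------------------
  if (length(cfg@activeScales)) {
    F <- cfg@cnnFilters
    g$conv <- list()
    for (k in cfg@activeScales) {
      ck <- as.character(k)
      cv <- cache$conv[[ck]]
      dpool <- dfeat[, (off + 1L):(off + F), drop = FALSE]
      off <- off + F
      dA <- matrix(0, n * L, F)
      for (f in seq_len(F)) {
        rows <- (cv$amax[, f] - 1L) * n + seq_len(n)
        dA[cbind(rows, f)] <- dpool[, f]
      }
      dY <- dA * (cv$relu > 0)
      g$conv[[ck]] <- list(W = crossprod(cv$M, dY), b = colSums(dY))
      dM <- dY %*% t(params$conv[[ck]]$W)
      for (j in seq_len(k)) {
        src <- cv$src[[j]]
        sel <- src <= n * L
        tgt <- src[sel]
        dEmat[tgt, ] <- dEmat[tgt, , drop = FALSE] +
          dM[sel, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
      }
    }
  }

  ## ---- embedding ---------------------------------------------------------
  agg <- rowsum(dEmat, group = cache$idx)
  dWemb <- matrix(0, cfg@vocabSize, d)
  dWemb[as.integer(rownames(agg)), ] <- agg
  ## order gradient list like params
  out <- list(Wemb = dWemb)
  for (nm in names(params)[-1]) out[[nm]] <- g[[nm]]
  out
}

## ---- Adam ----------------------------------------------------------------

zerosLike <- function(p) {
  if (is.list(p)) lapply(p, zerosLike)
  else if (is.null(dim(p))) numeric(length(p))
  else array(0, dim = dim(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamStep <- function(params, grads, m, v, step, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      r <- Map(walk, p, g[names(p)], m, v)   # grads may be ordered differently
      list(p = lapply(r, `[[`, "p"), m = lapply(r, `[[`, "m"),
           v = lapply(r, `[[`, "v"))
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      mh <- m2 / (1 - beta1^step)
      vh <- v2 / (1 - beta2^step)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
    }
  }
  walk(params, grads, m, v)
}
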