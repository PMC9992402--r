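#' Train the epitope classifier
#'
#' Minimizes mean binary cross-entropy with Adam over shuffled minibatches.
#' Everything stochastic (weight initialization, epoch shuffles, dropout)
#' is driven by `config@seed`, so two runs with the same inputs and config
#' produce identical weights and history.  When a validation batch is
#' supplied, per-epoch validation loss and metrics are recorded and early
#' stopping (patience `config@patience`, minimum improvement 1e-4) restores
#' the best-validation-loss weights.
#'
#' @param config a [ModelConfig-class].
#' @param batch labelled training [EncodedBatch-class] (both classes
#'   required).
#' @param validBatch optional labelled validation [EncodedBatch-class].
#' @param epochs epoch budget (default `config@epochs`).
#' @param verbose print per-epoch progress.
#' @return a trained [LBCEModel-class]; `trainingHistory()` holds columns
#'   `epoch`, `loss` and, with validation, `val_loss`, `val_sn`, `val_sp`,
#'   `val_acc`, `val_mcc`.
#' @export
trainModel <- function(config, batch, validBatch = NULL,
                       epochs = config@epochs, verbose = FALSE) {
  validObject(config)
  y <- batch@labels
  if (!length(y)) stop("training batch carries no labels", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; both classes are required",
         call. = FALSE)
  X <- batch@codes
  n <- nrow(X)

  set.seed(config@seed)
  params <- initParams(config)
  m <- zerosLike(params); v <- zerosLike(params)
  step <- 0L
  hist <- vector("list", epochs)
  bestVal <- Inf; bestParams <- NULL; bestEpoch <- 0L; wait <- 0L
  minDelta <- 1e-4

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0
    starts <- seq(1L, n, by = config@batchSize)
    for (s in starts) {
      sel <- ord[s:min(s + config@batchSize - 1L, n)]
      cache <- modelForward(params, config, X[sel, , drop = FALSE],
                            train = TRUE)
      loss <- bceLoss(cache$probs, y[sel])
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", ep,
             " (learning rate ", config@learningRate, ")", call. = FALSE)
      epochLoss <- epochLoss + loss * length(sel)
      grads <- modelBackward(params, config, cache, y[sel])
      step <- step + 1L
      upd <- adamStep(params, grads, m, v, step, config@learningRate)
      params <- upd$p; m <- upd$m; v <- upd$v
    }
    row <- data.frame(epoch = ep, loss = epochLoss / n)

    if (!is.null(validBatch)) {
      vp <- numeric(length(validBatch@ids))
      for (st in seq(1L, nrow(validBatch@codes), by = 256L)) {
        ii <- st:min(st + 255L, nrow(validBatch@codes))
        vp[ii] <- modelForward(params, config,
                               validBatch@codes[ii, , drop = FALSE])$probs
      }
      vLoss <- bceLoss(vp, validBatch@labels)
      vm <- computeMetrics(confusionCounts(validBatch@labels,
                                           as.integer(vp >= 0.5)))
      row$val_loss <- vLoss
      row$val_sn <- vm@sn; row$val_sp <- vm@sp
      row$val_acc <- vm@acc; row$val_mcc <- vm@mcc
      if (vLoss < bestVal - minDelta) {
        bestVal <- vLoss; bestParams <- params; bestEpoch <- ep; wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist[[ep]] <- row
    if (verbose)
      message(sprintf("epoch %d: loss %.4f%s", ep, row$loss,
                      if (!is.null(validBatch))
                        sprintf(", val loss %.4f", row$val_loss) else ""))
    if (!is.null(validBatch) && config@patience > 0L &&
        wait >= config@patience) {
      if (verbose)
        message("early stopping at epoch ", ep,
                " (best validation loss at epoch ", bestEpoch, ")")
      break
    }
  }
  if (!is.null(bestParams)) params <- bestParams
  new("LBCEModel", config = config, params = params,
      history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
      trained = TRUE)
}
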