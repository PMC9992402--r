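## round half up, used wherever the protocol calls for round(fraction * n)
roundHalfUp <- function(x) floor(x + 0.5)

#' Stratified fold assignment
#'
#' Partitions samples into `k` near-equal folds, stratified by label:
#' within each class, indices are shuffled and dealt round-robin, so fold
#' test sizes differ by at most one per class.
#'
#' @param labels binary 0/1 label vector.
#' @param k fold count, >= 2.
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids (1..k), one per sample.
#' @export
stratifiedFolds <- function(labels, k, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (length(labels) < k)
    stop("need at least k samples", call. = FALSE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## Stratified train/test index split.  Per-class train counts apportion the
## overall target round(frac * n) by largest remainder, so class balance is
## kept while the split sizes come out exact (e.g. 10 samples at 0.5 give
## 5/5 even though each class quota is 2.5).
stratifiedSplit <- function(labels, trainFraction, seed) {
  set.seed(seed)
  classes <- unique(labels)
  nc <- vapply(classes, function(cl) sum(labels == cl), 0L)
  quota <- trainFraction * nc
  nTr <- floor(quota)
  extra <- as.integer(roundHalfUp(trainFraction * length(labels)) - sum(nTr))
  if (extra > 0L) {
    give <- order(quota - nTr, decreasing = TRUE)[seq_len(extra)]
    nTr[give] <- nTr[give] + 1L
  }
  if (any(nTr == 0L) || any(nTr == nc))
    stop("too few samples to stratify a split at fraction ", trainFraction,
         call. = FALSE)
  trainIdx <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(labels == classes[i])
    trainIdx <- c(trainIdx, idx[sample.int(length(idx))][seq_len(nTr[i])])
  }
  list(train = sort(trainIdx),
       test = sort(setdiff(seq_along(labels), trainIdx)))
}

#' Single stratified holdout evaluation
#'
#' Splits the records into stratified train/test portions (default 80/20,
#' per class, seeded by `config@seed`), trains a fresh model on the
#' training portion and returns metrics on the held-out portion.
#'
#' @param records labelled record data.frame.
#' @param config a [ModelConfig-class].
#' @param trainFraction fraction of each class used for training.
#' @param epochs epoch budget override.
#' @return a [MetricsReport-class].
#' @export
holdoutEval <- function(records, config, trainFraction = 0.8,
                        epochs = config@epochs) {
  batch <- encodeBatch(records, config@L)
  if (!length(batch@labels))
    stop("records carry no labels", call. = FALSE)
  if (length(unique(batch@labels)) < 2L)
    stop("both classes are required", call. = FALSE)
  sp <- stratifiedSplit(batch@labels, trainFraction, config@seed)
  model <- trainModel(config, batchSubset(batch, sp$train), epochs = epochs)
  evaluateModel(model, batchSubset(batch, sp$test))
}

#' Stratified k-fold cross-validation
#'
#' Partitions the dataset into `k` stratified near-equal folds; each fold
#' serves once as the test set for a fresh model trained on the other
#' `k - 1` folds (no weight reuse).  Fold f uses seed `config@seed + f`.
#' The mean row is the arithmetic mean of the per-fold metrics.
#'
#' @param records labelled record data.frame.
#' @param config a [ModelConfig-class].
#' @param k fold count (default 10).
#' @param epochs epoch budget override.
#' @param verbose log per-fold progress.
#' @return a [CVReport-class].
#' @export
kfoldCV <- function(records, config, k = 10L, epochs = config@epochs,
                    verbose = FALSE) {
  batch <- encodeBatch(records, config@L)
  if (!length(batch@labels))
    stop("records carry no labels", call. = FALSE)
  if (length(unique(batch@labels)) < 2L)
    stop("both classes are required", call. = FALSE)
  fold <- stratifiedFolds(batch@labels, k, seed = config@seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    cfg <- config
    cfg@seed <- config@seed + f
    model <- trainModel(cfg, batchSubset(batch, tr), epochs = epochs)
    mr <- evaluateModel(model, batchSubset(batch, te))
    rows[[f]] <- data.frame(fold = f, n_test = length(te),
                            as.data.frame(mr))
    if (verbose)
      message(sprintf("fold %d/%d: ACC %.3f MCC %.3f", f, k, mr@acc, mr@mcc))
  }
  folds <- do.call(rbind, rows)
  means <- data.frame(Sn = mean(folds$Sn), Sp = mean(folds$Sp),
                      ACC = mean(folds$ACC), MCC = mean(folds$MCC))
  new("CVReport", k = as.integer(k), folds = folds, means = means,
      assignment = stats::setNames(fold, batch@ids), config = config,
      seed = config@seed)
}

#' Grid search over convolution kernel-width triples
#'
#' Evaluates every unordered triple of distinct candidate widths with a
#' stratified holdout run and returns one row per combination plus the best
#' row (argmax ACC, ties broken by MCC, then by smaller kernels).
#'
#' @param records labelled record data.frame.
#' @param config base [ModelConfig-class]; each evaluated config replaces
#'   `cnnScales`/`activeScales` with the triple.
#' @param candidateWidths integer candidate kernel widths (default
#'   7, 9, 11, 13, 15), all <= `config@L`.
#' @param trainFraction holdout training fraction.
#' @param epochs epoch budget override (the grid is usually run with a
#'   reduced budget).
#' @param verbose log per-combination progress.
#' @return list with `table` (data.frame: scale1..scale3, Sn, Sp, ACC, MCC)
#'   and `best` (its selected row).
#' @export
scaleSearch <- function(records, config,
                        candidateWidths = c(7L, 9L, 11L, 13L, 15L),
                        trainFraction = 0.8, epochs = config@epochs,
                        verbose = FALSE) {
  candidateWidths <- sort(unique(as.integer(candidateWidths)))
  if (length(candidateWidths) < 3L)
    stop("need at least 3 candidate widths", call. = FALSE)
  if (any(candidateWidths > config@L))
    stop("all candidate widths must be <= L", call. = FALSE)
  combos <- utils::combn(candidateWidths, 3L)
  rows <- vector("list", ncol(combos))
  for (i in seq_len(ncol(combos))) {
    triple <- combos[, i]
    cfg <- config
    cfg@cnnScales <- triple
    cfg@activeScales <- triple
    mr <- holdoutEval(records, cfg, trainFraction, epochs = epochs)
    rows[[i]] <- data.frame(scale1 = triple[1], scale2 = triple[2],
                            scale3 = triple[3], as.data.frame(mr))
    if (verbose)
      message(sprintf("scales %s: ACC %.3f MCC %.3f",
                      paste(triple, collapse = "/"), mr@acc, mr@mcc))
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$ACC, -tab$MCC, tab$scale1, tab$scale2, tab$scale3)
  list(table = tab, best = tab[ord[1L], ])
}

#' Run all five ablation variants plus the full model
#'
#' Trains the full configuration and each ablation variant on the same
#' stratified split and reports a comparison table (one metrics row per
#' variant, full model last).
#'
#' @param records labelled record data.frame.
#' @param config full-model [ModelConfig-class].
#' @param trainFraction holdout training fraction.
#' @param epochs epoch budget override.
#' @param verbose log progress.
#' @return data.frame with columns variant, n_params, Sn, Sp, ACC, MCC.
#' @export
ablationStudy <- function(records, config, trainFraction = 0.8,
                          epochs = config@epochs, verbose = FALSE) {
  variants <- c(ABLATION_VARIANTS, "full")
  rows <- lapply(variants, function(vv) {
    cfg <- if (vv == "full") config else ablateConfig(config, vv)
    mr <- holdoutEval(records, cfg, trainFraction, epochs = epochs)
    if (verbose)
      message(sprintf("%s: ACC %.3f MCC %.3f", vv, mr@acc, mr@mcc))
    data.frame(variant = vv, n_params = nParams(buildModel(cfg)),
               as.data.frame(mr))
  })
  do.call(rbind, rows)
}
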