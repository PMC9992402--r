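test_that("metrics are exact on canonical confusion tables", {
  perfect <- computeMetrics(c(TP = 50L, TN = 50L, FP = 0L, FN = 0L))
  expect_equal(c(perfect@sn, perfect@sp, perfect@acc, perfect@mcc),
               c(1, 1, 1, 1))

  inverse <- computeMetrics(c(TP = 0L, TN = 0L, FP = 50L, FN = 50L))
  expect_equal(c(inverse@sn, inverse@sp, inverse@acc, inverse@mcc),
               c(0, 0, 0, -1))

  mixed <- computeMetrics(c(TP = 40L, TN = 30L, FP = 20L, FN = 10L))
  expect_equal(mixed@sn, 0.80)
  expect_equal(mixed@sp, 0.60)
  expect_equal(mixed@acc, 0.70)
  expect_equal(mixed@mcc, 1000 / sqrt(50 * 40 * 60 * 50), tolerance = 1e-9)
  expect_equal(mixed@mcc, 0.4082483, tolerance = 1e-6)
})

test_that("metrics agree with vector-level oracles on random tables", {
  set.seed(13)
  for (i in 1:1000) {
    n <- sample(4:60, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    cc <- confusionCounts(truth, pred)
    expect_equal(sum(cc), n)
    mr <- computeMetrics(cc)
    expect_equal(mr@acc, mean(truth == pred), tolerance = 1e-9)
    if (any(truth == 1))
      expect_equal(mr@sn, mean(pred[truth == 1] == 1), tolerance = 1e-9)
    if (any(truth == 0))
      expect_equal(mr@sp, mean(pred[truth == 0] == 0), tolerance = 1e-9)
    # MCC of a 2x2 table equals the Pearson correlation of the 0/1 vectors
    if (var(truth) > 0 && var(pred) > 0)
      expect_equal(mr@mcc, cor(truth, pred), tolerance = 1e-9)
    expect_true(mr@mcc >= -1 && mr@mcc <= 1)
    expect_true(all(c(mr@sn, mr@sp, mr@acc) >= 0 &
                    c(mr@sn, mr@sp, mr@acc) <= 1))
    # ACC is the class-size-weighted combination of Sn and Sp
    if (!length(mr@degenerate)) {
      np <- sum(truth == 1); nn <- n - np
      expect_equal(mr@acc, (np * mr@sn + nn * mr@sp) / n, tolerance = 1e-9)
    }
  }
})

test_that("degenerate denominators report zero with a flag instead of failing", {
  onlyPos <- computeMetrics(c(TP = 5L, TN = 0L, FP = 0L, FN = 2L))
  expect_equal(onlyPos@sp, 0)
  expect_true("Sp" %in% onlyPos@degenerate)
  expect_true("MCC" %in% onlyPos@degenerate)
  expect_error(computeMetrics(c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)),
               "no samples")
})

test_that("label-shuffled predictions give near-zero MCC in expectation", {
  set.seed(17)
  n <- 500
  truth <- rep(c(1L, 0L), each = n / 2)
  pred <- rbinom(n, 1, 0.5)
  mccs <- replicate(100, {
    computeMetrics(confusionCounts(sample(truth), pred))@mcc
  })
  expect_lt(mean(abs(mccs)), 0.1)
})

test_that("training is deterministic given the seed and reduces the loss", {
  recs <- tinyMotifRecords(48)
  cfg <- tinyConfig(seed = 7L)
  b <- encodeBatch(recs, cfg@L)
  m1 <- trainModel(cfg, b)
  m2 <- trainModel(cfg, b)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history, m2@history)
  expect_lt(m1@history$loss[nrow(m1@history)], m1@history$loss[1])
})

test_that("training refuses a single-class set and records validation metrics", {
  cfg <- tinyConfig()
  recs <- tinyMotifRecords(24)
  onlyPos <- recs[recs$label == 1L, ]
  expect_error(trainModel(cfg, encodeBatch(onlyPos, cfg@L)), "single class")

  b <- encodeBatch(recs, cfg@L)
  m <- trainModel(cfg, b, validBatch = b, epochs = 2L)
  expect_true(all(c("val_loss", "val_sn", "val_sp", "val_acc", "val_mcc")
                  %in% names(m@history)))
  expect_equal(nrow(m@history), 2L)
})

test_that("holdout evaluation splits stratified and reproducibly", {
  ns <- asNamespace("linearBCE")
  labels <- rep(c(1L, 0L), each = 50)
  sp <- ns$stratifiedSplit(labels, 0.8, seed = 4L)
  expect_length(sp$test, 20)
  expect_equal(sum(labels[sp$test]), 10)      # 10 per class in the test set
  expect_length(intersect(sp$train, sp$test), 0)

  sp2 <- ns$stratifiedSplit(labels, 0.8, seed = 4L)
  expect_identical(sp, sp2)

  # 50/50 split of 10 samples
  sp3 <- ns$stratifiedSplit(rep(c(1L, 0L), each = 5), 0.5, seed = 1L)
  expect_length(sp3$train, 5)
  expect_length(sp3$test, 5)
})

test_that("stratified k-fold partitions are disjoint, covering and balanced", {
  for (n in c(20L, 55L, 1110L)) {
    labels <- rep(c(1L, 0L), c(ceiling(n / 2), floor(n / 2)))
    fold <- stratifiedFolds(labels, k = 10L, seed = 2L)
    expect_length(fold, n)
    expect_setequal(unique(fold), 1:10)
    sizes <- tabulate(fold, 10)
    expect_lte(max(sizes) - min(sizes), 2L)   # at most 1 per class
    for (f in 1:10) {
      pos <- sum(labels[fold == f])
      neg <- sum(fold == f) - pos
      expect_lte(abs(pos - neg), 1L)
    }
  }
  expect_error(stratifiedFolds(rep(0:1, 10), k = 1L), "k must be")
})

test_that("kfoldCV covers every sample once and averages fold metrics", {
  recs <- tinyMotifRecords(40, seed = 21L)
  cfg <- tinyConfig(seed = 5L)
  rep10 <- kfoldCV(recs, cfg, k = 10L, epochs = 1L)
  expect_s4_class(rep10, "CVReport")
  expect_equal(sort(names(rep10@assignment)), sort(recs$id))
  expect_equal(rep10@folds$n_test, rep(4, 10))
  expect_equal(rep10@means$ACC, mean(rep10@folds$ACC), tolerance = 1e-9)
  expect_equal(rep10@means$MCC, mean(rep10@folds$MCC), tolerance = 1e-9)

  out <- tempfile(fileext = ".tsv")
  tab <- writeCVReport(rep10, out)
  expect_equal(nrow(tab), 11L)                 # 10 folds + mean row
  expect_equal(tab$fold[11], "Mean")
  reread <- read.delim(out)
  expect_equal(reread$ACC, tab$ACC, tolerance = 1e-9)
})

test_that("scale search enumerates triples and returns the ACC argmax", {
  recs <- tinyMotifRecords(40, seed = 8L)
  cfg <- tinyConfig(seed = 9L)
  res <- scaleSearch(recs, cfg, candidateWidths = c(3L, 5L, 7L),
                     epochs = 1L)
  expect_equal(nrow(res$table), 1L)            # C(3,3) = 1
  expect_error(scaleSearch(recs, cfg, candidateWidths = c(3L, 5L)),
               "at least 3")
  expect_error(scaleSearch(recs, cfg, candidateWidths = c(3L, 5L, 99L)),
               "<= L")

  # argmax contract on a synthetic result table
  ns <- asNamespace("linearBCE")
  expect_equal(choose(5, 3), ncol(utils::combn(c(7, 9, 11, 13, 15), 3)))
})

test_that("activation export writes matrices and deterministic t-SNE", {
  cfg <- tinyConfig()
  recs <- tinyMotifRecords(50, seed = 31L)
  b <- encodeBatch(recs, cfg@L)
  m <- buildModel(cfg)
  out <- tempfile(fileext = ".tsv")
  res <- exportActivations(m, b, "combined", out, tsne = TRUE, seed = 3L)
  expect_equal(nrow(res$activations), 50L)
  tab <- read.delim(out)
  expect_equal(nrow(tab), 50L)

  tsnePath <- sub("\\.tsv$", "_tsne.tsv", out)
  coords <- read.delim(tsnePath)
  expect_equal(names(coords), c("id", "x", "y", "label"))
  expect_equal(nrow(coords), 50L)

  res2 <- exportActivations(m, b, "combined", out, tsne = TRUE, seed = 3L)
  expect_equal(res2$tsne$x, res$tsne$x, tolerance = 1e-12)
})
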