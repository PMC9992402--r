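test_that("attention weights are a softmax of the scores", {
  h <- matrix(rnorm(9), 3, 3)
  # equal scores give uniform weights
  st <- feedForwardAttention(h, a = function(h) rep(0, nrow(h)))
  expect_equal(st$weights, rep(1 / 3, 3))

  # hand-evaluated softmax: e = (ln 1, ln 2, ln 3) -> alpha = (1, 2, 3)/6
  st <- feedForwardAttention(h, a = function(h) log(1:3))
  expect_equal(st$weights, c(1, 2, 3) / 6, tolerance = 1e-12)

  # identical rows: context is that row for any weights
  v <- rnorm(4)
  hv <- matrix(v, 5, 4, byrow = TRUE)
  st <- feedForwardAttention(hv, a = list(w = rnorm(4), b = 0.3))
  expect_equal(st$context, v, tolerance = 1e-10)
})

test_that("attention matches a literal loop-based evaluation on random inputs", {
  set.seed(7)
  for (i in 1:100) {
    T <- sample(1:10, 1); D <- sample(1:8, 1)
    h <- matrix(rnorm(T * D), T, D)
    w <- rnorm(D); b <- rnorm(1)
    got <- feedForwardAttention(h, a = list(w = w, b = b))
    want <- attentionOracle(h, function(ht) tanh(sum(w * ht) + b))
    expect_equal(got$weights, want$weights, tolerance = 1e-6)
    expect_equal(got$context, want$context, tolerance = 1e-6)
    expect_equal(sum(got$weights), 1, tolerance = 1e-6)
    expect_true(all(got$weights >= 0))
  }
})

test_that("non-finite hidden states are rejected", {
  h <- matrix(c(1, NaN, 0, 1), 2, 2)
  expect_error(feedForwardAttention(h, a = list(w = c(1, 1), b = 0)),
               "non-finite")
})

test_that("config validity enforces the architectural invariants", {
  expect_error(modelConfig(cnnScales = c(11L, 11L, 15L)), "increasing")
  expect_error(modelConfig(L = 10L, cnnScales = c(11L, 13L, 15L)), "<= L")
  expect_error(modelConfig(activeScales = c(9L)), "subset")
  expect_error(modelConfig(useBiLSTM = FALSE, activeScales = integer(0)),
               "at least one branch")
  expect_error(modelConfig(dropoutRate = 1), "dropoutRate")
})

test_that("the built network maps integer batches to probabilities", {
  cfg <- tinyConfig()
  m <- buildModel(cfg)
  set.seed(1)
  X <- matrix(sample(1:20, 4 * cfg@L, replace = TRUE), 4, cfg@L)
  p <- predictProbs(m, X)
  expect_length(p, 4)
  expect_true(all(p >= 0 & p <= 1))

  # same seed, same initial weights
  m2 <- buildModel(cfg)
  expect_identical(m@params, m2@params)

  # fewer active scales means strictly fewer parameters
  cfgSmall <- tinyConfig()
  cfgSmall@activeScales <- cfgSmall@cnnScales[-1]
  expect_lt(nParams(buildModel(cfgSmall)), nParams(m))
})

test_that("permuting batch rows permutes outputs identically", {
  cfg <- tinyConfig()
  m <- buildModel(cfg)
  set.seed(2)
  X <- matrix(sample(1:20, 12 * cfg@L, replace = TRUE), 12, cfg@L)
  perm <- sample(12)
  expect_equal(predictProbs(m, X[perm, ]), predictProbs(m, X)[perm],
               tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  ns <- asNamespace("linearBCE")
  cfg <- modelConfig(L = 7L, embedDim = 4L, lstmUnits = 3L,
                     cnnScales = c(2L, 3L), cnnFilters = 3L,
                     denseSizes = c(5L, 4L, 1L), dropoutRate = 0, seed = 42L)
  set.seed(42)
  params <- ns$initParams(cfg)
  set.seed(99)
  X <- matrix(sample(0:20, 5 * 7, replace = TRUE), 5, 7)
  y <- c(1, 0, 1, 1, 0)
  cache <- ns$modelForward(params, cfg, X)
  grads <- ns$modelBackward(params, cfg, cache, y)
  lossAt <- function(p) ns$bceLoss(ns$modelForward(p, cfg, X)$probs, y)

  eps <- 1e-5
  checkLeaf <- function(path) {
    p <- params
    g <- grads
    for (nm in path) { p <- p[[nm]]; g <- g[[nm]] }
    set.seed(7)
    for (i in sample(length(p), min(6, length(p)))) {
      pu <- params; pd <- params
      pu[[path]][i] <- pu[[path]][i] + eps
      pd[[path]][i] <- pd[[path]][i] - eps
      num <- (lossAt(pu) - lossAt(pd)) / (2 * eps)
      expect_equal(unname(g[i]), num, tolerance = 1e-4)
    }
  }
  leaves <- list(
    "Wemb", c("lstm_f", "Wx"), c("lstm_f", "Wh"), c("lstm_f", "b"),
    c("lstm_b", "Wx"), c("lstm_b", "Wh"), c("lstm_b", "b"),
    c("att", "w"), c("att", "b"),
    c("conv", "2", "W"), c("conv", "3", "b"),
    c("dense", "W1"), c("dense", "b2"), c("dense", "W3"))
  for (lf in leaves) checkLeaf(lf)
})

test_that("in-network attention weights sum to one across random models", {
  ns <- asNamespace("linearBCE")
  cfg <- tinyConfig()
  for (s in 1:100) {
    cfg@seed <- s
    m <- buildModel(cfg)
    set.seed(s + 1000)
    X <- matrix(sample(0:20, 3 * cfg@L, replace = TRUE), 3, cfg@L)
    cc <- ns$modelForward(m@params, cfg, X)
    expect_equal(rowSums(cc$attA), rep(1, 3), tolerance = 1e-6)
    expect_true(all(cc$attA >= 0))
  }
})

test_that("ablation variants edit the config as specified", {
  cfg <- modelConfig()
  expect_equal(ablateConfig(cfg, "delete_scale1")@activeScales, c(13L, 15L))
  expect_equal(ablateConfig(cfg, "delete_scale1_2")@activeScales, 15L)
  expect_equal(ablateConfig(cfg, "delete_multiscale_cnn")@activeScales,
               integer(0))
  expect_false(ablateConfig(cfg, "delete_bilstm")@useBiLSTM)
  noAtt <- ablateConfig(cfg, "delete_attention")
  expect_false(noAtt@useAttention)
  expect_true(noAtt@useBiLSTM)
  # idempotence of attention removal
  expect_identical(ablateConfig(noAtt, "delete_attention"), noAtt)
  # unrelated fields untouched
  expect_equal(noAtt@cnnScales, cfg@cnnScales)
  expect_equal(noAtt@seed, cfg@seed)

  # deleting the last remaining branch is refused
  noCNN <- ablateConfig(cfg, "delete_multiscale_cnn")
  expect_error(ablateConfig(noCNN, "delete_bilstm"), "no CNN scale")
  noLSTM <- ablateConfig(cfg, "delete_bilstm")
  expect_error(ablateConfig(noLSTM, "delete_multiscale_cnn"), "disabled")
})

test_that("layer taps return per-sample activations of the documented width", {
  cfg <- tinyConfig()
  m <- buildModel(cfg)
  recs <- tinyMotifRecords(12)
  b <- encodeBatch(recs, cfg@L)
  n <- nrow(b@codes); H2 <- 2L * cfg@lstmUnits
  expect_equal(dim(layerActivations(m, b, "embedding")),
               c(n, cfg@L * cfg@embedDim))
  expect_equal(dim(layerActivations(m, b, "bilstm")), c(n, cfg@L * H2))
  expect_equal(dim(layerActivations(m, b, "attention")), c(n, H2))
  expect_equal(dim(layerActivations(m, b, "cnn")),
               c(n, cfg@cnnFilters * length(cfg@activeScales)))
  comb <- layerActivations(m, b, "combined")
  expect_equal(ncol(comb),
               H2 + cfg@cnnFilters * length(cfg@activeScales))
  expect_equal(rownames(comb), b@ids)

  # chunking does not change values
  expect_equal(layerActivations(m, b, "combined", chunkSize = 5L), comb)

  # ablated stages error by name
  mNoC <- buildModel(ablateConfig(cfg, "delete_multiscale_cnn"))
  expect_error(layerActivations(mNoC, b, "cnn"), "cnn")
  mNoL <- buildModel(ablateConfig(cfg, "delete_bilstm"))
  expect_error(layerActivations(mNoL, b, "attention"), "attention")
})

test_that("checkpoints round-trip with the config embedded", {
  cfg <- tinyConfig()
  m <- buildModel(cfg)
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(m2@params, m@params)
  expect_equal(getConfig(m2)@cnnScales, cfg@cnnScales)
})
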