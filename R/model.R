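#' Build an untrained epitope classifier
#'
#' Instantiates the two-branch network described by a [ModelConfig-class]:
#' an embedding layer (21 tokens -> `embedDim`), in parallel a Bi-LSTM over
#' the `L` positions pooled by feed-forward attention and one 1-D
#' convolution (+ ReLU + global max pooling) per active kernel width, with
#' the flattened branch outputs concatenated, passed through dropout and a
#' 64/9/1 dense head ending in a sigmoid.  Weight initialization is fully
#' determined by `config@seed`.
#'
#' @param config a [ModelConfig-class].
#' @return an untrained [LBCEModel-class].
#' @examples
#' m <- buildModel(modelConfig(embedDim = 8L, lstmUnits = 8L,
#'                             cnnFilters = 8L, seed = 1L))
#' nParams(m)
#' @export
buildModel <- function(config) {
  validObject(config)
  set.seed(config@seed)
  new("LBCEModel", config = config, params = initParams(config),
      history = data.frame(), trained = FALSE)
}

#' Number of trainable parameters of a model
#'
#' @param model an [LBCEModel-class].
#' @return integer parameter count.
#' @export
nParams <- function(model) as.integer(countLeaves(model@params))

#' Accessor: the configuration a model was built with
#' @param model an [LBCEModel-class].
#' @export
getConfig <- function(model) model@config

#' Accessor: per-epoch training history
#' @param model an [LBCEModel-class].
#' @export
trainingHistory <- function(model) model@history

#' Predict epitope probabilities
#'
#' @param model an [LBCEModel-class].
#' @param batch an [EncodedBatch-class] (or bare integer code matrix).
#' @param chunkSize samples per forward chunk (memory control).
#' @return numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predictProbs <- function(model, batch, chunkSize = 128L) {
  X <- if (is(batch, "EncodedBatch")) batch@codes else batch
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, n)
    out[idx] <- modelForward(model@params, model@config,
                             X[idx, , drop = FALSE])$probs
  }
  out
}

#' Feed-forward attention pooling
#'
#' Scores each time step's hidden state with a learnable function `a`,
#' softmax-normalizes the scores into weights, and returns the
#' weighted sum of hidden states as the context vector:
#' `alpha_t = exp(e_t) / sum_k exp(e_k)` with `e_t = a(h_t)` and
#' `c = sum_t alpha_t h_t`.
#'
#' @param h T x D matrix of hidden states (one row per time step).
#' @param a the scoring function: either a list with elements `w`
#'   (length-D numeric) and `b` (scalar), giving the package's learned
#'   scorer `e_t = tanh(w . h_t + b)`, or an arbitrary function mapping the
#'   T x D matrix to a length-T score vector.
#' @return list with elements `scores` (e, length T), `weights` (alpha,
#'   length T, non-negative, summing to 1), and `context` (length D).
#' @examples
#' h <- matrix(rnorm(12), 4, 3)
#' st <- feedForwardAttention(h, a = function(h) rep(0, nrow(h)))
#' st$weights  # uniform 1/4
#' @export
feedForwardAttention <- function(h, a) {
  stopifnot(is.matrix(h), nrow(h) >= 1L, ncol(h) >= 1L)
  if (!all(is.finite(h))) stop("non-finite hidden states", call. = FALSE)
  e <- if (is.function(a)) a(h)
       else as.vector(tanh(h %*% matrix(a$w, ncol = 1L) + a$b))
  if (length(e) != nrow(h) || !all(is.finite(e)))
    stop("scorer must return one finite score per time step", call. = FALSE)
  w <- exp(e - max(e))
  w <- w / sum(w)
  list(scores = e, weights = w, context = as.vector(crossprod(h, w)))
}

ABLATION_VARIANTS <- c("delete_bilstm", "delete_scale1", "delete_scale1_2",
                       "delete_multiscale_cnn", "delete_attention")

#' Derive an ablated configuration
#'
#' Produces the configuration of one of the five branch-ablation variants:
#' removing the Bi-LSTM (with its attention), the smallest kernel scale,
#' the two smallest scales, the whole multi-scale CNN branch, or the
#' attention pooling (the Bi-LSTM then contributes its concatenated final
#' forward/backward hidden states).
#'
#' @param config a [ModelConfig-class].
#' @param variant one of `"delete_bilstm"`, `"delete_scale1"`,
#'   `"delete_scale1_2"`, `"delete_multiscale_cnn"`, `"delete_attention"`.
#' @return the modified [ModelConfig-class]; all other fields unchanged.
#' @export
ablateConfig <- function(config, variant = ABLATION_VARIANTS) {
  variant <- match.arg(variant)
  cfg <- config
  switch(variant,
    delete_bilstm = {
      if (length(cfg@activeScales) == 0L)
        stop("cannot delete the Bi-LSTM branch: no CNN scale would remain",
             call. = FALSE)
      cfg@useBiLSTM <- FALSE; cfg@useAttention <- FALSE
    },
    delete_scale1 = {
      if (length(cfg@activeScales) < 1L)
        stop("no CNN scale to delete", call. = FALSE)
      remaining <- cfg@activeScales[-1L]
      if (length(remaining) == 0L && !cfg@useBiLSTM)
        stop("deleting scale 1 would leave no branch", call. = FALSE)
      cfg@activeScales <- remaining
    },
    delete_scale1_2 = {
      if (length(cfg@activeScales) < 2L)
        stop("fewer than two CNN scales to delete", call. = FALSE)
      remaining <- cfg@activeScales[-(1:2)]
      if (length(remaining) == 0L && !cfg@useBiLSTM)
        stop("deleting scales 1 and 2 would leave no branch", call. = FALSE)
      cfg@activeScales <- remaining
    },
    delete_multiscale_cnn = {
      if (!cfg@useBiLSTM)
        stop("cannot delete the CNN branch: the Bi-LSTM branch is disabled",
             call. = FALSE)
      cfg@activeScales <- integer(0)
    },
    delete_attention = {
      if (!cfg@useBiLSTM)
        stop("no attention to delete: the Bi-LSTM branch is disabled",
             call. = FALSE)
      cfg@useAttention <- FALSE
    })
  validObject(cfg)
  cfg
}

MODEL_STAGES <- c("embedding", "bilstm", "attention", "cnn", "combined")

#' Per-sample activations at a named network stage
#'
#' Runs a forward pass and returns the activation at one of the stages
#' `embedding` (n x L*embedDim), `bilstm` (n x L*2*lstmUnits, the
#' per-position hidden states), `attention` (n x 2*lstmUnits context
#' vectors), `cnn` (n x filters*scales pooled features) or `combined`
#' (the concatenated branch features before dropout), flattened to one row
#' per input sequence.
#'
#' @param model an [LBCEModel-class].
#' @param batch an [EncodedBatch-class].
#' @param stage stage name.
#' @param chunkSize samples per forward chunk.
#' @return numeric matrix, one row per sequence (rownames = ids).
#' @export
layerActivations <- function(model, batch, stage = MODEL_STAGES,
                             chunkSize = 128L) {
  stage <- match.arg(stage)
  cfg <- model@config
  if (stage %in% c("bilstm", "attention") && !cfg@useBiLSTM)
    stop("stage '", stage, "' is absent: this network has no Bi-LSTM branch",
         call. = FALSE)
  if (stage == "attention" && !cfg@useAttention)
    stop("stage 'attention' is absent: attention pooling was ablated",
         call. = FALSE)
  if (stage == "cnn" && length(cfg@activeScales) == 0L)
    stop("stage 'cnn' is absent: this network has no CNN branch",
         call. = FALSE)
  X <- batch@codes
  n <- nrow(X)
  rows <- vector("list", 0L)
  for (start in seq(1L, n, by = chunkSize)) {
    sel <- start:min(start + chunkSize - 1L, n)
    cc <- modelForward(model@params, cfg, X[sel, , drop = FALSE])
    m <- length(sel)
    blockFlat <- function(mats)   # list over t of m x w -> m x (L*w)
      do.call(cbind, mats)
    part <- switch(stage,
      embedding = blockFlat(lapply(cc$rowsT,
        function(r) cc$Emat[r, , drop = FALSE])),
      bilstm = blockFlat(cc$Hcat),
      attention = cc$bilstmOut,
      cnn = do.call(cbind, lapply(cc$conv, `[[`, "pooled")),
      combined = cc$feat)
    rows[[length(rows) + 1L]] <- part
  }
  out <- do.call(rbind, rows)
  rownames(out) <- batch@ids
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full [ModelConfig-class], so it is
#' self-describing.
#'
#' @param model an [LBCEModel-class].
#' @param path file path (RDS).
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "LBCEModel"))
    stop("'", path, "' is not a saved LBCEModel checkpoint", call. = FALSE)
  model
}
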