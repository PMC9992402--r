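#' @import methods
NULL

#' Model and training configuration
#'
#' Holds every architectural and training hyperparameter of the two-branch
#' epitope classifier in one validated object.  The network maps an integer
#' encoded peptide batch (codes 0--20, length `L`) through an embedding
#' layer into two parallel branches -- a bidirectional LSTM pooled by
#' feed-forward attention, and one 1-D convolution per active kernel width
#' -- whose flattened outputs are concatenated and passed through dense
#' layers of sizes `denseSizes` (last unit sigmoid).
#'
#' @slot L standardized sequence length (default 25).
#' @slot vocabSize token count, 21 (20 residues + padding code 0).
#' @slot embedDim embedding width.
#' @slot lstmUnits hidden units per LSTM direction.
#' @slot cnnScales ordered convolution kernel widths (default 11, 13, 15).
#' @slot cnnFilters filters per convolution scale.
#' @slot denseSizes dense head sizes, fixed to c(64, 9, 1) unless overridden.
#' @slot dropoutRate dropout probability applied after branch concatenation.
#' @slot useBiLSTM,useAttention branch flags; attention requires the Bi-LSTM.
#' @slot activeScales subset of `cnnScales` actually built.
#' @slot seed integer seed governing initialization and training shuffles.
#' @slot learningRate,batchSize,epochs,patience Adam learning rate, minibatch
#'   size, epoch budget and early-stopping patience (epochs without
#'   validation-loss improvement; only used when a validation set is given).
#' @exportClass ModelConfig
setClass("ModelConfig", representation(
  L = "integer", vocabSize = "integer", embedDim = "integer",
  lstmUnits = "integer", cnnScales = "integer", cnnFilters = "integer",
  denseSizes = "integer", dropoutRate = "numeric",
  useBiLSTM = "logical", useAttention = "logical",
  activeScales = "integer", seed = "integer",
  learningRate = "numeric", batchSize = "integer",
  epochs = "integer", patience = "integer"
))

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  if (object@L < 1L) msg <- c(msg, "L must be >= 1")
  if (object@vocabSize != 21L) msg <- c(msg, "vocabSize must be 21")
  if (length(object@cnnScales) &&
      any(diff(object@cnnScales) <= 0))
    msg <- c(msg, "cnnScales must be strictly increasing")
  if (any(object@cnnScales > object@L))
    msg <- c(msg, "every cnnScales entry must be <= L")
  if (!all(object@activeScales %in% object@cnnScales))
    msg <- c(msg, "activeScales must be a subset of cnnScales")
  if (length(object@activeScales) &&
      any(diff(object@activeScales) <= 0))
    msg <- c(msg, "activeScales must be strictly increasing")
  if (!object@useBiLSTM && length(object@activeScales) == 0L)
    msg <- c(msg, "at least one branch (Bi-LSTM or >= 1 CNN scale) must be enabled")
  if (object@useAttention && !object@useBiLSTM)
    msg <- c(msg, "useAttention requires useBiLSTM")
  if (length(object@denseSizes) != 3L || any(object@denseSizes < 1L))
    msg <- c(msg, "denseSizes must be three positive integers")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must lie in [0, 1)")
  if (object@embedDim < 1L || object@lstmUnits < 1L || object@cnnFilters < 1L)
    msg <- c(msg, "embedDim, lstmUnits and cnnFilters must be positive")
  if (object@batchSize < 1L || object@epochs < 1L)
    msg <- c(msg, "batchSize and epochs must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#'
#' Defaults follow the published architecture where it is explicit (length 25,
#' 21-token vocabulary, kernel widths 11/13/15, dense head 64/9/1) and this
#' package's fixed choices where it is silent (embedding 64, 64 LSTM units per
#' direction, 64 filters per scale, dropout 0.3, Adam at 1e-3, batch 32,
#' 50 epochs, patience 10).
#'
#' @param L standardized peptide length.
#' @param vocabSize number of integer codes (always 21).
#' @param embedDim embedding width.
#' @param lstmUnits LSTM hidden units per direction.
#' @param cnnScales integer vector of kernel widths, strictly increasing.
#' @param cnnFilters convolution filters per scale.
#' @param denseSizes three dense layer sizes.
#' @param dropoutRate dropout probability after concatenation, in `[0, 1)`.
#' @param useBiLSTM,useAttention enable the recurrent branch / its attention
#'   pooling.
#' @param activeScales kernel widths actually instantiated (default: all).
#' @param seed integer seed for weight initialization and training.
#' @param learningRate,batchSize,epochs,patience training recipe.
#' @return a validated [ModelConfig-class] object.
#' @examples
#' cfg <- modelConfig(seed = 7L)
#' cfg
#' @export
modelConfig <- function(L = 25L, vocabSize = 21L, embedDim = 64L,
                        lstmUnits = 64L, cnnScales = c(11L, 13L, 15L),
                        cnnFilters = 64L, denseSizes = c(64L, 9L, 1L),
                        dropoutRate = 0.3, useBiLSTM = TRUE,
                        useAttention = TRUE, activeScales = cnnScales,
                        seed = 1L, learningRate = 1e-3, batchSize = 32L,
                        epochs = 50L, patience = 10L) {
  new("ModelConfig",
      L = as.integer(L), vocabSize = as.integer(vocabSize),
      embedDim = as.integer(embedDim), lstmUnits = as.integer(lstmUnits),
      cnnScales = as.integer(sort(cnnScales)),
      cnnFilters = as.integer(cnnFilters),
      denseSizes = as.integer(denseSizes), dropoutRate = dropoutRate,
      useBiLSTM = useBiLSTM, useAttention = useAttention,
      activeScales = as.integer(sort(activeScales)),
      seed = as.integer(seed), learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      patience = as.integer(patience))
}

setMethod("show", "ModelConfig", function(object) {
  branches <- c(
    if (object@useBiLSTM)
      sprintf("Bi-LSTM(%d units/direction)%s", object@lstmUnits,
              if (object@useAttention) " + feed-forward attention"
              else " (final-state pooling)"),
    if (length(object@activeScales))
      sprintf("CNN scales {%s} x %d filters",
              paste(object@activeScales, collapse = ", "),
              object@cnnFilters))
  cat("ModelConfig\n",
      "  L = ", object@L, ", embedDim = ", object@embedDim, "\n",
      "  branches: ", paste(branches, collapse = " || "), "\n",
      "  dense head: ", paste(object@denseSizes, collapse = "/"),
      ", dropout ", object@dropoutRate, "\n",
      "  recipe: Adam lr ", object@learningRate, ", batch ",
      object@batchSize, ", epochs ", object@epochs,
      ", seed ", object@seed, "\n", sep = "")
})

#' Integer-encoded peptide batch
#'
#' A fixed-length integer matrix ready for the embedding layer: entry codes
#' run 0--20 where 0 is the padding token 'X' and 1--20 are the amino acids
#' in alphabetical order (A=1 ... Y=20).  Padding 0s may only appear as a
#' contiguous row suffix.
#'
#' @slot codes n x L integer matrix with entries in `[0, 20]`.
#' @slot ids character identifiers, one per row.
#' @slot labels integer binary labels aligned to rows (length 0 when absent).
#' @exportClass EncodedBatch
setClass("EncodedBatch", representation(
  codes = "matrix", ids = "character", labels = "integer"))

setValidity("EncodedBatch", function(object) {
  msg <- character(0)
  cd <- object@codes
  if (nrow(cd) != length(object@ids))
    msg <- c(msg, "row count must equal id count")
  if (length(cd) && (any(cd < 0L) || any(cd > 20L)))
    msg <- c(msg, "codes must lie in [0, 20]")
  if (nrow(cd)) {
    badPad <- apply(cd, 1L, function(r) {
      z <- which(r == 0L)
      length(z) && !all(z == seq.int(min(z), length(r)))
    })
    if (any(badPad))
      msg <- c(msg, sprintf("padding code 0 must be a contiguous suffix (row %d)",
                            which(badPad)[1L]))
  }
  if (length(object@labels) &&
      length(object@labels) != nrow(cd))
    msg <- c(msg, "labels must be empty or one per row")
  if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be binary 0/1")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "ids must be unique within a batch")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EncodedBatch", function(object) {
  cat("EncodedBatch: ", nrow(object@codes), " peptides x L=",
      ncol(object@codes), if (length(object@labels)) " (labelled)" else "",
      "\n", sep = "")
})

#' @describeIn EncodedBatch number of peptides in the batch
#' @param x an `EncodedBatch`
#' @export
setMethod("length", "EncodedBatch", function(x) nrow(x@codes))

#' Fitted epitope classifier
#'
#' Wraps the learned parameter list together with the [ModelConfig-class]
#' that built it (so a saved model is self-describing) and the per-epoch
#' training history.
#'
#' @slot config the `ModelConfig` used to build/train the network.
#' @slot params named list of weight matrices/vectors.
#' @slot history per-epoch data.frame (loss, and validation metrics when a
#'   validation set was supplied).
#' @slot trained logical; FALSE for a freshly initialized network.
#' @exportClass LBCEModel
setClass("LBCEModel", representation(
  config = "ModelConfig", params = "list", history = "data.frame",
  trained = "logical"))

setMethod("show", "LBCEModel", function(object) {
  cat("LBCEModel (", if (object@trained) "trained" else "untrained",
      ", ", format(nParams(object), big.mark = ","),
      " parameters)\n", sep = "")
  show(object@config)
  if (nrow(object@history))
    cat("  final training loss: ",
        signif(object@history$loss[nrow(object@history)], 4), " after ",
        nrow(object@history), " epochs\n", sep = "")
})

#' Classification metrics from a confusion table
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), accuracy
#' ACC = (TP+TN)/n and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FN)(TP+FP)(TN+FP)).
#' A metric whose denominator is zero is reported as 0 and listed in
#' `degenerate`.
#'
#' @slot sn,sp,acc numeric in `[0, 1]`.
#' @slot mcc numeric in `[-1, 1]`.
#' @slot counts named integer TP, TN, FP, FN.
#' @slot degenerate names of metrics whose denominator was zero.
#' @exportClass MetricsReport
setClass("MetricsReport", representation(
  sn = "numeric", sp = "numeric", acc = "numeric", mcc = "numeric",
  counts = "integer", degenerate = "character"))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport  Sn=%.4f Sp=%.4f ACC=%.4f MCC=%.4f  (TP=%d TN=%d FP=%d FN=%d)\n",
              object@sn, object@sp, object@acc, object@mcc,
              object@counts[["TP"]], object@counts[["TN"]],
              object@counts[["FP"]], object@counts[["FN"]]))
  if (length(object@degenerate))
    cat("  degenerate (zero denominator):",
        paste(object@degenerate, collapse = ", "), "\n")
})

#' @describeIn MetricsReport one-row data.frame with Sn, Sp, ACC, MCC
#' @param x a `MetricsReport`
#' @param row.names,optional,... ignored (S3/S4 compatibility)
#' @export
setMethod("as.data.frame", "MetricsReport",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(Sn = x@sn, Sp = x@sp, ACC = x@acc, MCC = x@mcc)
})

#' k-fold cross-validation report
#'
#' @slot k fold count.
#' @slot folds per-fold data.frame (fold, n_test, Sn, Sp, ACC, MCC).
#' @slot means `MetricsReport`-style arithmetic means over folds.
#' @slot assignment named integer mapping sample id to its test fold.
#' @slot config config snapshot used for every fold.
#' @slot seed seed that produced the partition.
#' @exportClass CVReport
setClass("CVReport", representation(
  k = "integer", folds = "data.frame", means = "data.frame",
  assignment = "integer", config = "ModelConfig", seed = "integer"))

setMethod("show", "CVReport", function(object) {
  cat(object@k, "-fold cross-validation (seed ", object@seed, ")\n", sep = "")
  print(rbind(object@folds[, c("Sn", "Sp", "ACC", "MCC")],
              Mean = object@means[, c("Sn", "Sp", "ACC", "MCC")]),
        digits = 3)
})

#' Synthetic peptide benchmark specification
#'
#' Describes a balanced (or unbalanced) labelled peptide set with a planted
#' class-discriminative motif: lengths uniform on `lengthRange`, residues
#' drawn from `background`, and the motif overwritten at a random offset in
#' exactly `round(penetrance * nPos)` positives and
#' `round(contamination * nNeg)` negatives.
#'
#' @slot nPos,nNeg class sizes.
#' @slot lengthRange integer c(min, max) peptide lengths (default 11--25).
#' @slot motif planted peptide motif (default a fixed 5-mer).
#' @slot penetrance fraction of positives carrying the motif.
#' @slot contamination fraction of negatives carrying the motif.
#' @slot background length-20 residue sampling probabilities (named A..Y).
#' @slot seed integer seed.
#' @exportClass SynthSpec
setClass("SynthSpec", representation(
  nPos = "integer", nNeg = "integer", lengthRange = "integer",
  motif = "character", penetrance = "numeric", contamination = "numeric",
  background = "numeric", seed = "integer"))

setValidity("SynthSpec", function(object) {
  msg <- character(0)
  if (object@nPos < 0L || object@nNeg < 0L) msg <- c(msg, "counts must be >= 0")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1] > object@lengthRange[2] ||
      object@lengthRange[1] < 1L)
    msg <- c(msg, "lengthRange must be c(min, max) with 1 <= min <= max")
  if (nchar(object@motif) > object@lengthRange[1])
    msg <- c(msg, "motif length must be <= minimum peptide length")
  bad <- setdiff(strsplit(object@motif, "")[[1]], AA_LETTERS)
  if (length(bad))
    msg <- c(msg, sprintf("motif contains illegal residue '%s'", bad[1]))
  if (object@penetrance < 0 || object@penetrance > 1 ||
      object@contamination < 0 || object@contamination > 1)
    msg <- c(msg, "penetrance and contamination must lie in [0, 1]")
  if (object@penetrance < object@contamination)
    msg <- c(msg, "penetrance must be >= contamination")
  if (length(object@background) != 20L ||
      any(object@background < 0) || abs(sum(object@background) - 1) > 1e-8)
    msg <- c(msg, "background must be 20 probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SynthSpec", function(object) {
  cat("SynthSpec: ", object@nPos, " pos / ", object@nNeg, " neg, lengths [",
      object@lengthRange[1], ", ", object@lengthRange[2], "], motif '",
      object@motif, "' (penetrance ", object@penetrance, ", contamination ",
      object@contamination, "), seed ", object@seed, "\n", sep = "")
})
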