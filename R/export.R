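#' Export per-sample activations at a network stage
#'
#' Writes a tab-separated matrix of activations (one row per sample, id
#' first) at the named stage, and optionally a 2-D t-SNE embedding of them
#' as a second file with columns id, x, y and (when the batch is labelled)
#' label.
#'
#' @param model an [LBCEModel-class].
#' @param batch an [EncodedBatch-class].
#' @param stage one of `"embedding"`, `"bilstm"`, `"attention"`, `"cnn"`,
#'   `"combined"`.
#' @param path output TSV path for the activation matrix.
#' @param tsne also compute and write t-SNE coordinates.
#' @param tsnePath output TSV for the coordinates (default: `path` with a
#'   `_tsne` suffix).
#' @param seed seed for the t-SNE initialization.
#' @param perplexity t-SNE perplexity.
#' @return invisible list with `activations` and (when requested) `tsne`.
#' @export
exportActivations <- function(model, batch, stage, path, tsne = FALSE,
                              tsnePath = NULL, seed = 1L, perplexity = 30) {
  act <- layerActivations(model, batch, stage)
  utils::write.table(
    data.frame(id = rownames(act), act, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(activations = act)
  if (tsne) {
    if (is.null(tsnePath))
      tsnePath <- sub("(\\.[^.]+)?$", "_tsne.tsv", path)
    Y <- tsneEmbed(act, perplexity = perplexity, seed = seed)
    tab <- data.frame(id = rownames(Y), x = Y[, "x"], y = Y[, "y"])
    if (length(batch@labels)) tab$label <- batch@labels
    utils::write.table(tab, tsnePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$tsne <- tab
  }
  invisible(out)
}

#' Write a cross-validation report as a TSV table
#'
#' One row per fold plus a final "Mean" row, columns Sn, Sp, ACC, MCC.
#'
#' @param report a [CVReport-class].
#' @param path output TSV path.
#' @return the written data.frame, invisibly.
#' @export
writeCVReport <- function(report, path) {
  tab <- data.frame(fold = c(as.character(report@folds$fold), "Mean"),
                    rbind(report@folds[, c("Sn", "Sp", "ACC", "MCC")],
                          report@means))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
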