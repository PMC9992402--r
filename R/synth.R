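#' Construct a synthetic benchmark specification
#'
#' Describes a labelled peptide set shaped like the curated epitope
#' benchmarks this package targets: balanced classes, lengths uniform on
#' 11--25 residues, uniform background composition, and a planted
#' class-discriminative motif whose penetrance (fraction of positives
#' carrying it) and contamination (fraction of negatives) set the
#' difficulty.
#'
#' @param nPos,nNeg class sizes (default 500/500).
#' @param lengthRange integer c(min, max) lengths (default c(11, 25)).
#' @param motif planted motif (default "CWKHY", a fixed 5-mer).
#' @param penetrance fraction of positives carrying the motif.
#' @param contamination fraction of negatives carrying the motif
#'   (must be <= penetrance).
#' @param background 20 residue probabilities in A..Y code order
#'   (default uniform).
#' @param seed integer seed.
#' @return a validated [SynthSpec-class].
#' @export
synthSpec <- function(nPos = 500L, nNeg = 500L, lengthRange = c(11L, 25L),
                      motif = "CWKHY", penetrance = 1.0, contamination = 0.0,
                      background = rep(1 / 20, 20), seed = 1L) {
  new("SynthSpec", nPos = as.integer(nPos), nNeg = as.integer(nNeg),
      lengthRange = as.integer(lengthRange), motif = toupper(motif),
      penetrance = penetrance, contamination = contamination,
      background = stats::setNames(background, AA_LETTERS),
      seed = as.integer(seed))
}

#' Generate a synthetic labelled peptide dataset
#'
#' Draws `nPos` positive and `nNeg` negative peptides with lengths uniform
#' on the spec's range and residues from the background distribution.  The
#' motif is written over a uniformly chosen window in exactly
#' `round(penetrance * nPos)` positives and `round(contamination * nNeg)`
#' negatives (round half up); overwriting, rather than insertion, keeps the
#' length distribution exact.  Non-carrier sequences are resampled until
#' they do not contain the motif by chance, so substring counts match the
#' targets exactly for every seed.  Fully deterministic given `spec@seed`.
#'
#' @param spec a [SynthSpec-class].
#' @return labelled record data.frame (`id`, `sequence`, `label`),
#'   positives first.
#' @export
generatePeptides <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  k <- nchar(spec@motif)
  lmin <- spec@lengthRange[1]; lmax <- spec@lengthRange[2]

  drawSeq <- function(len)
    paste(sample(AA_LETTERS, len, replace = TRUE, prob = spec@background),
          collapse = "")
  drawNonCarrier <- function(len) {
    repeat {
      s <- drawSeq(len)
      if (!grepl(spec@motif, s, fixed = TRUE)) return(s)
    }
  }
  drawCarrier <- function(len) {
    s <- strsplit(drawSeq(len), "")[[1]]
    off <- sample.int(len - k + 1L, 1L)
    s[off:(off + k - 1L)] <- strsplit(spec@motif, "")[[1]]
    paste(s, collapse = "")
  }

  makeClass <- function(nTotal, nCarrier, prefix) {
    if (nTotal == 0L) return(character(0))
    lens <- sample(lmin:lmax, nTotal, replace = TRUE)
    carrier <- logical(nTotal)
    if (nCarrier > 0L) carrier[sample.int(nTotal, nCarrier)] <- TRUE
    vapply(seq_len(nTotal), function(i)
      if (carrier[i]) drawCarrier(lens[i]) else drawNonCarrier(lens[i]), "")
  }

  nPosCar <- as.integer(roundHalfUp(spec@penetrance * spec@nPos))
  nNegCar <- as.integer(roundHalfUp(spec@contamination * spec@nNeg))
  posSeq <- makeClass(spec@nPos, nPosCar, "pos")
  negSeq <- makeClass(spec@nNeg, nNegCar, "neg")

  data.frame(
    id = c(sprintf("pos_%d", seq_len(spec@nPos)),
           sprintf("neg_%d", seq_len(spec@nNeg))),
    sequence = c(posSeq, negSeq),
    label = rep(c(1L, 0L), c(spec@nPos, spec@nNeg)))
}

#' Balanced label permutation for null-control training
#'
#' Produces permuted labels that preserve the overall label counts while
#' being exactly independent of the original classes: each original class
#' contributes a proportional share (largest-remainder apportionment) of
#' the positive labels.  This is the exact permutation null for
#' label-shuffled control experiments -- a plain random permutation leaves
#' a chance association between class and permuted label that
#' trained-to-convergence models can amplify.
#'
#' @param labels binary 0/1 label vector.
#' @param seed integer seed for the within-class draws.
#' @return integer 0/1 vector of the same length and total.
#' @export
shuffleLabels <- function(labels, seed = 1L) {
  labels <- as.integer(labels)
  set.seed(seed)
  n1 <- sum(labels == 1L)
  classes <- unique(labels)
  nc <- vapply(classes, function(cl) sum(labels == cl), 0L)
  quota <- n1 * nc / length(labels)
  give <- floor(quota)
  extra <- n1 - sum(give)
  if (extra > 0L) {
    ord <- order(quota - give, decreasing = TRUE)[seq_len(extra)]
    give[ord] <- give[ord] + 1L
  }
  out <- integer(length(labels))
  for (i in seq_along(classes)) {
    idx <- which(labels == classes[i])
    out[idx[sample.int(length(idx), give[i])]] <- 1L
  }
  out
}

#' Length statistics of a record set
#'
#' @param records record data.frame.
#' @return list with integer `min` and `max` and numeric `mean` length.
#' @export
lengthStats <- function(records) {
  if (!nrow(records)) stop("records must be non-empty", call. = FALSE)
  lens <- nchar(records$sequence)
  list(min = min(lens), mean = mean(lens), max = max(lens))
}

#' Write a synthetic dataset as paired FASTA files plus a label table
#'
#' Emits exactly the formats the sequence-I/O module consumes: a positives
#' FASTA, a negatives FASTA and an id<TAB>label TSV.
#'
#' @param records labelled record data.frame.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
writeSynthDataset <- function(records, dir, prefix = "synth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pos = file.path(dir, paste0(prefix, "_pos.fasta")),
             neg = file.path(dir, paste0(prefix, "_neg.fasta")),
             labels = file.path(dir, paste0(prefix, "_labels.tsv")))
  writeFasta(records[records$label == 1L, , drop = FALSE], paths[["pos"]])
  writeFasta(records[records$label == 0L, , drop = FALSE], paths[["neg"]])
  utils::write.table(records[, c("id", "label")], paths[["labels"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(paths)
}
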