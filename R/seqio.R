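## Integer coding of the 20 standard amino acids: padding 'X' = 0, then
## A=1 ... Y=20 in alphabetical order.

#' The 20-letter amino-acid alphabet, in code order (A=1 ... Y=20)
#' @export
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Residue-to-integer code table (X=0, A=1, ..., Y=20)
#' @export
AA_CODES <- stats::setNames(c(0L, seq_along(AA_LETTERS)), c("X", AA_LETTERS))

validateSequences <- function(ids, seqs, what = "record") {
  if (anyDuplicated(ids))
    stop("duplicate ", what, " id '", ids[anyDuplicated(ids)], "'", call. = FALSE)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i]))
      stop("empty sequence for ", what, " '", ids[i], "'", call. = FALSE)
    chars <- strsplit(seqs[i], "")[[1]]
    bad <- setdiff(chars, AA_LETTERS)
    if (length(bad))
      stop("Format Error: record '", ids[i], "' contains illegal character '",
           bad[1], "' (allowed: ", paste(AA_LETTERS, collapse = ""), ")",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Read peptides from a FASTA file
#'
#' Parses a (multi-line) FASTA file of peptides, uppercases the sequences,
#' and validates them against the 20-letter amino-acid alphabet.  The id is
#' the header up to the first whitespace; the rest of the description is
#' ignored.  Any character outside ACDEFGHIKLMNPQRSTVWY (including B, J, O,
#' U, Z and X) is rejected with an error naming the record and the
#' character.
#'
#' @param path path to a FASTA file.
#' @param label optional binary label (0/1) attached to every record.
#' @return data.frame with columns `id`, `sequence`, `label` (NA when no
#'   label was given), one row per FASTA entry in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDY", ">p2", "KLM"), fa)
#' readFasta(fa, label = 1L)
#' @export
readFasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    warning("FASTA file '", path, "' contains no sequences", call. = FALSE)
    return(data.frame(id = character(0), sequence = character(0),
                      label = integer(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (any(!nzchar(ids)))
    stop("malformed FASTA '", path, "': entry ", which(!nzchar(ids))[1],
         " has an empty id", call. = FALSE)
  seqs <- toupper(as.character(set))
  validateSequences(ids, seqs)
  data.frame(id = ids, sequence = unname(seqs),
             label = if (is.null(label)) NA_integer_
                     else rep(as.integer(label), length(ids)))
}

#' Read paired positive/negative FASTA files as one labelled dataset
#'
#' @param posPath FASTA of positives (label 1).
#' @param negPath FASTA of negatives (label 0).
#' @return labelled record data.frame, positives first.
#' @export
readPairedFasta <- function(posPath, negPath) {
  recs <- rbind(readFasta(posPath, label = 1L), readFasta(negPath, label = 0L))
  if (anyDuplicated(recs$id))
    stop("duplicate id across positive/negative files: '",
         recs$id[anyDuplicated(recs$id)], "'", call. = FALSE)
  recs
}

#' Read an id-to-label table (TSV: id<TAB>label) and attach it to records
#'
#' @param records record data.frame from [readFasta()].
#' @param path two-column tab-separated file, no header, id then 0/1 label.
#' @return records with the `label` column filled.
#' @export
readLabels <- function(records, path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = c("character", "integer"))
  if (!all(tab$label %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  miss <- setdiff(records$id, tab$id)
  if (length(miss))
    stop("no label for record '", miss[1], "'", call. = FALSE)
  records$label <- tab$label[match(records$id, tab$id)]
  records
}

#' Integer-encode one peptide to a fixed length
#'
#' Residue i maps to its code (A=1 ... Y=20); positions beyond the peptide
#' length are filled with the padding code 0 ('X').  Sequences longer than
#' `L` are truncated at the tail (first `L` residues kept) with a warning.
#'
#' @param seq peptide string over the 20-letter alphabet (case-insensitive).
#' @param L standardized length, >= 1.
#' @return integer vector of length `L` with entries in `[0, 20]`.
#' @examples
#' encodeSequence("ACDY", L = 6)  # 1 2 3 20 0 0
#' @export
encodeSequence <- function(seq, L = 25L) {
  stopifnot(length(seq) == 1L, L >= 1L)
  seq <- toupper(seq)
  validateSequences("(sequence)", seq, what = "sequence")
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) > L) {
    warning("sequence of length ", length(chars), " truncated to L = ", L,
            call. = FALSE)
    chars <- chars[seq_len(L)]
  }
  unname(c(AA_CODES[chars], rep(0L, L - length(chars))))
}

#' Encode a set of records into a fixed-length integer batch
#'
#' @param records record data.frame (columns `id`, `sequence`, optional
#'   `label`) as returned by [readFasta()] or [generatePeptides()].
#' @param L standardized length (default 25).
#' @return an [EncodedBatch-class]; labels are carried along when present
#'   and non-NA.
#' @export
encodeBatch <- function(records, L = 25L) {
  if (!nrow(records)) stop("records must be non-empty", call. = FALSE)
  codes <- t(vapply(records$sequence, encodeSequence, integer(L), L = L))
  dimnames(codes) <- NULL
  labels <- if (!is.null(records$label) && !anyNA(records$label))
    as.integer(records$label) else integer(0)
  new("EncodedBatch", codes = codes, ids = records$id, labels = labels)
}

## subset a batch by row index, keeping labels aligned
batchSubset <- function(batch, idx) {
  new("EncodedBatch", codes = batch@codes[idx, , drop = FALSE],
      ids = batch@ids[idx],
      labels = if (length(batch@labels)) batch@labels[idx] else integer(0))
}

#' Decode an encoded row back to a peptide string (padding stripped)
#'
#' @param codes integer vector with entries in `[0, 20]`.
#' @return peptide string.
#' @export
decodeSequence <- function(codes) {
  codes <- codes[codes != 0L]
  paste(AA_LETTERS[codes], collapse = "")
}

#' Write a prediction table
#'
#' Writes a tab-separated table with columns id, sequence, probability and
#' call ("BCE" when probability >= threshold, else "non-BCE"; ties at the
#' threshold classify positive).  Row order follows the input.
#'
#' @param records record data.frame.
#' @param probabilities numeric vector in `[0, 1]`, one per record.
#' @param threshold decision threshold (default 0.5).
#' @param path output file path.
#' @return the written table, invisibly.
#' @export
writePredictions <- function(records, probabilities, threshold = 0.5, path) {
  if (length(probabilities) != nrow(records))
    stop("need one probability per record (", nrow(records), " records, ",
         length(probabilities), " probabilities)", call. = FALSE)
  if (length(probabilities) &&
      (any(probabilities < 0) || any(probabilities > 1)))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  out <- data.frame(id = records$id, sequence = records$sequence,
                    probability = probabilities,
                    call = ifelse(probabilities >= threshold, "BCE", "non-BCE"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write records as FASTA
#'
#' @param records record data.frame.
#' @param path output FASTA path.
#' @export
writeFasta <- function(records, path) {
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
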