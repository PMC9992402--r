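#!/usr/bin/env Rscript

## Optional reproduction on the curated epitope benchmarks.
##
## The benchmark FASTA files (a 555+555 training set and two independent
## test sets) are distributed as supplementary material of the BCEPS study
## at https://www.mdpi.com/article/10.3390/cells10102744/s1 and are NOT
## bundled here.  Download them, export the training set as paired FASTA
## files, and run:
##
##   Rscript scripts/reproduce_benchmark.R --pos train_pos.fasta \
##       --neg train_neg.fasta --out-dir results/benchmark
##
## This performs the default 10-fold cross-validation.  Training is
## stochastic, so expect mean metrics in the vicinity of (not identical
## to) published values.

suppressPackageStartupMessages(library(linearBCE))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i)) args[i + 1L] else default
}
posPath <- getArg("--pos"); negPath <- getArg("--neg")
outDir <- getArg("--out-dir", "results/benchmark")
seed <- as.integer(getArg("--seed", "1"))

if (is.null(posPath) || is.null(negPath) ||
    !file.exists(posPath) || !file.exists(negPath)) {
  message("benchmark FASTA files not supplied or not found; see the header ",
          "of this script for where to obtain them")
  quit(status = 0, save = "no")
}

dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
recs <- readPairedFasta(posPath, negPath)
message("loaded ", nrow(recs), " peptides")
cfg <- modelConfig(seed = seed)
cv <- kfoldCV(recs, cfg, k = 10L, verbose = TRUE)
writeCVReport(cv, file.path(outDir, "cv_report.tsv"))
print(cv)
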