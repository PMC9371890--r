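#!/usr/bin/env Rscript
# Stage 3: align consensus sequences to the germline V reference, call
# point mutations with hotspot subtypes, and group sequences into CDR3
# clones.

suppressPackageStartupMessages(library(shmspectra))

dat <- "results/data"
cons <- "results/consensus"
out <- "results/annotation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

germline <- read_germline(file.path(dat, "germline.fasta"),
                          file.path(dat, "germline_regions.tsv"))

for (g in c("WT-like", "DA-like", "KO-like")) {
  slug <- gsub("[^A-Za-z0-9]+", "_", g)
  consensus <- read_consensus_fasta(file.path(cons, paste0(slug, "_consensus.fasta")))
  ann <- annotate_repertoire(consensus, germline, max_mismatch_frac = 0.15)
  grp <- group_clones(ann$sequences)
  write.table(ann$mutations, file.path(out, paste0(slug, "_mutations.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(grp$sequences, file.path(out, paste0(slug, "_sequences.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(grp$clones, file.path(out, paste0(slug, "_clones.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  by_sub <- table(factor(ann$mutations$subtype,
                         levels = c("GC_AID_HOT", "GC_OTHER",
                                    "AT_POL_HOT", "AT_OTHER")))
  cat(sprintf("%s: %d sequences (%d rejected), %d clones; mutations %s\n",
              g, nrow(grp$sequences), nrow(ann$rejected), nrow(grp$clones),
              paste(names(by_sub), by_sub, sep = "=", collapse = " ")))
}
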