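#!/usr/bin/env Rscript
# Stage 2: assemble read pairs and collapse them by UMI into one consensus
# sequence per input molecule. Ties inside a UMI family become N and are
# excluded from downstream mutation calling.

suppressPackageStartupMessages(library(shmspectra))

dat <- "results/data"
out <- "results/consensus"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (g in c("WT-like", "DA-like", "KO-like")) {
  slug <- gsub("[^A-Za-z0-9]+", "_", g)
  reads <- read_fastq_pairs(file.path(dat, paste0(slug, "_R1.fastq")),
                            file.path(dat, paste0(slug, "_R2.fastq")))
  col <- collapse_reads(reads, umi_length = 8, min_overlap = 20,
                        max_mismatch_frac = 0.1, min_family_size = 1)
  write_consensus_fasta(col$consensus,
                        file.path(out, paste0(slug, "_consensus.fasta")))
  rej <- rbind(
    data.frame(record = col$rejected_pairs$read_id,
               reason = col$rejected_pairs$reason),
    data.frame(record = col$rejected_families$umi,
               reason = col$rejected_families$reason))
  write.table(rej, file.path(out, paste0(slug, "_rejects.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_amb <- sum(grepl("N", col$consensus$sequence, fixed = TRUE))
  cat(sprintf("%s: %d read pairs -> %d UMI families (%d rejected records, %d consensi with ties)\n",
              g, nrow(reads), nrow(col$consensus), nrow(rej), n_amb))
}
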