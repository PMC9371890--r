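#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with recorded ground truth.
#
# Three mouse-like cohorts are simulated around one germline V reference:
# a WT-like genotype with strong A:T (Pol-eta hotspot) mutagenesis, and two
# repair-compromised genotypes (DA-like, KO-like) with reduced A:T and
# elevated G:C (AID hotspot) mutagenesis. Each repertoire is emitted as
# UMI-tagged paired FASTQ; switch-junction cohorts and per-animal switching
# fractions accompany them.

suppressPackageStartupMessages(library(shmspectra))

seed <- 17L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
tsv <- function(df, f) write.table(df, file.path(out, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)

germline <- make_germline(length = 294, gc_fraction = 0.5, seed = seed)
write_germline(germline, file.path(out, "germline.fasta"),
               file.path(out, "germline_regions.tsv"))
cat("germline:", nchar(germline$sequence), "bases;",
    sum(germline$subtype_mask == "GC_AID_HOT"), "AID-hotspot and",
    sum(germline$subtype_mask == "AT_POL_HOT"), "Pol-eta-hotspot sites\n")

profiles <- default_profiles()
mixtures <- default_junction_mixtures()
for (gi in seq_along(profiles)) {
  g <- names(profiles)[gi]
  slug <- gsub("[^A-Za-z0-9]+", "_", g)
  sim <- simulate_repertoire(germline, profiles[[g]], n_clones = 150,
                             inherited_fraction = 0.2, seed = seed + 10L * gi)
  rd <- simulate_reads(sim$sequences, reads_per_molecule = 2,
                       error_rate = 0.001, seed = seed + 10L * gi + 1L)
  write_fastq_pairs(rd$reads, file.path(out, paste0(slug, "_R1.fastq")),
                    file.path(out, paste0(slug, "_R2.fastq")))
  tsv(rd$umi_map, paste0(slug, "_umi_map.tsv"))
  tsv(sim$truth$mutations, paste0(slug, "_truth_mutations.tsv"))
  tsv(sim$truth$clones, paste0(slug, "_truth_clones.tsv"))

  js <- simulate_junctions(mixtures[[g]], 40, seed = seed + 10L * gi + 2L)
  write_fasta(js$junctions, file.path(out, paste0(slug, "_junctions.fasta")))
  write_fasta(c(donor = js$donor, acceptor = js$acceptor),
              file.path(out, paste0(slug, "_junction_refs.fasta")))
  tsv(js$truth, paste0(slug, "_junction_truth.tsv"))

  cat(sprintf("%s: %d molecules in %d clones, %d true mutations; %d junctions\n",
              g, length(sim$sequences), nrow(sim$truth$clones),
              nrow(sim$truth$mutations), length(js$junctions)))
}

# per-animal switched-cell fractions (LPS-driven IgG3-like switching)
csr <- rbind(
  data.frame(genotype = "WT-like",
             fraction = simulate_csr_counts(0.30, 10000, 8, seed + 91L)),
  data.frame(genotype = "DA-like",
             fraction = simulate_csr_counts(0.12, 10000, 8, seed + 92L)),
  data.frame(genotype = "KO-like",
             fraction = simulate_csr_counts(0.12, 10000, 5, seed + 93L)))
tsv(csr, "csr_fractions.tsv")
cat("wrote per-animal switching fractions for",
    length(unique(csr$genotype)), "genotypes\n")
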