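test_that("hotspot classification follows the WRC/GYW and WA/TW motifs", {
  # C at index 4 sits in trinucleotide AGC = W,R,C; G at index 3 starts GCT = G,Y,W
  expect_equal(classify_site("AAGCT", 4), "GC_AID_HOT")
  expect_equal(classify_site("AAGCT", 3), "GC_AID_HOT")
  # A preceded by C (not W) stays non-hotspot; A preceded by T (W) is a hotspot
  expect_equal(classify_site("CCA", 3), "AT_OTHER")
  expect_equal(classify_site("TA", 2), "AT_POL_HOT")
  expect_equal(classify_sites("AAGCT"),
               c("AT_OTHER", "AT_POL_HOT", "GC_AID_HOT", "GC_AID_HOT",
                 "AT_OTHER"))
  # context positions outside the sequence never match
  expect_equal(classify_site("CG", 1), "GC_OTHER")
  expect_error(classify_site("ACGT", 5), "out of range")
})

test_that("subtype mask partitions every germline and respects composition", {
  for (seed in 1:5) {
    g <- make_germline(length = 294, gc_fraction = 0.5, seed = seed)
    counts <- table(factor(g$subtype_mask, levels = c(
      "GC_AID_HOT", "GC_OTHER", "AT_POL_HOT", "AT_OTHER")))
    expect_equal(sum(counts), 294)
    gc_sites <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
    expect_equal(unname(counts["GC_AID_HOT"] + counts["GC_OTHER"]),
                 gc_sites)
  }
  g0 <- make_germline(length = 120, gc_fraction = 0, seed = 2)
  expect_true(all(strsplit(g0$sequence, "")[[1]] %in% c("A", "T")))
  expect_equal(sum(g0$subtype_mask %in% c("GC_AID_HOT", "GC_OTHER")), 0)
})

test_that("hotspot counts are invariant under reverse complement", {
  # WRC<->GYW and WA<->TW are mutual reverse complements, so total hotspot
  # counts per class must survive reverse-complementing the sequence
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  for (seed in 1:5) {
    g <- make_germline(length = 200, gc_fraction = 0.45, seed = seed)
    fw <- table(factor(classify_sites(g$sequence),
                       levels = c("GC_AID_HOT", "AT_POL_HOT")))
    rc <- table(factor(classify_sites(revcomp(g$sequence)),
                       levels = c("GC_AID_HOT", "AT_POL_HOT")))
    expect_equal(fw, rc)
  }
})

test_that("germline construction validates regions and matches the V span", {
  g <- make_germline(length = 294, seed = 1)
  expect_equal(nchar(g$sequence), 294)  # span of the V readout locus
  expect_error(
    make_germline(length = 100, regions = data.frame(
      label = c("FR1", "CDR1"), start = c(1, 40), end = c(50, 90))),
    "overlap")
  expect_error(
    make_germline(length = 100, regions = data.frame(
      label = "FR1", start = 1, end = 150)),
    "out of range")
})

test_that("a zero-rate profile yields unmutated sequences with empty truth", {
  g <- make_germline(seed = 1)
  p0 <- genotype_profile("null", 0, 0, 0, 0)
  sim <- simulate_repertoire(g, p0, n_clones = 10, seed = 2)
  expect_equal(nrow(sim$truth$mutations), 0)
  tag <- cdr3_interval(g)
  body <- function(s) paste0(substr(s, 1, min(tag) - 1))
  expect_true(all(vapply(sim$sequences, body, "") == body(g$sequence)))
})

test_that("truth mutations equal sequence mismatches and are clone-shared", {
  g <- make_germline(seed = 3)
  prof <- default_profiles()[["WT-like"]]
  sim <- simulate_repertoire(g, prof, n_clones = 40,
                             clone_size_dist = function(n) sample(1:4, n, TRUE),
                             inherited_fraction = 0.5, seed = 4)
  tag <- cdr3_interval(g)
  gch <- strsplit(g$sequence, "")[[1]]
  by_mol <- split(sim$truth$mutations, sim$truth$mutations$molecule_id)
  for (id in names(sim$sequences)) {
    sch <- strsplit(sim$sequences[[id]], "")[[1]]
    mism <- setdiff(which(sch != gch), tag)
    tr <- by_mol[[id]]
    expect_equal(sort(mism), sort(if (is.null(tr)) integer(0) else tr$position))
  }
  # inherited mutations are shared by every member of the clone
  inh <- sim$truth$mutations[sim$truth$mutations$inherited, ]
  if (nrow(inh)) {
    key <- paste(inh$clone_id, inh$position, inh$to_base)
    carriers <- tapply(inh$molecule_id, key, function(x) length(unique(x)))
    clone_size <- setNames(sim$truth$clones$size, sim$truth$clones$clone_id)
    expect_equal(as.vector(carriers),
                 unname(clone_size[sub(" .*", "", names(carriers))]))
  }
})

test_that("hotspot mutation counts follow the configured binomial rate", {
  g <- make_germline(seed = 5)
  n_hot <- sum(g$subtype_mask[setdiff(seq_len(294), cdr3_interval(g))] ==
                 "GC_AID_HOT")
  n_mol <- ceiling(200 / n_hot) * 10  # ~ several hundred opportunities
  prof <- genotype_profile("gc-only", 0.02, 0, 0, 0)
  sim <- simulate_repertoire(g, prof, n_clones = n_mol, clone_size_dist = 1,
                             inherited_fraction = 0, seed = 6)
  opp <- n_hot * n_mol
  bounds <- binom_central(opp, 0.02, 0.99)
  count <- sum(sim$truth$mutations$subtype == "GC_AID_HOT")
  expect_equal(nrow(sim$truth$mutations), count)  # only G:C hotspots mutate
  expect_gte(count, bounds[1])
  expect_lte(count, bounds[2])
})

test_that("read simulation assigns distinct UMIs and validates geometry", {
  g <- make_germline(seed = 7)
  sim <- simulate_repertoire(g, default_profiles()[["WT-like"]],
                             n_clones = 30, seed = 8)
  rd <- simulate_reads(sim$sequences, umi_length = 8, reads_per_molecule = 2,
                       error_rate = 0, seed = 9)
  expect_equal(anyDuplicated(rd$umi_map$umi), 0)
  expect_equal(nrow(rd$reads), 2 * length(sim$sequences))
  expect_error(simulate_reads(sim$sequences, read_length = 400, seed = 1),
               "exceeds molecule length")
  expect_error(simulate_reads(sim$sequences, read_length = 150,
                              min_overlap = 60, seed = 1),
               "shorter than min_overlap")
})

test_that("junction mixtures produce the labelled outcomes", {
  blunt_only <- junction_mixture(1, 0, 0)
  js <- simulate_junctions(blunt_only, 30, seed = 10)
  expect_true(all(js$truth$score == 0))

  ins2 <- junction_mixture(0, 0, 1, ins_lengths = c(0, 1))
  ji <- simulate_junctions(ins2, 30, seed = 11)
  expect_true(all(ji$truth$score == -2))

  half <- junction_mixture(0.5, 0.3, 0.2)
  jh <- simulate_junctions(half, 100, seed = 12)
  n_blunt <- sum(jh$truth$score == 0)
  bounds <- binom_central(100, 0.5, 0.99)
  expect_gte(n_blunt, bounds[1])
  expect_lte(n_blunt, bounds[2])
})

test_that("junction mixture probabilities are validated", {
  expect_error(junction_mixture(0.5, 0.4, 0.2), "must equal 1")
  expect_error(junction_mixture(0.5, 0.5, 0, mh_lengths = c(-1, 2)),
               "non-negative")
})

test_that("per-animal switch fractions follow the binomial model", {
  expect_true(all(simulate_csr_counts(0, 1000, 5, seed = 1) == 0))
  expect_true(all(simulate_csr_counts(1, 1000, 5, seed = 2) == 1))
  fr <- simulate_csr_counts(0.3, 10000, 50, seed = 3)
  se <- sqrt(0.3 * 0.7 / 10000) / sqrt(50)
  expect_lt(abs(mean(fr) - 0.3), 3 * se)
})

test_that("fastq round trip preserves reads and qualities", {
  g <- make_germline(seed = 13)
  sim <- simulate_repertoire(g, default_profiles()[["WT-like"]],
                             n_clones = 5, seed = 14)
  rd <- simulate_reads(sim$sequences, seed = 15)
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  write_fastq_pairs(rd$reads, r1, r2)
  back <- read_fastq_pairs(r1, r2)
  expect_equal(back$r1_seq, rd$reads$r1_seq)
  expect_equal(back$r2_seq, rd$reads$r2_seq)
  expect_equal(back$r1_qual, rd$reads$r1_qual)
  unlink(c(r1, r2))
})
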