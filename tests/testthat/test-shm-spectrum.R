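test_that("eligible site counts partition the filtered germline", {
  toy <- toy_germline("AAGCT")
  S <- eligible_site_counts(toy)
  expect_equal(unname(S), c(2L, 0L, 1L, 2L))  # by classify_site on all 5
  expect_equal(sum(S), 5)

  at_only <- toy_germline("ATTATA")
  S2 <- eligible_site_counts(at_only)
  expect_equal(unname(S2[c("GC_AID_HOT", "GC_OTHER")]), c(0L, 0L))

  g <- make_germline(seed = 51)
  Sg <- eligible_site_counts(g)
  expect_equal(sum(Sg), 294 - length(cdr3_interval(g)))
  Scdr <- eligible_site_counts(g, region_filter = c("CDR1", "CDR2"))
  r <- g$regions
  expect_equal(sum(Scdr),
               sum((r$end - r$start + 1)[r$label %in% c("CDR1", "CDR2")]))
})

test_that("iteration frequencies normalise to the potential maximum", {
  toy <- toy_germline("AAGCT")  # S_GC_AID_HOT = 2
  muts <- data.frame(seq_id = "s1", position = 4L, subtype = "GC_AID_HOT")
  f <- iteration_frequencies("s1", muts, toy)
  expect_equal(unname(f["GC_AID_HOT"]), 0.5)  # 1 / (2 sites x 1 seq)
  expect_equal(unname(f["AT_POL_HOT"]), 0)
  expect_true(is.na(f["GC_OTHER"]))  # zero eligible sites: undefined, not 0

  none <- iteration_frequencies("s1", muts[0, ], toy)
  expect_equal(unname(none[c("GC_AID_HOT", "AT_POL_HOT", "AT_OTHER")]),
               c(0, 0, 0))

  # upper bound attained: every eligible site mutated in every sequence
  all_mut <- data.frame(seq_id = rep(c("a", "b"), each = 2),
                        position = rep(c(3L, 4L), 2),
                        subtype = "GC_AID_HOT")
  f_max <- iteration_frequencies(c("a", "b"), all_mut, toy)
  expect_equal(unname(f_max["GC_AID_HOT"]), 1)
})

test_that("resampling picks one member per clone uniformly", {
  singles <- list(c1 = "a", c2 = "b", c3 = "c")
  expect_equal(resample_iteration(singles), c(c1 = "a", c2 = "b", c3 = "c"))

  set.seed(7); first <- resample_iteration(list(c1 = c("x", "y")))
  set.seed(7); second <- resample_iteration(list(c1 = c("x", "y")))
  expect_equal(first, second)

  # clone sizes {2,2}: each member should appear about half the time
  clones <- list(c1 = c("a1", "a2"), c2 = c("b1", "b2"))
  set.seed(8)
  draws <- replicate(2000, resample_iteration(clones))
  frac_a1 <- mean(draws["c1", ] == "a1")
  bounds <- binom_central(2000, 0.5, 0.999) / 2000
  expect_gte(frac_a1, bounds[1])
  expect_lte(frac_a1, bounds[2])
  expect_error(resample_iteration(list(c1 = character(0))), "non-empty")
})

test_that("aggregation bounds, degenerate SD and positional scaling hold", {
  g <- make_germline(seed = 52)
  sim <- simulate_repertoire(g, default_profiles()[["WT-like"]],
                             n_clones = 60, clone_size_dist = 1,
                             inherited_fraction = 0, seed = 53)
  ann <- annotated_from_truth(sim$truth)
  spec <- aggregate_spectrum(ann, g, spectrum_config(50, seed = 54))
  # all clones size 1: every iteration identical, zero resampling variance
  expect_equal(unname(spec$summary$sd), rep(0, 4))
  expect_true(all(spec$per_iteration >= 0 & spec$per_iteration <= 1))
  for (s in colnames(spec$per_iteration)) {
    m <- spec$summary$mean[spec$summary$subtype == s]
    expect_gte(m, min(spec$per_iteration[, s]))
    expect_lte(m, max(spec$per_iteration[, s]))
  }
  # positional profile peaks at exactly 1 for every mutated subtype
  present <- unique(ann$mutations$subtype)
  for (s in present) {
    v <- spec$positional$value[spec$positional$subtype == s]
    expect_equal(max(v), 1)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("spectra are bit-reproducible under a fixed seed", {
  g <- make_germline(seed = 55)
  sim <- simulate_repertoire(g, default_profiles()[["WT-like"]],
                             n_clones = 40,
                             clone_size_dist = function(n) sample(1:3, n, TRUE),
                             seed = 56)
  ann <- annotated_from_truth(sim$truth)
  a <- aggregate_spectrum(ann, g, spectrum_config(40, seed = 57))
  b <- aggregate_spectrum(ann, g, spectrum_config(40, seed = 57))
  expect_identical(a$per_iteration, b$per_iteration)
  expect_identical(a$summary, b$summary)
  expect_identical(a$positional, b$positional)
})

test_that("resampling de-inflates clonal mutations to the closed form", {
  # one 10-member clone carrying an inherited hotspot mutation among 50
  # singletons: the resampled frequency must match counting the clone once
  g <- make_germline(seed = 58)
  hot <- setdiff(which(g$subtype_mask == "GC_AID_HOT"), cdr3_interval(g))[1]
  n_singles <- 50
  mols <- data.frame(
    molecule_id = sprintf("m%03d", 1:(n_singles + 10)),
    clone_id = c(sprintf("c%03d", 1:n_singles), rep("cBIG", 10)))
  muts <- data.frame(seq_id = mols$molecule_id[(n_singles + 1):(n_singles + 10)],
                     position = hot, subtype = "GC_AID_HOT")
  ann <- list(sequences = data.frame(seq_id = mols$molecule_id,
                                     clone_id = mols$clone_id),
              mutations = muts)
  spec <- aggregate_spectrum(ann, g, spectrum_config(200, seed = 59))
  S <- eligible_site_counts(g)
  n_clones <- n_singles + 1
  closed_form <- 1 / (S[["GC_AID_HOT"]] * n_clones)
  got <- spec$summary$mean[spec$summary$subtype == "GC_AID_HOT"]
  expect_equal(got, closed_form)  # every draw carries the mutation: exact
  naive <- 10 / (S[["GC_AID_HOT"]] * (n_singles + 10))
  expect_gt(naive / got, 8)  # naive pooling inflates ~10x here
})

test_that("genotype contrasts apply the Yates-corrected chi-square", {
  # identical tables: statistic clamps to 0, p = 1
  mk_result <- function(mean_counts, S, n_seq) {
    structure(list(summary = NULL,
                   per_iteration = NULL, positional = NULL,
                   site_counts = S, n_seq = n_seq,
                   mean_counts = mean_counts,
                   config = spectrum_config(1)), class = "spectrum_result")
  }
  S <- setNames(c(25L, 100L, 60L, 94L),
                c("GC_AID_HOT", "GC_OTHER", "AT_POL_HOT", "AT_OTHER"))
  a <- mk_result(setNames(c(10, 10, 10, 10), names(S)), S, 4L)
  ct_same <- compare_genotypes(a, a)
  expect_equal(ct_same$statistic, rep(0, 4))
  expect_equal(ct_same$p_value, rep(1, 4))

  # hand-computed Yates statistic for the table [[20,80],[5,95]]
  b <- mk_result(setNames(c(20, 10, 10, 10), names(S)), S, 4L)
  c_ <- mk_result(setNames(c(5, 10, 10, 10), names(S)), S, 4L)
  tab <- rbind(c(20, 80), c(5, 95))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((abs(tab - E) - 0.5)^2 / E)
  ct <- compare_genotypes(b, c_)
  expect_equal(ct$statistic[1], stat_hand)
  expect_equal(ct$p_value[1], pchisq(stat_hand, 1, lower.tail = FALSE))
  # symmetry: swapping the genotypes leaves the statistic unchanged
  expect_equal(compare_genotypes(c_, b)$statistic, ct$statistic)
})

test_that("spectra from matched profiles recover the configured rates", {
  g <- make_germline(seed = 60)
  mu <- c(GC_AID_HOT = 0.02, GC_OTHER = 0.005,
          AT_POL_HOT = 0.015, AT_OTHER = 0.003)
  prof <- genotype_profile("recovery", mu[1], mu[2], mu[3], mu[4])
  sim <- simulate_repertoire(g, prof, n_clones = 400, clone_size_dist = 1,
                             inherited_fraction = 0, seed = 61)
  ann <- annotated_from_truth(sim$truth)
  spec <- aggregate_spectrum(ann, g, spectrum_config(10, seed = 62))
  S <- eligible_site_counts(g)
  for (s in names(mu)) {
    se <- sqrt(mu[[s]] * (1 - mu[[s]]) / (S[[s]] * 400))
    got <- spec$summary$mean[spec$summary$subtype == s]
    expect_lt(abs(got - mu[[s]]), 3 * se)
  }
})
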