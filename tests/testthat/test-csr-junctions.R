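rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

test_that("junction scoring calls blunt, microhomology and insertion", {
  set.seed(201)
  donor <- rand_seq(80)
  acceptor <- rand_seq(80)

  # blunt by construction (retry seeds the boundary can accidentally extend)
  j_blunt <- paste0(substr(donor, 1, 30), substr(acceptor, 41, 70))
  sb <- score_junction(j_blunt, donor, acceptor)
  expect_true(sb$resolved)
  expect_equal(sb$score, brute_force_score(j_blunt, donor, acceptor)$score)

  # engineered 3-base microhomology: acceptor carries donor[28..30]
  acc_mh <- paste0(substr(acceptor, 1, 39), substr(donor, 28, 30),
                   substr(acceptor, 43, 80))
  j_mh <- paste0(substr(donor, 1, 30), substr(acc_mh, 43, 72))
  smh <- score_junction(j_mh, donor, acc_mh)
  oracle <- brute_force_score(j_mh, donor, acc_mh)
  expect_equal(smh$score, oracle$score)
  expect_gte(smh$score, 3)

  # untemplated 2-mer: force both boundary bases to match neither flank
  ins <- "CC"
  while (substr(ins, 1, 1) == substr(donor, 31, 31) ||
         substr(ins, 2, 2) == substr(acceptor, 40, 40)) {
    ins <- rand_seq(2)
  }
  j_ins <- paste0(substr(donor, 1, 30), ins, substr(acceptor, 41, 70))
  sin <- score_junction(j_ins, donor, acceptor)
  expect_equal(sin$score, brute_force_score(j_ins, donor, acceptor)$score)
  expect_lte(sin$score, 0)

  # anchors below the minimum are unresolved, not mis-scored
  j_short <- paste0(rand_seq(25), substr(acceptor, 41, 70))
  s_un <- score_junction(j_short, donor, acceptor, anchor_min = 26)
  expect_false(s_un$resolved)
  expect_true(is.na(s_un$score))
})

test_that("decomposition conserves junction length on simulated cohorts", {
  mix <- default_junction_mixtures()[["DA-like"]]
  js <- simulate_junctions(mix, 60, seed = 202)
  sj <- score_junctions(js$junctions, js$donor, js$acceptor)
  expect_true(all(sj$resolved))
  # prefix + suffix - overlap + insertion = junction length
  lens <- unname(nchar(js$junctions))
  expect_equal(sj$prefix_len + sj$suffix_len - pmax(sj$score, 0L) +
                 pmax(-sj$score, 0L), lens)
  expect_equal(nchar(sj$insert), pmax(-sj$score, 0L))
})

test_that("scorer matches exhaustive enumeration on random junctions", {
  mixes <- default_junction_mixtures()
  agree <- 0L; total <- 0L
  for (i in 1:3) {
    mix <- mixes[[i]]
    small_mix <- junction_mixture(mix$p_blunt, mix$p_mh, mix$p_ins,
                                  mh_lengths = mix$mh_lengths[1:4],
                                  ins_lengths = mix$ins_lengths)
    js <- simulate_junctions(small_mix, 40, donor = NULL, acceptor = NULL,
                             seed = 210 + i, prefix_range = c(15L, 22L),
                             suffix_range = c(15L, 22L))
    for (k in seq_along(js$junctions)) {
      got <- score_junction(js$junctions[[k]], js$donor, js$acceptor)
      want <- brute_force_score(js$junctions[[k]], js$donor, js$acceptor)
      total <- total + 1L
      agree <- agree + as.integer(identical(got$score, want$score) &&
                                    got$resolved == want$resolved)
    }
  }
  expect_equal(agree, total)
})

test_that("junction truth labels are recovered exactly", {
  for (g in names(default_junction_mixtures())) {
    js <- simulate_junctions(default_junction_mixtures()[[g]], 80,
                             seed = 220 + match(g, names(default_junction_mixtures())))
    sj <- score_junctions(js$junctions, js$donor, js$acceptor)
    expect_true(all(sj$resolved))
    expect_equal(sj$score, js$truth$score)
  }
})

test_that("insertion frequency is the negative-score proportion", {
  expect_equal(insertion_frequency(c(0, 1, 2, 5)), 0)
  expect_equal(insertion_frequency(c(-1, -2, -3)), 1)
  expect_equal(insertion_frequency(c(rep(-1, 3), rep(0, 10), rep(2, 12))),
               0.12)
  expect_error(insertion_frequency(numeric(0)), "no resolved")
})

test_that("identical cohorts give a null Kruskal-Wallis result", {
  res <- compare_mh_distributions(list(a = c(0, 1, 2), b = c(0, 1, 2)))
  expect_equal(res$H, 0)
  expect_equal(res$p_value, 1)
  res0 <- compare_mh_distributions(list(a = c(3, 3), b = c(3, 3)))
  expect_equal(res0$H, 0)
  expect_equal(res0$p_value, 1)
  expect_true(all(res0$dunn$p_value == 1))
})

test_that("the exact permutation p matches full enumeration of assignments", {
  # {0,0,0} vs {5,5,5}: of the 20 equal-size assignments only the 2 fully
  # separated ones reach the observed H, so p = 2/20
  res <- compare_mh_distributions(list(a = c(0, 0, 0), b = c(5, 5, 5)),
                                  exact = TRUE)
  expect_equal(res$p_value, 0.1)
})

test_that("Dunn post-tests use tie-corrected rank statistics", {
  set.seed(230)
  cohorts <- list(a = c(0, 0, 1, 2, 2, 3), b = c(2, 3, 3, 4, 5, 5),
                  c = c(0, 1, 1, 2, 4, 4))
  res <- compare_mh_distributions(cohorts, p_adjust = "bonferroni")
  # recompute one pair by hand
  values <- unlist(cohorts); grp <- rep(names(cohorts), each = 6)
  r <- rank(values); N <- length(values)
  ties <- table(r)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / 6 + 1 / 6))
  z_ab <- (mean(r[grp == "a"]) - mean(r[grp == "b"])) / se
  row <- res$dunn[res$dunn$group_a == "a" & res$dunn$group_b == "b", ]
  expect_equal(row$z, z_ab)
  expect_equal(row$p_value, 2 * pnorm(-abs(z_ab)))
  expect_equal(row$p_adjusted, min(1, 3 * row$p_value))
})

test_that("insertion-frequency contrasts follow the Fisher exact law", {
  # zero margin: p = 1 by convention
  res0 <- compare_insertion_frequencies(rep(0, 10), rep(1, 12))
  expect_equal(res0$p_value, 1)

  # [[5,0],[0,5]]: p = 2/choose(10,5)
  res <- compare_insertion_frequencies(rep(-1, 5), rep(0, 5))
  expect_equal(res$p_value, 2 / choose(10, 5))

  # transpose invariance
  a <- c(rep(-1, 4), rep(0, 9)); b <- c(rep(-2, 2), rep(3, 11))
  expect_equal(compare_insertion_frequencies(a, b)$p_value,
               compare_insertion_frequencies(b, a)$p_value)
  # and both match explicit hypergeometric enumeration
  tab <- compare_insertion_frequencies(a, b)$table
  expect_equal(compare_insertion_frequencies(a, b)$p_value,
               fisher_enum_p(tab))
})

test_that("relative switching efficiency rescales to the reference mean", {
  ref <- c(0.2, 0.4)
  expect_equal(relative_csr_efficiency(0.3, ref), 100)
  expect_equal(relative_csr_efficiency(0, ref), 0)
  expect_equal(relative_csr_efficiency(0.15, ref), 50)
  expect_equal(relative_csr_efficiency(c(0.3, 0.6), ref), c(100, 200))
  expect_error(relative_csr_efficiency(0.1, numeric(0)), "empty")
  expect_error(relative_csr_efficiency(0.1, c(0, 0)), "positive")
})

test_that("integer percentages round half away from zero", {
  expect_equal(proportion_percent(14, 24), 58L)
  expect_equal(proportion_percent(17, 17), 100L)
  expect_equal(proportion_percent(0, 24), 0L)
  expect_equal(proportion_percent(1, 8), 13L)   # 12.5 rounds up
  expect_equal(proportion_percent(3, 24), 13L)
  expect_error(proportion_percent(5, 0), ">= 1")
  expect_error(proportion_percent(-1, 10), "\\[0, n\\]")
})

test_that("cohort summaries bin long microhomologies only for reporting", {
  sc <- c(-3, -1, 0, 0, 2, 2, 5, 12, 15)
  s <- summarize_junction_cohort(sc, "WT-like")
  expect_equal(s$n, 9L)
  expect_equal(s$n_blunt, 2L)
  expect_equal(s$n_mh, 5L)
  expect_equal(s$n_long_mh, 2L)
  expect_equal(s$n_ins, 2L)
  expect_equal(s$insertion_freq, 2 / 9)
})
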