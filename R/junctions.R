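# longest k such that the length-k prefix (or suffix) of `x` occurs in
# `subject`; occurrence is monotone in k, so binary search on substring hits
.longest_match <- function(x, subject, from_start = TRUE) {
  n <- min(nchar(x), nchar(subject))
  piece <- function(k) if (from_start) substr(x, 1L, k) else
    substr(x, nchar(x) - k + 1L, nchar(x))
  occurs <- function(k) grepl(piece(k), subject, fixed = TRUE)
  if (n < 1L || !occurs(1L)) return(0L)
  lo <- 1L; hi <- n
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (occurs(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Score a switch junction against donor and acceptor references
#'
#' Decomposes a junction sequence into a donor-derived prefix and an
#' acceptor-derived suffix by exact matching: the longest junction prefix
#' occurring contiguously in the donor (leftmost occurrence on ties) and
#' the longest suffix occurring in the acceptor. If prefix and suffix
#' overlap by k bases the junction used a k-base microhomology (score +k);
#' if they abut it is blunt (score 0); if g bases lie between them they are
#' untemplated insertion (score -g). Because both anchors are maximal, an
#' overlap call is always the longest decomposition and an insertion call
#' cannot be shortened — the conservative convention for microhomology-
#' biased repair calls. Junctions whose maximal prefix or suffix anchor is
#' shorter than `anchor_min` are reported unresolved and excluded from
#' distributions.
#'
#' @param junction Junction sequence (>= 20 bases).
#' @param donor,acceptor Reference sequences flanking the break.
#' @param anchor_min Minimum anchor length for a resolvable junction.
#' @return A list with `score` (signed integer, `NA` if unresolved),
#'   `resolved`, `prefix_len`, `suffix_len`, `donor_break` (1-based end of
#'   the donor anchor in the donor), `acceptor_break` (1-based start of the
#'   acceptor anchor in the acceptor), and `insert` (the untemplated bases,
#'   `""` unless score < 0).
#' @export
score_junction <- function(junction, donor, acceptor, anchor_min = 10L) {
  if (nchar(junction) < 20L) stop("junction shorter than 20 bases")
  L <- nchar(junction)
  p <- .longest_match(junction, donor, from_start = TRUE)
  q <- .longest_match(junction, acceptor, from_start = FALSE)
  if (p < anchor_min || q < anchor_min) {
    return(list(score = NA_integer_, resolved = FALSE,
                prefix_len = p, suffix_len = q,
                donor_break = NA_integer_, acceptor_break = NA_integer_,
                insert = NA_character_))
  }
  d_pos <- regexpr(substr(junction, 1L, p), donor, fixed = TRUE)
  a_pos <- regexpr(substr(junction, L - q + 1L, L), acceptor, fixed = TRUE)
  score <- p + q - L
  list(score = as.integer(score), resolved = TRUE,
       prefix_len = p, suffix_len = q,
       donor_break = as.integer(d_pos) + p - 1L,
       acceptor_break = as.integer(a_pos),
       insert = if (score < 0L) substr(junction, p + 1L, L - q) else "")
}

#' Score a set of junctions
#'
#' @param junctions Named character vector of junction sequences.
#' @inheritParams score_junction
#' @return Data.frame with one row per junction: `id`, `score`, `resolved`,
#'   `prefix_len`, `suffix_len`, `donor_break`, `acceptor_break`, `insert`.
#' @export
score_junctions <- function(junctions, donor, acceptor, anchor_min = 10L) {
  res <- lapply(junctions, score_junction, donor = donor, acceptor = acceptor,
                anchor_min = anchor_min)
  data.frame(
    id = if (is.null(names(junctions))) sprintf("jct%04d", seq_along(junctions))
         else names(junctions),
    score = vapply(res, `[[`, integer(1), "score"),
    resolved = vapply(res, `[[`, logical(1), "resolved"),
    prefix_len = vapply(res, `[[`, integer(1), "prefix_len"),
    suffix_len = vapply(res, `[[`, integer(1), "suffix_len"),
    donor_break = vapply(res, `[[`, integer(1), "donor_break"),
    acceptor_break = vapply(res, `[[`, integer(1), "acceptor_break"),
    insert = vapply(res, `[[`, character(1), "insert"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Insertion frequency of a junction cohort
#'
#' @param scores Signed junction scores (negative = insertion).
#' @return Proportion of junctions with score < 0.
#' @export
insertion_frequency <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no resolved junctions")
  mean(scores < 0L)
}

.kw_stat <- function(r, g, N, tie_corr) {
  Rsum <- tapply(r, g, sum)
  n <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  if (tie_corr > 0) H / tie_corr else 0
}

# enumerate every assignment of the pooled observations to groups of the
# observed sizes and count assignments with H at least as extreme
.kw_exact_p <- function(values, groups) {
  N <- length(values)
  sizes <- tabulate(groups)
  n_assign <- prod(choose(cumsum(rev(sizes)), rev(sizes)))
  if (n_assign > 2e5) stop("too many assignments for the exact test")
  r <- rank(values)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H_obs <- .kw_stat(r, groups, N, tie_corr)
  grp_of <- integer(N)
  total <- 0L; hits <- 0L
  recurse <- function(avail, gi) {
    if (gi == length(sizes)) {
      grp_of[avail] <<- gi
      H <- .kw_stat(r, grp_of, N, tie_corr)
      total <<- total + 1L
      if (H >= H_obs - 1e-9) hits <<- hits + 1L
      return(invisible())
    }
    sets <- combn(avail, sizes[gi], simplify = FALSE)
    for (s in sets) {
      grp_of[s] <<- gi
      recurse(setdiff(avail, s), gi + 1L)
    }
  }
  recurse(seq_len(N), 1L)
  hits / total
}

#' Compare microhomology-score distributions across cohorts
#'
#' Kruskal-Wallis test on the signed junction scores (tie-corrected ranks)
#' followed by Dunn's pairwise post-tests with the tie correction. Pairwise
#' p-values are unadjusted by default; pass `p_adjust = "bonferroni"` (or
#' any [stats::p.adjust()] method) to adjust. For very small cohorts an
#' exact permutation p-value for the global test is available with
#' `exact = TRUE` (the default is the usual asymptotic chi-square).
#'
#' @param cohorts Named list of numeric score vectors, one per genotype
#'   (each n >= 2).
#' @param exact Use full enumeration over group assignments for the global
#'   p-value.
#' @param p_adjust Adjustment method for Dunn p-values.
#' @return A list with `H`, `df`, `p_value`, `method` and `dunn` (data.frame
#'   `group_a`, `group_b`, `z`, `p_value`, `p_adjusted`).
#' @export
compare_mh_distributions <- function(cohorts, exact = FALSE,
                                     p_adjust = "none") {
  stopifnot(is.list(cohorts), length(cohorts) >= 2L)
  if (is.null(names(cohorts))) names(cohorts) <- paste0("g", seq_along(cohorts))
  if (any(lengths(cohorts) < 2L)) stop("each cohort needs n >= 2")
  values <- unlist(cohorts, use.names = FALSE)
  groups <- factor(rep(names(cohorts), lengths(cohorts)),
                   levels = names(cohorts))
  k <- nlevels(groups)
  N <- length(values)

  if (length(unique(values)) == 1L) {
    dunn <- do.call(rbind, lapply(combn(levels(groups), 2L, simplify = FALSE),
      function(pr) data.frame(group_a = pr[1L], group_b = pr[2L], z = 0,
                              p_value = 1, p_adjusted = 1,
                              stringsAsFactors = FALSE)))
    return(list(H = 0, df = k - 1L, p_value = 1, method = "degenerate",
                dunn = dunn))
  }

  if (exact) {
    r <- rank(values)
    ties <- table(r)
    tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
    H <- .kw_stat(r, groups, N, tie_corr)
    p <- .kw_exact_p(values, groups)
    method <- "exact permutation"
  } else {
    kt <- kruskal.test(values, groups)
    H <- unname(kt$statistic); p <- kt$p.value
    method <- "asymptotic chi-square"
  }

  r <- rank(values)
  ties <- table(r)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tabulate(groups)
  pairs <- combn(seq_len(k), 2L, simplify = FALSE)
  dunn <- do.call(rbind, lapply(pairs, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    data.frame(group_a = levels(groups)[i], group_b = levels(groups)[j],
               z = unname(z), p_value = 2 * pnorm(-abs(unname(z))),
               stringsAsFactors = FALSE)
  }))
  dunn$p_adjusted <- p.adjust(dunn$p_value, method = p_adjust)
  list(H = H, df = k - 1L, p_value = p, method = method, dunn = dunn)
}

#' Compare insertion frequencies of two cohorts
#'
#' Two-sided Fisher exact test on the 2x2 table of insertion-bearing versus
#' other junctions in the two cohorts. A table with a zero margin gives
#' p = 1 by convention.
#'
#' @param scores_a,scores_b Signed score vectors of the two cohorts.
#' @return A list with `p_value`, `odds_ratio` (conditional MLE), and the
#'   2x2 `table`.
#' @export
compare_insertion_frequencies <- function(scores_a, scores_b) {
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  if (!length(scores_a) || !length(scores_b)) stop("empty cohort")
  tab <- rbind(a = c(ins = sum(scores_a < 0), other = sum(scores_a >= 0)),
               b = c(ins = sum(scores_b < 0), other = sum(scores_b >= 0)))
  ft <- fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Relative class-switch efficiency
#'
#' Rescales per-animal switched fractions so the mean of a reference group
#' (typically wild type under the same stimulation) is 100 percent.
#'
#' @param fractions Per-animal switched fractions.
#' @param reference_fractions Fractions of the reference group (non-empty,
#'   mean > 0).
#' @return Numeric vector of percentages.
#' @export
relative_csr_efficiency <- function(fractions, reference_fractions) {
  if (!length(reference_fractions)) stop("reference group is empty")
  ref <- mean(reference_fractions)
  if (!is.finite(ref) || ref <= 0) stop("reference mean must be positive")
  100 * fractions / ref
}

#' Integer percentage of a count
#'
#' `round(100 * k / n)` to the nearest integer, halves away from zero —
#' the convention used when reporting incidence proportions such as tumor
#' profiles or insertion frequencies.
#'
#' @param k Numerator count(s), `0 <= k <= n`.
#' @param n Denominator count(s), `n >= 1`.
#' @return Integer percentage(s).
#' @export
proportion_percent <- function(k, n) {
  if (any(n < 1L)) stop("n must be >= 1")
  if (any(k < 0L) || any(k > n)) stop("k must lie in [0, n]")
  as.integer(floor(100 * k / n + 0.5))
}

#' Summarise a junction cohort
#'
#' Report-level summary with the conventional binning (microhomologies
#' longer than 10 bases pooled as "long"); statistics elsewhere always use
#' the raw signed scores.
#'
#' @param scores Signed junction scores (resolved junctions only).
#' @param genotype Cohort label.
#' @return One-row data.frame.
#' @export
summarize_junction_cohort <- function(scores, genotype = "cohort") {
  scores <- scores[!is.na(scores)]
  data.frame(
    genotype = genotype,
    n = length(scores),
    n_blunt = sum(scores == 0L),
    n_mh = sum(scores > 0L),
    n_long_mh = sum(scores > 10L),
    n_ins = sum(scores < 0L),
    median_score = stats::median(scores),
    insertion_freq = insertion_frequency(scores),
    stringsAsFactors = FALSE
  )
}
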