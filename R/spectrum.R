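#' Spectrum analysis configuration
#'
#' @param n_iterations Number of resampling iterations (>= 1; the analysis
#'   convention is 1000).
#' @param seed Integer seed for the resampling draws.
#' @param region_filter Optional character vector of region labels to
#'   include (e.g. `c("CDR1","CDR2")`); `NULL` means every V position.
#'   The CDR3 tag window is always excluded — it carries clone identity,
#'   not biology.
#' @param alpha Significance level used by genotype contrasts.
#' @return A `spectrum_config` object.
#' @export
spectrum_config <- function(n_iterations = 1000L, seed = 17L,
                            region_filter = NULL, alpha = 0.05) {
  stopifnot(n_iterations >= 1L, alpha > 0, alpha < 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 region_filter = region_filter, alpha = alpha),
            class = "spectrum_config")
}

.eligible_positions <- function(germline, region_filter = NULL) {
  tag <- cdr3_interval(germline)
  r <- germline$regions
  if (is.null(region_filter)) {
    pos <- seq_len(nchar(germline$sequence))
  } else {
    keep <- r[r$label %in% region_filter, , drop = FALSE]
    if (nrow(keep) == 0L) stop("region_filter matches no region")
    pos <- unlist(lapply(seq_len(nrow(keep)),
                         function(i) seq.int(keep$start[i], keep$end[i])))
  }
  setdiff(pos, tag)
}

#' Potential mutation opportunities per subtype
#'
#' Counts, within the filtered region, the germline positions carrying each
#' of the four subtypes. These counts are the composition correction of the
#' spectrum: dividing observed mutation counts by them (times the number of
#' sampled sequences) normalises each subtype's frequency to its potential
#' maximum, so sequence composition cannot masquerade as mutability.
#'
#' @param germline A `germline_reference`.
#' @param region_filter See [spectrum_config()].
#' @return Named integer vector over the four subtypes.
#' @export
eligible_site_counts <- function(germline, region_filter = NULL) {
  pos <- .eligible_positions(germline, region_filter)
  if (length(pos) == 0L) stop("region filter leaves no eligible positions")
  tab <- table(factor(germline$subtype_mask[pos], levels = SUBTYPES))
  setNames(as.integer(tab), SUBTYPES)
}

#' Draw one sequence per clone
#'
#' One resampling round: a uniformly chosen member from every clone. Uses
#' the current RNG state; callers seed once per analysis.
#'
#' @param clone_members Named list, one character vector of sequence ids
#'   per clone (all non-empty).
#' @return Character vector with one sequence id per clone.
#' @export
resample_iteration <- function(clone_members) {
  if (any(lengths(clone_members) == 0L)) stop("every clone must be non-empty")
  vapply(clone_members, function(m) m[sample.int(length(m), 1L)], character(1))
}

#' Normalised subtype frequencies for one sampled sequence set
#'
#' For subtype s with S_s eligible sites and N_s called mutations across the
#' n sampled sequences, the normalised frequency is f_s = N_s / (S_s * n).
#' Under the one-mutation-per-site model this is bounded by 1. Subtypes with
#' S_s = 0 are reported as `NA` (undefined), never as 0.
#'
#' @param sampled_ids Sequence ids of the sampled set.
#' @param mutations Mutation table with `seq_id`, `position`, `subtype`.
#' @param germline A `germline_reference`.
#' @param region_filter See [spectrum_config()].
#' @return Named numeric vector of the four f_s values.
#' @export
iteration_frequencies <- function(sampled_ids, mutations, germline,
                                  region_filter = NULL) {
  S <- eligible_site_counts(germline, region_filter)
  pos <- .eligible_positions(germline, region_filter)
  m <- mutations[mutations$seq_id %in% sampled_ids &
                   mutations$position %in% pos, , drop = FALSE]
  N <- table(factor(m$subtype, levels = SUBTYPES))
  f <- as.numeric(N) / (S * length(sampled_ids))
  f[S == 0L] <- NA_real_
  setNames(f, SUBTYPES)
}

#' Clonal-resampling mutation spectrum
#'
#' The central statistic: over `n_iterations` rounds, one sequence is drawn
#' uniformly from every CDR3 clone and mutations are counted per subtype,
#' so mutations inherited within a clonal lineage are counted once per
#' clone rather than once per sequence. Each round's counts are normalised
#' to the potential maximum of the subtype (eligible sites x sampled
#' sequences) and the rounds are aggregated as mean, SD and 2.5–97.5
#' percentile interval. A positional profile accumulates, per germline
#' position and subtype, how often a mutation was carried there across
#' iterations x sequences, rescaled within each subtype to a maximum of 1.
#'
#' @param annotated A list with `sequences` (data.frame with `seq_id`,
#'   `clone_id`) and `mutations` (data.frame with `seq_id`, `position`,
#'   `subtype`), as from [annotate_repertoire()] + [group_clones()].
#' @param germline A `germline_reference`.
#' @param config A [spectrum_config()].
#' @return A `spectrum_result`: list with `summary` (per-subtype mean, sd,
#'   ci_lo, ci_hi), `per_iteration` (iterations x subtypes matrix of f_s),
#'   `positional` (data.frame `position`, `subtype`, `value`),
#'   `site_counts`, `n_seq` (clones sampled per round), `mean_counts`
#'   (mean mutated opportunities per subtype) and the `config`.
#' @export
aggregate_spectrum <- function(annotated, germline, config = spectrum_config()) {
  stopifnot(inherits(config, "spectrum_config"))
  seqs <- annotated$sequences
  muts <- annotated$mutations
  if (!"clone_id" %in% names(seqs)) stop("sequences need a clone_id column")
  set.seed(config$seed)

  pos <- .eligible_positions(germline, config$region_filter)
  S <- eligible_site_counts(germline, config$region_filter)
  n_iter <- config$n_iterations

  ids <- seqs$seq_id
  members <- split(seq_along(ids), seqs$clone_id)
  n_clones <- length(members)

  m <- muts[muts$position %in% pos & muts$seq_id %in% ids, , drop = FALSE]
  m_seq <- match(m$seq_id, ids)
  m_sub <- match(m$subtype, SUBTYPES)
  # per-sequence subtype counts
  C <- matrix(0L, length(ids), 4L, dimnames = list(NULL, SUBTYPES))
  if (nrow(m)) {
    inc <- table(factor(m_seq, levels = seq_along(ids)),
                 factor(m_sub, levels = 1:4))
    C[] <- as.integer(inc)
  }

  # sampled member index per iteration x clone
  sampled <- matrix(0L, n_iter, n_clones)
  for (j in seq_len(n_clones)) {
    mem <- members[[j]]
    sampled[, j] <- if (length(mem) == 1L) rep.int(mem, n_iter) else
      mem[sample.int(length(mem), n_iter, replace = TRUE)]
  }

  per_iter_N <- vapply(1:4, function(s) {
    rowSums(matrix(C[, s][sampled], n_iter, n_clones))
  }, numeric(n_iter))
  if (n_iter == 1L) per_iter_N <- matrix(per_iter_N, 1L, 4L)
  colnames(per_iter_N) <- SUBTYPES
  denom <- S * n_clones
  per_iter_f <- sweep(per_iter_N, 2L, denom, "/")
  per_iter_f[, S == 0L] <- NA_real_

  qs <- apply(per_iter_f, 2L, function(v) {
    if (anyNA(v)) c(NA_real_, NA_real_) else
      quantile(v, probs = c(0.025, 0.975), names = FALSE)
  })
  summary <- data.frame(
    subtype = SUBTYPES,
    mean = colMeans(per_iter_f),
    sd = apply(per_iter_f, 2L, sd),
    ci_lo = qs[1L, ], ci_hi = qs[2L, ],
    row.names = NULL, stringsAsFactors = FALSE
  )

  # positional profile: weight each sequence's mutations by how often the
  # sequence was sampled over all iterations
  times_sampled <- tabulate(sampled, nbins = length(ids))
  positional <- expand.grid(position = pos, subtype = SUBTYPES,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  positional$value <- 0
  if (nrow(m)) {
    w <- times_sampled[m_seq]
    acc <- tapply(w, list(factor(m$position, levels = pos),
                          factor(m$subtype, levels = SUBTYPES)), sum)
    acc[is.na(acc)] <- 0
    mx <- apply(acc, 2L, max)
    scaled <- sweep(acc, 2L, ifelse(mx > 0, mx, 1), "/")
    positional$value <- as.vector(scaled)
  }

  structure(list(
    summary = summary,
    per_iteration = per_iter_f,
    positional = positional,
    site_counts = S,
    n_seq = n_clones,
    mean_counts = colMeans(per_iter_N),
    config = config
  ), class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("spectrum_result:", x$config$n_iterations, "iterations over",
      x$n_seq, "clones\n")
  print(transform(x$summary, mean = signif(mean, 4), sd = signif(sd, 4),
                  ci_lo = signif(ci_lo, 4), ci_hi = signif(ci_hi, 4)))
  invisible(x)
}

#' Contrast two genotype spectra
#'
#' For each subtype, builds a 2x2 contingency table of rounded mean mutated
#' site-opportunities versus remaining (unmutated) opportunities for the two
#' genotypes and applies Pearson's chi-squared test with Yates' continuity
#' correction (1 df). Contrasts whose expected counts contain a zero are
#' reported as not computable. With `pooled = TRUE` a single table summed
#' over subtypes is tested instead.
#'
#' @param result_a,result_b `spectrum_result` objects computed on the same
#'   germline and region filter.
#' @param pooled Test one pooled table instead of per-subtype tables.
#' @return Data.frame with `subtype`, `statistic`, `p_value`, `computable`.
#' @export
compare_genotypes <- function(result_a, result_b, pooled = FALSE) {
  stopifnot(inherits(result_a, "spectrum_result"),
            inherits(result_b, "spectrum_result"))
  if (!identical(result_a$site_counts, result_b$site_counts)) {
    stop("spectra computed on different germlines or region filters")
  }
  one <- function(ka, na, kb, nb, label) {
    tab <- rbind(c(ka, na - ka), c(kb, nb - kb))
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(E == 0)) {
      return(data.frame(subtype = label, statistic = NA_real_,
                        p_value = NA_real_, computable = FALSE,
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
    data.frame(subtype = label, statistic = unname(ct$statistic),
               p_value = ct$p.value, computable = TRUE,
               stringsAsFactors = FALSE)
  }
  opp_a <- result_a$site_counts * result_a$n_seq
  opp_b <- result_b$site_counts * result_b$n_seq
  ka <- round(result_a$mean_counts); kb <- round(result_b$mean_counts)
  if (pooled) {
    return(one(sum(ka), sum(opp_a), sum(kb), sum(opp_b), "pooled"))
  }
  out <- lapply(SUBTYPES, function(s) one(ka[s], opp_a[s], kb[s], opp_b[s], s))
  do.call(rbind, out)
}
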