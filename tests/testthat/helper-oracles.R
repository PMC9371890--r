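# Independent oracles used across tests. These deliberately take different
# computational routes from the package implementation.

# Exhaustive junction decomposition: enumerate every (prefix length, donor
# occurrence, suffix length, acceptor occurrence) by direct substring
# comparison and pick the decomposition maximising the overlap k, then
# minimising the gap g, then the leftmost donor break.
brute_force_score <- function(junction, donor, acceptor, anchor_min = 10L) {
  L <- nchar(junction); nd <- nchar(donor); na <- nchar(acceptor)
  occ_starts <- function(pattern, subject, n) {
    w <- nchar(pattern)
    if (w > n) return(integer(0))
    starts <- seq_len(n - w + 1L)
    starts[substring(subject, starts, starts + w - 1L) == pattern]
  }
  best <- NULL
  for (p in anchor_min:min(L, nd)) {
    d_occ <- occ_starts(substr(junction, 1L, p), donor, nd)
    if (!length(d_occ)) next
    for (q in anchor_min:min(L, na)) {
      a_occ <- occ_starts(substr(junction, L - q + 1L, L), acceptor, na)
      if (!length(a_occ)) next
      k <- max(p + q - L, 0L)
      g <- max(L - p - q, 0L)
      for (i in d_occ) {
        cand <- list(k = k, g = g, donor_break = i + p - 1L,
                     acceptor_break = min(a_occ), score = p + q - L)
        better <- is.null(best) ||
          cand$k > best$k ||
          (cand$k == best$k && cand$g < best$g) ||
          (cand$k == best$k && cand$g == best$g &&
             cand$donor_break < best$donor_break)
        if (better) best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(list(score = NA_integer_, resolved = FALSE))
  }
  list(score = as.integer(best$score), resolved = TRUE,
       donor_break = best$donor_break, acceptor_break = best$acceptor_break)
}

# Two-sided Fisher exact p by explicit hypergeometric enumeration: sum the
# probabilities of every table with the observed margins whose probability
# does not exceed that of the observed table.
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Central binomial interval bounds at the given coverage.
binom_central <- function(n, p, coverage = 0.99) {
  alpha <- (1 - coverage) / 2
  c(qbinom(alpha, n, p), qbinom(1 - alpha, n, p))
}

# Small fixed toy germline: the 5-mer used in worked examples, with a
# single full-length region and no CDR3 tag window.
toy_germline <- function(seq = "AAGCT") {
  germline_reference("toy", seq,
                     data.frame(label = "FR1", start = 1L, end = nchar(seq)))
}

# Build the annotated-repertoire structure straight from simulation truth,
# bypassing reads/consensus, for spectrum-level tests.
annotated_from_truth <- function(truth) {
  muts <- truth$mutations
  list(
    sequences = data.frame(seq_id = truth$molecules$molecule_id,
                           clone_id = truth$molecules$clone_id,
                           stringsAsFactors = FALSE),
    mutations = data.frame(seq_id = muts$molecule_id, position = muts$position,
                           from_base = muts$from_base, to_base = muts$to_base,
                           subtype = muts$subtype, stringsAsFactors = FALSE)
  )
}
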