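#' Align a consensus sequence to the germline and call point mutations
#'
#' Positional comparison against the germline V reference, excluding the
#' CDR3 tag window (which carries clone identity, not biology). Every
#' mismatch whose consensus base is A/C/G/T becomes a mutation annotated
#' with the germline-context subtype and region; consensus `N` positions
#' are skipped so sequencing ties never produce a mutation call. Sequences
#' whose mismatch fraction exceeds `max_mismatch_frac` are rejected as
#' likely misassemblies, as are sequences whose length differs from the
#' germline (substitution-only model; indels are out of scope).
#'
#' @param consensus A consensus sequence (single string).
#' @param germline A `germline_reference`.
#' @param max_mismatch_frac Rejection threshold on the mismatch fraction
#'   outside the CDR3 window.
#' @return A list with `ok`, `mutations` (data.frame: `position`,
#'   `from_base`, `to_base`, `subtype`, `region`), `cdr3`, `n_compared` and
#'   `reason` when rejected.
#' @export
align_and_call <- function(consensus, germline, max_mismatch_frac = 0.15) {
  L <- nchar(germline$sequence)
  if (nchar(consensus) != L) {
    return(list(ok = FALSE, mutations = NULL, cdr3 = NA_character_,
                n_compared = 0L, reason = "length_mismatch"))
  }
  tag <- cdr3_interval(germline)
  g <- .chars(germline$sequence)
  s <- .chars(toupper(consensus))
  cmp <- setdiff(seq_len(L), tag)
  callable <- cmp[s[cmp] %in% DNA_BASES]
  mism <- callable[s[callable] != g[callable]]
  if (length(mism) / length(cmp) > max_mismatch_frac) {
    return(list(ok = FALSE, mutations = NULL, cdr3 = NA_character_,
                n_compared = length(callable), reason = "mismatch_fraction"))
  }
  region_of <- function(pos) {
    r <- germline$regions
    idx <- findInterval(pos, r$start)
    lab <- rep(NA_character_, length(pos))
    inside <- idx >= 1L & pos <= r$end[pmax(idx, 1L)]
    lab[inside] <- r$label[idx[inside]]
    lab
  }
  muts <- data.frame(
    position = mism,
    from_base = g[mism],
    to_base = s[mism],
    subtype = germline$subtype_mask[mism],
    region = region_of(mism),
    stringsAsFactors = FALSE
  )
  list(ok = TRUE, mutations = muts,
       cdr3 = .collapse(s[tag]), n_compared = length(callable),
       reason = NA_character_)
}

#' Annotate a whole set of consensus sequences
#'
#' Runs [align_and_call()] over a consensus table and assembles the
#' per-sequence and per-mutation tables used by the spectrum stage.
#'
#' @param consensus Data.frame with columns `umi` (used as sequence id) and
#'   `sequence`, as produced by [collapse_families()]; alternatively a
#'   named character vector.
#' @inheritParams align_and_call
#' @return A list with `sequences` (data.frame: `seq_id`, `cdr3`, `n_mut`),
#'   `mutations` (data.frame with `seq_id` plus the [align_and_call()]
#'   columns) and `rejected` (data.frame: `seq_id`, `reason`).
#' @export
annotate_repertoire <- function(consensus, germline, max_mismatch_frac = 0.15) {
  if (is.character(consensus)) {
    consensus <- data.frame(umi = names(consensus), sequence = unname(consensus),
                            stringsAsFactors = FALSE)
  }
  res <- lapply(consensus$sequence, align_and_call, germline = germline,
                max_mismatch_frac = max_mismatch_frac)
  ok <- vapply(res, `[[`, logical(1), "ok")
  ids <- consensus$umi
  mut_tabs <- lapply(which(ok), function(i) {
    m <- res[[i]]$mutations
    if (nrow(m) == 0L) return(NULL)
    cbind(data.frame(seq_id = ids[i], stringsAsFactors = FALSE), m)
  })
  mut_tabs <- mut_tabs[!vapply(mut_tabs, is.null, logical(1))]
  mutations <- if (length(mut_tabs)) do.call(rbind, mut_tabs) else
    data.frame(seq_id = character(), position = integer(),
               from_base = character(), to_base = character(),
               subtype = character(), region = character(),
               stringsAsFactors = FALSE)
  sequences <- data.frame(
    seq_id = ids[ok],
    cdr3 = vapply(res[ok], `[[`, character(1), "cdr3"),
    n_mut = vapply(res[ok], function(r) nrow(r$mutations), integer(1)),
    stringsAsFactors = FALSE
  )
  rejected <- data.frame(
    seq_id = ids[!ok],
    reason = vapply(res[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  rownames(mutations) <- NULL
  list(sequences = sequences, mutations = mutations, rejected = rejected)
}

#' Group annotated sequences into CDR3 clones
#'
#' Clonal lineages are defined by exact CDR3 nucleotide identity. Clone
#' identifiers are stable under input order: they are assigned in
#' lexicographic order of the CDR3 string.
#'
#' @param sequences Data.frame with `seq_id` and `cdr3` columns (empty
#'   CDR3s are rejected).
#' @return A list with `sequences` (input plus a `clone_id` column),
#'   `clones` (data.frame: `clone_id`, `cdr3`, `size`) and `rejected`.
#' @export
group_clones <- function(sequences) {
  stopifnot(all(c("seq_id", "cdr3") %in% names(sequences)))
  bad <- is.na(sequences$cdr3) | nchar(sequences$cdr3) == 0L
  rejected <- data.frame(seq_id = sequences$seq_id[bad],
                         reason = rep("empty_cdr3", sum(bad)),
                         stringsAsFactors = FALSE)
  seqs <- sequences[!bad, , drop = FALSE]
  lev <- sort(unique(seqs$cdr3))
  idx <- match(seqs$cdr3, lev)
  seqs$clone_id <- sprintf("clone%05d", idx)
  clones <- data.frame(clone_id = sprintf("clone%05d", seq_along(lev)),
                       cdr3 = lev,
                       size = as.integer(tabulate(idx, length(lev))),
                       stringsAsFactors = FALSE)
  rownames(seqs) <- NULL
  list(sequences = seqs, clones = clones, rejected = rejected)
}
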