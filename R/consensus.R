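#' Merge a read pair by overlap alignment
#'
#' Reverse-complements mate 2 (reversing its quality string), scans every
#' candidate overlap of at least `min_overlap` bases between the 3' end of
#' read 1 and the 5' end of the reverse-complemented read 2, and keeps the
#' overlap with the fewest mismatches (ties resolved towards the longer
#' overlap). The pair is rejected when the best overlap's mismatch fraction
#' exceeds `max_mismatch_frac`. Where the mates disagree inside the overlap
#' the base with the higher quality is kept; on a quality tie the read-1
#' base wins.
#'
#' @param r1_seq,r2_seq Mate sequences (read 2 in sequencing orientation).
#' @param r1_qual,r2_qual Phred+33 quality strings; `NULL` means uniform.
#' @param min_overlap Minimum admissible overlap (>= 10).
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return A list with `merged` (the merged sequence or `NA`), `ok`
#'   (logical), `overlap`, `mismatches` and `reason` (for rejections).
#' @export
merge_pair <- function(r1_seq, r2_seq, r1_qual = NULL, r2_qual = NULL,
                       min_overlap = 20L, max_mismatch_frac = 0.1) {
  stopifnot(min_overlap >= 10L)
  r2rc <- .revcomp(r2_seq)
  a1 <- utf8ToInt(r1_seq)
  a2 <- utf8ToInt(r2rc)
  q1 <- if (is.null(r1_qual)) rep.int(40L, length(a1)) else utf8ToInt(r1_qual) - 33L
  q2 <- if (is.null(r2_qual)) rep.int(40L, length(a2)) else rev(utf8ToInt(r2_qual) - 33L)
  n1 <- length(a1); n2 <- length(a2)
  max_ov <- min(n1, n2)
  if (max_ov < min_overlap) {
    return(list(merged = NA_character_, ok = FALSE, overlap = NA_integer_,
                mismatches = NA_integer_, reason = "reads_too_short"))
  }
  best_ov <- NA_integer_; best_mm <- Inf
  for (ov in seq.int(min_overlap, max_ov)) {
    mm <- sum(a1[(n1 - ov + 1L):n1] != a2[seq_len(ov)])
    if (mm < best_mm || (mm == best_mm && !is.na(best_ov) && ov > best_ov)) {
      best_mm <- mm; best_ov <- ov
    }
  }
  if (best_mm / best_ov > max_mismatch_frac) {
    return(list(merged = NA_character_, ok = FALSE, overlap = best_ov,
                mismatches = as.integer(best_mm), reason = "no_admissible_overlap"))
  }
  i1 <- (n1 - best_ov + 1L):n1
  i2 <- seq_len(best_ov)
  ov_bases <- a1[i1]
  disagree <- which(a1[i1] != a2[i2])
  if (length(disagree)) {
    take2 <- q2[i2][disagree] > q1[i1][disagree]
    ov_bases[disagree[take2]] <- a2[i2][disagree[take2]]
  }
  merged <- intToUtf8(c(a1[seq_len(n1 - best_ov)], ov_bases,
                        a2[(best_ov + 1L):n2][seq_len(max(n2 - best_ov, 0L))]))
  list(merged = merged, ok = TRUE, overlap = best_ov,
       mismatches = as.integer(best_mm), reason = NA_character_)
}

#' Merge all read pairs of a run
#'
#' Applies [merge_pair()] to every row of a reads table and separates
#' merged records from rejections.
#'
#' @param reads Data.frame with `read_id`, `r1_seq`, `r2_seq` and optional
#'   `r1_qual`, `r2_qual` columns.
#' @inheritParams merge_pair
#' @return A list with `merged` (data.frame: `read_id`, `merged`) and
#'   `rejected` (data.frame: `read_id`, `reason`).
#' @export
merge_pairs <- function(reads, min_overlap = 20L, max_mismatch_frac = 0.1) {
  has_q <- all(c("r1_qual", "r2_qual") %in% names(reads))
  res <- lapply(seq_len(nrow(reads)), function(i) {
    merge_pair(reads$r1_seq[i], reads$r2_seq[i],
               if (has_q) reads$r1_qual[i], if (has_q) reads$r2_qual[i],
               min_overlap = min_overlap, max_mismatch_frac = max_mismatch_frac)
  })
  ok <- vapply(res, `[[`, logical(1), "ok")
  list(
    merged = data.frame(read_id = reads$read_id[ok],
                        merged = vapply(res[ok], `[[`, character(1), "merged"),
                        stringsAsFactors = FALSE),
    rejected = data.frame(read_id = reads$read_id[!ok],
                          reason = vapply(res[!ok], `[[`, character(1), "reason"),
                          stringsAsFactors = FALSE)
  )
}

#' Split a merged read into UMI and insert
#'
#' @param merged Merged sequence(s); the UMI is the leading `umi_length`
#'   bases by construction of the library.
#' @param umi_length UMI length in bases.
#' @return A data.frame with columns `umi` and `insert`.
#' @export
extract_umi <- function(merged, umi_length = 8L) {
  if (any(nchar(merged) <= umi_length)) {
    stop("merged read(s) not longer than the UMI")
  }
  data.frame(umi = substr(merged, 1L, umi_length),
             insert = substr(merged, umi_length + 1L, nchar(merged)),
             stringsAsFactors = FALSE)
}

.majority_consensus <- function(inserts) {
  if (length(unique(inserts)) == 1L) return(inserts[[1L]])
  mat <- do.call(rbind, strsplit(inserts, "", fixed = TRUE))
  counts <- vapply(DNA_BASES, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1L) counts <- matrix(counts, nrow = 1L,
                                        dimnames = list(NULL, DNA_BASES))
  top <- max.col(counts, ties.method = "first")
  best <- counts[cbind(seq_len(nrow(counts)), top)]
  tie <- rowSums(counts == best) > 1L
  out <- DNA_BASES[top]
  out[tie] <- "N"
  .collapse(out)
}

#' Collapse UMI families into consensus sequences
#'
#' Groups records by exact UMI and computes a per-position majority base
#' for each family; positions with a tied vote become `N` (never fabricate
#' a base from a sequencing tie). Families whose inserts differ in length
#' are rejected as misassemblies; families below `min_family_size` are
#' dropped.
#'
#' @param records Data.frame with columns `umi` and `insert`.
#' @param min_family_size Minimum reads per family to emit a consensus.
#' @return A list with `consensus` (data.frame: `umi`, `sequence`,
#'   `family_size`) and `rejected` (data.frame: `umi`, `reason`).
#' @export
collapse_families <- function(records, min_family_size = 1L) {
  stopifnot(all(c("umi", "insert") %in% names(records)), min_family_size >= 1L)
  fam <- split(records$insert, records$umi)
  lens_ok <- vapply(fam, function(x) length(unique(nchar(x))) == 1L, logical(1))
  sizes <- lengths(fam)
  keep <- lens_ok & sizes >= min_family_size
  consensus <- data.frame(
    umi = names(fam)[keep],
    sequence = vapply(fam[keep], .majority_consensus, character(1)),
    family_size = unname(sizes[keep]),
    stringsAsFactors = FALSE
  )
  rej_len <- names(fam)[!lens_ok]
  rej_small <- names(fam)[lens_ok & sizes < min_family_size]
  rejected <- data.frame(
    umi = c(rej_len, rej_small),
    reason = c(rep("unequal_insert_lengths", length(rej_len)),
               rep("family_below_min_size", length(rej_small))),
    stringsAsFactors = FALSE
  )
  rownames(consensus) <- NULL
  list(consensus = consensus, rejected = rejected)
}

#' Full read-to-consensus stage
#'
#' Convenience wrapper: merge pairs, split off UMIs, collapse families.
#'
#' @inheritParams merge_pairs
#' @inheritParams extract_umi
#' @inheritParams collapse_families
#' @return A list with `consensus`, `rejected_pairs`, `rejected_families`
#'   and the intermediate `records`.
#' @export
collapse_reads <- function(reads, umi_length = 8L, min_overlap = 20L,
                           max_mismatch_frac = 0.1, min_family_size = 1L) {
  m <- merge_pairs(reads, min_overlap = min_overlap,
                   max_mismatch_frac = max_mismatch_frac)
  recs <- extract_umi(m$merged$merged, umi_length = umi_length)
  cf <- collapse_families(recs, min_family_size = min_family_size)
  list(consensus = cf$consensus, rejected_pairs = m$rejected,
       rejected_families = cf$rejected, records = recs)
}

#' Write consensus sequences as FASTA
#'
#' Headers carry the UMI and family size as `umi=...;size=...`.
#'
#' @param consensus The consensus data.frame from [collapse_families()].
#' @param path Output FASTA path.
#' @export
write_consensus_fasta <- function(consensus, path) {
  ids <- sprintf("%s umi=%s;size=%d", consensus$umi, consensus$umi,
                 consensus$family_size)
  write_fasta(setNames(consensus$sequence, ids), path)
  invisible(consensus)
}

#' @rdname write_consensus_fasta
#' @param path FASTA path written by `write_consensus_fasta()`.
#' @export
read_consensus_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  hdr <- names(dna)
  umi <- sub(" .*", "", hdr)
  size <- as.integer(sub(".*;size=", "", hdr))
  data.frame(umi = umi, sequence = as.character(dna), family_size = size,
             row.names = NULL, stringsAsFactors = FALSE)
}
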