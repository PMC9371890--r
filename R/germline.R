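#' @importFrom stats rbinom rgeom runif sd quantile setNames chisq.test
#'   kruskal.test fisher.test p.adjust pnorm pchisq
#' @importFrom utils write.table read.table combn packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")
SUBTYPES <- c("GC_AID_HOT", "GC_OTHER", "AT_POL_HOT", "AT_OTHER")

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.collapse <- function(x) paste0(x, collapse = "")

#' Classify germline sites into mutation subtypes
#'
#' Assigns each position of a germline V sequence to one of four mutation
#' subtypes used throughout the spectrum analysis: \code{GC_AID_HOT} (C in a
#' WRC trinucleotide or G in a GYW trinucleotide, the AID deamination
#' hotspots and their reverse complement), \code{GC_OTHER} (any other G or
#' C), \code{AT_POL_HOT} (A preceded by W or T followed by W, the
#' polymerase-eta hotspots), and \code{AT_OTHER} (any other A or T). IUPAC
#' codes: W = \{A,T\}, R = \{A,G\}, Y = \{C,T\}. Context positions outside
#' the sequence never match, so terminal bases can only be \code{*_OTHER}.
#'
#' @param sequence A single DNA string over A/C/G/T.
#' @return `classify_sites()` returns a character vector, one subtype per
#'   position; `classify_site()` returns the subtype of one position.
#' @examples
#' classify_sites("AAGCT")
#' classify_site("AAGCT", 4) # the C in context AGC = WRC
#' @export
classify_sites <- function(sequence) {
  s <- .chars(toupper(sequence))
  if (!all(s %in% DNA_BASES)) {
    stop("germline sequence must contain only A/C/G/T")
  }
  n <- length(s)
  prev1 <- c(NA_character_, s[-n])
  prev2 <- c(NA_character_, NA_character_, s[seq_len(max(n - 2L, 0L))])
  next1 <- c(s[-1L], NA_character_)
  next2 <- c(s[-seq_len(min(2L, n))], rep(NA_character_, min(2L, n)))
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T")
  in_set <- function(x, set) !is.na(x) & x %in% set

  out <- character(n)
  is_c <- s == "C"
  is_g <- s == "G"
  is_a <- s == "A"
  is_t <- s == "T"
  hot_c <- is_c & in_set(prev1, R) & in_set(prev2, W)      # WRC ending here
  hot_g <- is_g & in_set(next1, Y) & in_set(next2, W)      # GYW starting here
  hot_a <- is_a & in_set(prev1, W)                         # WA
  hot_t <- is_t & in_set(next1, W)                         # TW
  out[is_c | is_g] <- "GC_OTHER"
  out[hot_c | hot_g] <- "GC_AID_HOT"
  out[is_a | is_t] <- "AT_OTHER"
  out[hot_a | hot_t] <- "AT_POL_HOT"
  out
}

#' @param position 1-based position within `sequence`.
#' @rdname classify_sites
#' @export
classify_site <- function(sequence, position) {
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    stop("position out of range")
  }
  classify_sites(sequence)[position]
}

.validate_regions <- function(regions, len) {
  stopifnot(is.data.frame(regions), all(c("label", "start", "end") %in% names(regions)))
  if (any(regions$start < 1L) || any(regions$end > len) ||
      any(regions$start > regions$end)) {
    stop("region bounds out of range for sequence of length ", len)
  }
  ord <- order(regions$start)
  r <- regions[ord, , drop = FALSE]
  if (nrow(r) > 1L && any(r$start[-1L] <= r$end[-nrow(r)])) {
    stop("regions overlap")
  }
  r
}

#' Default V-region layout
#'
#' Framework/CDR intervals for a synthetic V amplicon, scaled from a 294-base
#' template (the span of a murine VH gene commonly used as an SHM readout).
#' The final interval, labelled \code{CDR3}, is the clone-tag window the
#' simulator fills with a clone-specific sequence.
#'
#' @param length Sequence length in bases (>= 60).
#' @param cdr3_length Width of the terminal CDR3 tag window.
#' @return A data.frame with columns `label`, `start`, `end` (1-based,
#'   inclusive).
#' @export
default_v_regions <- function(length = 294L, cdr3_length = 15L) {
  stopifnot(length >= 60L, cdr3_length >= 6L, cdr3_length < length / 2)
  body_len <- length - cdr3_length
  # proportions roughly matching FR1/CDR1/FR2/CDR2/FR3 widths of a V exon
  cuts <- round(body_len * cumsum(c(0.28, 0.13, 0.18, 0.18, 0.23)))
  cuts[5L] <- body_len
  starts <- c(1L, cuts[-5L] + 1L)
  data.frame(
    label = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3"),
    start = c(starts, body_len + 1L),
    end = c(cuts, length),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic germline V reference
#'
#' Draws a random sequence with the requested G+C fraction, attaches region
#' annotations and computes the per-site mutation-subtype mask. The default
#' length of 294 bases matches the span of the VH gene segment used as the
#' hypermutation readout locus in C57BL/6 mice.
#'
#' @param length Sequence length in bases (>= 30).
#' @param gc_fraction Expected proportion of G+C bases.
#' @param regions Optional region data.frame (`label`, `start`, `end`,
#'   1-based inclusive, non-overlapping); defaults to
#'   [default_v_regions()].
#' @param seed Integer seed for the base draw.
#' @param name Reference name used in FASTA output.
#' @return A `germline_reference` object: a list with `name`, `sequence`,
#'   `regions` and `subtype_mask`.
#' @export
make_germline <- function(length = 294L, gc_fraction = 0.5, regions = NULL,
                          seed = 17L, name = "synthetic_V") {
  stopifnot(length >= 30L, gc_fraction >= 0, gc_fraction <= 1)
  if (is.null(regions)) regions <- default_v_regions(length)
  regions <- .validate_regions(regions, length)
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- .collapse(sample(DNA_BASES, length, replace = TRUE, prob = p))
  new_germline(name, seq, regions)
}

#' Build a germline reference from an explicit sequence
#'
#' @param name Reference name.
#' @param sequence DNA string over A/C/G/T.
#' @param regions Region data.frame (`label`, `start`, `end`); a region
#'   labelled `CDR3` marks the clone-tag window.
#' @return A `germline_reference`.
#' @export
germline_reference <- function(name, sequence, regions) {
  new_germline(name, toupper(sequence), regions)
}

new_germline <- function(name, sequence, regions) {
  regions <- .validate_regions(regions, nchar(sequence))
  structure(
    list(name = name, sequence = sequence, regions = regions,
         subtype_mask = classify_sites(sequence)),
    class = "germline_reference"
  )
}

#' @export
print.germline_reference <- function(x, ...) {
  cat("germline_reference '", x$name, "': ", nchar(x$sequence), " bases\n", sep = "")
  tab <- table(factor(x$subtype_mask, levels = SUBTYPES))
  cat("  subtype sites:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  regions:", paste0(x$regions$label, "[", x$regions$start, "-",
                           x$regions$end, "]", collapse = " "), "\n")
  invisible(x)
}

#' CDR3 tag interval of a germline reference
#'
#' @param germline A `germline_reference`.
#' @return Integer vector of the positions covered by the region labelled
#'   `CDR3`, or `integer(0)` if there is none.
#' @export
cdr3_interval <- function(germline) {
  r <- germline$regions
  row <- r[r$label == "CDR3", , drop = FALSE]
  if (nrow(row) == 0L) return(integer(0))
  seq.int(row$start[1L], row$end[1L])
}

#' Read and write germline references
#'
#' The on-disk form is a FASTA file plus a sidecar region TSV with columns
#' `name`, `start`, `end`, `label` (1-based inclusive coordinates).
#'
#' @param germline A `germline_reference`.
#' @param fasta,regions_tsv File paths.
#' @return `read_germline()` returns a `germline_reference`.
#' @export
write_germline <- function(germline, fasta, regions_tsv) {
  dna <- Biostrings::DNAStringSet(setNames(germline$sequence, germline$name))
  Biostrings::writeXStringSet(dna, fasta)
  out <- data.frame(name = germline$name, start = germline$regions$start,
                    end = germline$regions$end, label = germline$regions$label)
  write.table(out, regions_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(germline)
}

#' @rdname write_germline
#' @export
read_germline <- function(fasta, regions_tsv) {
  dna <- Biostrings::readDNAStringSet(fasta)
  if (length(dna) != 1L) stop("germline FASTA must contain exactly one record")
  reg <- read.table(regions_tsv, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  new_germline(names(dna)[1L], as.character(dna[[1L]]),
               reg[, c("label", "start", "end")])
}
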