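#' Construct a junction outcome mixture
#'
#' Describes how simulated switch junctions are formed: with probability
#' `p_blunt` the donor prefix and acceptor suffix are joined directly; with
#' `p_mh` they overlap by a shared k-mer written once in the product
#' (microhomology); with `p_ins` untemplated bases are inserted between
#' them. Length distributions are given as probability vectors indexed by
#' length (element k = probability of length k).
#'
#' @param p_blunt,p_mh,p_ins Outcome probabilities; must sum to 1.
#' @param mh_lengths Numeric probability vector over microhomology lengths
#'   1..length(mh_lengths).
#' @param ins_lengths Numeric probability vector over insertion lengths.
#' @return A `junction_mixture` object.
#' @export
junction_mixture <- function(p_blunt, p_mh, p_ins,
                             mh_lengths = c(0.4, 0.3, 0.2, 0.1),
                             ins_lengths = c(0.5, 0.3, 0.2)) {
  probs <- c(p_blunt, p_mh, p_ins)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("p_blunt + p_mh + p_ins must equal 1")
  }
  norm <- function(x) {
    if (any(x < 0) || sum(x) <= 0) stop("length distributions must be non-negative")
    x / sum(x)
  }
  structure(list(p_blunt = p_blunt, p_mh = p_mh, p_ins = p_ins,
                 mh_lengths = norm(mh_lengths), ins_lengths = norm(ins_lengths)),
            class = "junction_mixture")
}

#' Stock junction mixtures per genotype
#'
#' Emulates the qualitative end-joining phenotypes contrasted across
#' resection-proficient and resection-compromised B cells: a WT-like group
#' with frequent, sometimes long microhomologies; a DA-like group skewed
#' towards blunt joints with more and longer insertions; and a KO-like group
#' with mostly short microhomologies.
#'
#' @return Named list of `junction_mixture` objects.
#' @export
default_junction_mixtures <- function() {
  geom_tail <- function(r, k) { v <- r^(seq_len(k)); v / sum(v) }
  list(
    `WT-like` = junction_mixture(0.22, 0.68, 0.10,
                                 mh_lengths = geom_tail(0.78, 12L),
                                 ins_lengths = c(0.6, 0.3, 0.1)),
    `DA-like` = junction_mixture(0.42, 0.30, 0.28,
                                 mh_lengths = geom_tail(0.45, 6L),
                                 ins_lengths = c(0.30, 0.25, 0.20, 0.15, 0.10)),
    `KO-like` = junction_mixture(0.30, 0.60, 0.10,
                                 mh_lengths = geom_tail(0.60, 8L),
                                 ins_lengths = c(0.6, 0.3, 0.1))
  )
}

# place one acceptor slot per requested microhomology length; slot k holds a
# copy of the donor k-mer ending at the fixed donor break, flanked by bases
# chosen to stop prefix/suffix extension at the engineered breakpoints
.plant_mh_blocks <- function(donor, acceptor, ks, p0, suffix_max) {
  a <- .chars(acceptor); d <- .chars(donor)
  slots <- integer(length(ks)); names(slots) <- ks
  cur <- 15L
  for (i in seq_along(ks)) {
    k <- ks[i]
    a_k <- cur + 1L
    if (a_k + k + suffix_max - 1L > length(a)) {
      stop("acceptor too short for requested microhomology lengths")
    }
    a[a_k:(a_k + k - 1L)] <- d[(p0 - k + 1L):p0]
    a[a_k - 1L] <- sample(setdiff(DNA_BASES, d[p0 - k]), 1L)
    a[a_k + k] <- sample(setdiff(DNA_BASES, d[p0 + 1L]), 1L)
    slots[i] <- a_k
    cur <- a_k + k + 1L
  }
  list(acceptor = .collapse(a), slots = slots)
}

#' Simulate switch-junction sequences with known scores
#'
#' Builds `n` junction sequences from a donor (S-mu-like) and acceptor
#' (S-gamma3-like) reference according to a [junction_mixture()]. Blunt
#' junctions join a donor prefix directly to an acceptor suffix;
#' microhomology junctions share an engineered k-mer, present in both
#' references at the breakpoints but written once in the product; insertion
#' junctions carry untemplated bases matching neither reference
#' continuation. Every emitted junction is verified by direct substring
#' checks to have an unambiguous breakpoint context (the maximal donor
#' prefix and acceptor suffix are exactly the engineered ones), so the
#' recorded truth score is recoverable by exact decomposition.
#'
#' Microhomology junctions share one fixed donor breakpoint per length
#' (breakpoint clustering, as seen in real switch regions); blunt and
#' insertion junctions draw their breakpoints freely.
#'
#' @param mixture A `junction_mixture`.
#' @param n Number of junctions.
#' @param donor,acceptor Reference sequences (default: random 200/260-mers).
#' @param seed Integer seed.
#' @param prefix_range,suffix_range Ranges (min,max) for donor prefix and
#'   acceptor suffix lengths in the junction.
#' @param anchor_min Minimum anchor used downstream; ranges must exceed it.
#' @return A list: `junctions` (named character), `truth` (data.frame with
#'   `id`, `type`, `score`, `donor_break`, `acceptor_break`), `donor`,
#'   `acceptor`.
#' @export
simulate_junctions <- function(mixture, n, donor = NULL, acceptor = NULL,
                               seed = 17L, prefix_range = c(25L, 40L),
                               suffix_range = c(25L, 40L), anchor_min = 10L) {
  stopifnot(inherits(mixture, "junction_mixture"), n >= 1L,
            prefix_range[1L] >= anchor_min, suffix_range[1L] >= anchor_min)
  set.seed(seed)
  if (is.null(donor)) donor <- .random_dna(200L)
  if (is.null(acceptor)) acceptor <- .random_dna(260L)
  if (nchar(donor) < 40L || nchar(acceptor) < 40L) {
    stop("donor and acceptor must each be at least 40 bases")
  }
  d <- .chars(donor)
  lenD <- length(d); lenA <- nchar(acceptor)
  p0 <- prefix_range[2L]
  kmax <- length(mixture$mh_lengths)
  if (mixture$p_mh > 0 && (p0 - kmax < 1L || p0 + 1L > lenD)) {
    stop("donor too short for the fixed microhomology breakpoint")
  }

  types <- sample(c("blunt", "mh", "ins"), n, replace = TRUE,
                  prob = c(mixture$p_blunt, mixture$p_mh, mixture$p_ins))
  mh_k <- which(types == "mh")
  ks_drawn <- if (length(mh_k)) {
    sample.int(kmax, length(mh_k), replace = TRUE, prob = mixture$mh_lengths)
  } else integer(0)
  planted <- if (length(ks_drawn)) {
    .plant_mh_blocks(donor, acceptor, sort(unique(ks_drawn)), p0,
                     suffix_range[2L])
  } else list(acceptor = acceptor, slots = integer(0))
  acceptor <- planted$acceptor
  a <- .chars(acceptor)

  pick <- function(x) x[sample.int(length(x), 1L)]
  draw_range <- function(r) pick(seq.int(r[1L], r[2L]))
  not_in <- function(pat, subject) !grepl(pat, subject, fixed = TRUE)

  juncs <- character(n)
  truth <- data.frame(id = sprintf("jct%04d", seq_len(n)), type = types,
                      score = NA_integer_, donor_break = NA_integer_,
                      acceptor_break = NA_integer_, stringsAsFactors = FALSE)
  k_iter <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(200L)) {
      if (types[i] == "mh") {
        k_cur <- ks_drawn[match(i, mh_k)]
        a_k <- planted$slots[[as.character(k_cur)]]
        q <- min(draw_range(suffix_range), lenA - (a_k + k_cur) + 1L)
        J <- paste0(substr(donor, 1L, p0),
                    substr(acceptor, a_k + k_cur, a_k + k_cur + q - 1L))
        Lj <- nchar(J)
        ext_p <- substr(J, 1L, p0 + 1L)
        ext_s <- substr(J, Lj - (q + k_cur), Lj)
        if (not_in(ext_p, donor) && not_in(ext_s, acceptor)) {
          truth$score[i] <- k_cur
          truth$donor_break[i] <- p0
          truth$acceptor_break[i] <- a_k + k_cur
          juncs[i] <- J; ok <- TRUE
        }
      } else {
        p <- draw_range(prefix_range)
        q <- draw_range(suffix_range)
        j <- pick(seq.int(2L, lenA - q + 1L))
        if (types[i] == "blunt") {
          if (a[j - 1L] == d[p] || a[j] == d[p + 1L]) next
          J <- paste0(substr(donor, 1L, p), substr(acceptor, j, j + q - 1L))
          ext_p <- substr(J, 1L, p + 1L)
          ext_s <- paste0(d[p], substr(J, nchar(J) - q + 1L, nchar(J)))
          if (not_in(ext_p, donor) && not_in(ext_s, acceptor)) {
            truth$score[i] <- 0L
            truth$donor_break[i] <- p; truth$acceptor_break[i] <- j
            juncs[i] <- J; ok <- TRUE
          }
        } else {
          m <- sample.int(length(mixture$ins_lengths), 1L,
                          prob = mixture$ins_lengths)
          ins <- .chars(.random_dna(m))
          alt <- function(b) sample(setdiff(DNA_BASES, b), 1L)
          if (ins[1L] == d[p + 1L]) ins[1L] <- alt(d[p + 1L])
          if (ins[m] == a[j - 1L]) ins[m] <- alt(a[j - 1L])
          J <- paste0(substr(donor, 1L, p), .collapse(ins),
                      substr(acceptor, j, j + q - 1L))
          ext_p <- substr(J, 1L, p + 1L)
          ext_s <- paste0(ins[m], substr(acceptor, j, j + q - 1L))
          if (not_in(ext_p, donor) && not_in(ext_s, acceptor)) {
            truth$score[i] <- -m
            truth$donor_break[i] <- p; truth$acceptor_break[i] <- j
            juncs[i] <- J; ok <- TRUE
          }
        }
      }
      if (ok) break
    }
    if (!ok) stop("failed to engineer an unambiguous junction after 200 attempts")
  }
  names(juncs) <- truth$id
  list(junctions = juncs, truth = truth, donor = donor, acceptor = acceptor)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(sequences)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), names(dna))
}
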