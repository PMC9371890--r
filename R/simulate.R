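.random_dna <- function(n, gc_fraction = 0.5) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  .collapse(sample(DNA_BASES, n, replace = TRUE, prob = p))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sample target bases for a vector of source bases under a bias matrix
.draw_targets <- function(from, bias) {
  out <- character(length(from))
  for (b in DNA_BASES) {
    idx <- which(from == b)
    if (length(idx)) {
      out[idx] <- sample(DNA_BASES, length(idx), replace = TRUE,
                         prob = bias[b, ])
    }
  }
  out
}

#' Simulate a clonally structured VH repertoire
#'
#' Generates mutated copies of a germline V reference organised into CDR3
#' clones. Each clone receives (i) a distinct random tag written into the
#' germline's CDR3 window, which downstream stages use for clonal grouping,
#' and (ii) a founder set of inherited mutations shared by every clone
#' member, drawn per site at the profile rate scaled by
#' `inherited_fraction`. Each member additionally acquires private mutations
#' at the full profile rate at sites not already mutated in its founder set,
#' so no site mutates more than once per molecule. Target bases follow the
#' profile's substitution bias. The inherited/private split reproduces the
#' clonal inflation artifact that single-sequence-per-clone resampling is
#' designed to remove.
#'
#' @param germline A `germline_reference` with a `CDR3` region.
#' @param profile A `genotype_profile`.
#' @param n_clones Number of clones (>= 1).
#' @param clone_size_dist Either a single integer (all clones that size), an
#'   integer vector of length `n_clones`, or a function `n -> sizes`.
#'   Default: 1 + geometric(0.5), mean size 2.
#' @param inherited_fraction Scale in [0,1] applied to the profile rates
#'   when drawing the founder (inherited) mutation set.
#' @param seed Integer seed.
#' @return A list with `sequences` (named character vector, one molecule
#'   per entry) and `truth` (a `simulation_truth` object with `clones`,
#'   `molecules` and `mutations` data.frames).
#' @export
simulate_repertoire <- function(germline, profile, n_clones = 200L,
                                clone_size_dist = NULL,
                                inherited_fraction = 0.2, seed = 17L) {
  stopifnot(inherits(germline, "germline_reference"),
            inherits(profile, "genotype_profile"),
            n_clones >= 1L,
            inherited_fraction >= 0, inherited_fraction <= 1)
  tag <- cdr3_interval(germline)
  if (length(tag) == 0L) stop("germline has no CDR3 region to carry clone tags")
  set.seed(seed)

  sizes <- if (is.null(clone_size_dist)) {
    1L + rgeom(n_clones, prob = 0.5)
  } else if (is.function(clone_size_dist)) {
    as.integer(clone_size_dist(n_clones))
  } else if (length(clone_size_dist) == 1L) {
    rep(as.integer(clone_size_dist), n_clones)
  } else {
    if (length(clone_size_dist) != n_clones) {
      stop("clone_size_dist vector must have length n_clones")
    }
    as.integer(clone_size_dist)
  }
  if (any(sizes < 1L)) stop("clone sizes must be >= 1")

  L <- nchar(germline$sequence)
  g_chars <- .chars(germline$sequence)
  elig <- setdiff(seq_len(L), tag)
  mu_site <- unname(profile$mu[germline$subtype_mask[elig]])
  n_elig <- length(elig)

  # distinct clone tags
  tags <- vapply(seq_len(n_clones), function(i) .random_dna(length(tag)),
                 character(1))
  while (anyDuplicated(tags)) {
    dup <- which(duplicated(tags))
    tags[dup] <- vapply(dup, function(i) .random_dna(length(tag)), character(1))
  }

  clone_ids <- sprintf("clone%05d", seq_len(n_clones))
  n_mol <- sum(sizes)
  mol_clone <- rep.int(seq_len(n_clones), sizes)
  mol_ids <- sprintf("mol%05d", seq_len(n_mol))

  # founder (inherited) mutation sites, one draw per clone x eligible site
  founder <- matrix(runif(n_clones * n_elig), n_clones, n_elig) <
    rep(mu_site * inherited_fraction, each = n_clones)
  # private sites per molecule, blocked at that clone's founder sites
  private <- matrix(runif(n_mol * n_elig), n_mol, n_elig) <
    rep(mu_site, each = n_mol)
  private <- private & !founder[mol_clone, , drop = FALSE]

  # founder substitutions are shared within the clone: draw once per event
  f_idx <- which(founder, arr.ind = TRUE)
  f_pos <- elig[f_idx[, 2L]]
  f_to <- .draw_targets(g_chars[f_pos], profile$substitution_bias)
  p_idx <- which(private, arr.ind = TRUE)
  p_pos <- elig[p_idx[, 2L]]
  p_to <- .draw_targets(g_chars[p_pos], profile$substitution_bias)

  # expand founder events to clone members
  f_by_clone <- split(seq_along(f_pos), f_idx[, 1L])
  mut_list <- vector("list", n_mol)
  seqs <- character(n_mol)
  p_by_mol <- split(seq_along(p_pos), factor(p_idx[, 1L], levels = seq_len(n_mol)))
  for (m in seq_len(n_mol)) {
    cl <- mol_clone[m]
    fe <- f_by_clone[[as.character(cl)]]
    pe <- p_by_mol[[m]]
    pos <- c(f_pos[fe], p_pos[pe])
    to <- c(f_to[fe], p_to[pe])
    inh <- c(rep(TRUE, length(fe)), rep(FALSE, length(pe)))
    s <- g_chars
    s[pos] <- to
    s[tag] <- .chars(tags[cl])
    seqs[m] <- .collapse(s)
    if (length(pos)) {
      o <- order(pos)
      mut_list[[m]] <- data.frame(
        molecule_id = mol_ids[m], clone_id = clone_ids[cl],
        position = pos[o], from_base = g_chars[pos][o], to_base = to[o],
        inherited = inh[o], stringsAsFactors = FALSE)
    }
  }
  mutations <- do.call(rbind, mut_list[!vapply(mut_list, is.null, logical(1))])
  if (is.null(mutations)) {
    mutations <- data.frame(molecule_id = character(), clone_id = character(),
                            position = integer(), from_base = character(),
                            to_base = character(), inherited = logical(),
                            stringsAsFactors = FALSE)
  }
  mutations$subtype <- germline$subtype_mask[mutations$position]

  truth <- structure(list(
    profile = profile,
    germline_name = germline$name,
    clones = data.frame(clone_id = clone_ids, cdr3 = tags, size = sizes,
                        stringsAsFactors = FALSE),
    molecules = data.frame(molecule_id = mol_ids,
                           clone_id = clone_ids[mol_clone],
                           stringsAsFactors = FALSE),
    mutations = mutations
  ), class = "simulation_truth")

  list(sequences = setNames(seqs, mol_ids), truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth:", nrow(x$molecules), "molecules in",
      nrow(x$clones), "clones;", nrow(x$mutations), "mutations (",
      sum(x$mutations$inherited), "inherited )\n")
  invisible(x)
}

.inject_errors <- function(strings, error_rate) {
  if (error_rate <= 0) return(strings)
  n_err <- rbinom(length(strings), nchar(strings), error_rate)
  for (i in which(n_err > 0L)) {
    s <- .chars(strings[i])
    pos <- sample.int(length(s), n_err[i])
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1))
    strings[i] <- .collapse(s)
  }
  strings
}

#' Simulate UMI-tagged paired-end reads
#'
#' Each molecule is assigned a distinct random UMI, prepended to read 1.
#' Read 1 covers the 5' end of the molecule (after the UMI), read 2 is the
#' reverse complement of the 3' end; read lengths are chosen so the two
#' mates overlap in the middle, as in an overlap-assembled amplicon design.
#' Substitution errors are injected i.i.d. at `error_rate` into the
#' molecule-derived bases (UMI bases are kept error-free, matching the
#' exact-UMI collapse downstream). Qualities are the constant Phred+33
#' character `I`.
#'
#' @param sequences Named character vector of molecule sequences (equal
#'   lengths).
#' @param umi_length UMI length in bases (>= 4).
#' @param reads_per_molecule Read pairs per molecule (>= 1).
#' @param error_rate Per-base substitution error probability.
#' @param read_length Length of each sequenced read (including the UMI on
#'   read 1).
#' @param min_overlap Required mate overlap; shorter geometries error out.
#' @param seed Integer seed.
#' @return A list with `reads` (data.frame: `read_id`, `molecule_id`,
#'   `r1_seq`, `r2_seq`, `r1_qual`, `r2_qual`) and `umi_map` (data.frame:
#'   `umi`, `molecule_id`).
#' @export
simulate_reads <- function(sequences, umi_length = 8L, reads_per_molecule = 3L,
                           error_rate = 0.001, read_length = 180L,
                           min_overlap = 20L, seed = 17L) {
  stopifnot(umi_length >= 4L, reads_per_molecule >= 1L,
            error_rate >= 0, error_rate < 1)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("molecules must have equal length")
  insert1 <- read_length - umi_length
  if (insert1 > L || read_length > L) {
    stop("read length exceeds molecule length")
  }
  overlap <- insert1 + read_length - L
  if (overlap < min_overlap) {
    stop("mate overlap (", overlap, ") shorter than min_overlap (",
         min_overlap, "); requested geometry does not cover the molecule")
  }
  set.seed(seed)
  n <- length(sequences)
  umis <- vapply(seq_len(n), function(i) .random_dna(umi_length), character(1))
  while (anyDuplicated(umis)) {
    dup <- which(duplicated(umis))
    umis[dup] <- vapply(dup, function(i) .random_dna(umi_length), character(1))
  }
  mol_ids <- names(sequences)
  rep_idx <- rep(seq_len(n), each = reads_per_molecule)
  copy <- rep(seq_len(reads_per_molecule), times = n)
  fwd <- substr(sequences[rep_idx], 1L, insert1)
  rev_tpl <- .revcomp(substr(sequences[rep_idx], L - read_length + 1L, L))
  fwd <- .inject_errors(fwd, error_rate)
  rev_tpl <- .inject_errors(rev_tpl, error_rate)
  reads <- data.frame(
    read_id = paste0(mol_ids[rep_idx], ":", copy),
    molecule_id = mol_ids[rep_idx],
    r1_seq = paste0(umis[rep_idx], fwd),
    r2_seq = rev_tpl,
    r1_qual = strrep("I", read_length),
    r2_qual = strrep("I", read_length),
    stringsAsFactors = FALSE
  )
  list(reads = reads,
       umi_map = data.frame(umi = umis, molecule_id = mol_ids,
                            stringsAsFactors = FALSE))
}

#' Write and read paired FASTQ files
#'
#' @param reads The `reads` data.frame from [simulate_reads()].
#' @param r1_path,r2_path Output FASTQ paths (uncompressed).
#' @return `read_fastq_pairs()` returns a data.frame in the same layout.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  r1 <- Biostrings::DNAStringSet(setNames(reads$r1_seq, reads$read_id))
  r2 <- Biostrings::DNAStringSet(setNames(reads$r2_seq, reads$read_id))
  Biostrings::writeXStringSet(r1, r1_path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$r1_qual))
  Biostrings::writeXStringSet(r2, r2_path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$r2_qual))
  invisible(reads)
}

#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2) || !identical(names(r1), names(r2))) {
    stop("mate files disagree in read ids")
  }
  data.frame(
    read_id = names(r1),
    r1_seq = as.character(r1), r2_seq = as.character(r2),
    r1_qual = as.character(S4Vectors::mcols(r1)$qualities),
    r2_qual = as.character(S4Vectors::mcols(r2)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-animal class-switch fractions
#'
#' Each animal's switched-cell fraction is Binomial(`n_cells`, `p_switch`)
#' divided by `n_cells`, emulating a flow-cytometry switching readout.
#'
#' @param p_switch True switching probability in [0,1].
#' @param n_cells Cells scored per animal.
#' @param n_animals Number of animals.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_animals`.
#' @export
simulate_csr_counts <- function(p_switch, n_cells, n_animals, seed = 17L) {
  stopifnot(p_switch >= 0, p_switch <= 1, n_cells >= 1L, n_animals >= 1L)
  set.seed(seed)
  rbinom(n_animals, n_cells, p_switch) / n_cells
}
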