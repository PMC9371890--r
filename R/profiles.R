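#' Default substitution bias matrix
#'
#' Target-base distribution given the germline source base. Rows are source
#' bases, columns target bases; each row sums to 1 with a zero diagonal.
#' The default favours transitions (probability 0.5) over each transversion
#' (0.25), the dominant pattern of point mutagenesis at immunoglobulin loci.
#'
#' @return A 4x4 numeric matrix with dimnames A/C/G/T.
#' @export
default_substitution_bias <- function() {
  m <- matrix(0.25, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  diag(m) <- 0
  m["A", "G"] <- 0.5; m["G", "A"] <- 0.5
  m["C", "T"] <- 0.5; m["T", "C"] <- 0.5
  # renormalise off-diagonal mass to 1 per row
  m / rowSums(m)
}

#' Construct a genotype mutation profile
#'
#' A profile holds the per-site, per-sequence mutation probabilities for the
#' four site subtypes, plus the substitution bias used to pick target bases.
#' The hotspot/non-hotspot split lets simulations reproduce the contrast
#' between AID-driven G:C mutagenesis (WRC/GYW sites) and polymerase-eta
#' driven A:T mutagenesis (WA/TW sites), and how that balance shifts when
#' error-prone mismatch repair is compromised.
#'
#' @param name Profile label.
#' @param mu_gc_hot,mu_gc_other,mu_at_hot,mu_at_other Per-site mutation
#'   probabilities in [0,1] for the four subtypes.
#' @param substitution_bias 4x4 target-base distribution; see
#'   [default_substitution_bias()].
#' @return A `genotype_profile` object.
#' @export
genotype_profile <- function(name, mu_gc_hot, mu_gc_other, mu_at_hot,
                             mu_at_other, substitution_bias = NULL) {
  mu <- setNames(as.numeric(c(mu_gc_hot, mu_gc_other, mu_at_hot, mu_at_other)),
                 SUBTYPES)
  if (anyNA(mu) || any(mu < 0 | mu > 1)) {
    stop("mutation probabilities must lie in [0,1]")
  }
  if (is.null(substitution_bias)) substitution_bias <- default_substitution_bias()
  b <- as.matrix(substitution_bias)
  if (!identical(dim(b), c(4L, 4L)) ||
      !isTRUE(all.equal(unname(rowSums(b)), rep(1, 4))) ||
      any(diag(b) != 0) || any(b < 0)) {
    stop("substitution_bias must be 4x4, rows summing to 1, zero diagonal")
  }
  dimnames(b) <- list(DNA_BASES, DNA_BASES)
  structure(list(name = name, mu = mu, substitution_bias = b),
            class = "genotype_profile")
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat("genotype_profile '", x$name, "'\n", sep = "")
  cat(" ", paste(names(x$mu), format(x$mu, digits = 3), sep = "=",
                 collapse = "  "), "\n")
  invisible(x)
}

#' Stock genotype profiles
#'
#' Three profiles emulating the qualitative SHM phenotypes contrasted in
#' knockout studies of error-prone mismatch repair:
#' \describe{
#'   \item{WT-like}{balanced spectrum with strong A:T hotspot mutagenesis.}
#'   \item{DA-like}{nuclease-dead-like: A:T mutations reduced to an
#'     intermediate level, G:C (especially AID-hotspot) mutations increased.}
#'   \item{KO-like}{null-like: A:T mutations nearly absent, G:C further
#'     concentrated.}
#' }
#' The WT rates double as the reference values for parameter-recovery
#' checks.
#'
#' @return Named list of three `genotype_profile` objects.
#' @export
default_profiles <- function() {
  list(
    `WT-like` = genotype_profile("WT-like",  0.020, 0.005, 0.015, 0.0030),
    `DA-like` = genotype_profile("DA-like",  0.030, 0.006, 0.006, 0.0015),
    `KO-like` = genotype_profile("KO-like",  0.032, 0.008, 0.002, 0.0008)
  )
}
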