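#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats lm coef rbinom rgeom rlnorm rpois runif phyper setNames
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of ACGT sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("AAACTG")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' @param n sequence length in bases.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

is_dna <- function(x) {
  all(grepl("^[ACGT]+$", x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sample() without the scalar-x surprise
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Position-wise homology between two equal-length targets
#'
#' Compares two nuclease target sequences base by base, as used when asking
#' how many positions a target shares with its homologue (e.g. the CCR5
#' right half-site versus its CCR2 counterpart).
#'
#' @param a,b equal-length ACGT strings.
#' @return list with `n_match`, `n_total` and the 1-based
#'   `mismatch_positions`.
#' @export
#' @examples
#' homology_matches(ccr5_right_target, ccr2_right_target)
homology_matches <- function(a, b) {
  if (nchar(a) != nchar(b)) stopf("sequences differ in length (%d vs %d)", nchar(a), nchar(b))
  if (!is_dna(a) || !is_dna(b)) stopf("sequences must be ACGT only")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  list(
    n_match = sum(av == bv),
    n_total = length(av),
    mismatch_positions = which(av != bv)
  )
}

#' Published CCR5/CCR2 right-monomer targets
#'
#' The 12-nt DNA sequence bound by the published 3' (right) CCR5 ZFN
#' monomer, and the homologous sequence at the corresponding position of
#' CCR2. The two differ at a single base (the 3'-most triplet AAG vs AAA),
#' which is the discriminatory position the selection system exploits.
#'
#' @format character scalars of 12 bases.
#' @export
ccr5_right_target <- "AAACTGCAAAAG"

#' @rdname ccr5_right_target
#' @export
ccr2_right_target <- "AAACTGCAAAAA"
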