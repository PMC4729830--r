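# SELEX discrimination profiling: strict read filtering against the library
# design, seeded subsampling, a flank-anchored position frequency matrix,
# two-strand alignment/trimming against the intended target, and per-position
# on-/off-base discrimination percentages.

#' SELEX library specification
#'
#' Describes the selection oligo: fixed 5'/3' flanks around a randomized
#' variable region. Defaults mirror the 24-nt flanks around a 22-nt core.
#'
#' @param flank5,flank3 fixed flanking sequences (ACGT).
#' @param variable_length length of the randomized core, nt.
#' @param intended_target optional target sequence the matrix is later
#'   aligned to.
#' @return list of class `selex_spec`.
#' @export
selex_spec <- function(flank5 = selex_flank5, flank3 = selex_flank3,
                       variable_length = 22L, intended_target = NULL) {
  if (!nzchar(flank5) || !nzchar(flank3) || !is_dna(flank5) || !is_dna(flank3)) {
    stopf("flanks must be nonempty ACGT sequences")
  }
  if (variable_length <= 0) stopf("variable_length must be > 0")
  if (!is.null(intended_target) && !is_dna(intended_target)) {
    stopf("intended_target must be ACGT")
  }
  structure(
    list(flank5 = flank5, flank3 = flank3,
         variable_length = as.integer(variable_length),
         intended_target = intended_target),
    class = "selex_spec"
  )
}

#' Filter SELEX reads for correct length and exact flanks
#'
#' A read is kept iff its length equals
#' `nchar(flank5) + variable_length + nchar(flank3)` and both flanks match
#' exactly; the variable region is extracted from kept reads.
#'
#' @param reads character vector of read sequences.
#' @param spec a [selex_spec()].
#' @return list: `cores` (variable regions of kept reads), `kept` (logical
#'   per input read), `rejections` (named tally: length, flank).
#' @export
filter_selex_reads <- function(reads, spec) {
  n5 <- nchar(spec$flank5); n3 <- nchar(spec$flank3)
  expected <- n5 + spec$variable_length + n3
  len_ok <- nchar(reads) == expected
  flank_ok <- rep(FALSE, length(reads))
  flank_ok[len_ok] <-
    substr(reads[len_ok], 1L, n5) == spec$flank5 &
    substr(reads[len_ok], expected - n3 + 1L, expected) == spec$flank3
  kept <- len_ok & flank_ok
  list(
    cores = substr(reads[kept], n5 + 1L, n5 + spec$variable_length),
    kept = kept,
    rejections = c(length = sum(!len_ok), flank = sum(len_ok & !flank_ok))
  )
}

#' Uniform subsample of filtered reads
#'
#' Seeded, reproducible sampling without replacement; by convention 200
#' reads feed the matrix build. When fewer are available, all are returned
#' with a warning.
#'
#' @param cores character vector of filtered variable regions.
#' @param n sample size, default 200.
#' @param seed RNG seed used for the draw.
#' @return character vector of sampled regions, with the seed recorded in
#'   attribute `"seed"`.
#' @export
sample_selex_reads <- function(cores, n = 200L, seed = 1L) {
  if (!length(cores)) stopf("no filtered reads to sample from")
  if (n < 1L) stopf("n must be >= 1")
  set.seed(seed)
  out <- if (length(cores) <= n) {
    if (length(cores) < n) {
      warning(sprintf("only %d filtered reads available (requested %d); using all",
                      length(cores), n), call. = FALSE)
    }
    cores
  } else {
    resample(cores, n)
  }
  attr(out, "seed") <- seed
  out
}

#' Build a position frequency matrix from aligned variable regions
#'
#' `frequency(b, i) = (count(b, i) + pseudocount) / (n + 4 * pseudocount)`.
#' The fixed flanks of the library anchor the register, so no de novo motif
#' discovery is needed: every region contributes at its native position.
#'
#' @param cores equal-length character vector of variable regions.
#' @param pseudocount added per cell, default 0.5.
#' @return 4 x L numeric matrix of class `pfm`, rows A/C/G/T, columns
#'   summing to 1; attributes `n_reads` and `pseudocount`.
#' @export
build_pfm <- function(cores, pseudocount = 0.5) {
  if (!length(cores)) stopf("no reads supplied")
  if (length(unique(nchar(cores))) != 1L) stopf("variable regions have mixed lengths")
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(cores))
  counts <- matrix(0, 4L, nchar(cores[1]), dimnames = list(DNA_BASES, NULL))
  for (b in intersect(rownames(cm), DNA_BASES)) counts[b, ] <- cm[b, ]
  n <- length(cores)
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  structure(freq, class = c("pfm", class(freq)),
            n_reads = n, pseudocount = pseudocount)
}

pfm_score <- function(pfm, target_chars, offset) {
  rows <- match(target_chars, rownames(pfm))
  sum(pfm[cbind(rows, offset + seq_along(target_chars))])
}

complement_rows <- function(m) {
  out <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' Align a PFM to the intended target and trim it
#'
#' Scores every (offset, strand) placement of the target under the matrix as
#' the summed frequency of the target base per column (the reverse strand
#' scores the reverse complement of the target). The exhaustive best
#' placement wins; ties prefer the forward strand, then the smallest offset.
#' The matrix is trimmed to the target-length columns under the best
#' placement and reported in target orientation.
#'
#' @param pfm a [build_pfm()] matrix of length L.
#' @param intended_target ACGT string with `nchar(.) <= L`.
#' @return list: `alignment` (offset 0-based, strand "forward"/"reverse",
#'   score) and `pfm_trimmed` (4 x nchar(target), target orientation).
#' @export
align_and_trim_pfm <- function(pfm, intended_target) {
  if (!is_dna(intended_target)) stopf("intended_target must be ACGT")
  L <- ncol(pfm); Tn <- nchar(intended_target)
  if (L < Tn) stopf("matrix (L=%d) shorter than target (%d)", L, Tn)
  fwd <- strsplit(intended_target, "")[[1]]
  rev_t <- strsplit(revcomp(intended_target), "")[[1]]
  best <- list(score = -Inf, offset = NA_integer_, strand = NA_character_)
  for (strand in c("forward", "reverse")) {
    chars <- if (strand == "forward") fwd else rev_t
    for (off in 0:(L - Tn)) {
      s <- pfm_score(pfm, chars, off)
      if (s > best$score + 1e-12) best <- list(score = s, offset = off, strand = strand)
    }
  }
  cols <- best$offset + seq_len(Tn)
  trimmed <- pfm[, cols, drop = FALSE]
  if (best$strand == "reverse") trimmed <- complement_rows(trimmed)
  colnames(trimmed) <- NULL
  list(alignment = best, pfm_trimmed = trimmed)
}

#' Orient variable regions per a matrix alignment
#'
#' Extracts, from each variable region, the window selected by an
#' [align_and_trim_pfm()] alignment and reports it in target orientation
#' (reverse-strand alignments are reverse complemented).
#'
#' @param cores character vector of variable regions.
#' @param alignment the `alignment` element of [align_and_trim_pfm()].
#' @param target_length length of the intended target.
#' @return character vector of target-length oriented windows.
#' @export
orient_regions <- function(cores, alignment, target_length) {
  win <- substr(cores, alignment$offset + 1L, alignment$offset + target_length)
  if (alignment$strand == "reverse") revcomp(win) else win
}

#' Discrimination percentages at critical positions
#'
#' For each discriminatory position, the percentage of reads carrying the
#' intended (on-target) base, the counter-selected (off-target) base, and
#' any other base; the three sum to 100.
#'
#' @param oriented character vector of target-oriented windows (see
#'   [orient_regions()]).
#' @param positions data.frame with columns `index` (1-based position in the
#'   target), `on_base`, `off_base`.
#' @return data.frame: index, on_base, off_base, pct_on, pct_off, pct_other.
#' @export
discrimination_at_positions <- function(oriented, positions) {
  if (!length(oriented)) stopf("empty read set")
  n <- length(oriented)
  out <- positions
  out$pct_on <- NA_real_; out$pct_off <- NA_real_; out$pct_other <- NA_real_
  for (i in seq_len(nrow(positions))) {
    b <- substr(oriented, positions$index[i], positions$index[i])
    on <- 100 * sum(b == positions$on_base[i]) / n
    off <- 100 * sum(b == positions$off_base[i]) / n
    out$pct_on[i] <- on
    out$pct_off[i] <- off
    out$pct_other[i] <- 100 - on - off
  }
  out
}

#' Write a PFM as TSV (position, A, C, G, T)
#' @param pfm a `pfm` matrix.
#' @param path output file.
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- data.frame(position = seq_len(ncol(pfm)), t(unclass(pfm)[DNA_BASES, , drop = FALSE]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a PFM as a minimal MEME-format motif record
#' @param pfm a `pfm` matrix.
#' @param path output file.
#' @param name motif name.
#' @export
write_pfm_meme <- function(pfm, path, name = "motif1") {
  n <- attr(pfm, "n_reads"); if (is.null(n)) n <- 0L
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            ncol(pfm), n),
    apply(unclass(pfm)[DNA_BASES, , drop = FALSE], 2,
          function(col) sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4]))
  )
  writeLines(lines, path)
  invisible(path)
}
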