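# Amplicon indel quantification: per-read global alignment against the
# locus reference, indel calls restricted to a padded cut window, treated vs
# control one-sided Fisher exact tests, Bonferroni correction, and the
# specificity summaries (on:off ratio, aggregate off-target activity, fold
# change versus a comparator).

#' Amplicon locus reference
#'
#' @param name locus name.
#' @param sequence reference amplicon sequence (ACGT).
#' @param cut_start,cut_end 0-based half-open cut interval on the reference.
#' @param pad bp added on each side of the cut interval when deciding
#'   whether an alignment gap counts as a lesion (default 10).
#' @return list of class `amplicon_ref`.
#' @export
amplicon_ref <- function(name, sequence, cut_start, cut_end, pad = 10L) {
  if (!is_dna(sequence)) stopf("reference must be ACGT only")
  L <- nchar(sequence)
  if (cut_start < 0 || cut_end > L || cut_start >= cut_end) {
    stopf("cut interval [%d,%d) not inside reference of length %d", cut_start, cut_end, L)
  }
  structure(
    list(name = name, sequence = sequence, cut_start = cut_start,
         cut_end = cut_end, pad = as.integer(pad)),
    class = "amplicon_ref"
  )
}

#' Globally align reads to an amplicon reference
#'
#' Needleman-Wunsch global alignment with affine gaps (defaults match +1,
#' mismatch -2, gap open -6, gap extend -1 per base), with gap coordinates
#' reported in 0-based reference space.
#'
#' @param reads character vector of read sequences (each >= 20 bp).
#' @param ref an [amplicon_ref()].
#' @param match,mismatch,gap_open,gap_extend scoring parameters (penalties
#'   as negative numbers).
#' @return list, one element per read, each with `score`, `identity`
#'   (fraction matching over non-gap columns), `deletions` (data.frame
#'   start/end, 0-based half-open in reference space), `insertions`
#'   (data.frame at/length; `at` = number of reference bases before the
#'   insertion point).
#' @export
align_reads <- function(reads, ref, match = 1, mismatch = -2,
                        gap_open = -6, gap_extend = -1) {
  if (!length(reads)) stopf("no reads supplied")
  if (any(nchar(reads) < 20L)) stopf("reads must be >= 20 bp")
  if (!all(grepl("^[ACGT]+$", reads))) stopf("reads must be ACGT only")
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE
  )
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads), Biostrings::DNAString(ref$sequence),
    type = "global", substitutionMatrix = submat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend)
  )
  scores <- Biostrings::score(aln)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  # indel accessors report 1-based reference (subject) coordinates
  del_start <- as.list(BiocGenerics::start(Biostrings::deletion(aln)))
  del_end <- as.list(BiocGenerics::end(Biostrings::deletion(aln)))
  ins_start <- as.list(BiocGenerics::start(Biostrings::insertion(aln)))
  ins_width <- as.list(BiocGenerics::width(Biostrings::insertion(aln)))
  lapply(seq_along(reads), function(i) {
    list(
      score = scores[i],
      identity = if (nm[i] + nmm[i] > 0) nm[i] / (nm[i] + nmm[i]) else 0,
      deletions = data.frame(start = del_start[[i]] - 1L, # 0-based half-open
                             end = del_end[[i]]),
      insertions = data.frame(at = ins_start[[i]] - 1L, # ref bases before gap
                              length = ins_width[[i]])
    )
  })
}

#' Call indels at a locus
#'
#' A read is indel-positive iff an alignment gap overlaps the padded cut
#' window `[cut_start - pad, cut_end + pad)`. Reads whose non-gap alignment
#' identity falls below `min_identity` are discarded rather than scored.
#'
#' @param reads character vector of reads.
#' @param ref an [amplicon_ref()].
#' @param min_identity minimum fraction of matching non-gap columns
#'   (default 0.6).
#' @param ... scoring parameters passed to [align_reads()].
#' @return list: `calls` (logical per scored read), `n_scored`, `n_indel`,
#'   `frequency` (percent), `n_discarded`.
#' @export
call_indels_for_locus <- function(reads, ref, min_identity = 0.6, ...) {
  alns <- align_reads(reads, ref, ...)
  ws <- ref$cut_start - ref$pad
  we <- ref$cut_end + ref$pad
  scored <- vapply(alns, function(a) a$identity >= min_identity, TRUE)
  if (!any(scored)) stopf("zero reads scored at locus '%s'", ref$name)
  calls <- vapply(alns[scored], function(a) {
    del_hit <- nrow(a$deletions) > 0 &&
      any(a$deletions$start < we & a$deletions$end > ws)
    ins_hit <- nrow(a$insertions) > 0 &&
      any(a$insertions$at >= ws & a$insertions$at <= we)
    del_hit || ins_hit
  }, TRUE)
  list(
    calls = calls, n_scored = sum(scored), n_indel = sum(calls),
    frequency = 100 * sum(calls) / sum(scored),
    n_discarded = sum(!scored)
  )
}

#' One-sided Fisher exact test of treated vs control indel counts
#'
#' Tests whether the treated indel proportion exceeds the control's, as the
#' one-sided Fisher exact probability of the 2x2 table — the upper
#' hypergeometric tail `P(X >= treated_indel)` with the table margins fixed.
#' Vectorised over tables.
#'
#' @param treated_indel,treated_total treated indel and total read counts.
#' @param control_indel,control_total control counts.
#' @return numeric vector of one-sided p-values.
#' @export
compare_to_control <- function(treated_indel, treated_total,
                               control_indel, control_total) {
  if (any(treated_total <= 0) || any(control_total <= 0)) stopf("totals must be > 0")
  if (any(treated_indel > treated_total) || any(control_indel > control_total)) {
    stopf("indel count exceeds total")
  }
  if (any(c(treated_indel, control_indel) < 0)) stopf("counts must be >= 0")
  phyper(treated_indel - 1, treated_total, control_total,
         treated_indel + control_indel, lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' `adjusted = min(1, p * m)` with `m` the number of loci tested in the
#' batch (defaults to `length(p)`).
#'
#' @param p p-values in \[0,1\].
#' @param m number of comparisons.
#' @return adjusted p-values.
#' @export
adjust_bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stopf("p-values must be in [0,1]")
  pmin(1, p * m)
}

#' On:off specificity ratio
#'
#' Ratio of on-target to off-target indel frequency. A zero off-target
#' frequency is censored against the batch background floor (for example
#' the GFP-control frequency) and reported as `> on/floor`.
#'
#' @param on,off frequencies (percent), >= 0.
#' @param floor background floor used when `off` is 0.
#' @return list: ratio, censored (ratio is a lower bound), undefined (both
#'   frequencies 0 and no usable floor), label (printable form).
#' @export
specificity_ratio <- function(on, off, floor = 0.1) {
  if (on < 0 || off < 0) stopf("frequencies must be >= 0")
  if (off > 0) {
    r <- on / off
    return(list(ratio = r, censored = FALSE, undefined = FALSE,
                label = formatC(r, format = "fg", digits = 3)))
  }
  if (on == 0 || is.null(floor) || floor <= 0) {
    return(list(ratio = NA_real_, censored = FALSE, undefined = TRUE, label = "undefined"))
  }
  r <- on / floor
  list(ratio = r, censored = TRUE, undefined = FALSE,
       label = paste0("> ", formatC(r, format = "fg", digits = 3)))
}

#' Aggregate off-target activity and fold change
#'
#' A locus is active when its Bonferroni-adjusted p-value is below `alpha`
#' and its treated frequency exceeds the control frequency. The aggregate is
#' the sum of active frequencies; when a comparator aggregate is supplied
#' the fold decrease `comparator / aggregate` is reported rounded to the
#' nearest integer.
#'
#' @param results data.frame with columns `frequency`, `control_frequency`,
#'   `adjusted_p` (one row per off-target locus).
#' @param alpha significance level, default 0.05.
#' @param comparator optional comparator aggregate (percent).
#' @param floor background floor used to censor the fold when the aggregate
#'   is 0.
#' @return list: active (logical per locus), n_active, aggregate (percent),
#'   fold (integer or NA), fold_censored, fold_label.
#' @export
aggregate_offtarget <- function(results, alpha = 0.05, comparator = NULL,
                                floor = 0.1) {
  need <- c("frequency", "control_frequency", "adjusted_p")
  if (!all(need %in% names(results))) {
    stopf("results must have columns %s", paste(need, collapse = ", "))
  }
  active <- results$adjusted_p < alpha & results$frequency > results$control_frequency
  aggregate <- sum(results$frequency[active])
  out <- list(active = active, n_active = sum(active), aggregate = aggregate,
              fold = NA_real_, fold_censored = FALSE, fold_label = NA_character_)
  if (!is.null(comparator)) {
    if (aggregate > 0) {
      out$fold <- round(comparator / aggregate)
      out$fold_label <- as.character(out$fold)
    } else {
      out$fold <- round(comparator / floor)
      out$fold_censored <- TRUE
      out$fold_label <- paste0(">= ", out$fold)
    }
  }
  out
}

#' Assemble per-locus results for treated vs control read sets
#'
#' Convenience wrapper: calls indels for both read sets, tests treated
#' against control, and returns one row per locus. Bonferroni adjustment is
#' applied over the batch.
#'
#' @param loci list of [amplicon_ref()] objects.
#' @param treated_reads,control_reads lists (parallel to `loci`) of read
#'   vectors.
#' @param alpha significance level for the `active` flag.
#' @param ... passed to [call_indels_for_locus()].
#' @return data.frame of class `locus_results`: locus, n_reads, n_indel,
#'   frequency, control_n_reads, control_n_indel, control_frequency,
#'   p_value, adjusted_p, active.
#' @export
locus_results <- function(loci, treated_reads, control_reads, alpha = 0.05, ...) {
  stopifnot(length(loci) == length(treated_reads),
            length(loci) == length(control_reads))
  rows <- lapply(seq_along(loci), function(i) {
    tr <- call_indels_for_locus(treated_reads[[i]], loci[[i]], ...)
    ct <- call_indels_for_locus(control_reads[[i]], loci[[i]], ...)
    data.frame(
      locus = loci[[i]]$name,
      n_reads = tr$n_scored, n_indel = tr$n_indel, frequency = tr$frequency,
      control_n_reads = ct$n_scored, control_n_indel = ct$n_indel,
      control_frequency = ct$frequency,
      p_value = compare_to_control(tr$n_indel, tr$n_scored, ct$n_indel, ct$n_scored),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$adjusted_p <- adjust_bonferroni(res$p_value, m = nrow(res))
  res$active <- res$adjusted_p < alpha & res$frequency > res$control_frequency
  class(res) <- c("locus_results", "data.frame")
  res
}
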