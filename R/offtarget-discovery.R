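# IDLV-capture off-target discovery: exact junction mapping on a toy
# genome, per-sample deduplication, 1-kb single-linkage clustering of
# integration coordinates, replicate-based filtering, ranking, and paired
# half-site (nuclease dimer) binding-site annotation.

empty_integration_table <- function() {
  data.frame(
    chrom = character(), position = numeric(), strand = character(),
    sample_id = character(), replicate = integer(), group = character(),
    stringsAsFactors = FALSE
  )
}

check_integration_table <- function(tab) {
  need <- c("chrom", "position", "strand", "sample_id", "replicate", "group")
  if (!all(need %in% names(tab))) {
    stopf("integration table must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(tab) && any(tab$position < 0)) stopf("positions must be >= 0")
  if (nrow(tab) && !all(tab$group %in% c("treated", "control"))) {
    stopf("group must be 'treated' or 'control'")
  }
  invisible(tab)
}

#' Map junction segments to a toy genome by exact search
#'
#' Locates each read's genomic segment by exact match over both strands of
#' the genome. Segments with exactly one hit yield an integration at the
#' match's forward-axis start coordinate (0-based); segments with zero or
#' multiple hits are discarded and tallied.
#'
#' @param segments data.frame with columns `seq`, `sample_id`, `replicate`,
#'   `group`.
#' @param genome a [Biostrings::DNAStringSet] of chromosomes.
#' @return list: `integrations` (integration table), `tally` (named counts:
#'   mapped, unmapped, ambiguous).
#' @export
map_junctions_exact <- function(segments, genome) {
  if (length(genome) == 0L) stopf("empty genome")
  if (is.null(names(genome))) stopf("genome chromosomes must be named")
  rows <- list()
  tally <- c(mapped = 0L, unmapped = 0L, ambiguous = 0L)
  for (i in seq_len(nrow(segments))) {
    seq <- segments$seq[i]
    hits <- list()
    for (cn in names(genome)) {
      hf <- Biostrings::matchPattern(seq, genome[[cn]])
      for (st in Biostrings::start(hf)) {
        hits[[length(hits) + 1L]] <- list(chrom = cn, pos = st - 1L, strand = "+")
      }
      hr <- Biostrings::matchPattern(revcomp(seq), genome[[cn]])
      for (st in Biostrings::start(hr)) {
        hits[[length(hits) + 1L]] <- list(chrom = cn, pos = st - 1L, strand = "-")
      }
    }
    if (length(hits) == 1L) {
      h <- hits[[1L]]
      tally["mapped"] <- tally["mapped"] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = h$chrom, position = h$pos, strand = h$strand,
        sample_id = segments$sample_id[i], replicate = segments$replicate[i],
        group = segments$group[i], stringsAsFactors = FALSE
      )
    } else if (length(hits) == 0L) {
      tally["unmapped"] <- tally["unmapped"] + 1L
    } else {
      tally["ambiguous"] <- tally["ambiguous"] + 1L
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else empty_integration_table()
  list(integrations = tab, tally = tally)
}

#' Collapse duplicate integrations within a sample
#'
#' Records identical in (chrom, position, strand, sample_id) collapse to a
#' single unique integration; the read multiplicity is kept as metadata.
#' The same coordinate seen in different replicates stays distinct.
#'
#' @param tab an integration table.
#' @return the deduplicated table with an added `multiplicity` column.
#' @export
dedupe_integrations <- function(tab) {
  check_integration_table(tab)
  if (!nrow(tab)) {
    out <- tab
    out$multiplicity <- integer()
    return(out)
  }
  key <- paste(tab$chrom, tab$position, tab$strand, tab$sample_id, sep = "\r")
  mult <- table(key)
  keep <- !duplicated(key)
  out <- tab[keep, , drop = FALSE]
  out$multiplicity <- as.integer(mult[paste(out$chrom, out$position, out$strand,
                                            out$sample_id, sep = "\r")])
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge integrations into single-linkage clusters
#'
#' Two integrations belong to one cluster iff they are on the same
#' chromosome and connected by a chain of pairwise gaps each at most
#' `distance` bp (strand ignored). This is the literal "within 1 kb of each
#' other" rule with transitive chaining.
#'
#' @param tab a deduplicated integration table.
#' @param distance maximum chaining distance in bp (default 1000).
#' @return data.frame of clusters: cluster_id, chrom, start, end (0-based
#'   half-open span of member integrations; width 1 for singletons),
#'   n_unique, total_treated, total_control, n_treated_reps,
#'   n_control_reps, ratio (`Inf` when control count is 0), plus
#'   `treated_rep_counts` / `control_rep_counts` list-columns of
#'   per-replicate unique-integration counts. Attribute `"members"` maps
#'   each input row to its cluster_id.
#' @export
merge_clusters <- function(tab, distance = 1000) {
  if (distance <= 0) stopf("distance must be > 0")
  check_integration_table(tab)
  if (!nrow(tab)) {
    return(structure(data.frame(), members = integer()))
  }
  o <- order(tab$chrom, tab$position)
  tab_o <- tab[o, , drop = FALSE]
  new_chrom <- c(TRUE, tab_o$chrom[-1] != tab_o$chrom[-nrow(tab_o)])
  gap_break <- c(TRUE, diff(tab_o$position) > distance)
  cl_o <- cumsum(new_chrom | gap_break)
  members <- integer(nrow(tab)); members[o] <- cl_o

  nc <- cl_o[length(cl_o)]
  first_of <- match(seq_len(nc), cl_o)
  is_tr <- tab_o$group == "treated"
  start <- as.numeric(tapply(tab_o$position, cl_o, min))
  end <- as.numeric(tapply(tab_o$position, cl_o, max)) + 1
  n_unique <- tabulate(cl_o, nc)
  total_treated <- as.integer(rowsum(as.integer(is_tr), cl_o))
  total_control <- n_unique - total_treated
  rep_first <- !duplicated(paste(cl_o, tab_o$group, tab_o$replicate, sep = "\r"))
  n_treated_reps <- as.integer(rowsum(as.integer(rep_first & is_tr), cl_o))
  n_control_reps <- as.integer(rowsum(as.integer(rep_first & !is_tr), cl_o))

  count_by_rep <- function(sel) {
    lst <- rep(list(integer(0)), nc)
    if (any(sel)) {
      sp <- split(tab_o$replicate[sel], cl_o[sel])
      for (nm in names(sp)) {
        tb <- table(sp[[nm]])
        lst[[as.integer(nm)]] <- setNames(as.integer(tb), names(tb))
      }
    }
    lst
  }

  out <- data.frame(
    cluster_id = seq_len(nc),
    chrom = tab_o$chrom[first_of],
    start = start, end = end, n_unique = n_unique,
    total_treated = total_treated, total_control = total_control,
    n_treated_reps = n_treated_reps, n_control_reps = n_control_reps,
    ratio = ifelse(total_control == 0, Inf, total_treated / total_control),
    stringsAsFactors = FALSE
  )
  out$treated_rep_counts <- I(count_by_rep(is_tr))
  out$control_rep_counts <- I(count_by_rep(!is_tr))
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Filter clusters by replicate support
#'
#' Retains clusters with integrations from at least `min_treated_reps`
#' treated replicates and at most `max_control_reps` control replicates —
#' the rule that suppresses background capture into spontaneous breaks.
#'
#' @param clusters output of [merge_clusters()].
#' @param min_treated_reps minimum treated replicates present (default 2).
#' @param max_control_reps maximum control replicates present (default 1).
#' @return list: `kept` (candidate clusters) and `dropped` (with a
#'   machine-readable `drop_reason` column).
#' @export
filter_clusters <- function(clusters, min_treated_reps = 2L, max_control_reps = 1L) {
  if (!nrow(clusters)) return(list(kept = clusters, dropped = clusters))
  too_few <- clusters$n_treated_reps < min_treated_reps
  too_many <- clusters$n_control_reps > max_control_reps
  keep <- !too_few & !too_many
  dropped <- clusters[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$drop_reason <- paste0(
      ifelse(too_few[!keep], "too_few_treated_replicates", ""),
      ifelse(too_few[!keep] & too_many[!keep], ";", ""),
      ifelse(too_many[!keep], "too_many_control_replicates", "")
    )
  } else {
    dropped$drop_reason <- character()
  }
  list(kept = clusters[keep, , drop = FALSE], dropped = dropped)
}

#' Rank candidate clusters
#'
#' Primary key: total unique integrations in treated samples, descending.
#' Ties break by treated replicates present (descending), then the
#' treated:control count ratio (descending; a zero control count ranks
#' first as ratio infinity), then (chrom, start) ascending.
#'
#' @param candidates `kept` element of [filter_clusters()].
#' @param top_n number of clusters to return (default 20).
#' @return the top `top_n` clusters with a `rank` column (1..N).
#' @export
rank_clusters <- function(candidates, top_n = 20L) {
  if (!nrow(candidates)) {
    out <- candidates
    out$rank <- integer()
    return(out)
  }
  o <- order(-candidates$total_treated, -candidates$n_treated_reps,
             -candidates$ratio, candidates$chrom, candidates$start)
  out <- head(candidates[o, , drop = FALSE], top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Scan a window for paired half-site (dimer) binding sites
#'
#' Exhaustively searches a genomic window for the obligate-dimer geometry:
#' one half-site on one strand, a spacer of `spacer_range` bp, and the other
#' half-site on the opposite strand, with the two half-site identities
#' (`left`, `right`) allowed in either order. Hamming mismatches are counted
#' per half-site.
#'
#' @param window ACGT string of the genomic window (forward strand).
#' @param left,right half-site target sequences (ACGT, as bound 5'->3' by
#'   each monomer).
#' @param spacer_range integer vector of allowed spacer lengths (default
#'   4:7).
#' @param max_mismatch maximum Hamming mismatches allowed per half-site.
#' @param window_start genomic coordinate (0-based) of the window's first
#'   base, used to report absolute coordinates.
#' @return data.frame sorted by total mismatches: orientation
#'   ("left-right"/"right-left"), first_start, first_end, spacer,
#'   second_start, second_end (absolute 0-based half-open; first half on
#'   "+", second on "-"), mm_first, mm_second, mm_total.
#' @export
scan_dimer_sites <- function(window, left, right, spacer_range = 4:7,
                             max_mismatch = 2L, window_start = 0) {
  if (!length(spacer_range)) stopf("spacer range is empty")
  if (!is_dna(left) || !is_dna(right)) stopf("half-site targets must be ACGT")
  if (!is_dna(window)) stopf("window must be ACGT")
  wv <- strsplit(window, "")[[1]]
  W <- length(wv)

  mism_profile <- function(site) {
    sv <- strsplit(site, "")[[1]]
    k <- length(sv)
    n_off <- W - k + 1L
    if (n_off < 1L) return(integer(0))
    mm <- integer(n_off)
    for (j in seq_len(k)) mm <- mm + (wv[seq_len(n_off) + j - 1L] != sv[j])
    mm
  }

  pairs <- list(
    list(orientation = "left-right", a = left, b = right),
    list(orientation = "right-left", a = right, b = left)
  )
  out <- list()
  for (p in pairs) {
    mm_a <- mism_profile(p$a) # first half on + strand
    mm_b <- mism_profile(revcomp(p$b)) # second half on - strand, scanned as revcomp
    la <- nchar(p$a); lb <- nchar(p$b)
    for (s in spacer_range) {
      n_pos <- W - la - s - lb + 1L
      if (n_pos < 1L) next
      i <- seq_len(n_pos)
      j <- i + la + s
      ok <- mm_a[i] <= max_mismatch & mm_b[j] <= max_mismatch
      if (any(ok)) {
        io <- i[ok]; jo <- j[ok]
        out[[length(out) + 1L]] <- data.frame(
          orientation = p$orientation,
          first_start = window_start + io - 1L,
          first_end = window_start + io - 1L + la,
          spacer = s,
          second_start = window_start + jo - 1L,
          second_end = window_start + jo - 1L + lb,
          mm_first = mm_a[io], mm_second = mm_b[jo],
          mm_total = mm_a[io] + mm_b[jo],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    orientation = character(), first_start = integer(), first_end = integer(),
    spacer = integer(), second_start = integer(), second_end = integer(),
    mm_first = integer(), mm_second = integer(), mm_total = integer(),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$mm_total, res$first_start, res$spacer), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' End-to-end off-target discovery
#'
#' Runs dedupe -> merge -> filter -> rank on an integration table (or maps
#' junction segments first when `segments` is given), and optionally
#' annotates each ranked cluster with the best paired half-site match in a
#' flanked window of the genome.
#'
#' @param integrations integration table (ignored when `segments` given).
#' @param segments optional junction segments for [map_junctions_exact()].
#' @param genome optional [Biostrings::DNAStringSet]; required for mapping
#'   and for binding-site annotation.
#' @param targets optional list with `left` and `right` half-site sequences.
#' @param distance cluster merge distance, bp.
#' @param min_treated_reps,max_control_reps replicate filter thresholds.
#' @param top_n number of ranked candidates.
#' @param flank bp of genomic context added around a cluster span when
#'   scanning for binding sites (default 250).
#' @param spacer_range,max_mismatch passed to [scan_dimer_sites()].
#' @return list: `candidates` (ranked, annotated), `dropped` (with
#'   reasons), `clusters` (all merged clusters), `tally` (mapping tally or
#'   NULL).
#' @export
discover_offtargets <- function(integrations = NULL, segments = NULL,
                                genome = NULL, targets = NULL,
                                distance = 1000,
                                min_treated_reps = 2L, max_control_reps = 1L,
                                top_n = 20L, flank = 250L,
                                spacer_range = 4:7, max_mismatch = 2L) {
  tally <- NULL
  if (!is.null(segments)) {
    if (is.null(genome)) stopf("mapping junction segments requires a genome")
    mapped <- map_junctions_exact(segments, genome)
    integrations <- mapped$integrations
    tally <- mapped$tally
  }
  if (is.null(integrations)) stopf("either integrations or segments must be supplied")
  uniq <- dedupe_integrations(integrations)
  clusters <- merge_clusters(uniq, distance = distance)
  filt <- filter_clusters(clusters, min_treated_reps, max_control_reps)
  ranked <- rank_clusters(filt$kept, top_n = top_n)

  if (!is.null(targets) && !is.null(genome) && nrow(ranked)) {
    ranked$n_site_matches <- NA_integer_
    ranked$best_site_mm <- NA_integer_
    for (i in seq_len(nrow(ranked))) {
      cn <- ranked$chrom[i]
      if (!cn %in% names(genome)) next
      ws <- max(0, ranked$start[i] - flank)
      we <- min(length(genome[[cn]]), ranked$end[i] + flank)
      win <- as.character(Biostrings::subseq(genome[[cn]], ws + 1, we))
      hits <- scan_dimer_sites(win, targets$left, targets$right,
                               spacer_range = spacer_range,
                               max_mismatch = max_mismatch, window_start = ws)
      ranked$n_site_matches[i] <- nrow(hits)
      ranked$best_site_mm[i] <- if (nrow(hits)) hits$mm_total[1] else NA_integer_
    }
  }
  list(candidates = ranked, dropped = filt$dropped, clusters = clusters,
       tally = tally)
}
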