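# Synthetic-data module: every input the pipeline consumes can be generated
# here with planted ground truth, so all downstream stages are testable
# without external data.

#' Default SELEX library flanks
#'
#' Fixed 5' and 3' flanking sequences of the SELEX selection oligo; the
#' randomized variable region (22 nt by default) sits between them, giving a
#' 70-nt read.
#' @format character scalars (24 bases each).
#' @export
selex_flank5 <- "CAGGGATCCATGCACTGTACGCCC"

#' @rdname selex_flank5
#' @export
selex_flank3 <- "GGGCCACTTGACTGCGGATCCTGG"

#' Simulation configuration
#'
#' Central configuration object for the synthetic-data generators. Every
#' generator is deterministic given the same configuration (including
#' `seed`).
#'
#' @param seed integer RNG seed.
#' @param genome_length total genome length in bp, split evenly over
#'   `n_chromosomes` chromosomes named `chr1..chrN`.
#' @param n_chromosomes number of chromosomes.
#' @param planted_sites list of sites; each a list with elements `chrom`,
#'   `position` (0-based), optional `seq` (ACGT; required when writing the
#'   site into a genome sequence), `kind` (`"on_target"` or `"off_target"`),
#'   `intensity` (Poisson mean of captured integrations per treated
#'   replicate), optional `name` and optional `indel_rate` (truth lesion
#'   rate used by the end-to-end pipeline).
#' @param background_rate uniform background integrations per Mb per
#'   replicate (treated and control alike).
#' @param n_treated,n_control replicate counts per group.
#' @param capture_offset_scale bp scale of the signed geometric offset of a
#'   captured integration around a cut-site center.
#' @param amplicon list: `reference` (ACGT string), `cut_start`/`cut_end`
#'   (0-based half-open cut interval on the reference), `indel_rate`
#'   (fraction of reads carrying a true indel), `indel_lengths` (integer
#'   vector the indel length is drawn from, uniformly), `indel_kinds`
#'   (subset of `c("ins", "del")`), `substitution_error` (per-base
#'   substitution probability), `n_reads`.
#' @param selex list: `flank5`, `flank3`, `variable_length`, `matrix`
#'   (4 x L generating probability matrix, rows A/C/G/T; `NULL` = uniform),
#'   `contaminant_fraction`, `n_reads`.
#' @param facs list: `n_events` (default 20000, the conventional
#'   acquisition floor) and `populations`, a list of components each with
#'   `weight`, `gfp = c(meanlog, sdlog)`, `mcherry = c(meanlog, sdlog)`.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6,
                       n_chromosomes = 1L,
                       planted_sites = list(),
                       background_rate = 1,
                       n_treated = 3L,
                       n_control = 3L,
                       capture_offset_scale = 50,
                       amplicon = list(),
                       selex = list(),
                       facs = list()) {
  amp_default <- list(
    reference = NULL, cut_start = NULL, cut_end = NULL,
    indel_rate = 0, indel_lengths = 1:10, indel_kinds = c("ins", "del"),
    substitution_error = 0.001, n_reads = 5000L
  )
  selex_default <- list(
    flank5 = selex_flank5, flank3 = selex_flank3, variable_length = 22L,
    matrix = NULL, contaminant_fraction = 0, n_reads = 1000L
  )
  facs_default <- list(
    n_events = 20000L,
    populations = list(list(weight = 1, gfp = c(4, 0.5), mcherry = c(4, 0.5)))
  )
  facs_in <- facs
  amplicon <- utils::modifyList(amp_default, amplicon)
  selex <- utils::modifyList(selex_default, selex)
  facs <- utils::modifyList(facs_default, facs)
  # populations is a list of components: replace wholesale, never deep-merge
  if (!is.null(facs_in$populations)) facs$populations <- facs_in$populations

  cfg <- structure(
    list(
      seed = as.integer(seed), genome_length = genome_length,
      n_chromosomes = as.integer(n_chromosomes),
      planted_sites = planted_sites, background_rate = background_rate,
      n_treated = as.integer(n_treated), n_control = as.integer(n_control),
      capture_offset_scale = capture_offset_scale,
      amplicon = amplicon, selex = selex, facs = facs
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$background_rate < 0) stopf("background_rate must be >= 0")
  if (cfg$capture_offset_scale <= 0) stopf("capture_offset_scale must be > 0")
  if (cfg$n_treated < 1) stopf("need at least one treated replicate")
  amp <- cfg$amplicon
  if (amp$indel_rate < 0 || amp$indel_rate > 1) stopf("amplicon indel_rate must be in [0,1]")
  if (amp$substitution_error < 0 || amp$substitution_error > 1) {
    stopf("substitution_error must be in [0,1]")
  }
  sx <- cfg$selex
  if (!is_dna(sx$flank5) || !is_dna(sx$flank3)) stopf("SELEX flanks must be ACGT only")
  if (sx$contaminant_fraction < 0 || sx$contaminant_fraction > 1) {
    stopf("contaminant_fraction must be in [0,1]")
  }
  if (!is.null(sx$matrix)) {
    if (nrow(sx$matrix) != 4L || ncol(sx$matrix) != sx$variable_length) {
      stopf("selex matrix must be 4 x variable_length")
    }
    if (any(abs(colSums(sx$matrix) - 1) > 1e-6)) stopf("selex matrix columns must sum to 1")
  }
  w <- vapply(cfg$facs$populations, function(p) p$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stopf("FACS population weights must sum to 1")
  for (p in cfg$facs$populations) {
    if (p$gfp[2] <= 0 || p$mcherry[2] <= 0) stopf("FACS log-sd must be positive")
  }
  lens <- chromosome_lengths(cfg)
  for (s in cfg$planted_sites) {
    if (!s$chrom %in% names(lens)) stopf("planted site on unknown chromosome '%s'", s$chrom)
    w <- if (!is.null(s$seq)) nchar(s$seq) else 1L
    if (s$position < 0 || s$position + w > lens[[s$chrom]]) {
      stopf("planted site at %s:%d outside chromosome bounds", s$chrom, s$position)
    }
    if (!is.null(s$intensity) && s$intensity < 0) stopf("site intensity must be >= 0")
  }
  invisible(cfg)
}

#' Chromosome lengths implied by a simulation configuration
#' @param config a [sim_config()].
#' @return named numeric vector of lengths (bp).
#' @export
chromosome_lengths <- function(config) {
  n <- config$n_chromosomes
  setNames(rep(floor(config$genome_length / n), n), paste0("chr", seq_len(n)))
}

site_name <- function(s, i) if (!is.null(s$name)) s$name else sprintf("site%d", i)

#' Generate a toy genome with planted nuclease sites
#'
#' Builds random-base chromosomes and writes each planted site's exact
#' sequence at its registered 0-based coordinate.
#'
#' @param config a [sim_config()]; each planted site must carry a `seq`.
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `registry`,
#'   a data.frame of chrom, start, end (0-based half-open), strand, kind,
#'   name and intensity.
#' @export
make_genome_with_sites <- function(config) {
  set.seed(config$seed)
  lens <- chromosome_lengths(config)
  sites <- config$planted_sites
  for (s in sites) {
    if (is.null(s$seq)) stopf("make_genome_with_sites: every planted site needs a 'seq'")
    if (!is_dna(s$seq)) stopf("planted site sequences must be ACGT only")
  }
  reg <- if (!length(sites)) data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    strand = character(), kind = character(), name = character(),
    intensity = numeric(), stringsAsFactors = FALSE
  ) else data.frame(
    chrom = vapply(sites, `[[`, "", "chrom"),
    start = vapply(sites, function(s) as.numeric(s$position), 0),
    end = vapply(sites, function(s) s$position + nchar(s$seq), 0),
    strand = "+",
    kind = vapply(sites, function(s) if (is.null(s$kind)) "off_target" else s$kind, ""),
    name = vapply(seq_along(sites), function(i) site_name(sites[[i]], i), ""),
    intensity = vapply(sites, function(s) if (is.null(s$intensity)) 0 else s$intensity, 0),
    stringsAsFactors = FALSE
  )
  if (nrow(reg) > 1L) {
    o <- order(reg$chrom, reg$start)
    ro <- reg[o, ]
    for (i in seq_len(nrow(ro) - 1L)) {
      if (ro$chrom[i] == ro$chrom[i + 1L] && ro$end[i] > ro$start[i + 1L]) {
        stopf("planted sites '%s' and '%s' overlap", ro$name[i], ro$name[i + 1L])
      }
    }
  }
  chroms <- vapply(names(lens), function(cn) random_dna(lens[[cn]]), "")
  if (nrow(reg)) {
    for (i in seq_len(nrow(reg))) {
      cn <- reg$chrom[i]
      substr(chroms[[cn]], reg$start[i] + 1L, reg$end[i]) <-
        sites[[i]]$seq
    }
  }
  genome <- Biostrings::DNAStringSet(chroms)
  names(genome) <- names(lens)
  list(genome = genome, registry = reg)
}

#' Simulate IDLV-capture integration replicates
#'
#' Treated replicates receive, per planted site, a Poisson(intensity) number
#' of integrations placed at the site center plus a signed geometric offset
#' of scale `capture_offset_scale`; every replicate (treated and control)
#' additionally receives uniform background at `background_rate` per Mb.
#' Truth labels (site name or `"background"`) are retained.
#'
#' @param config a [sim_config()].
#' @param registry optional registry from [make_genome_with_sites()]; when
#'   absent, site centers are taken from `config$planted_sites` directly.
#' @return an integration table: data.frame with chrom, position (0-based),
#'   strand, sample_id, replicate, group, truth; sorted by chrom, position.
#' @export
simulate_integration_replicates <- function(config, registry = NULL) {
  set.seed(config$seed + 1L)
  lens <- chromosome_lengths(config)
  if (is.null(registry)) {
    sites <- config$planted_sites
    centers <- data.frame(
      chrom = vapply(sites, `[[`, "", "chrom"),
      center = vapply(sites, function(s) {
        w <- if (!is.null(s$seq)) nchar(s$seq) else 1L
        floor(s$position + w / 2)
      }, 0),
      intensity = vapply(sites, function(s) if (is.null(s$intensity)) 0 else s$intensity, 0),
      name = vapply(seq_along(sites), function(i) site_name(sites[[i]], i), ""),
      stringsAsFactors = FALSE
    )
  } else {
    centers <- data.frame(
      chrom = registry$chrom,
      center = floor((registry$start + registry$end) / 2),
      intensity = registry$intensity,
      name = registry$name,
      stringsAsFactors = FALSE
    )
  }
  if (any(centers$intensity < 0)) stopf("site intensities must be >= 0")
  if (config$background_rate < 0) stopf("background_rate must be >= 0")

  scale <- config$capture_offset_scale
  rows <- list()
  add <- function(chrom, pos, group, rep_i, truth) {
    n <- length(pos)
    if (!n) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = rep(chrom, length.out = n), position = pos,
      strand = sample(c("+", "-"), n, replace = TRUE),
      sample_id = sprintf("%s%d", substr(group, 1, 1), rep_i),
      replicate = rep_i, group = group, truth = truth,
      stringsAsFactors = FALSE
    )
  }
  groups <- c(rep("treated", config$n_treated), rep("control", config$n_control))
  reps <- c(seq_len(config$n_treated), seq_len(config$n_control))
  for (k in seq_along(groups)) {
    grp <- groups[k]; rep_i <- reps[k]
    if (grp == "treated" && nrow(centers)) {
      for (i in seq_len(nrow(centers))) {
        n_int <- rpois(1L, centers$intensity[i])
        if (n_int > 0L) {
          off <- rgeom(n_int, prob = 1 / scale) * sample(c(-1L, 1L), n_int, replace = TRUE)
          pos <- pmin(pmax(centers$center[i] + off, 0), lens[[centers$chrom[i]]] - 1)
          add(centers$chrom[i], pos, grp, rep_i, centers$name[i])
        }
      }
    }
    for (cn in names(lens)) {
      n_bg <- rpois(1L, config$background_rate * lens[[cn]] / 1e6)
      if (n_bg > 0L) {
        add(cn, floor(runif(n_bg, 0, lens[[cn]])), grp, rep_i, "background")
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chrom = character(), position = numeric(), strand = character(),
    sample_id = character(), replicate = integer(), group = character(),
    truth = character(), stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$chrom, tab$position, tab$sample_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Simulate amplicon deep-sequencing reads with planted indels
#'
#' Each read is the amplicon reference that, with probability
#' `amplicon$indel_rate`, receives exactly one insertion or deletion (50/50)
#' whose length is drawn uniformly from `amplicon$indel_lengths` and which is
#' anchored inside the cut interval; per-base substitution noise is then
#' applied at `amplicon$substitution_error`.
#'
#' @param config a [sim_config()] whose `amplicon` block has `reference`,
#'   `cut_start` and `cut_end` set.
#' @return data.frame with read (character), truth_indel (logical),
#'   indel_kind ("ins"/"del"/""), indel_length.
#' @export
simulate_amplicon_reads <- function(config) {
  amp <- config$amplicon
  if (is.null(amp$reference)) stopf("amplicon$reference is required")
  if (!is_dna(amp$reference)) stopf("amplicon reference must be ACGT only")
  L <- nchar(amp$reference)
  if (is.null(amp$cut_start) || is.null(amp$cut_end) ||
      amp$cut_start < 0 || amp$cut_end > L || amp$cut_start >= amp$cut_end) {
    stopf("cut interval must be 0-based half-open and inside the reference")
  }
  if (any(amp$indel_lengths >= L)) stopf("indel length >= amplicon length")
  set.seed(config$seed + 2L)

  n <- amp$n_reads
  has_indel <- runif(n) < amp$indel_rate
  kind <- ifelse(has_indel,
                 resample(amp$indel_kinds, n, replace = TRUE), "")
  len <- ifelse(has_indel, sample(rep(amp$indel_lengths, 2L), n, replace = TRUE), 0L)
  ref_chars <- strsplit(amp$reference, "")[[1]]

  reads <- vapply(seq_len(n), function(i) {
    x <- ref_chars
    if (has_indel[i]) {
      if (kind[i] == "del") {
        # deletion starting inside the cut interval, clipped to the reference
        start <- resample(seq(amp$cut_start, amp$cut_end - 1L), 1L) + 1L
        drop <- start:min(start + len[i] - 1L, length(x))
        x <- x[-drop]
      } else {
        at <- resample(seq(amp$cut_start, amp$cut_end), 1L) # 0-based insertion point
        ins <- sample(DNA_BASES, len[i], replace = TRUE)
        x <- append(x, ins, after = at)
      }
    }
    if (amp$substitution_error > 0) {
      hit <- which(runif(length(x)) < amp$substitution_error)
      for (j in hit) x[j] <- sample(setdiff(DNA_BASES, x[j]), 1L)
    }
    paste(x, collapse = "")
  }, "")

  data.frame(
    read = reads, truth_indel = has_indel, indel_kind = kind,
    indel_length = as.integer(len), stringsAsFactors = FALSE
  )
}

#' Simulate two-channel fluorescence events
#'
#' Draws events from a mixture of bivariate log-normal populations (GFP and
#' mCherry channels independent within a population).
#'
#' @param config a [sim_config()]; see the `facs` block.
#' @param sample_label label stored in the event table.
#' @return an [event_table()].
#' @export
simulate_facs_events <- function(config, sample_label = "sim") {
  facs <- config$facs
  set.seed(config$seed + 3L)
  n <- facs$n_events
  w <- vapply(facs$populations, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stopf("population weights must sum to 1")
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  gfp <- numeric(n); mch <- numeric(n)
  for (k in seq_along(w)) {
    idx <- comp == k
    p <- facs$populations[[k]]
    if (p$gfp[2] <= 0 || p$mcherry[2] <= 0) stopf("log-sd must be positive")
    gfp[idx] <- rlnorm(sum(idx), p$gfp[1], p$gfp[2])
    mch[idx] <- rlnorm(sum(idx), p$mcherry[1], p$mcherry[2])
  }
  ev <- event_table(gfp, mch, sample = sample_label)
  attr(ev, "component") <- comp
  ev
}

#' Simulate a SELEX read pool from a generating matrix
#'
#' Reads are `flank5 + variable + flank3`, the variable region sampled
#' column-wise from the generating probability matrix (uniform when `NULL`).
#' A `contaminant_fraction` of reads is corrupted — wrong variable-region
#' length or a mutated flank base — to exercise the read filter.
#'
#' @param config a [sim_config()]; see the `selex` block.
#' @return data.frame with read and truth_contaminant (logical).
#' @export
simulate_selex_reads <- function(config) {
  sx <- config$selex
  set.seed(config$seed + 4L)
  L <- sx$variable_length
  mat <- sx$matrix
  if (is.null(mat)) mat <- matrix(0.25, 4, L, dimnames = list(DNA_BASES, NULL))
  if (is.null(rownames(mat))) rownames(mat) <- DNA_BASES
  n <- sx$n_reads
  cores <- vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(L), function(j) sample(DNA_BASES, 1L, prob = mat[, j]), ""),
          collapse = "")
  }, "")
  contaminant <- runif(n) < sx$contaminant_fraction
  reads <- paste0(sx$flank5, cores, sx$flank3)
  for (i in which(contaminant)) {
    if (runif(1) < 0.5) { # wrong length: drop or duplicate one core base
      core <- strsplit(cores[i], "")[[1]]
      core <- if (runif(1) < 0.5 && L > 1L) core[-sample(L, 1L)] else
        append(core, sample(DNA_BASES, 1L), after = sample(L, 1L))
      reads[i] <- paste0(sx$flank5, paste(core, collapse = ""), sx$flank3)
    } else { # mutate one flank base
      r <- strsplit(reads[i], "")[[1]]
      j <- sample(c(seq_len(nchar(sx$flank5)),
                    length(r) - seq_len(nchar(sx$flank3)) + 1L), 1L)
      r[j] <- sample(setdiff(DNA_BASES, r[j]), 1L)
      reads[i] <- paste(r, collapse = "")
    }
  }
  data.frame(read = reads, truth_contaminant = contaminant, stringsAsFactors = FALSE)
}
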