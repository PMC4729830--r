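# Independent oracles used to validate package computations. These are
# deliberately written as naive brute-force implementations, sharing no code
# with the package internals.

# Full Gotoh dynamic-programming score for global alignment with affine
# gaps; gap of length k costs gap_open + k * gap_extend.
gotoh_score <- function(a, b, match = 1, mismatch = -2,
                        gap_open = 6, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in b
  Y <- matrix(NEG, n + 1, m + 1) # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + gap_extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + gap_extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# One-sided Fisher exact p by explicit enumeration of all 2x2 tables with
# the observed margins, using binomial coefficients directly.
fisher_enum_oracle <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  support <- max(0, k - n2):min(k, n1)
  weight <- choose(n1, support) * choose(n2, k - support)
  sum(weight[support >= x1]) / sum(weight)
}

# Transitive-closure clustering oracle: build the full adjacency matrix of
# pairwise distances <= d (same chromosome) and take connected components.
cluster_oracle <- function(chrom, pos, distance) {
  comp <- integer(length(pos))
  next_id <- 0L
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    adj <- abs(outer(pos[idx], pos[idx], "-")) <= distance
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cc <- igraph::components(g)$membership
    comp[idx] <- next_id + cc
    next_id <- next_id + max(cc)
  }
  comp
}

# Two partitions of the same items are equal iff their co-membership
# relations are identical.
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Naive all-positions paired half-site scan.
dimer_scan_oracle <- function(window, left, right, spacers, max_mm) {
  wv <- strsplit(window, "")[[1]]
  W <- length(wv)
  hamming <- function(i, site) {
    sv <- strsplit(site, "")[[1]]
    sum(wv[i:(i + length(sv) - 1L)] != sv)
  }
  out <- list()
  for (ori in c("left-right", "right-left")) {
    a <- if (ori == "left-right") left else right
    b <- if (ori == "left-right") right else left
    la <- nchar(a)
    lb <- nchar(b)
    for (s in spacers) {
      for (i in seq_len(max(0L, W - la - s - lb + 1L))) {
        j <- i + la + s
        ma <- hamming(i, a)
        mb <- hamming(j, rc_chr(b))
        if (ma <= max_mm && mb <= max_mm) {
          out[[length(out) + 1L]] <- data.frame(
            orientation = ori, first_start = i - 1L, spacer = s,
            second_start = j - 1L, mm_first = ma, mm_second = mb,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# Exhaustive (offset, strand) PFM-to-target alignment scorer.
pfm_align_oracle <- function(pfm, target) {
  L <- ncol(pfm)
  Tn <- nchar(target)
  score_at <- function(chars, off) {
    sum(vapply(seq_len(Tn), function(i) pfm[chars[i], off + i], 0))
  }
  best <- NULL
  for (strand in c("forward", "reverse")) {
    chars <- strsplit(if (strand == "forward") target else rc_chr(target), "")[[1]]
    for (off in 0:(L - Tn)) {
      s <- score_at(chars, off)
      if (is.null(best) || s > best$score + 1e-12) {
        best <- list(score = s, offset = off, strand = strand)
      }
    }
  }
  best
}

# Small integration-table builder for clustering tests.
make_integrations <- function(pos, chrom = "chr1", replicate = 1L,
                              group = "treated", strand = "+") {
  if (!length(pos)) {
    return(data.frame(chrom = character(), position = numeric(),
                      strand = character(), sample_id = character(),
                      replicate = integer(), group = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = chrom, position = pos, strand = strand,
    sample_id = paste0(substr(group, 1, 1), replicate),
    replicate = replicate, group = group, stringsAsFactors = FALSE
  )
}
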