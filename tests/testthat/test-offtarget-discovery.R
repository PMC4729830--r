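test_that("junction segments map by exact search over both strands", {
  set.seed(161)
  cfg <- sim_config(seed = 61, genome_length = 10000,
                    planted_sites = list(list(chrom = "chr1", position = 5000,
                                              seq = random_dna(40))))
  gs <- make_genome_with_sites(cfg)
  chr <- as.character(gs$genome[["chr1"]])

  seg_fwd <- substr(chr, 5001, 5025) # the planted 25-mer at position 5000
  seg_rev <- rc_chr(substr(chr, 7001, 7025))
  segs <- data.frame(seq = c(seg_fwd, seg_rev, strrep("A", 25)),
                     sample_id = "t1", replicate = 1, group = "treated",
                     stringsAsFactors = FALSE)
  m <- map_junctions_exact(segs, gs$genome)
  expect_equal(m$integrations$position, c(5000, 7000))
  expect_equal(m$integrations$strand, c("+", "-"))
  expect_equal(unname(m$tally), c(2, 1, 0))

  # a repeated segment is ambiguous and discarded
  genome2 <- Biostrings::DNAStringSet(c(chr1 = paste0(chr, substr(chr, 1, 300))))
  m2 <- map_junctions_exact(
    data.frame(seq = substr(chr, 101, 125), sample_id = "t1", replicate = 1,
               group = "treated", stringsAsFactors = FALSE),
    genome2
  )
  expect_equal(unname(m2$tally["ambiguous"]), 1)
  expect_equal(nrow(m2$integrations), 0)

  expect_error(map_junctions_exact(segs, Biostrings::DNAStringSet()), "empty genome")
})

test_that("deduplication is per sample and keeps multiplicity", {
  ten <- make_integrations(rep(1000, 10))
  d <- dedupe_integrations(ten)
  expect_equal(nrow(d), 1)
  expect_equal(d$multiplicity, 10)

  two_reps <- rbind(make_integrations(1000, replicate = 1L),
                    make_integrations(1000, replicate = 2L))
  d2 <- dedupe_integrations(two_reps)
  expect_equal(nrow(d2), 2)

  empty <- dedupe_integrations(make_integrations(numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("cluster merging is single-linkage chaining at the cutoff", {
  cl <- merge_clusters(make_integrations(c(100, 900, 2500)), distance = 1000)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, c(100, 2500))
  expect_equal(cl$end, c(901, 2501))

  chain <- merge_clusters(make_integrations(c(0, 900, 1800, 2700)), distance = 1000)
  expect_equal(nrow(chain), 1)
  expect_equal(c(chain$start, chain$end), c(0, 2701))
  oracle <- cluster_oracle(rep("chr1", 4), c(0, 900, 1800, 2700), 1000)
  expect_true(same_partition(attr(chain, "members"), oracle))

  expect_equal(nrow(merge_clusters(make_integrations(numeric(0)))), 0)
  expect_error(merge_clusters(make_integrations(1), distance = 0), "distance")

  # cluster count is monotonically non-increasing in merge distance
  set.seed(62)
  tab <- make_integrations(sort(sample(1:50000, 120)))
  counts <- vapply(c(10, 100, 500, 1000, 5000, 50000),
                   function(d) nrow(merge_clusters(tab, d)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster merging equals the transitive-closure oracle on random inputs", {
  set.seed(63)
  for (i in 1:60) {
    n <- sample(2:150, 1)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    pos <- floor(runif(n, 0, 30000))
    tab <- data.frame(chrom = chrom, position = pos, strand = "+",
                      sample_id = "t1", replicate = 1L, group = "treated",
                      stringsAsFactors = FALSE)
    cl <- merge_clusters(tab, distance = 1000)
    expect_true(same_partition(attr(cl, "members"),
                               cluster_oracle(chrom, pos, 1000)))
  }
})

test_that("replicate filter applies the 2-of-3 treated, 1-of-3 control rule", {
  mk <- function(treated_reps, control_reps) {
    tabs <- c(
      lapply(treated_reps, function(r) make_integrations(500, replicate = r)),
      lapply(control_reps, function(r) make_integrations(500, replicate = r,
                                                         group = "control"))
    )
    merge_clusters(do.call(rbind, tabs))
  }
  expect_equal(nrow(filter_clusters(mk(c(1, 2), integer(0)))$kept), 1)
  expect_equal(nrow(filter_clusters(mk(1, integer(0)))$kept), 0)
  dropped <- filter_clusters(mk(c(1, 2, 3), c(1, 2)))$dropped
  expect_equal(nrow(dropped), 1)
  expect_equal(dropped$drop_reason, "too_many_control_replicates")

  # every drop carries a reason; kept + dropped partition the input
  f <- filter_clusters(mk(1, c(1, 2)))
  expect_equal(f$dropped$drop_reason,
               "too_few_treated_replicates;too_many_control_replicates")
  expect_equal(nrow(f$kept) + nrow(f$dropped), 1)
})

test_that("ranking uses totals, replicate support, ratio, then coordinates", {
  base <- data.frame(
    chrom = "chr1", start = c(100, 200, 300), end = c(101, 201, 301),
    total_treated = c(12, 5, 30), n_treated_reps = 3, n_control_reps = 0,
    ratio = Inf, stringsAsFactors = FALSE
  )
  r <- rank_clusters(base)
  expect_equal(r$total_treated, c(30, 12, 5))
  expect_equal(r$rank, 1:3)

  tie <- data.frame(
    chrom = "chr1", start = c(100, 200), end = c(101, 201),
    total_treated = 10, n_treated_reps = c(2, 3), n_control_reps = 0,
    ratio = Inf, stringsAsFactors = FALSE
  )
  expect_equal(rank_clusters(tie)$n_treated_reps, c(3, 2))

  many <- data.frame(
    chrom = "chr1", start = 1:35, end = 2:36, total_treated = 35:1,
    n_treated_reps = 3, n_control_reps = 0, ratio = Inf,
    stringsAsFactors = FALSE
  )
  expect_equal(nrow(rank_clusters(many, top_n = 20)), 20)

  # deterministic: repeated runs give identical orderings
  set.seed(64)
  rand <- data.frame(
    chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
    start = sample(1e6, 30), total_treated = sample(1:5, 30, replace = TRUE),
    n_treated_reps = sample(2:3, 30, replace = TRUE),
    n_control_reps = sample(0:1, 30, replace = TRUE),
    ratio = sample(c(2, 5, Inf), 30, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rand$end <- rand$start + 1
  expect_identical(rank_clusters(rand), rank_clusters(rand))
})

test_that("dimer site scan equals the naive all-positions oracle", {
  left <- "GTCATCCTCATC"
  right <- "AAACTGCAAAAG"
  set.seed(65)

  # planted exact site: left + 5-bp spacer + revcomp(right)
  win <- paste0(random_dna(60), left, "ACGTA", rc_chr(right), random_dna(60))
  hits <- scan_dimer_sites(win, left, right, spacer_range = 4:7, max_mismatch = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$orientation, "left-right")
  expect_equal(hits$first_start, 60)
  expect_equal(hits$spacer, 5)
  expect_equal(hits$mm_total, 0)

  # two substitutions in the right half are tolerated and counted
  right_mut <- right
  substr(right_mut, 2, 2) <- "C"; substr(right_mut, 7, 7) <- "T"
  win2 <- paste0(random_dna(40), left, "ACGTA", rc_chr(right_mut), random_dna(40))
  hits2 <- scan_dimer_sites(win2, left, right, spacer_range = 4:7, max_mismatch = 3)
  planted <- hits2[hits2$first_start == 40 & hits2$spacer == 5 &
                     hits2$orientation == "left-right", ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$mm_first, 0)
  expect_equal(planted$mm_second, 2)

  # random window: full agreement with the exhaustive oracle
  win3 <- random_dna(10000)
  impl <- scan_dimer_sites(win3, left, right, spacer_range = 4:7, max_mismatch = 1)
  oracle <- dimer_scan_oracle(win3, left, right, 4:7, 1)
  if (is.null(oracle)) {
    expect_equal(nrow(impl), 0)
  } else {
    key <- function(d) sort(paste(d$orientation, d$first_start, d$spacer,
                                  d$mm_first, d$mm_second))
    expect_equal(key(impl), key(oracle))
  }
  expect_error(scan_dimer_sites(win3, left, right, spacer_range = integer(0)),
               "spacer")
})

test_that("end-to-end discovery recovers planted sites and ranks on-target first", {
  sites <- c(
    lapply(1:4, function(i) list(chrom = "chr1", position = i * 1.1e6,
                                 kind = "off_target", intensity = 6,
                                 name = sprintf("off%d", i))),
    list(list(chrom = "chr2", position = 2e6, kind = "on_target",
              intensity = 18, name = "on"))
  )
  cfg <- sim_config(seed = 71, genome_length = 1e7, n_chromosomes = 2,
                    planted_sites = sites, background_rate = 10)
  tab <- simulate_integration_replicates(cfg)
  disc <- discover_offtargets(tab)
  cand <- disc$candidates
  planted_pos <- vapply(sites, `[[`, 0, "position")
  planted_chrom <- vapply(sites, `[[`, "", "chrom")
  found <- vapply(seq_along(sites), function(i) {
    any(cand$chrom == planted_chrom[i] &
          cand$start - 1000 <= planted_pos[i] & cand$end + 1000 >= planted_pos[i])
  }, TRUE)
  expect_true(all(found))
  # the on-target site (3x intensity) ranks first
  expect_equal(cand$chrom[1], "chr2")
  expect_lt(abs(cand$start[1] - 2e6), 1000)

  # background-only runs at default rates yield no candidates
  n_cand <- vapply(72:81, function(s) {
    bg <- sim_config(seed = s, genome_length = 1e6, n_chromosomes = 2)
    nrow(discover_offtargets(simulate_integration_replicates(bg))$candidates)
  }, 0)
  expect_gte(mean(n_cand == 0), 0.95)
})

test_that("discovery annotates candidates with binding-site matches", {
  left <- "GTCATCCTCATC"
  right <- "AAACTGCAAAAG"
  site_seq <- paste0(left, "ACGTA", rc_chr(right))
  cfg <- sim_config(seed = 73, genome_length = 2e5, background_rate = 0,
                    planted_sites = list(list(chrom = "chr1", position = 1e5,
                                              seq = site_seq, intensity = 12)))
  gs <- make_genome_with_sites(cfg)
  tab <- simulate_integration_replicates(cfg, gs$registry)
  disc <- discover_offtargets(tab, genome = gs$genome,
                              targets = list(left = left, right = right),
                              max_mismatch = 1)
  expect_equal(nrow(disc$candidates), 1)
  expect_gte(disc$candidates$n_site_matches[1], 1)
  expect_equal(disc$candidates$best_site_mm[1], 0)
})
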