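test_that("block merging uses a strict 200-nt gap and is order-insensitive", {
  loci <- tibble::tibble(contig = "c1",
                         start = c(1000L, 1219L), end = c(1020L, 1239L))
  # inter-locus distance = 1219 - 1020 = 199 < 200: one block
  b1 <- merge_blocks(loci, gap_limit = 200)
  expect_equal(length(unique(b1$block_id)), 1)
  # distance exactly 200: two blocks
  loci2 <- tibble::tibble(contig = "c1",
                          start = c(1000L, 1220L), end = c(1020L, 1240L))
  b2 <- merge_blocks(loci2, gap_limit = 200)
  expect_equal(length(unique(b2$block_id)), 2)
  # a single read is its own block
  expect_equal(length(unique(merge_blocks(loci[1, ])$block_id)), 1)
  # shuffling the input changes nothing after sorting
  set.seed(1)
  many <- tibble::tibble(contig = "c1",
                         start = sort(sample.int(10000, 30)) * 3L)
  many$end <- many$start + 22L
  a <- merge_blocks(many)
  b <- merge_blocks(many[sample(nrow(many)), ])
  expect_identical(a, b)
  # idempotence: re-merging merged blocks yields the same grouping
  expect_identical(merge_blocks(a[, c("contig", "start", "end")]),
                   a[, c("contig", "start", "end", "block_id")])
})

test_that("context extraction adds 150-nt flanks clipped at contig bounds", {
  genome <- c(c1 = strrep("ACGT", 2500))
  blocks <- tibble::tibble(contig = "c1", start = c(500L, 10L),
                           end = c(520L, 40L))
  out <- extract_context(blocks, genome, flank = 150)
  expect_equal(out$window_start, c(350L, 0L))
  expect_equal(out$window_end, c(670L, 190L))
  expect_equal(nchar(out$window_seq[1]), 520 - 500 + 300)
  expect_true(out$clipped[2])
  expect_false(out$clipped[1])
})

test_that("inverted repeats are reported at the score threshold", {
  arm <- "ACGTTGCAGG" # 10 bp, perfect score 30
  hp <- paste0(strrep("A", 30), arm, "TTTTT", rc(arm), strrep("A", 30))
  irs <- find_inverted_repeats(hp)
  expect_equal(nrow(irs), 1)
  expect_equal(irs$score, 30)
  expect_equal(c(irs$left_start, irs$left_end), c(31, 40))
  expect_equal(c(irs$right_start, irs$right_end), c(46, 55))
  # a 9-bp perfect repeat scores 27 and is not reported
  arm9 <- substr(arm, 1, 9)
  hp9 <- paste0(strrep("A", 30), arm9, "TTTTT", rc(arm9), strrep("A", 30))
  expect_equal(nrow(find_inverted_repeats(hp9)), 0)
})

test_that("a planted 20-bp repeat with one mismatch scores 3*19 - 3 = 54", {
  set.seed(44)
  arm <- rand_dna(20, gc = 0.5)
  right <- rc(arm)
  # introduce one internal mismatch in the right arm
  mid <- substr(right, 10, 10)
  substr(right, 10, 10) <- setdiff(c("A", "C", "G", "T"), mid)[1]
  s <- paste0(strrep("A", 100), arm, "CCCCCCCC", right, strrep("A", 150))
  irs <- find_inverted_repeats(s)
  expect_equal(irs$score[1], 54)
  expect_equal(c(irs$left_start[1], irs$left_end[1]), c(101, 120))
  expect_equal(c(irs$right_start[1], irs$right_end[1]), c(129, 148))
  # and equals the independent plain-R alignment oracle
  expect_equal(irs$score[1], oracle_ir_score(s))
})

test_that("the repeat kernel matches the alignment oracle on random sequences", {
  set.seed(45)
  for (i in 1:12) {
    s <- rand_dna(sample(80:200, 1), gc = runif(1, 0.3, 0.7))
    got <- tormir:::cpp_ir_best(tormir:::encode_seq(s), 3, -3, 6,
                                rep(FALSE, nchar(s)))
    expect_equal(got$score, oracle_ir_score(s))
  }
})

test_that("repeats longer than the maximum extent are discarded", {
  set.seed(46)
  arm <- rand_dna(40)
  long_hp <- paste0(arm, rand_dna(200), rc(arm)) # span 280 > 240
  irs <- find_inverted_repeats(long_hp)
  expect_true(nrow(irs) == 0 || all(irs$right_end - irs$left_start + 1 <= 240))
})

test_that("folding maximises weighted pairs with a 3-nt minimum loop", {
  expect_equal(fold_rna("AAAA")$n_pairs, 0)
  f <- fold_rna("GGGAAACCC")
  expect_equal(f$n_pairs, 3)
  expect_equal(f$score, 9) # three G:C pairs
  expect_equal(f$dotbracket, "(((...)))")
  expect_error(fold_rna("ACGTX"), "non-ACGU")
})

test_that("fold scores equal the brute-force maximum for short sequences", {
  set.seed(47)
  for (i in 1:20) {
    s <- rand_dna(sample(8:25, 1), gc = runif(1, 0.2, 0.8))
    expect_equal(fold_rna(s)$score, oracle_fold_score(s), info = s)
  }
  # validate the memoised oracle against true exhaustive enumeration once
  for (i in 1:5) {
    s <- rand_dna(sample(8:12, 1))
    expect_equal(oracle_fold_score(s), oracle_fold_enumerate(s), info = s)
  }
})

test_that("returned structures are valid nested pairings", {
  set.seed(48)
  for (i in 1:10) {
    s <- rand_dna(sample(20:60, 1))
    f <- fold_rna(s)
    p <- f$pairing
    idx <- which(p > 0)
    expect_true(all(p[p[idx]] == idx)) # involution
    # no pseudoknots: for pairs (i,j), (k,l) with i<k: either nested or disjoint
    op <- which(p > seq_along(p))
    for (i1 in op) {
      j1 <- p[i1]
      inside <- op[op > i1 & op < j1]
      expect_true(all(p[inside] < j1))
    }
    # minimum hairpin loop
    expect_true(all(p[idx] - idx >= 0 | idx - p[idx] >= 4))
    expect_true(all(abs(p[idx] - idx) >= 4))
  }
})

test_that("hairpin criteria pass canonical stems and enumerate failures", {
  set.seed(49)
  arm <- rand_dna(22, gc = 0.55)
  prec <- paste0(arm, "TTCATTAG", rc(arm))
  fd <- fold_rna(prec)
  ok <- check_hairpin(fd, c(1, 22))
  expect_true(ok$pass)
  expect_length(ok$reasons, 0)
  # a mature span covering the terminal loop fails with that reason
  bad <- check_hairpin(fd, c(18, 35))
  expect_false(bad$pass)
  expect_true(any(grepl("loop", bad$reasons)))
  # an overlong precursor fails on length
  long_arm <- rand_dna(130, gc = 0.55)
  long_prec <- paste0(long_arm, "TTCATTAG", rc(long_arm)) # 268 nt
  fd2 <- fold_rna(long_prec)
  bad2 <- check_hairpin(fd2, c(1, 22))
  expect_true(any(grepl("maximum length", bad2$reasons)))
  # a span outside the structure errors
  expect_error(check_hairpin(fd, c(0, 10)), "outside")
})

test_that("mature calling requires both arms and picks top variants", {
  arm <- "GCTAGGCTTACGATCCGGTAC"
  prec <- paste0(arm, "TTCATTAG", rc(arm))
  fd <- fold_rna(prec)
  both <- tibble::tibble(
    sequence = c(substr(prec, 1, 21), substr(prec, 2, 22),
                 substr(prec, 30, 50)),
    start = c(1L, 2L, 30L), end = c(21L, 22L, 50L),
    total = c(50, 10, 30))
  call <- call_mature(both, fd)
  expect_equal(call$confidence, "high") # two 5p variants within +/-2 nt
  expect_equal(call$mature5p$mature, substr(prec, 1, 21)) # count-50 wins
  # one arm only: rejected
  one <- both[1:2, ]
  expect_null(call_mature(one, fd))
  # single variant per arm: candidate confidence
  single <- both[c(1, 3), ]
  expect_equal(call_mature(single, fd)$confidence, "candidate")
})

test_that("discovery recovers planted hairpins and rejects decoy-only input", {
  cfg <- sim_config(genome_length = 40000, n_hairpins = 6,
                    n_ncrna_decoys = 5,
                    n_repeat_elements = c(LINE = 1, SINE = 1),
                    library_depth = 4000, seed = 23)
  sim <- simulate_genome(cfg)
  reads <- dplyr::bind_rows(lapply(c("HB", "AB"), function(l)
    simulate_reads(sim, l)))
  clean <- clean_reads(trim_adapter(reads, cfg$adapter_sequence))
  collapsed <- collapse_unique(clean)
  hits <- map_reads(collapsed, genome_index(sim$genome))
  retained <- filter_hits(collapsed, hits)
  classified <- classify_reads(retained, hits,
                               known_mature = sim$known_mature,
                               ncrna = sim$ncrna[, c("sequence", "subclass")],
                               repeats = sim$repeats)
  cand <- classified[classified$class %in% c("known_miRNA", "unknown"), ]
  cand_hits <- hits[hits$sequence %in% cand$sequence, ]
  disc <- discover_mirna(cand_hits, cand, sim$genome,
                         known_mature = sim$known_mature)
  hit_truth <- vapply(seq_len(nrow(sim$truth)), function(i) {
    any(disc$precursor_start < sim$truth$end[i] &
          sim$truth$start[i] < disc$precursor_end)
  }, logical(1))
  expect_gte(mean(hit_truth), 5 / 6)
  # conserved/novel labelling matches the planted conservation flags
  expect_true(any(disc$novelty == "conserved"))
  expect_true(any(disc$novelty == "novel"))
  # empty input
  expect_equal(nrow(discover_mirna(cand_hits[0, ], cand, sim$genome)), 0)
  # decoy-only reads (no mature-origin): no candidates
  decoy_seqs <- clean$sequence[clean$read_id %in%
                                 reads$read_id[reads$origin != "mature"]]
  dec <- classified[classified$sequence %in% decoy_seqs &
                      classified$class == "unknown", ]
  dec_hits <- hits[hits$sequence %in% dec$sequence, ]
  disc0 <- discover_mirna(dec_hits, dec, sim$genome)
  fp <- if (nrow(disc0)) {
    vapply(seq_len(nrow(disc0)), function(i) {
      !any(sim$truth$start < disc0$precursor_end[i] &
             disc0$precursor_start[i] < sim$truth$end)
    }, logical(1))
  } else logical(0)
  expect_equal(sum(fp), 0)
})
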