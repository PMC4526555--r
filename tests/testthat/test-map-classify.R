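test_that("exact mapping finds planted 20-mers on both strands", {
  set.seed(21)
  flank1 <- rand_dna(200)
  probe <- "ACGTTGCAGGTCAATCCGTA"
  genome <- c(contig1 = paste0(flank1, probe, rand_dna(200)))
  idx <- genome_index(genome)
  h <- map_reads(probe, idx)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 200L)
  expect_equal(h$end, 220L)
  expect_equal(h$strand, "+")
  # the reverse complement maps to the same interval, minus strand
  h2 <- map_reads(rc(probe), idx)
  expect_equal(h2$start, 200L)
  expect_equal(h2$strand, "-")
  # absent read
  expect_equal(nrow(map_reads("GGGGGGGGGGGGGGGGGGGG", idx)), 0)
})

test_that("index mapping equals naive full-scan matching on random reads", {
  set.seed(22)
  genome <- c(c1 = rand_dna(5000), c2 = rand_dna(3000))
  idx <- genome_index(genome)
  # mix of planted substrings (guaranteed hits) and random reads
  reads <- c(
    vapply(1:60, function(i) {
      ctg <- sample(names(genome), 1)
      len <- sample(18:25, 1)
      s <- sample(nchar(genome[[ctg]]) - len, 1)
      x <- substr(genome[[ctg]], s + 1, s + len)
      if (runif(1) < 0.5) rc(x) else x
    }, character(1)),
    replicate(40, rand_dna(sample(18:25, 1))))
  got <- map_reads(reads, idx)
  want <- dplyr::bind_rows(lapply(unique(reads), oracle_map,
                                  genome_seqs = genome))
  key <- function(d) sort(paste(d$sequence, d$contig, d$start, d$strand))
  expect_equal(key(got), key(want))
})

test_that("multi-locus and singleton filters use the stated bounds", {
  mk_hits <- function(seqs, n_loci) {
    dplyr::bind_rows(lapply(seq_along(seqs), function(i) {
      tibble::tibble(sequence = seqs[i], contig = "c1",
                     start = seq_len(n_loci[i]) * 100L,
                     end = seq_len(n_loci[i]) * 100L + 20L, strand = "+")
    }))
  }
  collapsed <- tibble::tibble(sequence = c("S20", "S21", "S1", "SOK"),
                              total = c(5, 5, 1, 2))
  hits <- mk_hits(collapsed$sequence, c(20, 21, 1, 3))
  out <- filter_hits(collapsed, hits)
  expect_setequal(out$sequence, c("S20", "SOK")) # 20 loci kept, 21 removed
  removed <- attr(out, "removed")
  expect_equal(removed$reason[removed$sequence == "S21"], "multi_locus")
  expect_equal(removed$reason[removed$sequence == "S1"], "singleton")
})

test_that("known-miRNA matching allows two mismatches and 2-nt end slack", {
  known <- tibble::tibble(mirna_id = c("mir-a", "mir-b"),
                          sequence = c("ACGTACGTACGTACGTACGTA",
                                       "TTTTCCCCGGGGAAAATTTTC"))
  exact <- known$sequence[1]
  two_mm <- paste0("AGGTACGTACGTACGTACGTG") # 2 changes
  three_mm <- paste0("AGGTACGAACGTACGTACGTG") # 3 changes
  sub_read <- substr(known$sequence[1], 3, 21) # 2-nt shorter at the 5' end
  res <- match_known_mirna(c(exact, two_mm, three_mm, sub_read), known)
  expect_equal(res$mirna_id, c("mir-a", "mir-a", NA, "mir-a"))
  expect_equal(res$mismatches, c(0L, 2L, NA, 0L))
})

test_that("classification precedence resolves collisions and partitions reads", {
  genome <- c(c1 = paste0(rand_dna(100), "ACGTTGCAGGTCAATCCGTACG",
                          rand_dna(100)))
  read <- "ACGTTGCAGGTCAATCCGTACG"
  collapsed <- tibble::tibble(sequence = read, HB = 5L, total = 5L)
  hits <- map_reads(read, genome_index(genome))
  # the read is simultaneously a known miRNA, inside an ncRNA reference and
  # inside a repeat interval: known miRNA must win
  known <- tibble::tibble(mirna_id = "mir-x", sequence = read)
  ncrna <- tibble::tibble(sequence = paste0("TT", read, "AA"),
                          subclass = "rRNA")
  repeats <- tibble::tibble(contig = "c1", start = 90L, end = 230L,
                            class = "LINE")
  out <- classify_reads(collapsed, hits, known_mature = known,
                        ncrna = ncrna, repeats = repeats)
  expect_equal(out$class, "known_miRNA")
  # without the known set, ncRNA wins over repeat
  out2 <- classify_reads(collapsed, hits, ncrna = ncrna, repeats = repeats)
  expect_equal(out2$class, "rRNA")
  # repeat assignment requires full containment of the hit interval
  out3 <- classify_reads(collapsed, hits,
                         repeats = tibble::tibble(contig = "c1", start = 105L,
                                                  end = 230L, class = "LINE"))
  expect_equal(out3$class, "unknown")
  out4 <- classify_reads(collapsed, hits, repeats = repeats)
  expect_equal(out4$class, "LINE")
})

test_that("an annotation class outside the vocabulary errors", {
  collapsed <- tibble::tibble(sequence = "ACGTACGTACGTACGTAC", total = 2L)
  hits <- tibble::tibble(sequence = "ACGTACGTACGTACGTAC", contig = "c1",
                         start = 0L, end = 18L, strand = "+")
  expect_error(classify_reads(collapsed, hits,
                              repeats = tibble::tibble(contig = "c1",
                                                       start = 0L, end = 50L,
                                                       class = "ALU")),
               "unknown repeat class")
  expect_error(classify_reads(collapsed, hits,
                              ncrna = tibble::tibble(sequence = "AAA",
                                                     subclass = "piRNA")),
               "unknown ncRNA subclass")
})

test_that("classification is a partition with conserved counts", {
  set.seed(33)
  sim <- simulate_genome(sim_config(genome_length = 30000, n_hairpins = 3,
                                    n_ncrna_decoys = 4,
                                    n_repeat_elements = c(SINE = 2),
                                    library_depth = 1200, seed = 17))
  reads <- dplyr::bind_rows(lapply(c("HB", "AB"), function(l)
    simulate_reads(sim, l)))
  clean <- clean_reads(trim_adapter(reads, sim$config$adapter_sequence))
  collapsed <- collapse_unique(clean)
  hits <- map_reads(collapsed, genome_index(sim$genome))
  retained <- filter_hits(collapsed, hits)
  classified <- classify_reads(retained, hits,
                               known_mature = sim$known_mature,
                               ncrna = sim$ncrna[, c("sequence", "subclass")],
                               repeats = sim$repeats)
  expect_equal(nrow(classified), nrow(retained))
  expect_false(any(is.na(classified$class)))
  tab <- classification_table(classified, libraries = c("HB", "AB"))
  overall <- tab[tab$library == "overall", ]
  expect_equal(sum(overall$unique_reads), nrow(retained))
  expect_equal(sum(overall$total_reads), sum(retained$total))
})

test_that("percentage summaries reproduce published table arithmetic", {
  expect_equal(class_percentage(15068478, 31590053), 47.7)
  expect_equal(class_percentage(31590053, 45161406), 69.9)
  expect_equal(class_percentage(100, 100), 100)
  expect_true(is.na(class_percentage(5, 0)))
})
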