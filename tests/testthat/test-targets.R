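test_that("UTR inference falls back to the 3-kb downstream window", {
  set.seed(51)
  long_seq <- rand_dna(10000)
  u <- infer_utr(long_seq)
  expect_equal(u$length, 3000)
  expect_equal(u$provenance, "fallback_3kb")
  expect_equal(u$sequence, substr(long_seq, 1, 3000))
  short_seq <- rand_dna(1200)
  u2 <- infer_utr(short_seq)
  expect_equal(u2$length, 1200)
  expect_error(infer_utr(""), "empty")
})

test_that("ortholog alignment trims the UTR at the last aligned base", {
  set.seed(52)
  window <- rand_dna(2000)
  ortho <- substr(window, 1, 800) # identical to the first 800 nt
  u <- infer_utr(window, ortho)
  expect_equal(u$provenance, "ortholog_trimmed")
  expect_equal(u$length, 800)
  expect_equal(u$sequence, substr(window, 1, 800))
})

test_that("seed sites require exact 7mer complementarity with 8mer upgrade", {
  mirna <- "TAGCTTATCAGACTGATGTTGA" # positions 2-8 = AGCTTAT
  seed_rc <- rc(substr(mirna, 2, 8))
  utr_hit <- paste0(strrep("A", 40), seed_rc, strrep("C", 40))
  sites <- find_seed_sites(mirna, utr_hit)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$site_start, 41L)
  # one seed mismatch: no site
  mm <- seed_rc
  substr(mm, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(mm, 4, 4))[1]
  expect_equal(nrow(find_seed_sites(mirna, paste0(strrep("A", 40), mm))), 0)
  # complement of positions 1-8 classifies as 8mer
  utr8 <- paste0(strrep("C", 40), rc(substr(mirna, 1, 8)), strrep("C", 40))
  expect_equal(find_seed_sites(mirna, utr8)$seed_class, "8mer")
  # an A facing position 1 also upgrades
  utrA <- paste0(strrep("C", 40), seed_rc, "A", strrep("C", 30))
  expect_equal(find_seed_sites(mirna, utrA)$seed_class, "8mer")
  expect_error(find_seed_sites("ACGTACG", "AAAA"), "at least 8")
})

test_that("duplex energies order GC above AU and penalise mismatches", {
  gc8 <- "GGGGCCCC"
  au8 <- "AAAATTTT"
  e_gc <- duplex_energy(gc8, rc(gc8))
  e_au <- duplex_energy(au8, rc(au8))
  expect_lt(e_gc, e_au)
  expect_lt(e_au, 0)
  # a central mismatch raises the energy
  site <- rc(gc8)
  substr(site, 4, 4) <- "T"
  expect_gt(duplex_energy(gc8, site), e_gc)
  # nothing pairable scores zero
  expect_equal(duplex_energy("AAAAAAAA", "AAAAAAAACC"), 0)
})

test_that("extending complementarity never raises the duplex energy", {
  mirna <- "TAGCTTATCAGACTGATGTTGA"
  full <- rc(mirna)
  energies <- vapply(8:nchar(mirna), function(k) {
    # site complementary to the first k miRNA bases (suffix of the full
    # complement); the option set only grows with k
    duplex_energy(mirna, substr(full, nchar(full) - k + 1, nchar(full)))
  }, numeric(1))
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("opening energy is the cost of unpairing the site", {
  # unstructured context: nothing to open
  expect_equal(open_energy(strrep("A", 100), 40, 47), 0)
  # a site inside a planted perfect stem costs energy to open
  set.seed(54)
  arm <- rand_dna(25, gc = 0.6)
  hp <- paste0(strrep("A", 20), arm, "TTTTT", rc(arm), strrep("A", 20))
  e <- open_energy(hp, 25, 40)
  expect_gt(e, 0)
  expect_error(open_energy(hp, 10, 90, window = 20), "window")
})

test_that("constrained folds match the oracle on short windows", {
  set.seed(55)
  for (i in 1:8) {
    s <- rand_dna(sample(15:30, 1), gc = 0.6)
    free <- fold_rna(s)$score
    expect_equal(free, oracle_fold_score(s))
    # blocking everything forbids all pairs
    expect_equal(fold_rna(s, blocked = seq_len(nchar(s)))$score, 0)
    # blocking a margin equals folding with those bases absent from pairing
    blocked <- 1:3
    con <- fold_rna(s, blocked = blocked)$score
    expect_lte(con, free)
  }
})

test_that("target prediction applies the inclusive ddG cutoff", {
  # purine-only miRNA: its complement is pyrimidine-only, so the site
  # context cannot base-pair with itself and accessibility costs nothing
  mirna <- tibble::tibble(mirna_id = "mir-t",
                          sequence = "AAGGAGAGAAGGAAGAGAGGAA")
  strong <- paste0(strrep("C", 60), rc(mirna$sequence), strrep("C", 60))
  utrs <- tibble::tibble(gene_id = "g_strong", sequence = strong)
  res <- predict_targets(mirna, utrs)
  expect_equal(nrow(res), 1)
  expect_true(res$retained)
  expect_equal(res$ddG, res$dG_duplex - res$dG_open) # identity
  expect_equal(res$dG_open, 0) # pyrimidine-only context is unstructured
  # boundary behaviour of the cutoff itself
  expect_true(-10.0 <= -10)
  expect_false(-9.9 <= -10)
  # a gene with no seed match yields no site
  expect_equal(nrow(predict_targets(mirna,
                                    tibble::tibble(gene_id = "g0",
                                                   sequence = strrep("A", 300)))),
               0)
})

test_that("sites retained at a stricter cutoff are a subset", {
  set.seed(56)
  mirna <- tibble::tibble(mirna_id = "mir-t",
                          sequence = "TAGCTTATCAGACTGATGTTGA")
  utrs <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:6),
    sequence = vapply(1:6, function(i) {
      paste0(rand_dna(80), rc(substr(mirna$sequence, 1, sample(8:20, 1))),
             rand_dna(80))
    }, character(1)))
  at10 <- predict_targets(mirna, utrs, cutoff = -10)
  at12 <- predict_targets(mirna, utrs, cutoff = -12)
  expect_true(all(at12$gene_id[at12$retained] %in% at10$gene_id[at10$retained]))
  expect_equal(at10$ddG, at10$dG_duplex - at10$dG_open)
  expect_true(all(at10$dG_open >= 0))
  expect_true(all(at10$ddG <= at10$dG_duplex + 1e-12))
})

test_that("the stack table is symmetric under strand exchange", {
  E <- energy_model()$stacks
  flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p1 in rownames(E)) {
    for (p2 in colnames(E)) {
      expect_equal(E[p1, p2], E[flip(p2), flip(p1)])
    }
  }
})
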