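test_that("reads are counted into matures through the +/-2 nt window", {
  matures <- tibble::tibble(mirna_id = "cand-001-5p", contig = "c1",
                            start = 100L, end = 122L)
  collapsed <- tibble::tibble(
    sequence = c("R_in", "R_edge", "R_out"),
    HB = c(5L, 2L, 7L), AB = c(1L, 0L, 3L))
  hits <- tibble::tibble(
    sequence = c("R_in", "R_edge", "R_out"),
    contig = "c1",
    start = c(101L, 98L, 97L),  # +1 offset; -2 edge; -3 outside
    end = c(121L, 120L, 119L), strand = "+")
  q <- quantify_mature(collapsed, hits, matures, libraries = c("HB", "AB"))
  expect_equal(q$HB, 5L + 2L)
  expect_equal(q$AB, 1L + 0L)
  # no reads at all: zero matrix over all features
  q0 <- quantify_mature(collapsed[0, ], hits[0, ], matures,
                        libraries = c("HB", "AB"))
  expect_equal(q0$HB, 0L)
})

test_that("TPM normalisation scales to parts per million", {
  counts <- tibble::tibble(feature_id = c("a", "b"),
                           HB = c(2, 8), AB = c(10, 0))
  out <- tpm(counts, c(HB = 10, AB = 10))
  expect_equal(out$HB, c(200000, 800000))
  expect_equal(sum(out$HB), 1e6) # all counts assigned
  expect_equal(out$AB, c(1e6, 0))
  expect_error(tpm(counts, c(HB = 0, AB = 10)), "positive")
  lt <- log_tpm(counts, c(HB = 10, AB = 10))
  expect_equal(lt$HB, log2(c(200000, 800000) + 1))
})

test_that("exact NB test honours its stated conventions", {
  # zero counts in both libraries: p = 1 (and logFC 0 downstream)
  expect_equal(exact_nb_test(0, 0, 1e6, 1e6, dispersion = 0.1), 1)
  # (5, 0) at equal totals, Poisson limit: exact binomial two-sided 0.0625
  expect_equal(exact_nb_test(5, 0, 1e6, 1e6, dispersion = 0), 0.0625)
  # equal counts are the conditional mode: p = 1 for any dispersion
  for (phi in c(0, 0.1, 0.5)) {
    expect_equal(exact_nb_test(7, 7, 1e6, 1e6, dispersion = phi), 1)
  }
  expect_error(exact_nb_test(-1, 0, 1e6, 1e6), "non-negative")
  expect_error(exact_nb_test(1, 0, 1e6, 1e6, dispersion = -1), "dispersion")
})

test_that("exact-test p equals full conditional enumeration for small totals", {
  for (phi in c(0, 0.05, 0.2)) {
    for (case in list(c(0, 12), c(3, 10), c(25, 25), c(50, 0), c(18, 30))) {
      expect_equal(
        exact_nb_test(case[1], case[2], 1e6, 1e6, dispersion = phi),
        oracle_exact_nb(case[1], case[2], phi),
        tolerance = 1e-12,
        info = paste(phi, case[1], case[2]))
    }
  }
})

test_that("the exact test agrees with an independent implementation", {
  skip_if_not_installed("edgeR")
  cases <- list(c(30, 5), c(10, 3), c(100, 40), c(0, 12), c(400, 100))
  for (case in cases) {
    mine <- exact_nb_test(case[1], case[2], 1e6, 1e6, dispersion = 0.1)
    ed <- edgeR::exactTest(
      edgeR::DGEList(counts = cbind(h = case[1], a = case[2]),
                     lib.size = c(1e6, 1e6), group = c("h", "a")),
      dispersion = 0.1, pair = c("a", "h"))$table$PValue
    expect_equal(mine, ed, tolerance = 1e-10)
  }
})

test_that("p-values are symmetric under library swap", {
  set.seed(3)
  for (i in 1:20) {
    yh <- rpois(1, 40); ya <- rpois(1, 40)
    expect_equal(exact_nb_test(yh, ya, 2e6, 1e6, 0.1),
                 exact_nb_test(ya, yh, 1e6, 2e6, 0.1))
  }
})

test_that("moderated logFC is finite, zero-centred and monotone", {
  expect_equal(log_fc(10, 10, 1e6, 1e6), 0)
  one_sided <- log_fc(95, 0, 1e6, 1e6)
  expect_true(is.finite(one_sided) && one_sided > 0)
  expect_gt(log_fc(20, 10, 1e6, 1e6), log_fc(10, 10, 1e6, 1e6))
})

test_that("DE calling applies inclusive thresholds", {
  de <- tibble::tibble(feature_id = c("a", "b", "c"),
                       comparison = "HB_vs_AB",
                       logFC = c(1.0, 3, 0.5), p_value = c(0.01, 0.02, 0.001),
                       direction = c("UP", "UP", "UP"))
  class(de) <- c("tormir_de", class(de))
  out <- call_de(de)
  expect_equal(out$feature_id, "a") # p = 0.01 and |lfc| = 1 both inclusive
  # a tighter p cutoff yields a subset
  loose <- call_de(de, p_max = 0.05)
  tight <- call_de(de, p_max = 0.001)
  expect_true(all(tight$feature_id %in% loose$feature_id))
})

test_that("test_de marks absent features and computes directions", {
  counts <- tibble::tibble(feature_id = c("m1", "m2"),
                           HB = c(0L, 200L), AB = c(0L, 20L),
                           HA = c(5L, 10L), AA = c(50L, 10L))
  de <- test_de(counts, totals = c(HB = 1e5, AB = 1e5, HA = 1e5, AA = 1e5),
                dispersion = 0)
  m1b <- de[de$feature_id == "m1" & de$comparison == "HB_vs_AB", ]
  expect_equal(m1b$p_value, 1)
  expect_equal(m1b$logFC, 0)
  expect_equal(m1b$direction, "absent")
  m2b <- de[de$feature_id == "m2" & de$comparison == "HB_vs_AB", ]
  expect_equal(m2b$direction, "UP")
  m1w <- de[de$feature_id == "m1" & de$comparison == "HA_vs_AA", ]
  expect_equal(m1w$direction, "DOWN")
  g <- glance(de)
  expect_equal(g$n_features, c(2L, 2L))
  expect_s3_class(tidy(de), "tbl_df")
})

test_that("type-I error is calibrated under null simulation", {
  cs <- simulate_counts(count_sim_spec(n_features = 2000,
                                       baseline_mean = 100,
                                       dispersion = 0.1, de_fraction = 0,
                                       seed = 31))
  de <- test_de(cs$counts, totals = c(HB = 1e6, AB = 1e6, HA = 1e6, AA = 1e6),
                dispersion = 0.1)
  brain <- de[de$comparison == "HB_vs_AB", ]
  frac <- mean(brain$p_value <= 0.05)
  band <- 2.576 * sqrt(0.05 * 0.95 / nrow(brain))
  expect_lt(abs(frac - 0.05), band)
})

test_that("specificity calls follow the zero-count rules", {
  counts <- tibble::tibble(
    feature_id = c("brain_only", "ubiq", "state", "none"),
    HB = c(150L, 3L, 5L, 0L), AB = c(120L, 4L, 0L, 0L),
    HA = c(0L, 5L, 3L, 0L), AA = c(0L, 6L, 0L, 0L))
  out <- call_specific(counts)
  expect_equal(out$pattern, c("tissue_specific_brain", "ubiquitous",
                              "state_specific", "not_detected"))
  expect_equal(out$high_count, c(TRUE, FALSE, FALSE, FALSE))
})
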