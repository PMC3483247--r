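# Small-table helpers: inserts of length 8 with a matching config so every
# branch of the procedure can be exercised cheaply.
small_cfg <- function(...) {
  validation_config(expected_sizes = 8L, min_reads_per_individual = 10L, ...)
}

test_that("size filter removes frame-shifted lengths globally", {
  tb <- tibble::tibble(
    sequence = c(strrep("A", 212), strrep("C", 213), strrep("G", 221)),
    sample = "s1", count = c(10L, 10L, 10L))
  out <- step1_size_filter(tb, validation_config())
  expect_setequal(nchar(out$sequence), c(212L, 221L))
  expect_identical(nrow(step1_size_filter(tb[0, ], validation_config())), 0L)
})

test_that("global filter keeps four copies and removes three", {
  tb <- tibble::tibble(sequence = rep(c("AAAAAAAA", "CCCCCCCC"), c(2, 2)),
                       sample = c("s1", "s2", "s1", "s2"),
                       count = c(2L, 1L, 2L, 2L))
  out <- step2_global_filter(tb, small_cfg())
  expect_setequal(unique(out$sequence), "CCCCCCCC")
})

test_that("coverage filter drops individuals below the read floor", {
  tb <- tibble::tibble(sequence = "AAAAAAAA",
                       sample = c("lo", "hi", "edge"),
                       count = c(199L, 500L, 200L))
  out <- step3_coverage_filter(tb, validation_config())
  expect_setequal(out$sample, c("hi", "edge"))
  expect_warning(
    step3_coverage_filter(tb[tb$sample == "lo", ], validation_config()),
    "below")
})

test_that("MPAF is the maximum within-sample frequency", {
  tb <- tibble::tibble(
    sequence = c("v", "x", "v", "y"),
    sample = c("s1", "s1", "s2", "s2"),
    count = c(5L, 495L, 20L, 380L))
  m <- mpaf(tb)
  expect_equal(m$mpaf[m$sequence == "v"], 0.05)
  tb2 <- tibble::tibble(sequence = c("v", "x"), sample = "s1",
                        count = c(2L, 198L))
  expect_equal(mpaf(tb2)$mpaf[1], 0.01)
})

test_that("single-basepair test is exact Hamming distance one", {
  expect_true(is_single_bp("ACGTACGT", "ACGAACGT"))
  expect_false(is_single_bp("ACGTACGT", "ACAAACGT"))
  expect_false(is_single_bp("ACGTACGT", "ACGTACG"))
  expect_false(is_single_bp("ACGT", "ACGT"))
})

test_that("chimera detection finds single-breakpoint concatenations", {
  a <- "AAAACCCC"; b <- "GGGGTTTT"
  hit <- find_chimera("AAAATTTT", c(a, b))
  expect_true(hit$found)
  expect_identical(hit$breakpoint, 4L)
  expect_identical(hit$a, a)
  expect_identical(hit$b, b)
  # identity is excluded by construction
  expect_false(find_chimera(a, c(a, b))$found)
  # interior breakpoint matching only part of the prefix
  expect_true(find_chimera("AAAGTTTT", c("AAAGCCCC", b))$found)
})

test_that("chimera detection equals brute force on random parent sets", {
  set.seed(77)
  for (rep in 1:200) {
    parents <- random_dna(sample(2:4, 1), 8)
    v <- if (runif(1) < 0.6 && length(parents) >= 2) {
      k <- sample(7, 1)
      paste0(substr(parents[1], 1, k), substr(parents[2], k + 1, 8))
    } else {
      random_dna(1, 8)
    }
    if (v %in% parents) next
    expect_identical(find_chimera(v, parents)$found,
                     chimera_brute(v, parents),
                     info = paste(v, paste(parents, collapse = ",")))
  }
  # parents of differing lengths: prefix from a longer parent
  a <- strrep("A", 10); b <- strrep("T", 8)
  v <- paste0("AAA", strrep("T", 5))
  expect_true(find_chimera(v, c(a, b))$found)
  expect_true(chimera_brute(v, c(a, b)))
})

test_that("explainability requires strictly more common parents", {
  sc <- tibble::tibble(sequence = c("AAAACCCC", "GGGGTTTT", "AAAACCCA"),
                       count = c(50L, 40L, 3L))
  expect_true(explainable("AAAACCCA", sc))  # 1-bp from the top variant
  expect_true(explainable("AAAATTTT", sc))  # chimera of the top two
  # ties are not parents
  tie <- tibble::tibble(sequence = c("AAAACCCC", "AAAACCCA"),
                        count = c(3L, 3L))
  expect_false(explainable("AAAACCCA", tie))
  # nothing more common
  expect_false(explainable("AAAACCCC", sc))
})

test_that("MPAF classification rejects, reviews and keeps by band", {
  # s1 has 1000 reads: top alleles 600/390, artefacts at controlled MPAF
  top1 <- "AAAACCCC"; top2 <- "GGGGTTTT"
  chim <- "AAAATTTT"          # explainable chimera, MPAF 0.015
  rare <- "CACACACA"          # MPAF 0.008 -> rejected outright
  real <- "TGCATGCA"          # MPAF 0.030 -> kept unexamined
  band_real <- "CCCCGGGG"     # MPAF 0.015, not explainable -> kept
  tb <- tibble::tibble(
    sequence = c(top1, top2, chim, rare, real, band_real),
    sample = "s1",
    count = c(559L, 390L, 15L, 8L, 30L, 15L))
  tb$count <- as.integer(tb$count * 1000 / sum(tb$count))
  tb <- tb[tb$count > 0, ]
  out <- step4_mpaf_classify(tb, small_cfg())
  expect_true(all(c(top1, top2, real, band_real) %in% out$sequence))
  expect_false(chim %in% out$sequence)
  expect_false(rare %in% out$sequence)
})

test_that("review-band variants are removed only if explainable in all top carriers", {
  top1 <- "AAAACCCC"; top2 <- "GGGGTTTT"; v <- "AAAATTTT"
  mk <- function(s, counts) {
    tibble::tibble(sequence = c(top1, top2, v), sample = s, count = counts)
  }
  # v sits in the review band and is a chimera of the two top alleles in
  # every carrier: removed
  tb <- dplyr::bind_rows(mk("s1", c(600L, 385L, 15L)),
                         mk("s2", c(600L, 385L, 15L)),
                         mk("s3", c(500L, 480L, 20L)))
  out <- step4_mpaf_classify(tb, small_cfg())
  expect_false(v %in% out$sequence)
  tb2 <- dplyr::bind_rows(mk("s1", c(600L, 385L, 15L)),
                          mk("s2", c(600L, 385L, 15L)),
                          mk("s3", c(490L, 10L, 500L)))
  out2 <- step4_mpaf_classify(tb2, small_cfg())
  expect_true(v %in% out2$sequence) # MPAF 0.5 > review band: kept
})

test_that("per-individual filter applies the copy-number rules", {
  top1 <- "AAAACCCC"; top2 <- "GGGGTTTT"
  tb <- tibble::tibble(
    sequence = c(top1, top2, "AAAATTTT", "CCCCGGGG", "TGCATGCA"),
    sample = "s1",
    count = c(100L, 80L, 3L, 3L, 1L))
  g <- step5_individual_filter(tb, small_cfg())
  expect_true(all(c(top1, top2) %in% g$sequence))
  expect_false("AAAATTTT" %in% g$sequence) # 3 copies, chimera-explainable
  expect_true("CCCCGGGG" %in% g$sequence)  # 3 copies, not explainable
  expect_false("TGCATGCA" %in% g$sequence) # singleton
  tb5 <- tibble::tibble(sequence = c(top1, top2, "AAAATTTT"), sample = "s1",
                        count = c(100L, 80L, 5L))
  expect_true("AAAATTTT" %in%
                step5_individual_filter(tb5, small_cfg())$sequence)
})

test_that("five-step procedure equals the brute-force oracle on small tables", {
  cfg <- small_cfg()
  set.seed(123)
  n_checked <- 0L
  for (rep in 1:60) {
    tb <- random_small_table()
    got <- run_validation(tb, cfg)$genotypes
    want <- validation_brute(tb, cfg)
    got <- dplyr::arrange(got, sample, sequence)
    expect_equal(as.data.frame(got), as.data.frame(want))
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 60L)
})

test_that("no kept allele is a singleton in its individual", {
  set.seed(9)
  for (rep in 1:10) {
    g <- run_validation(random_small_table(), small_cfg())$genotypes
    if (nrow(g)) expect_true(all(g$copies >= 2))
  }
})

test_that("relaxing thresholds never removes a kept allele", {
  cfg <- sim_config(n_individuals = 30, depth_mean = 120, depth_sd = 40,
                    seed = 31)
  truth <- simulate_genotypes(cfg)
  sim <- simulate_reads(truth, cfg)
  tb <- tally_variants(parse_reads(sim$reads), sim$sample_sheet)$table
  strict <- validation_config(min_reads_per_individual = 100L)
  relax <- list(
    validation_config(min_reads_per_individual = 100L,
                      min_global_copies = 2L),
    validation_config(min_reads_per_individual = 100L,
                      mpaf_reject = 0.005),
    validation_config(min_reads_per_individual = 100L,
                      per_individual_keep = 3L))
  g0 <- run_validation(tb, strict)$genotypes
  keys0 <- paste(g0$sample, g0$sequence)
  for (cfg_r in relax) {
    gr <- run_validation(tb, cfg_r)$genotypes
    expect_true(all(keys0 %in% paste(gr$sample, gr$sequence)))
  }
})

test_that("the funnel is recorded per step with retention fractions", {
  tb <- tibble::tibble(
    sequence = c(strrep("A", 212), strrep("C", 213)),
    sample = "s1", count = c(300L, 50L))
  res <- run_validation(tb, validation_config())
  expect_identical(res$funnel$step[1], "input")
  expect_identical(res$funnel$reads[1], 350L)
  expect_identical(res$funnel$reads[2], 300L)
  expect_equal(res$funnel$retained_reads[2], 300 / 350)
  expect_s3_class(tidy(res), "tbl_df")
})
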