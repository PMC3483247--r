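test_that("degenerate matching follows the IUPAC sets exactly", {
  expect_true(match_degenerate("TTMY", "TTAT"))   # M contains A, Y contains T
  expect_false(match_degenerate("TTMY", "TTGT"))  # M does not contain G
  expect_true(match_degenerate("TTMYGGCTGTGACCTCCTG", "TTATGGCTGTGACCTCCTG"))
  expect_false(match_degenerate("TTMY", "TTA"))   # unequal lengths
})

test_that("degenerate matching equals brute-force expansion of the pattern", {
  pattern <- "TTMYGGCTGTGACCTCCTG"
  # expand the degenerate set explicitly
  expand <- function(prefixes, opts) {
    unlist(lapply(prefixes, function(p) paste0(p, opts)))
  }
  sets <- list(M = c("A", "C"), Y = c("C", "T"))
  concrete <- ""
  for (ch in strsplit(pattern, "")[[1]]) {
    concrete <- expand(concrete, if (ch %in% names(sets)) sets[[ch]] else ch)
  }
  expect_length(concrete, 4L)
  set.seed(42)
  windows <- c(concrete, random_dna(50, nchar(pattern)))
  expect_identical(match_degenerate(pattern, windows),
                   windows %in% concrete)
})

test_that("constructed reads parse on both strands to the same insert", {
  insert <- strrep("ACGT", 53) # 212 bp
  rd <- make_read(default_mids[["MID1"]], "TTATGGCTGTGACCTCCTG", insert,
                  "TTGCGCTTCAGCTCTTTC", default_mids[["MID2"]])
  reads <- tibble::tibble(read_id = c("f", "r"),
                          sequence = c(rd, revcomp(rd)))
  parsed <- parse_reads(reads)
  expect_identical(parsed$orientation, c("forward", "reverse"))
  expect_identical(parsed$insert, c(insert, insert))
  expect_identical(parsed$mid_f, c("MID1", "MID1"))
  expect_identical(parsed$mid_r, c("MID2", "MID2"))
})

test_that("reads with ambiguous bases or broken layout are unassigned", {
  insert <- strrep("ACGT", 53)
  good <- make_read(default_mids[["MID1"]], "TTATGGCTGTGACCTCCTG", insert,
                    "TTGCGCTTCAGCTCTTTC", default_mids[["MID2"]])
  withN <- good
  substr(withN, 40, 40) <- "N"
  broken <- paste0("AAAA", substr(good, 5, nchar(good))) # MID destroyed
  parsed <- parse_reads(tibble::tibble(
    read_id = c("n", "b"), sequence = c(withN, broken)))
  expect_identical(parsed$orientation, c("unassigned", "unassigned"))
  expect_identical(parsed$reason,
                   c("ambiguous_base", "incomplete_tag_or_primer"))
})

test_that("tally canonicalises strand and logs discards by reason", {
  insert <- strrep("ACGT", 53)
  rd <- make_read(default_mids[["MID1"]], "TTATGGCTGTGACCTCCTG", insert,
                  "TTGCGCTTCAGCTCTTTC", default_mids[["MID2"]])
  rd_unknown <- make_read(default_mids[["MID3"]], "TTATGGCTGTGACCTCCTG",
                          insert, "TTGCGCTTCAGCTCTTTC",
                          default_mids[["MID4"]])
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:7),
    sequence = c(rep(rd, 3), rep(revcomp(rd), 2), rd_unknown, "ACGTNNNN"))
  sheet <- tibble::tibble(region = "R01", mid_f = "MID1", mid_r = "MID2",
                          sample = "ind1")
  tl <- tally_variants(parse_reads(reads), sheet, region = "R01")
  expect_identical(nrow(tl$table), 1L)
  expect_identical(tl$table$count, 5L)
  expect_identical(tl$table$sequence, insert)
  expect_setequal(tl$discards$reason,
                  c("ambiguous_base", "unknown_tag_pair"))
  # conservation: reads in = assigned + discards
  expect_identical(sum(tl$table$count) + sum(tl$discards$n), nrow(reads))
})

test_that("zero-error simulation demultiplexes to the ground truth, weighted by depth", {
  cfg <- sim_config(n_individuals = 12, n_loci = 4, n_pool_alleles = 10,
                    depth_mean = 60, depth_sd = 20,
                    pcr_mut_rate = 0, chimera_rate = 0,
                    seq_sub_rate = 0, seq_indel_rate = 0, seed = 5)
  truth <- simulate_genotypes(cfg)
  sim <- simulate_reads(truth, cfg)
  tl <- tally_variants(parse_reads(sim$reads), sim$sample_sheet)
  # per-sample variant sets equal the true genotypes
  for (s in unique(truth$genotypes$sample)) {
    expect_setequal(tl$table$sequence[tl$table$sample == s],
                    truth$genotypes$sequence[truth$genotypes$sample == s])
  }
  # counts equal template use from provenance
  prov_counts <- sim$provenance |>
    dplyr::left_join(truth$copies |>
                       dplyr::distinct(.data$allele_id, .data$sequence),
                     by = c(template = "allele_id")) |>
    dplyr::count(.data$sample, .data$sequence, name = "n")
  joined <- dplyr::inner_join(tl$table, prov_counts,
                              by = c("sample", "sequence"))
  expect_identical(nrow(joined), nrow(tl$table))
  expect_identical(joined$count, joined$n)
})
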