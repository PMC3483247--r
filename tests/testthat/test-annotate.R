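test_that("translation counts stop codons in the requested frame", {
  tr <- translate_alleles(c("TAATAA", "ATGGCC", "ATGTAAGGGTGA"))
  expect_identical(tr$stop_count, c(2L, 0L, 2L))
  # trailing partial codon ignored; frame offset shifts the grid
  expect_identical(translate_alleles("ATAATT", frame_offset = 1)$aa, "*")
  expect_identical(translate_alleles("AATGGC", frame_offset = 1)$aa, "M")
})

test_that("engineered double-stop alleles are flagged like a pseudogene family", {
  set.seed(6)
  base <- random_coding(1, 20)
  ps <- base
  substr(ps, 10, 12) <- "TAA"
  substr(ps, 31, 33) <- "TGA"
  expect_identical(translate_alleles(ps)$stop_count, 2L)
})

test_that("group assignment uses nearest reference with a distance gate", {
  set.seed(8)
  g1 <- random_coding(1, 20)
  g2 <- random_coding(1, 20)
  refs <- tibble::tibble(group = c("group1", "group2"), sequence = c(g1, g2))
  near_g1 <- g1
  substr(near_g1, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                   substr(g1, 4, 4))[1]
  far <- paste(rev(strsplit(g1, "")[[1]]), collapse = "")
  al <- tibble::tibble(allele_id = c("a1", "a2", "a3"),
                       sequence = c(g1, near_g1, far))
  out <- assign_group(al, refs, max_dist = 0.1)
  expect_identical(out$group, c("group1", "group1", "unassigned"))
  expect_identical(out$functional, c(FALSE, FALSE, FALSE))

  # stop-bearing allele near a pseudogene exemplar
  ps_ref <- g2
  substr(ps_ref, 10, 12) <- "TAA"
  refs2 <- tibble::tibble(group = c("pseudogene", "group2"),
                          sequence = c(ps_ref, g2))
  ps_allele <- ps_ref
  substr(ps_allele, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                       substr(ps_ref, 40, 40))[1]
  out2 <- assign_group(tibble::tibble(allele_id = "p", sequence = ps_allele),
                       refs2)
  expect_identical(out2$group, "pseudogene")
  expect_false(out2$functional)
  # a clean allele matching the functional exemplar is functional
  out3 <- assign_group(tibble::tibble(allele_id = "f", sequence = g2), refs2)
  expect_identical(out3$group, "group2")
  expect_true(out3$functional)
})

test_that("nucleotide diversity matches brute force and closed cases", {
  s <- c("AAAAAAAAAA", "AAAAAAAAAA")
  d <- nucleotide_diversity(s)
  expect_equal(unlist(d[c("pi", "k", "segregating_sites")]),
               c(pi = 0, k = 0, segregating_sites = 0))
  s2 <- c("AAAAAAAAAA", "AAAAAAAAAC")
  d2 <- nucleotide_diversity(s2)
  expect_equal(d2$pi, 0.1)
  expect_equal(d2$k, 1)
  expect_identical(d2$segregating_sites, 1L)

  # 4-sequence toy alignment vs all-pairs counting
  toy <- c("ACGTACGTAC", "ACGTACGTAA", "TCGTACGTAC", "ACGAACGTCC")
  pairs <- combn(4, 2)
  brute_k <- mean(apply(pairs, 2, function(ij) {
    sum(strsplit(toy[ij[1]], "")[[1]] != strsplit(toy[ij[2]], "")[[1]])
  }))
  d4 <- nucleotide_diversity(toy)
  expect_equal(d4$k, brute_k)
  expect_equal(d4$pi, brute_k / 10)
  expect_true(d4$pi >= 0 && d4$pi <= 1)
  expect_lte(d4$segregating_sites, 10L)
})

test_that("diversity agrees with an independent phylogenetics implementation", {
  skip_if_not_installed("ape")
  set.seed(14)
  seqs <- random_coding(6, 30, mut = 0.1)
  d <- nucleotide_diversity(seqs)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  raw <- ape::dist.dna(bin, model = "raw")
  expect_equal(d$pi, mean(raw), tolerance = 1e-12)
  expect_equal(d$k, mean(raw) * 90, tolerance = 1e-9)
})

test_that("mixed-length sets are summarised within length class", {
  seqs <- c(strrep("A", 212), strrep("C", 212),
            strrep("G", 215), strrep("T", 215), strrep("A", 221))
  d <- diversity_by_length_class(seqs)
  expect_identical(nrow(d), 2L) # the singleton 221 class is skipped
  expect_setequal(d$length, c(212L, 215L))
})

test_that("allele annotation produces stable ids and length classes", {
  set.seed(15)
  seqs <- random_coding(3, 70, mut = 0.08)
  seqs <- vapply(seqs, function(s) substr(s, 1, 210), character(1),
                 USE.NAMES = FALSE)
  g <- tibble::tibble(sample = rep(c("i1", "i2"), each = 3),
                      sequence = rep(seqs, 2),
                      copies = c(30L, 20L, 10L, 5L, 25L, 15L))
  ann <- annotate_alleles(g, references = NULL)
  expect_identical(ann$alleles$allele_id, sprintf("mhc%04d", 1:3))
  # ids ordered by total copies
  expect_true(all(diff(ann$alleles$total_copies) <= 0))
  expect_true(all(ann$genotypes$allele_id %in% ann$alleles$allele_id))
})
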