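#' Default 454 multiplex identifier (MID) set
#'
#' The first ten 10-bp standard multiplex identifiers used with GS FLX
#' Titanium fusion primers. A forward/reverse MID pair identifies one sample
#' within a plate region.
#' @export
default_mids <- c(
  MID1  = "ACGAGTGCGT", MID2  = "ACGCTCGACA", MID3  = "AGACGCACTC",
  MID4  = "AGCACTGTAG", MID5  = "ATCAGACACG", MID6  = "ATATCGCGAG",
  MID7  = "CGTGTCTCTA", MID8  = "CTCGCGTGTC", MID9  = "TAGTATCAGC",
  MID10 = "TCTCTATGCG"
)

#' Simulation configuration
#'
#' Parameters of the synthetic tagged-amplicon experiment. Defaults emulate a
#' bidirectional 454 survey of a highly duplicated passerine MHC class I
#' system: up to 16 co-amplifying diploid loci with allele sharing across
#' loci, amplicon inserts of 212/215/221 bp, per-individual read depth with
#' mean 286 and standard deviation 173 (strongly super-Poissonian, hence a
#' moment-matched negative binomial), PCR point mutations, two-parent PCR
#' chimeras, and pyrosequencing substitution/indel errors.
#'
#' @param n_loci Number of diploid loci co-amplified by the primer pair.
#' @param n_individuals Number of diploid individuals.
#' @param allele_pool Tibble `(locus, allele_id, sequence, freq)`; frequencies
#'   sum to 1 within each locus and the same sequence may appear at several
#'   loci. `NULL` generates a pool with [simulate_allele_pool()].
#' @param n_pool_alleles Distinct sequences in the generated pool (used only
#'   when `allele_pool` is `NULL`).
#' @param depth_mean,depth_sd Mean and SD of reads per individual.
#' @param pcr_mut_rate Per-base probability of a PCR substitution per read.
#' @param chimera_rate Per-read probability of a two-parent chimera.
#' @param seq_sub_rate,seq_indel_rate Per-base sequencing substitution and
#'   indel probabilities.
#' @param homopolymer_indels If `TRUE`, indel positions are weighted by the
#'   local homopolymer run length (over/under-calls concentrate in runs);
#'   default is uniform positions.
#' @param mid_set Named character vector of 10-bp MID tags.
#' @param primer_f,primer_r Template-specific primers, IUPAC degenerate
#'   strings, written 5'->3' on their own strands.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 16,
                       n_individuals = 100,
                       allele_pool = NULL,
                       n_pool_alleles = 60,
                       depth_mean = 286,
                       depth_sd = 173,
                       pcr_mut_rate = 2e-4,
                       chimera_rate = 0.01,
                       seq_sub_rate = 1e-3,
                       seq_indel_rate = 5e-4,
                       homopolymer_indels = FALSE,
                       mid_set = default_mids,
                       primer_f = "TTMYGGCTGTGACCTCCTG",
                       primer_r = "TTGCGCTYCAGCTCTTTC",
                       seed = 1L) {
  rates <- c(pcr_mut_rate = pcr_mut_rate, chimera_rate = chimera_rate,
             seq_sub_rate = seq_sub_rate, seq_indel_rate = seq_indel_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  stopifnot(n_loci >= 1, n_individuals >= 1, depth_mean > 0,
            all(nchar(mid_set) == 10L))
  cfg <- list(
    n_loci = as.integer(n_loci), n_individuals = as.integer(n_individuals),
    allele_pool = allele_pool, n_pool_alleles = as.integer(n_pool_alleles),
    depth_mean = depth_mean, depth_sd = depth_sd,
    pcr_mut_rate = pcr_mut_rate, chimera_rate = chimera_rate,
    seq_sub_rate = seq_sub_rate, seq_indel_rate = seq_indel_rate,
    homopolymer_indels = isTRUE(homopolymer_indels),
    mid_set = mid_set, primer_f = primer_f, primer_r = primer_r,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Generate an allele pool with sharing across loci
#'
#' Builds a pool of distinct allele sequences in three length classes
#' (212/215/221 bp; the shorter classes carry in-frame 6- and 9-bp deletions
#' of a common ancestral insert, mirroring length variation among real
#' alleles) and assigns each locus a random subset with Dirichlet-like
#' frequencies. Alleles are deliberately shared among loci, as in highly
#' duplicated MHC regions where locus assignment of an amplicon variant is
#' impossible.
#'
#' @param n_loci Number of loci.
#' @param n_alleles Number of distinct sequences in the pool.
#' @param lengths Allowed insert lengths.
#' @param alleles_per_locus Range of alleles segregating per locus.
#' @param divergence Per-base substitution probability applied to the
#'   ancestral insert per allele (pairwise diversity is roughly twice this).
#' @param seed Integer seed.
#' @return Tibble `(locus, allele_id, sequence, freq)`.
#' @export
simulate_allele_pool <- function(n_loci = 16, n_alleles = 60,
                                 lengths = c(212L, 215L, 221L),
                                 alleles_per_locus = c(2L, 6L),
                                 divergence = 0.05,
                                 seed = 1L) {
  stopifnot(n_alleles >= 2, all(lengths %in% c(212L, 215L, 221L)))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  # ancestor built from sense codons: functional alleles carry an open
  # reading frame (frame offset 0), like the real amplicons they emulate
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  n_cod <- ceiling(max(lengths) / 3)
  anc <- strsplit(paste(sample(sense, n_cod, replace = TRUE), collapse = ""),
                  "", fixed = TRUE)[[1]][seq_len(max(lengths))]
  # codon-aligned deletions produce the shorter length classes
  del <- list(`221` = integer(0), `215` = 100:105, `212` = 100:108)
  len_class <- sample(lengths, n_alleles, replace = TRUE)
  has_stop <- function(s) {
    translate_alleles(s)$stop_count > 0
  }
  seqs <- vapply(len_class, function(L) {
    tmpl <- anc[setdiff(seq_along(anc), del[[as.character(L)]])]
    for (try in 1:100) {
      cand <- tmpl
      mut <- stats::runif(length(cand)) < divergence
      cand[mut] <- vapply(cand[mut],
                          function(b) sample(setdiff(bases, b), 1L),
                          character(1))
      cand <- paste(cand, collapse = "")
      if (!has_stop(cand)) return(cand)
    }
    paste(tmpl, collapse = "")
  }, character(1))
  # rare collisions would break allele identity; remutate until distinct
  while (anyDuplicated(seqs)) {
    i <- which(duplicated(seqs))[1L]
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    p <- sample(length(s), 1L)
    s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  ids <- sprintf("allele%03d", seq_len(n_alleles))
  purrr::map_dfr(seq_len(n_loci), function(l) {
    k <- sample(alleles_per_locus[1]:alleles_per_locus[2], 1L)
    pick <- sample(n_alleles, k)
    w <- stats::rgamma(k, shape = 1)
    tibble::tibble(locus = l, allele_id = ids[pick], sequence = seqs[pick],
                   freq = w / sum(w))
  })
}

#' Simulate diploid multilocus genotypes
#'
#' Draws two allele copies per locus per individual according to the pool
#' frequencies. The same sequence drawn at different loci counts once in the
#' individual's distinct-allele set, so a diploid individual carries at most
#' `2 * n_loci` distinct alleles.
#'
#' @param cfg A [sim_config()].
#' @return A `ground_truth` list with `copies` (tibble `sample, locus, copy,
#'   allele_id, sequence`) and `genotypes` (tibble `sample, allele_id,
#'   sequence` of distinct alleles).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pool <- cfg$allele_pool
  if (is.null(pool)) {
    pool <- simulate_allele_pool(cfg$n_loci, cfg$n_pool_alleles,
                                 seed = cfg$seed)
  }
  if (nrow(pool) == 0) stop("allele pool is empty")
  by_locus <- split(pool, pool$locus)
  if (length(by_locus) < cfg$n_loci) {
    stop("allele pool must cover every locus")
  }
  samples <- sprintf("ind%04d", seq_len(cfg$n_individuals))
  copies <- purrr::map_dfr(seq_len(cfg$n_loci), function(l) {
    p <- by_locus[[as.character(l)]]
    idx <- sample.int(nrow(p), 2L * cfg$n_individuals,
                      replace = TRUE, prob = p$freq)
    tibble::tibble(
      sample = rep(samples, each = 2L),
      locus = l,
      copy = rep(1:2, times = cfg$n_individuals),
      allele_id = p$allele_id[idx],
      sequence = p$sequence[idx]
    )
  })
  copies <- dplyr::arrange(copies, .data$sample, .data$locus, .data$copy)
  genotypes <- dplyr::distinct(copies, .data$sample, .data$allele_id,
                               .data$sequence)
  structure(list(copies = copies, genotypes = genotypes, pool = pool),
            class = "ground_truth")
}

# Per-individual read depth: negative binomial moment-matched to
# (depth_mean, depth_sd), truncated at >= 1 by redrawing. The configured
# dispersion is strongly super-Poissonian, so a Poisson law would not do.
draw_depths <- function(cfg, n) {
  mu <- cfg$depth_mean
  v <- cfg$depth_sd^2
  if (v <= mu) stop("depth_sd^2 must exceed depth_mean for a negative binomial")
  size <- mu^2 / (v - mu)
  depth <- stats::rnbinom(n, size = size, mu = mu)
  while (any(depth < 1L)) {
    z <- depth < 1L
    depth[z] <- stats::rnbinom(sum(z), size = size, mu = mu)
  }
  depth
}

# Apply per-base substitutions to integer-coded sequences at the given rate;
# returns the modified list and per-read substitution counts.
apply_substitutions <- function(ints, rate) {
  if (rate <= 0) {
    return(list(ints = ints, n = integer(length(ints))))
  }
  lens <- lengths(ints)
  n_sub <- stats::rbinom(length(ints), lens, rate)
  bases_int <- utf8ToInt("ACGT")
  hit <- which(n_sub > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], n_sub[i])
    for (p in pos) {
      ints[[i]][p] <- sample(setdiff(bases_int, ints[[i]][p]), 1L)
    }
  }
  list(ints = ints, n = n_sub)
}

# Homopolymer run length at each position of an integer-coded sequence.
homopolymer_weights <- function(x) {
  r <- rle(x)
  rep(r$lengths, r$lengths)
}

# Apply indels (insertion or deletion, 50/50) to integer-coded sequences.
apply_indels <- function(ints, rate, homopolymer = FALSE) {
  if (rate <= 0) {
    return(list(ints = ints, n = integer(length(ints))))
  }
  lens <- lengths(ints)
  n_ind <- stats::rbinom(length(ints), lens, rate)
  bases_int <- utf8ToInt("ACGT")
  hit <- which(n_ind > 0L)
  for (i in hit) {
    for (e in seq_len(n_ind[i])) {
      x <- ints[[i]]
      w <- if (homopolymer) homopolymer_weights(x) else NULL
      p <- sample.int(length(x), 1L, prob = w)
      if (stats::runif(1) < 0.5 && length(x) > 1L) {
        ints[[i]] <- x[-p]
      } else {
        ints[[i]] <- append(x, sample(bases_int, 1L), after = p - 1L)
      }
    }
  }
  list(ints = ints, n = n_ind)
}

#' Simulate tagged amplicon reads with known provenance
#'
#' Per individual, a read depth is drawn from a moment-matched negative
#' binomial truncated at >= 1. Each read picks a template uniformly among the
#' individual's `2 * n_loci` allele copies; with probability `chimera_rate` a
#' second template and a uniform internal breakpoint produce a prefix+suffix
#' chimera. PCR substitutions, then sequencing substitutions and indels are
#' applied to the insert, which is wrapped as
#' `MID_f + primer_f + insert + revcomp(primer_r) + revcomp(MID_r)`
#' (degenerate primer positions realised at random, as in an oligo mixture);
#' about half of the reads are emitted reverse-complemented. Sequencing
#' adaptors are assumed already trimmed upstream.
#'
#' @param truth A `ground_truth` from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return A list with `reads` (tibble `read_id, sequence`), `provenance`
#'   (tibble `read_id, sample, template, template2, breakpoint, n_pcr_sub,
#'   n_seq_sub, n_indel, orientation`), and `sample_sheet` (tibble
#'   `region, mid_f, mid_r, sample`).
#' @export
simulate_reads <- function(truth, cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  samples <- unique(truth$copies$sample)
  n_ind <- length(samples)

  # dual-MID sample sheet: forward x reverse combinations within each region
  mids <- names(cfg$mid_set)
  combos <- expand.grid(mid_f = mids, mid_r = mids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  per_region <- nrow(combos)
  region <- sprintf("R%02d", ((seq_len(n_ind) - 1L) %/% per_region) + 1L)
  slot <- ((seq_len(n_ind) - 1L) %% per_region) + 1L
  sheet <- tibble::tibble(region = region,
                          mid_f = combos$mid_f[slot],
                          mid_r = combos$mid_r[slot],
                          sample = samples)

  depth <- draw_depths(cfg, n_ind)

  copies_by_sample <- split(truth$copies, truth$copies$sample)[samples]
  read_sample <- rep(samples, times = depth)
  n_reads <- length(read_sample)

  # template choice: uniform over the individual's allele copies
  pick_templates <- function(k) {
    idx <- unlist(lapply(depth, function(d) sample.int(k, d, replace = TRUE)))
    idx
  }
  n_copies <- 2L * cfg$n_loci
  t1 <- pick_templates(n_copies)
  is_chim <- stats::runif(n_reads) < cfg$chimera_rate
  t2 <- ifelse(is_chim, unlist(lapply(depth, function(d)
    sample.int(n_copies, d, replace = TRUE))), NA_integer_)

  sample_row0 <- match(read_sample, samples)
  seq_of <- function(srow, copy_idx) {
    vapply(seq_along(srow), function(i) {
      copies_by_sample[[srow[i]]]$sequence[copy_idx[i]]
    }, character(1))
  }
  id_of <- function(srow, copy_idx) {
    vapply(seq_along(srow), function(i) {
      copies_by_sample[[srow[i]]]$allele_id[copy_idx[i]]
    }, character(1))
  }
  tmpl_seq <- seq_of(sample_row0, t1)
  tmpl_id <- id_of(sample_row0, t1)
  tmpl2_seq <- rep(NA_character_, n_reads)
  tmpl2_id <- rep(NA_character_, n_reads)
  if (any(is_chim)) {
    tmpl2_seq[is_chim] <- seq_of(sample_row0[is_chim], t2[is_chim])
    tmpl2_id[is_chim] <- id_of(sample_row0[is_chim], t2[is_chim])
  }

  insert <- tmpl_seq
  breakpoint <- rep(NA_integer_, n_reads)
  for (i in which(is_chim)) {
    la <- nchar(tmpl_seq[i]); lb <- nchar(tmpl2_seq[i])
    kmax <- min(la, lb) - 1L
    k <- sample.int(kmax, 1L)
    breakpoint[i] <- k
    insert[i] <- paste0(substr(tmpl_seq[i], 1L, k),
                        substr(tmpl2_seq[i], k + 1L, lb))
  }

  ints <- lapply(insert, utf8ToInt)
  pcr <- apply_substitutions(ints, cfg$pcr_mut_rate)
  seqsub <- apply_substitutions(pcr$ints, cfg$seq_sub_rate)
  indel <- apply_indels(seqsub$ints, cfg$seq_indel_rate,
                        cfg$homopolymer_indels)
  insert <- vapply(indel$ints, intToUtf8, character(1))

  sheet_row <- match(read_sample, sheet$sample)
  mid_f_seq <- unname(cfg$mid_set[sheet$mid_f[sheet_row]])
  mid_r_seq <- unname(cfg$mid_set[sheet$mid_r[sheet_row]])
  pf <- expand_degenerate(cfg$primer_f, n_reads)
  pr <- expand_degenerate(cfg$primer_r, n_reads)
  full <- paste0(mid_f_seq, pf, insert, revcomp(pr), revcomp(mid_r_seq))
  flip <- stats::runif(n_reads) < 0.5
  full[flip] <- revcomp(full[flip])

  read_id <- sprintf("read%07d", seq_len(n_reads))
  list(
    reads = tibble::tibble(read_id = read_id,
                           region = sheet$region[sheet_row],
                           sequence = full),
    provenance = tibble::tibble(
      read_id = read_id, sample = read_sample,
      template = tmpl_id, template2 = tmpl2_id, breakpoint = breakpoint,
      n_pcr_sub = pcr$n, n_seq_sub = seqsub$n, n_indel = indel$n,
      orientation = ifelse(flip, "reverse", "forward")
    ),
    sample_sheet = sheet
  )
}

#' Write simulated reads to FASTA or FASTQ
#'
#' FASTQ records carry a constant placeholder quality (`I`); the simulator
#' does not model per-base quality scores.
#'
#' @param reads Tibble `(read_id, sequence)`.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    write_fasta(stats::setNames(reads$sequence, reads$read_id), path)
  } else {
    lines <- character(4L * nrow(reads))
    lines[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
    lines[c(FALSE, TRUE, FALSE, FALSE)] <- reads$sequence
    lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
    lines[c(FALSE, FALSE, FALSE, TRUE)] <-
      strrep("I", nchar(reads$sequence))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read simulated or real reads from FASTA/FASTQ
#'
#' @param path Input path; format detected from the first character.
#' @return Tibble `(read_id, sequence)`.
#' @export
read_reads <- function(path) {
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  x <- if (first == "@") {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path)
  }
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 sequence = as.character(x))
}
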