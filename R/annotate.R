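#' Translate alleles and count premature stop codons
#'
#' Standard genetic code; the trailing partial codon after applying the frame
#' offset is ignored. The amplicon is an internal fragment of exon 3, so the
#' reading frame is a configuration choice (default 0), not inferred.
#'
#' @param sequences Character vector of DNA sequences.
#' @param frame_offset 0, 1 or 2 bases skipped before the first codon.
#' @return Tibble `(sequence, aa, stop_count)`.
#' @export
translate_alleles <- function(sequences, frame_offset = 0) {
  stopifnot(frame_offset %in% 0:2)
  aa <- vapply(sequences, function(s) {
    s <- substr(s, frame_offset + 1L, nchar(s))
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1L, 3L * n_codon)),
      no.init.codon = TRUE))
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(sequence = sequences, aa = aa,
                 stop_count = stringr::str_count(aa, stringr::fixed("*")))
}

# Proportion of differing sites between two equal-length strings.
p_distance <- function(a, b) {
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  mean(ai != bi)
}

#' Assign alleles to functional groups by nearest reference
#'
#' Operationalises the tree-based partition of alleles into a pseudogene
#' family, a putatively non-functional cluster ("group1") and the functional
#' remainder ("group2"): each allele is assigned the group of its nearest
#' reference exemplar by p-distance, subject to a maximum-distance gate, with
#' comparisons restricted to equal-length references. Stop-codon-bearing
#' alleles within the gate of a pseudogene exemplar are pseudogene; other
#' stop-bearing alleles keep their nearest group but are flagged
#' non-functional. Alleles beyond every gate are `"unassigned"`.
#'
#' @param alleles Tibble with at least `allele_id`, `sequence`; a
#'   `stop_count` column is used if present (otherwise computed with
#'   `frame_offset = 0`).
#' @param references Tibble `(group, sequence)` of labelled exemplars; groups
#'   are typically `"pseudogene"`, `"group1"`, `"group2"`.
#' @param max_dist Assignment gate on p-distance (default 0.1).
#' @return `alleles` with columns `group`, `ref_dist`, `functional` added.
#' @export
assign_group <- function(alleles, references, max_dist = 0.1) {
  stopifnot(all(c("allele_id", "sequence") %in% names(alleles)),
            all(c("group", "sequence") %in% names(references)))
  if (!"stop_count" %in% names(alleles)) {
    alleles$stop_count <- translate_alleles(alleles$sequence)$stop_count
  }
  ref_len <- nchar(references$sequence)
  res <- purrr::map_dfr(seq_len(nrow(alleles)), function(i) {
    s <- alleles$sequence[i]
    cand <- which(ref_len == nchar(s))
    if (length(cand) == 0L) {
      return(tibble::tibble(group = "unassigned", ref_dist = NA_real_))
    }
    d <- vapply(references$sequence[cand], p_distance, numeric(1), a = s)
    j <- which.min(d)
    if (d[j] > max_dist) {
      tibble::tibble(group = "unassigned", ref_dist = unname(d[j]))
    } else {
      tibble::tibble(group = references$group[cand[j]],
                     ref_dist = unname(d[j]))
    }
  })
  out <- dplyr::bind_cols(alleles, res)
  stopbear <- out$stop_count >= 1L
  out$functional <- !stopbear & out$group == "group2"
  out
}

#' Annotate validated alleles
#'
#' Builds the allele record table: stable ids in decreasing order of total
#' copy number, length class, translation and stop-codon count, and (when
#' reference exemplars are supplied) functional group.
#'
#' @param genotypes Tibble `(sample, sequence, copies)` from
#'   [run_validation()].
#' @param references Optional tibble `(group, sequence)`; without it every
#'   stop-free allele is provisionally `"group2"` (functional) and
#'   stop-bearing alleles are non-functional.
#' @param frame_offset Reading-frame offset for translation.
#' @param max_dist Gate for [assign_group()].
#' @return A list: `alleles` (tibble `allele_id, sequence, length_class, aa,
#'   stop_count, group, functional, total_copies`) and `genotypes`
#'   (input genotypes with `allele_id` attached).
#' @export
annotate_alleles <- function(genotypes, references = NULL,
                             frame_offset = 0, max_dist = 0.1) {
  al <- genotypes |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(total_copies = sum(.data$copies), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$total_copies), .data$sequence)
  al$allele_id <- sprintf("mhc%04d", seq_len(nrow(al)))
  tr <- translate_alleles(al$sequence, frame_offset)
  al$aa <- tr$aa
  al$stop_count <- tr$stop_count
  al$length_class <- nchar(al$sequence)
  if (!is.null(references)) {
    al <- assign_group(al, references, max_dist)
  } else {
    al$group <- ifelse(al$stop_count >= 1L, "unassigned", "group2")
    al$functional <- al$stop_count == 0L
  }
  al <- dplyr::select(al, "allele_id", "sequence", "length_class", "aa",
                      "stop_count", "group", "functional", "total_copies",
                      dplyr::any_of("ref_dist"))
  geno <- dplyr::left_join(genotypes,
                           dplyr::select(al, "allele_id", "sequence"),
                           by = "sequence")
  list(alleles = al, genotypes = geno)
}

#' Nucleotide diversity of an alignment
#'
#' Mean pairwise p-distance (pi), mean pairwise difference count (k) and the
#' number of segregating sites (S) for equal-length sequences. Mixed-length
#' allele sets are summarised within each length class (cross-class pairs
#' would require an indel alignment, which may be supplied pre-aligned
#' instead).
#'
#' @param sequences Character vector of equal-length DNA sequences (>= 2).
#' @return Tibble `(n_seq, length, pi, k, segregating_sites)`.
#' @export
nucleotide_diversity <- function(sequences) {
  stopifnot(length(sequences) >= 2L,
            length(unique(nchar(sequences))) == 1L)
  m <- do.call(rbind, lapply(sequences, utf8ToInt))
  n <- nrow(m); L <- ncol(m)
  diffs <- 0
  for (i in seq_len(n - 1L)) {
    block <- m[(i + 1L):n, , drop = FALSE]
    diffs <- diffs + sum(sweep(block, 2L, m[i, ], `!=`))
  }
  n_pairs <- n * (n - 1L) / 2
  k <- diffs / n_pairs
  s <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  tibble::tibble(n_seq = n, length = L, pi = k / L, k = k,
                 segregating_sites = s)
}

#' @rdname nucleotide_diversity
#' @param sequences Character vector of DNA sequences of any of several
#'   lengths.
#' @export
diversity_by_length_class <- function(sequences) {
  split(sequences, nchar(sequences)) |>
    purrr::keep(~ length(.x) >= 2L) |>
    purrr::map_dfr(nucleotide_diversity)
}
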