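#' Validation configuration
#'
#' Thresholds of the five-step artefact-removal procedure. Defaults are the
#' published operating point for a 454 MHC class I survey: expected insert
#' sizes 212/215/221 bp, a global minimum of four copies, a 200-read
#' per-individual coverage floor, a maximum-per-amplicon-frequency (MPAF)
#' rejection threshold of 0.01 with a review band up to 0.025 examined in the
#' three highest-frequency carriers, and a per-individual keep threshold of
#' five copies.
#'
#' @param expected_sizes Integer vector of valid insert lengths (bp).
#' @param min_global_copies Minimum whole-dataset copies; variants with fewer
#'   are removed (default 4, i.e. totals of 1-3 are removed).
#' @param min_reads_per_individual Coverage floor; individuals below it are
#'   dropped entirely.
#' @param mpaf_reject Variants with MPAF strictly below this are removed.
#' @param mpaf_review Upper edge (inclusive) of the MPAF band in which
#'   variants are removed only if explainable as artefacts.
#' @param top_k_individuals Number of highest-frequency carrier individuals in
#'   which a review-band variant is examined.
#' @param per_individual_keep Within-individual copy number at or above which
#'   a variant is kept without examination.
#' @return A `validation_config` list.
#' @export
validation_config <- function(expected_sizes = c(212L, 215L, 221L),
                              min_global_copies = 4L,
                              min_reads_per_individual = 200L,
                              mpaf_reject = 0.01,
                              mpaf_review = 0.025,
                              top_k_individuals = 3L,
                              per_individual_keep = 5L) {
  stopifnot(mpaf_reject > 0, mpaf_reject <= mpaf_review, mpaf_review < 1,
            min_global_copies >= 1, per_individual_keep >= 1)
  structure(list(
    expected_sizes = as.integer(expected_sizes),
    min_global_copies = as.integer(min_global_copies),
    min_reads_per_individual = as.integer(min_reads_per_individual),
    mpaf_reject = mpaf_reject, mpaf_review = mpaf_review,
    top_k_individuals = as.integer(top_k_individuals),
    per_individual_keep = as.integer(per_individual_keep)
  ), class = "validation_config")
}

#' Size filter (step 1)
#'
#' Removes variants whose insert length is not an expected allele size;
#' frame-shifted products of sequencing indels fall here.
#'
#' @param table Variant count tibble `(sequence, sample, count)`.
#' @param cfg A [validation_config()].
#' @return Filtered table.
#' @export
step1_size_filter <- function(table, cfg = validation_config()) {
  dplyr::filter(table, nchar(.data$sequence) %in% cfg$expected_sizes)
}

#' Global rarity filter (step 2)
#'
#' Removes variants with fewer than `min_global_copies` copies in the whole
#' dataset; such variants are almost always isolated sequencing errors.
#'
#' @inheritParams step1_size_filter
#' @return Filtered table.
#' @export
step2_global_filter <- function(table, cfg = validation_config()) {
  table |>
    dplyr::group_by(.data$sequence) |>
    dplyr::filter(sum(.data$count) >= cfg$min_global_copies) |>
    dplyr::ungroup()
}

#' Coverage filter (step 3)
#'
#' Drops individuals whose retained read total (computed on the table as it
#' stands after step 2) is below the coverage floor; their genotypes would be
#' incomplete.
#'
#' @inheritParams step1_size_filter
#' @return Filtered table; warns if every sample is dropped.
#' @export
step3_coverage_filter <- function(table, cfg = validation_config()) {
  out <- table |>
    dplyr::group_by(.data$sample) |>
    dplyr::filter(sum(.data$count) >= cfg$min_reads_per_individual) |>
    dplyr::ungroup()
  if (nrow(out) == 0L && nrow(table) > 0L) {
    warning("all samples fall below the per-individual coverage threshold")
  }
  out
}

#' Maximum per-amplicon frequency
#'
#' For each variant, the maximum over samples of its within-sample read
#' fraction. MPAF is the key artefact-screening statistic: true alleles reach
#' an appreciable fraction of at least one individual's reads, while
#' artefacts stay rare everywhere.
#'
#' @param table Variant count tibble `(sequence, sample, count)`.
#' @return Tibble `(sequence, mpaf)`; a variant absent from the table would
#'   have MPAF 0.
#' @export
mpaf <- function(table) {
  table |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(mpaf = max(.data$freq), .groups = "drop")
}

#' Single-basepair difference test
#'
#' `TRUE` iff the two sequences have equal length and Hamming distance exactly
#' 1. Single indels shift the length and are already removed by the size
#' filter, so only substitutions are considered.
#'
#' @param v,u DNA strings.
#' @return Logical scalar.
#' @export
is_single_bp <- function(v, u) {
  if (nchar(v) != nchar(u)) return(FALSE)
  a <- utf8ToInt(v); b <- utf8ToInt(u)
  sum(a != b) == 1L
}

#' Chimera test with witness
#'
#' Tests whether `v` equals a single-breakpoint concatenation
#' `a[1..k] + b[k+1..|b|]` of two distinct, more common parent sequences,
#' with `v` differing from both parents. Only exact concatenations are
#' accepted (no mismatch slack), parents of differing valid lengths are
#' allowed, and the first witness in deterministic scan order (parents
#' sorted, breakpoint ascending) is returned.
#'
#' @param v Candidate DNA string (must not itself be in `parents`).
#' @param parents Character vector of candidate parent sequences.
#' @return A list `found` (logical), and when found `a`, `b`, `breakpoint`.
#' @export
find_chimera <- function(v, parents) {
  parents <- sort(setdiff(unique(parents), v))
  nv <- nchar(v)
  vi <- utf8ToInt(v)
  pi_ <- lapply(parents, utf8ToInt)
  lens <- nchar(parents)
  # v = a[1..k] ++ b[k+1..|b|] forces |v| = |b|
  b_idx <- which(lens == nv)
  if (length(b_idx) == 0L || length(parents) < 2L) {
    return(list(found = FALSE))
  }
  lcp_v <- vapply(pi_, function(p) lcp_len(vi, p), integer(1))
  lcs_v <- vapply(pi_, function(p) lcs_len(vi, p), integer(1))
  for (ai in seq_along(parents)) {
    for (bi in b_idx) {
      if (bi == ai) next
      k_lo <- max(1L, nv - lcs_v[bi])
      k_hi <- min(lcp_v[ai], nv - 1L, lens[ai])
      if (k_lo <= k_hi) {
        return(list(found = TRUE, a = parents[ai], b = parents[bi],
                    breakpoint = k_lo))
      }
    }
  }
  list(found = FALSE)
}

#' Chimera or single-mutation explainability
#'
#' A variant is explainable as an artefact within a sample if it differs by a
#' single basepair from a strictly more common co-occurring variant, or can
#' be written as a single-breakpoint chimera of two strictly more common
#' co-occurring variants. "More common" means a strictly greater read count
#' within that sample: ties are not parents, so equally supported true
#' alleles cannot explain each other away.
#'
#' @param v Variant sequence.
#' @param sample_counts Tibble `(sequence, count)` of all variants in the
#'   sample under examination (including `v`).
#' @return Logical scalar.
#' @export
explainable <- function(v, sample_counts) {
  cv <- sample_counts$count[match(v, sample_counts$sequence)]
  if (is.na(cv)) cv <- 0L
  parents <- sample_counts$sequence[sample_counts$count > cv]
  if (length(parents) == 0L) return(FALSE)
  for (u in parents) {
    if (is_single_bp(v, u)) return(TRUE)
  }
  find_chimera(v, parents)$found
}

#' MPAF classification (step 4)
#'
#' Whole-dataset artefact screening. Variants with MPAF below the rejection
#' threshold are removed everywhere. Variants in the review band
#' (`[mpaf_reject, mpaf_review]`) are examined in the `top_k_individuals`
#' carrier samples with the highest within-sample frequency of the variant
#' (ties broken by frequency descending, then sample id ascending); the
#' variant is removed, globally, only if it is explainable in all of them.
#' Variants above the band are kept unexamined.
#'
#' @inheritParams step1_size_filter
#' @return Filtered table.
#' @export
step4_mpaf_classify <- function(table, cfg = validation_config()) {
  if (nrow(table) == 0L) return(table)
  freqs <- table |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  mp <- freqs |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(mpaf = max(.data$freq), .groups = "drop")

  drop_reject <- mp$sequence[mp$mpaf < cfg$mpaf_reject]
  review <- mp$sequence[mp$mpaf >= cfg$mpaf_reject &
                          mp$mpaf <= cfg$mpaf_review]

  by_sample <- split(freqs[c("sequence", "count")], freqs$sample)
  drop_review <- character(0)
  for (v in review) {
    carriers <- freqs[freqs$sequence == v, ]
    carriers <- carriers[order(-carriers$freq, carriers$sample), ]
    top <- utils::head(carriers$sample, cfg$top_k_individuals)
    expl <- vapply(top, function(s) explainable(v, by_sample[[s]]), logical(1))
    if (all(expl)) drop_review <- c(drop_review, v)
  }
  dplyr::filter(table, !.data$sequence %in% c(drop_reject, drop_review))
}

#' Per-individual filter (step 5)
#'
#' Individual-level artefact screening on the table as it stands after step
#' 4: single-copy variants within an individual are removed; variants with
#' 2 to `per_individual_keep - 1` copies are removed in that individual iff
#' explainable there; variants at or above the keep threshold are retained.
#' Removal is per individual, not global.
#'
#' @inheritParams step1_size_filter
#' @return Genotype tibble `(sample, sequence, copies)`.
#' @export
step5_individual_filter <- function(table, cfg = validation_config()) {
  if (nrow(table) == 0L) {
    return(tibble::tibble(sample = character(0), sequence = character(0),
                          copies = integer(0)))
  }
  by_sample <- split(table[c("sequence", "count")], table$sample)
  purrr::map_dfr(names(by_sample), function(s) {
    sc <- by_sample[[s]]
    keep <- logical(nrow(sc))
    for (i in seq_len(nrow(sc))) {
      cv <- sc$count[i]
      if (cv <= 1L) next
      if (cv >= cfg$per_individual_keep) {
        keep[i] <- TRUE
      } else {
        keep[i] <- !explainable(sc$sequence[i], sc)
      }
    }
    tibble::tibble(sample = s, sequence = sc$sequence[keep],
                   copies = sc$count[keep])
  })
}

#' Run the five-step variant validation procedure
#'
#' Applies the steps strictly in order (size, global rarity, coverage, MPAF
#' classification, per-individual screening), recomputing counts after each
#' step, and logs the read/variant/sample funnel.
#'
#' @inheritParams step1_size_filter
#' @return A `validation_result` list: `genotypes` (tibble `sample, sequence,
#'   copies`), `funnel` (per-step reads/variants/samples with retention
#'   fractions), and `cfg`. `tidy()` returns the genotypes, `glance()` the
#'   funnel.
#' @export
run_validation <- function(table, cfg = validation_config()) {
  funnel_row <- function(tb, step) {
    tibble::tibble(step = step, reads = sum(tb$count),
                   variants = dplyr::n_distinct(tb$sequence),
                   samples = dplyr::n_distinct(tb$sample))
  }
  steps <- list(
    input = identity,
    size_filter = function(tb) step1_size_filter(tb, cfg),
    global_rarity_filter = function(tb) step2_global_filter(tb, cfg),
    coverage_filter = function(tb) step3_coverage_filter(tb, cfg),
    mpaf_classification = function(tb) step4_mpaf_classify(tb, cfg)
  )
  funnel <- list()
  tb <- table
  for (nm in names(steps)) {
    tb <- steps[[nm]](tb)
    funnel[[nm]] <- funnel_row(tb, nm)
  }
  genotypes <- step5_individual_filter(tb, cfg)
  funnel$individual_filter <- tibble::tibble(
    step = "individual_filter", reads = sum(genotypes$copies),
    variants = dplyr::n_distinct(genotypes$sequence),
    samples = dplyr::n_distinct(genotypes$sample))
  funnel <- dplyr::bind_rows(funnel)
  funnel$retained_reads <- funnel$reads / dplyr::lag(funnel$reads)
  structure(list(genotypes = genotypes, funnel = funnel, cfg = cfg),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("Five-step variant validation\n")
  print(x$funnel)
  cat(sprintf("%d alleles across %d samples retained\n",
              dplyr::n_distinct(x$genotypes$sequence),
              dplyr::n_distinct(x$genotypes$sample)))
  invisible(x)
}

#' @rdname run_validation
#' @param x A `validation_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.validation_result <- function(x, ...) x$genotypes

#' @rdname run_validation
#' @exportS3Method generics::glance
glance.validation_result <- function(x, ...) x$funnel
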