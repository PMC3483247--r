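#' Duplicate-pair repeatability
#'
#' Agreement score for samples genotyped twice: per pair,
#' `score = shared / (shared + unique)`, where `shared` counts alleles (or
#' supertypes) present in both replicates and `unique` those present in
#' exactly one; the score is 1 iff the genotypes are identical. The overall
#' repeatability is the unweighted mean of the pair scores. Full precision is
#' retained internally; the printed report rounds half-up to 2 decimals.
#'
#' @param pairs Tibble with columns `shared` and `unique` (one row per
#'   duplicate pair; extra columns such as a pair id or step label are kept).
#' @return List `pairs` (input with a `score` column) and `mean` (numeric).
#' @export
repeatability <- function(pairs) {
  stopifnot(all(c("shared", "unique") %in% names(pairs)),
            all(pairs$shared >= 0), all(pairs$unique >= 0),
            all(pairs$shared + pairs$unique > 0))
  pairs$score <- pairs$shared / (pairs$shared + pairs$unique)
  list(pairs = pairs, mean = mean(pairs$score))
}

# Round half-up (not banker's rounding) for display.
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Agreement counts between two replicate genotypes
#'
#' Computes the (shared, unique) counts that feed [repeatability()] from two
#' allele (or supertype) sets. Symmetric in the two replicates.
#'
#' @param set_a,set_b Character/integer vectors of allele ids or supertypes.
#' @return Tibble `(shared, unique)`.
#' @export
agreement_counts <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  shared <- length(intersect(a, b))
  tibble::tibble(shared = shared,
                 unique = length(a) + length(b) - 2L * shared)
}

#' Repeatability from genotype tables
#'
#' Scores every duplicate pair from a genotype table. Pseudogene and other
#' non-functional alleles should be removed before scoring (they are not
#' part of the typed repertoire); pass the allele annotation to do this.
#'
#' @param genotypes Tibble with `sample` and an item column (`allele_id` or
#'   `supertype`).
#' @param dup_pairs Tibble `(sample_a, sample_b)` of replicate pairs; both
#'   members must be present in `genotypes`.
#' @param item Name of the item column (default `"allele_id"`).
#' @return As [repeatability()], with pair ids attached.
#' @export
repeatability_from_genotypes <- function(genotypes, dup_pairs,
                                         item = "allele_id") {
  counts <- purrr::pmap_dfr(dup_pairs, function(sample_a, sample_b, ...) {
    a <- genotypes[[item]][genotypes$sample == sample_a]
    b <- genotypes[[item]][genotypes$sample == sample_b]
    dplyr::bind_cols(tibble::tibble(sample_a = sample_a,
                                    sample_b = sample_b),
                     agreement_counts(a, b))
  })
  repeatability(counts)
}

#' Minimum locus number under diploidy
#'
#' A diploid individual carries at most two alleles per locus, so observing
#' `a` distinct alleles in one individual implies at least `ceiling(a / 2)`
#' loci.
#'
#' @param max_alleles_per_individual Largest distinct-allele count observed
#'   in any single individual.
#' @return Integer lower bound on the locus number.
#' @examples
#' min_loci(37) # 19
#' min_loci(32) # 16
#' @export
min_loci <- function(max_alleles_per_individual) {
  as.integer(ceiling(max_alleles_per_individual / 2))
}

#' Genotyping summary with locus-number bounds
#'
#' Range, mean and SD of per-individual allele counts, plus the diploid
#' lower bound on locus number, for each allele category.
#'
#' @param genotypes Tibble with `sample`, `allele_id` and optionally a
#'   logical `functional` column and a `supertype` column.
#' @return Tibble, one row per category (`all`, and when available
#'   `functional` and `supertype`), with `min`, `max`, `mean`, `sd`,
#'   `n_loci` (NA for supertypes, which are not loci).
#' @export
loci_summary <- function(genotypes) {
  summarise_counts <- function(d, key, loci = TRUE) {
    per <- d |>
      dplyr::distinct(.data$sample, .data[[key]]) |>
      dplyr::count(.data$sample)
    tibble::tibble(
      min = min(per$n), max = max(per$n),
      mean = mean(per$n), sd = stats::sd(per$n),
      n_loci = if (loci) min_loci(max(per$n)) else NA_integer_)
  }
  out <- dplyr::bind_cols(tibble::tibble(category = "all"),
                          summarise_counts(genotypes, "allele_id"))
  if ("functional" %in% names(genotypes) && any(genotypes$functional)) {
    out <- dplyr::bind_rows(out, dplyr::bind_cols(
      tibble::tibble(category = "functional"),
      summarise_counts(dplyr::filter(genotypes, .data$functional),
                       "allele_id")))
  }
  if ("supertype" %in% names(genotypes)) {
    st <- dplyr::filter(genotypes, !is.na(.data$supertype))
    out <- dplyr::bind_rows(out, dplyr::bind_cols(
      tibble::tibble(category = "supertype"),
      summarise_counts(st, "supertype", loci = FALSE)))
  }
  out
}

#' Read-depth versus allele-count QC regression
#'
#' Above the coverage floor, allele number should not depend on read number;
#' a significant positive slope would indicate incomplete genotyping of
#' low-coverage individuals. Simple least squares of allele count on read
#' count.
#'
#' @param per_sample Tibble with `reads` and `n_alleles` columns (one row per
#'   retained sample).
#' @return Tibble `(r_squared, slope, p_value, n)`.
#' @export
qc_read_vs_allele <- function(per_sample) {
  stopifnot(all(c("reads", "n_alleles") %in% names(per_sample)))
  if (stats::var(per_sample$n_alleles) == 0) {
    return(tibble::tibble(r_squared = 0, slope = 0, p_value = NA_real_,
                          n = nrow(per_sample)))
  }
  fit <- stats::lm(n_alleles ~ reads, data = per_sample)
  sm <- summary(fit)
  tibble::tibble(r_squared = sm$r.squared,
                 slope = stats::coef(fit)[["reads"]],
                 p_value = sm$coefficients["reads", "Pr(>|t|)"],
                 n = nrow(per_sample))
}

#' Example duplicate agreement counts
#'
#' Loads the bundled duplicate-pair agreement counts from a bidirectional
#' 454 MHC class I genotyping survey of a wild passerine: for each of 12
#' duplicate pairs, the number of alleles shared by both replicates and the
#' number seen in exactly one, after validation steps 3-5 and after
#' supertype classification (step `"ST"`). Pseudogene alleles were removed
#' before counting.
#'
#' @return Tibble `(pair, step, shared, unique)`.
#' @export
example_duplicate_counts <- function() {
  path <- system.file("extdata", "duplicate_agreement.tsv",
                      package = "mhctyper", mustWork = TRUE)
  tb <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::as_tibble(tb)
}
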