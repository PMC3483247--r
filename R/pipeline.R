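#' Pipeline configuration
#'
#' Bundles the stage configurations for an end-to-end run: simulation (or
#' input files), demultiplexing, validation, annotation, selection masks and
#' supertyping. All randomness derives from explicit seeds inside the stage
#' configs, so a re-run with the same config is identical.
#'
#' @param sim A [sim_config()] (used when reads are simulated).
#' @param validation A [validation_config()].
#' @param references Optional tibble `(group, sequence)` for
#'   [assign_group()].
#' @param pss Optional integer PSS codon/residue mask (1-based amino-acid
#'   positions) for supertyping and selection.
#' @param abs_sites Optional integer ABS mask, same convention.
#' @param frame_offset Reading frame offset of the amplicon.
#' @param run_selection,run_supertypes Logical stage switches; a requested
#'   stage without its mask fails fast.
#' @param k Manual supertype count (`NULL` = BIC elbow).
#' @param k_max,n_starts Supertype clustering controls.
#' @param n_bootstrap Bootstrap replicates for selection tests.
#' @param seed Master seed for analysis stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            validation = validation_config(),
                            references = NULL,
                            pss = NULL,
                            abs_sites = NULL,
                            frame_offset = 0,
                            run_selection = !is.null(pss),
                            run_supertypes = !is.null(pss),
                            k = NULL, k_max = 20, n_starts = 50,
                            n_bootstrap = 1000,
                            seed = 1L) {
  if (run_selection && is.null(pss)) {
    stop("selection stage requested but no PSS mask supplied")
  }
  if (run_supertypes && is.null(pss)) {
    stop("supertype stage requested but no PSS mask supplied")
  }
  structure(list(sim = sim, validation = validation,
                 references = references, pss = pss, abs_sites = abs_sites,
                 frame_offset = frame_offset,
                 run_selection = run_selection,
                 run_supertypes = run_supertypes,
                 k = k, k_max = k_max, n_starts = n_starts,
                 n_bootstrap = n_bootstrap, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full genotyping pipeline
#'
#' Executes the stages in order - simulate, demultiplex, tally, five-step
#' validation, annotation, then (optionally) selection tests and
#' supertyping - logging a read-retention funnel line per stage. Stage
#' contracts compose: the demultiplexer's tally is the validation input
#' without transformation. Re-running with the same config reproduces every
#' artifact exactly.
#'
#' @param config A [pipeline_config()].
#' @param reads Optional tibble `(read_id, sequence)` of externally supplied
#'   reads; with `sample_sheet`, skips simulation.
#' @param sample_sheet Required with `reads`: tibble
#'   `(region, mid_f, mid_r, sample)`.
#' @param quiet Suppress funnel messages.
#' @return A `pipeline_result` list: `truth` (when simulated), `tally`,
#'   `validation`, `alleles`, `genotypes`, `diversity`, `selection`,
#'   `supertypes`, `supertype_genotypes`, `summary`, `qc`.
#' @export
run_pipeline <- function(config, reads = NULL, sample_sheet = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  truth <- NULL
  if (is.null(reads)) {
    truth <- simulate_genotypes(config$sim)
    sim <- simulate_reads(truth, config$sim)
    reads <- sim$reads
    sample_sheet <- sim$sample_sheet
    say("simulate: %d reads from %d individuals", nrow(reads),
        config$sim$n_individuals)
  } else if (is.null(sample_sheet)) {
    stop("external reads require a sample sheet")
  }

  parsed <- parse_reads(reads, config$sim$mid_set, config$sim$primer_f,
                        config$sim$primer_r)
  tl <- tally_variants(parsed, sample_sheet)
  n_assigned <- sum(tl$table$count)
  say("demultiplex: %d/%d reads assigned (%.1f%% of the previous step)",
      n_assigned, nrow(reads), 100 * n_assigned / nrow(reads))

  val <- run_validation(tl$table, config$validation)
  fin <- val$funnel[nrow(val$funnel), ]
  say("validate: %d reads, %d alleles, %d samples retained",
      fin$reads, fin$variants, fin$samples)

  ann <- annotate_alleles(val$genotypes, config$references,
                          config$frame_offset)
  genotypes <- dplyr::left_join(
    ann$genotypes,
    dplyr::select(ann$alleles, "allele_id", "group", "functional"),
    by = "allele_id")
  say("annotate: %d alleles (%d functional)", nrow(ann$alleles),
      sum(ann$alleles$functional))

  diversity <- if (dplyr::n_distinct(ann$alleles$sequence) >= 2) {
    diversity_by_length_class(ann$alleles$sequence)
  } else NULL

  selection <- NULL
  if (config$run_selection) {
    if (is.null(config$pss)) stop("stage 'selection' is missing its PSS mask")
    fun <- dplyr::filter(ann$alleles, .data$functional)
    classes <- split(fun$sequence, nchar(fun$sequence))
    main <- classes[[which.max(lengths(classes))]]
    n_codons <- (nchar(main[1L]) - config$frame_offset) %/% 3L
    masks <- list(PSS = config$pss,
                  `Non-PSS` = complement_mask(config$pss, n_codons),
                  All = seq_len(n_codons))
    if (!is.null(config$abs_sites)) {
      masks <- c(list(ABS = config$abs_sites,
                      `Non-ABS` = complement_mask(config$abs_sites,
                                                  n_codons)), masks)
    }
    selection <- selection_table(main, masks, config$frame_offset,
                                 config$n_bootstrap, config$seed)
    say("selection: %d site classes tested on %d alleles", length(masks),
        length(main))
  }

  st_model <- NULL; st_geno <- NULL
  if (config$run_supertypes) {
    if (is.null(config$pss)) stop("stage 'supertype' is missing its PSS mask")
    fun <- dplyr::filter(ann$alleles, .data$functional)
    aa_len <- nchar(fun$aa)
    keep <- aa_len == max(aa_len) # PSS positions are defined on one frame
    st_model <- supertype_fit(fun[keep, ], config$pss, k = config$k,
                              k_max = config$k_max,
                              n_starts = config$n_starts,
                              seed = config$seed)
    st_geno <- supertype_genotypes(genotypes, st_model$labels)
    say("supertype: k = %d over %d alleles", st_model$k, sum(keep))
    genotypes <- dplyr::left_join(
      genotypes, st_model$labels, by = "allele_id")
  }

  per_sample <- genotypes |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(reads = sum(.data$copies),
                     n_alleles = dplyr::n_distinct(.data$allele_id),
                     .groups = "drop")
  qc <- if (nrow(per_sample) >= 3) qc_read_vs_allele(per_sample) else NULL

  structure(list(
    truth = truth, tally = tl, validation = val,
    alleles = ann$alleles, genotypes = genotypes,
    diversity = diversity, selection = selection,
    supertypes = st_model, supertype_genotypes = st_geno,
    summary = loci_summary(genotypes), qc = qc,
    config = config
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("MHC amplicon genotyping pipeline result\n")
  print(x$validation$funnel)
  print(x$summary)
  invisible(x)
}

#' Write pipeline artifacts as plain-text files
#'
#' Genotypes and the funnel as TSV, validated allele sequences as FASTA with
#' their stable ids.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$genotypes, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$validation$funnel, file.path(dir, "funnel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$alleles[setdiff(names(result$alleles), "aa")],
                     file.path(dir, "alleles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(stats::setNames(result$alleles$sequence,
                              result$alleles$allele_id),
              file.path(dir, "alleles.fasta"))
  if (!is.null(result$supertypes)) {
    utils::write.table(tidy(result$supertypes),
                       file.path(dir, "supertypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
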