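#' Orient and parse tagged amplicon reads
#'
#' Re-implementation of the extraction step of MHC amplicon demultiplexers:
#' a read is assigned only if it bears a complete forward MID, forward primer,
#' reverse primer (reverse-complemented) and reverse MID
#' (reverse-complemented), in that layout, on either strand. Matching is
#' exact against the degenerate primer patterns (a mismatch budget exists but
#' defaults to 0), and any read containing an ambiguous base (N) is
#' unassigned.
#'
#' @param reads Tibble `(read_id, sequence)`.
#' @param mid_set Named character vector of 10-bp MID tags.
#' @param primer_f,primer_r IUPAC degenerate primers (5'->3' on their own
#'   strands).
#' @param max_mismatch Mismatches tolerated in each primer window (default 0;
#'   MID matching is always exact).
#' @return Tibble `(read_id, orientation, mid_f, mid_r, insert, reason)`;
#'   `orientation` is `"forward"`, `"reverse"` or `"unassigned"`, and for
#'   unassigned reads `reason` is `"ambiguous_base"` or
#'   `"incomplete_tag_or_primer"`. The insert excludes primers on both ends
#'   and is always reported on the canonical (forward-primer) strand, so a
#'   read and its reverse complement parse to the same insert.
#' @export
parse_reads <- function(reads, mid_set = default_mids,
                        primer_f = "TTMYGGCTGTGACCTCCTG",
                        primer_r = "TTGCGCTYCAGCTCTTTC",
                        max_mismatch = 0L) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  out <- tibble::tibble(
    read_id = reads$read_id,
    orientation = rep("unassigned", n),
    mid_f = NA_character_, mid_r = NA_character_,
    insert = NA_character_,
    reason = NA_character_
  )
  # region comes from the file/lane, never from sequence content
  if ("region" %in% names(reads)) {
    out <- dplyr::mutate(out, region = reads$region, .after = "read_id")
  }
  if (n == 0L) return(out)
  seqs <- toupper(reads$sequence)
  has_n <- grepl("N", seqs, fixed = TRUE)
  out$reason[has_n] <- "ambiguous_base"

  todo <- which(!has_n)
  fwd <- parse_layout(seqs[todo], mid_set, primer_f, primer_r, max_mismatch)
  ok <- fwd$ok
  out$orientation[todo[ok]] <- "forward"
  out$mid_f[todo[ok]] <- fwd$mid_f[ok]
  out$mid_r[todo[ok]] <- fwd$mid_r[ok]
  out$insert[todo[ok]] <- fwd$insert[ok]

  rest <- todo[!ok]
  if (length(rest)) {
    rev <- parse_layout(revcomp(seqs[rest]), mid_set, primer_f, primer_r,
                        max_mismatch)
    ok2 <- rev$ok
    out$orientation[rest[ok2]] <- "reverse"
    out$mid_f[rest[ok2]] <- rev$mid_f[ok2]
    out$mid_r[rest[ok2]] <- rev$mid_r[ok2]
    out$insert[rest[ok2]] <- rev$insert[ok2]
    out$reason[rest[!ok2]] <- "incomplete_tag_or_primer"
  }
  out
}

# Attempt the forward layout MID_f | primer_f | insert | rc(primer_r) |
# rc(MID_r) on a vector of sequences.
parse_layout <- function(seqs, mid_set, primer_f, primer_r, max_mismatch) {
  lf <- nchar(primer_f); lr <- nchar(primer_r)
  len <- nchar(seqs)
  long_enough <- len >= (20L + lf + lr + 1L)
  mid_f <- substr(seqs, 1L, 10L)
  mid_r_rc <- substr(seqs, len - 9L, len)
  pf_win <- substr(seqs, 11L, 10L + lf)
  pr_win_rc <- substr(seqs, len - 9L - lr, len - 10L)
  ok <- long_enough &
    mid_f %in% mid_set &
    revcomp(mid_r_rc) %in% mid_set &
    match_degenerate_tol(primer_f, pf_win, max_mismatch) &
    match_degenerate_tol(primer_r, revcomp(pr_win_rc), max_mismatch)
  insert <- substr(seqs, 11L + lf, len - 10L - lr)
  mid_names <- stats::setNames(names(mid_set), unname(mid_set))
  list(ok = ok,
       mid_f = unname(mid_names[mid_f]),
       mid_r = unname(mid_names[revcomp(mid_r_rc)]),
       insert = insert)
}

# Degenerate match with an optional mismatch budget.
match_degenerate_tol <- function(pattern, window, max_mismatch = 0L) {
  if (max_mismatch <= 0L) return(match_degenerate(pattern, window))
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  np <- length(pat)
  ok_len <- nchar(window) == np
  mism <- integer(length(window))
  mism[!ok_len] <- np
  win <- window[ok_len]
  m <- integer(length(win))
  for (i in seq_len(np)) {
    m <- m + !(substr(win, i, i) %in% iupac_sets[[pat[i]]])
  }
  mism[ok_len] <- m
  mism <= max_mismatch
}

#' Tally parsed reads into a variant count table
#'
#' Inserts are canonicalised to the forward-primer strand during parsing, so
#' identical amplicons sequenced in either direction collapse to one
#' variant. Reads that are unassigned, or
#' whose MID pair is absent from the sample sheet, are counted in a discard
#' log by reason.
#'
#' @param parsed Output of [parse_reads()]. MID tags are reused across plate
#'   regions, so reads must carry a `region` column (set from the file/lane,
#'   as in the simulator's output) whenever the sheet spans several regions.
#' @param sample_sheet Tibble `(region, mid_f, mid_r, sample)`; the mapping
#'   must be injective within each region.
#' @param region Region (plate lane) identifier applied to all reads when
#'   they lack a `region` column.
#' @return A list: `table` (tibble `sequence, sample, count`), `totals`
#'   (tibble `sample, reads`), and `discards` (tibble `reason, n`).
#' @export
tally_variants <- function(parsed, sample_sheet, region = NULL) {
  sheet <- sample_sheet
  if (anyDuplicated(sheet[c("region", "mid_f", "mid_r")])) {
    stop("sample sheet is not injective within region")
  }
  if (!"region" %in% names(parsed)) {
    if (is.null(region)) {
      if (dplyr::n_distinct(sheet$region) > 1L) {
        stop("reads lack a region and the sample sheet spans several regions")
      }
      region <- sheet$region[1L]
    }
    parsed <- dplyr::mutate(parsed, region = region)
  }
  assigned <- dplyr::filter(parsed, .data$orientation != "unassigned")
  assigned <- dplyr::left_join(
    assigned,
    dplyr::select(sheet, "region", "mid_f", "mid_r", "sample"),
    by = c("region", "mid_f", "mid_r"))
  unknown <- is.na(assigned$sample)
  kept <- assigned[!unknown, ]

  tab <- kept |>
    dplyr::rename(sequence = "insert") |>
    dplyr::count(.data$sequence, .data$sample, name = "count") |>
    dplyr::arrange(.data$sequence, .data$sample)
  totals <- kept |>
    dplyr::count(.data$sample, name = "reads")

  disc <- parsed |>
    dplyr::filter(.data$orientation == "unassigned") |>
    dplyr::count(.data$reason, name = "n") |>
    dplyr::rename(reason = "reason")
  if (any(unknown)) {
    disc <- dplyr::bind_rows(
      disc, tibble::tibble(reason = "unknown_tag_pair", n = sum(unknown)))
  }
  list(table = tab, totals = totals, discards = disc)
}
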