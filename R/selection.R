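# Codon machinery for the Nei-Gojobari (1986) method. Stop codons are
# excluded: a one-step change creating a stop contributes to neither
# synonymous nor nonsynonymous counts, and mutational pathways passing
# through a stop codon are dropped (with an all-pathways fallback if every
# shortest pathway is blocked).

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), names(gc))
}

aa_of <- local({
  tab <- NULL
  function(codon) {
    if (is.null(tab)) tab <<- codon_table()
    unname(tab[codon])
  }
})

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' Each codon position contributes the fraction of its viable one-step
#' changes (changes not creating a stop codon) that are synonymous; the
#' complement is nonsynonymous, so the two site counts always sum to 3.
#'
#' @param codon A 3-letter DNA string (non-stop codon).
#' @return Named numeric `c(syn, nonsyn)`.
#' @export
ng86_codon_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- aa_of(codon)
  if (is.na(aa0) || aa0 == "*") stop("not a sense codon: ", codon)
  syn <- 0
  for (p in 1:3) {
    b0 <- substr(codon, p, p)
    f_syn <- 0; f_tot <- 0
    for (b in setdiff(bases, b0)) {
      cod <- codon
      substr(cod, p, p) <- b
      aa1 <- aa_of(cod)
      if (aa1 == "*") next
      f_tot <- f_tot + 1
      if (aa1 == aa0) f_syn <- f_syn + 1
    }
    syn <- syn + if (f_tot > 0) f_syn / f_tot else 0
  }
  c(syn = syn, nonsyn = 3 - syn)
}

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' Codons differing at several positions are averaged over all shortest
#' mutational pathways (orders of single-base changes); pathways crossing a
#' stop codon are excluded. If every pathway is blocked, the unweighted
#' average over all pathways is used so the pair still contributes.
#'
#' @param ca,cb 3-letter DNA strings (sense codons).
#' @return Named numeric `c(syn, nonsyn)`; sums to the nucleotide distance
#'   between the codons (when at least one pathway is viable).
#' @export
ng86_codon_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  orders <- all_permutations(pos)
  path_counts <- function(order, allow_stop) {
    cur <- ca
    syn <- 0; nonsyn <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      aa1 <- aa_of(cur); aa2 <- aa_of(nxt)
      if (!allow_stop && aa2 == "*") return(NULL)
      if (aa1 == aa2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn, nonsyn)
  }
  res <- purrr::compact(lapply(orders, path_counts, allow_stop = FALSE))
  if (length(res) == 0L) {
    res <- lapply(orders, path_counts, allow_stop = TRUE)
  }
  avg <- Reduce(`+`, res) / length(res)
  c(syn = avg[1], nonsyn = avg[2])
}

# All permutations of a small vector (d <= 3 here).
all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Jukes-Cantor correction
#'
#' Corrects a proportion of observed differences for multiple hits:
#' `d = -(3/4) log(1 - (4/3) p)`. Proportions at or beyond the saturation
#' point 3/4 have no finite distance and return `NA`.
#'
#' @param p Proportion(s) of sites differing, in \[0, 3/4).
#' @return Corrected distance(s); `NA` where saturated.
#' @export
jukes_cantor <- function(p) {
  out <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
  if (anyNA(out) && any(p >= 0.75, na.rm = TRUE)) {
    warning("Jukes-Cantor saturation: p >= 3/4 for some comparisons")
  }
  out
}

# Per-pair, per-codon NG86 components for an alignment restricted to a codon
# mask. Returns arrays [pair, codon] of syn sites, nonsyn sites, syn diffs,
# nonsyn diffs.
ng86_components <- function(codons_mat) {
  n <- nrow(codons_mat); nc <- ncol(codons_mat)
  uniq <- unique(as.vector(codons_mat))
  sites <- vapply(uniq, ng86_codon_sites, numeric(2))
  colnames(sites) <- uniq
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  S <- Sd <- N <- Nd <- matrix(0, np, nc)
  diff_cache <- new.env(parent = emptyenv())
  for (pp in seq_len(np)) {
    i <- pairs[1L, pp]; j <- pairs[2L, pp]
    for (cc in seq_len(nc)) {
      ca <- codons_mat[i, cc]; cb <- codons_mat[j, cc]
      S[pp, cc] <- (sites["syn", ca] + sites["syn", cb]) / 2
      N[pp, cc] <- 3 - S[pp, cc]
      if (ca != cb) {
        key <- if (ca < cb) paste0(ca, cb) else paste0(cb, ca)
        dd <- diff_cache[[key]]
        if (is.null(dd)) {
          dd <- ng86_codon_diffs(ca, cb)
          diff_cache[[key]] <- dd
        }
        Sd[pp, cc] <- dd["syn"]; Nd[pp, cc] <- dd["nonsyn"]
      }
    }
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, pairs = pairs)
}

# Mean pairwise JC-corrected dN and dS from component arrays over a set of
# codon columns (possibly a bootstrap resample). Saturated pairs are dropped.
dn_ds_from_components <- function(comp, cols) {
  S <- rowSums(comp$S[, cols, drop = FALSE])
  N <- rowSums(comp$N[, cols, drop = FALSE])
  Sd <- rowSums(comp$Sd[, cols, drop = FALSE])
  Nd <- rowSums(comp$Nd[, cols, drop = FALSE])
  ps <- ifelse(S > 0, Sd / S, 0)
  pn <- ifelse(N > 0, Nd / N, 0)
  ds <- suppressWarnings(jukes_cantor(ps))
  dn <- suppressWarnings(jukes_cantor(pn))
  ok <- !is.na(ds) & !is.na(dn)
  c(dN = mean(dn[ok]), dS = mean(ds[ok]), n_dropped = sum(!ok))
}

#' Codon-based Z-test of positive selection
#'
#' Estimates mean pairwise dN and dS over a codon site class by the
#' Nei-Gojobari method with Jukes-Cantor correction, and tests dN > dS with a
#' one-tailed Z-test. Standard errors come from a seeded bootstrap over codon
#' sites. When Z <= 0 the p-value is reported as 1 (no evidence of positive
#' selection); pairs saturated under the correction are excluded with a
#' warning rather than failing the run.
#'
#' @param sequences Character vector (>= 2) of equal-length, codon-aligned
#'   DNA sequences; length must be a multiple of 3 after `frame_offset`.
#' @param mask Integer vector of 1-based codon positions defining the site
#'   class; `NULL` uses all codons.
#' @param frame_offset Bases skipped before the first codon.
#' @param n_bootstrap Bootstrap replicates for the standard errors.
#' @param seed Integer seed for the bootstrap.
#' @return A `selection_test` object; `tidy()` gives the one-row summary
#'   `(n, dN, dN_se, dS, dS_se, Z, p)` with `n` in nucleotide sites
#'   (3 per codon), as such tables are conventionally printed.
#' @export
z_test <- function(sequences, mask = NULL, frame_offset = 0,
                   n_bootstrap = 1000, seed = 1L) {
  stopifnot(length(sequences) >= 2L,
            length(unique(nchar(sequences))) == 1L)
  body <- substr(sequences, frame_offset + 1L, nchar(sequences))
  n_codon <- nchar(body[1L]) %/% 3L
  starts <- 3L * (seq_len(n_codon) - 1L) + 1L
  codons_mat <- do.call(rbind, lapply(body, function(s) {
    substring(s, starts, starts + 2L)
  }))
  if (is.null(mask)) mask <- seq_len(n_codon)
  stopifnot(all(mask >= 1L), all(mask <= n_codon))
  comp <- ng86_components(codons_mat[, mask, drop = FALSE])
  nc <- length(mask)
  est <- dn_ds_from_components(comp, seq_len(nc))
  if (!is.finite(est[["dN"]]) || !is.finite(est[["dS"]])) {
    warning("every pair is saturated under the Jukes-Cantor correction; ",
            "no dN/dS estimate is possible for this site class")
    return(structure(list(
      summary = tibble::tibble(n = 3L * nc, dN = NA_real_, dN_se = NA_real_,
                               dS = NA_real_, dS_se = NA_real_,
                               Z = NA_real_, p = NA_real_),
      mask = mask, n_bootstrap = n_bootstrap, seed = seed
    ), class = "selection_test"))
  }
  if (est[["n_dropped"]] > 0) {
    warning(sprintf("%d saturated pairs excluded from dN/dS", est[["n_dropped"]]))
  }
  set.seed(seed)
  boot <- replicate(n_bootstrap, {
    cols <- sample.int(nc, nc, replace = TRUE)
    b <- dn_ds_from_components(comp, cols)
    c(b[["dN"]], b[["dS"]])
  })
  dn_se <- stats::sd(boot[1L, ], na.rm = TRUE)
  ds_se <- stats::sd(boot[2L, ], na.rm = TRUE)
  diff_se <- stats::sd(boot[1L, ] - boot[2L, ], na.rm = TRUE)
  dn <- est[["dN"]]; ds <- est[["dS"]]
  z <- if (dn == ds) 0 else (dn - ds) / diff_se
  if (!is.finite(z)) z <- 0
  p <- if (z > 0) stats::pnorm(z, lower.tail = FALSE) else 1
  p <- max(p, .Machine$double.xmin)
  structure(list(
    summary = tibble::tibble(
      n = 3L * nc, dN = dn, dN_se = dn_se, dS = ds, dS_se = ds_se,
      Z = z, p = p),
    mask = mask, n_bootstrap = n_bootstrap, seed = seed
  ), class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat("Codon-based Z-test of selection (NG86 + Jukes-Cantor)\n")
  print(x$summary)
  invisible(x)
}

#' @rdname z_test
#' @param x A `selection_test`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.selection_test <- function(x, ...) x$summary

#' @rdname z_test
#' @exportS3Method generics::glance
glance.selection_test <- function(x, ...) {
  dplyr::mutate(x$summary, n_bootstrap = x$n_bootstrap)
}

#' Complement of a codon-position mask
#'
#' @param mask Integer codon positions.
#' @param n_codons Total codon count of the alignment.
#' @return The complementary positions.
#' @export
complement_mask <- function(mask, n_codons) {
  setdiff(seq_len(n_codons), mask)
}

#' Read a site mask from a whitespace-separated position list
#'
#' @param path File containing 1-based codon positions.
#' @return Sorted integer vector.
#' @export
read_mask <- function(path) {
  sort(unique(as.integer(scan(path, quiet = TRUE))))
}

#' Z-tests across the standard site classes
#'
#' Runs [z_test()] on each named site class (e.g. ABS / non-ABS / PSS /
#' non-PSS / all) and binds the results into one table shaped like the
#' conventional selection-test summaries.
#'
#' @param sequences As in [z_test()].
#' @param masks Named list of codon-position vectors; classes named
#'   `"non-<x>"` can be derived with [complement_mask()] beforehand.
#' @inheritParams z_test
#' @return Tibble with a `sites` column plus the [z_test()] summary columns.
#' @export
selection_table <- function(sequences, masks, frame_offset = 0,
                            n_bootstrap = 1000, seed = 1L) {
  purrr::imap_dfr(masks, function(m, nm) {
    res <- z_test(sequences, m, frame_offset, n_bootstrap, seed)
    dplyr::bind_cols(tibble::tibble(sites = nm), res$summary)
  })
}
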