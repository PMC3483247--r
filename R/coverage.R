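#' Exact multinomial coverage confidence
#'
#' Probability that, in `n` reads drawn uniformly from the `2m` allele copies
#' of a fully heterozygous diploid individual with `m` co-amplifying loci,
#' every allele is sequenced at least `r` times. This is the worst-case
#' ("negative multinomial") depth model used to justify a minimum per-individual
#' read threshold: `2m` equiprobable multinomial categories, all required to
#' reach count `r`.
#'
#' Computed exactly by inclusion-exclusion over the set of categories that fail
#' to reach `r` copies:
#' \deqn{P = \sum_{j=0}^{k} (-1)^j \binom{k}{j} P(\text{j designated cells each} < r)}
#' with \eqn{k = 2m}. The inner joint probability is evaluated by dynamic
#' programming over the bounded cell counts, in log space, so the function is
#' stable for `n` up to at least 1e4.
#'
#' @param n Number of reads (non-negative integer; vectorised).
#' @param m Number of loci (>= 1). The model uses `2m` equiprobable alleles.
#' @param r Minimum copies required per allele (>= 1).
#' @return Probability in \[0, 1\], one element per `n`.
#' @examples
#' coverage_confidence(9, m = 1, r = 2)   # 1 - 20/512
#' @export
coverage_confidence <- function(n, m, r = 2) {
  stopifnot(m >= 1, r >= 1, all(n >= 0))
  vapply(n, coverage_confidence_one, numeric(1), m = m, r = r)
}

coverage_confidence_one <- function(n, m, r) {
  k <- 2L * as.integer(m)
  if (n < k * r) return(0)
  # g_j(s): sum over compositions (c_1..c_j), each c_i in 0..r-1 summing to s,
  # of prod 1/c_i!. Built by repeated convolution with w_s = 1/s!.
  w <- 1 / factorial(0:(r - 1L))
  log_terms <- numeric(k + 1L)
  signs <- rep_len(c(1, -1), k + 1L)
  g <- 1 # g_0: point mass at s = 0
  log_terms[1L] <- 0 # j = 0 term: probability 1
  for (j in seq_len(k)) {
    # convolve previous g with w
    s_max <- (j - 1L) * (r - 1L)
    gn <- numeric(j * (r - 1L) + 1L)
    for (s in 0:(r - 1L)) {
      idx <- seq_len(s_max + 1L) + s
      gn[idx] <- gn[idx] + g * w[s + 1L]
    }
    g <- gn
    s_vals <- 0:(j * (r - 1L))
    s_vals <- s_vals[s_vals <= n]
    gg <- g[s_vals + 1L]
    # log P(j designated cells each < r), via logsumexp over s
    rest <- (k - j) / k
    lp_s <- ifelse(gg > 0,
      log(gg) + lgamma(n + 1) - lgamma(n - s_vals + 1) -
        s_vals * log(k) +
        ifelse(n - s_vals == 0, 0,
               if (rest > 0) (n - s_vals) * log(rest) else -Inf),
      -Inf)
    mx <- max(lp_s)
    lp <- if (is.finite(mx)) mx + log(sum(exp(lp_s - mx))) else -Inf
    log_terms[j + 1L] <- lchoose(k, j) + lp
  }
  mx <- max(log_terms)
  p <- sum(signs * exp(log_terms - mx)) * exp(mx)
  min(max(p, 0), 1)
}

#' Minimum reads for confident multilocus genotyping
#'
#' Smallest read count `n` such that [coverage_confidence()] reaches the
#' requested confidence. Confidence is nondecreasing in `n`, so an upward scan
#' terminates at the exact minimum.
#'
#' @param m Number of loci.
#' @param r Minimum copies per allele (default 2).
#' @param f Confidence level in (0, 1) (default 0.95).
#' @return Integer minimum read count.
#' @examples
#' min_reads(1) # 9
#' min_reads(4) # 55
#' @export
min_reads <- function(m, r = 2, f = 0.95) {
  stopifnot(m >= 1, r >= 1, f > 0, f < 1)
  n <- 2L * as.integer(m) * as.integer(r)
  while (coverage_confidence_one(n, m, r) < f) n <- n + 1L
  n
}

#' Linear extrapolation of the minimum-read curve
#'
#' The exact model is evaluated for small locus numbers; beyond the anchor the
#' required depth grows almost exactly linearly, so the last per-locus
#' increment (between `anchor - 1` and `anchor` loci) is extended to higher
#' locus counts.
#'
#' @param m_target Locus count to extrapolate to (> anchor).
#' @param r,f As in [min_reads()].
#' @param anchor Largest locus count evaluated exactly (default 4).
#' @return Integer extrapolated read requirement.
#' @examples
#' extrapolate_min_reads(10) # 151
#' extrapolate_min_reads(13) # 199
#' @export
extrapolate_min_reads <- function(m_target, r = 2, f = 0.95, anchor = 4) {
  stopifnot(m_target >= anchor)
  n_anchor <- min_reads(anchor, r, f)
  inc <- n_anchor - min_reads(anchor - 1, r, f)
  as.integer(n_anchor + (m_target - anchor) * inc)
}

#' Coverage model object
#'
#' Bundles the equiprobable-multinomial depth model for a range of locus
#' numbers: the exact minimum reads for `1..anchor` loci and the linear
#' extrapolation beyond.
#'
#' @param m_max Largest locus count tabulated.
#' @param r Minimum copies per allele.
#' @param f Confidence level.
#' @param anchor Largest locus count computed exactly.
#' @return A `coverage_model` object; `tidy()` gives the m-to-n table.
#' @examples
#' cm <- coverage_model(m_max = 13)
#' tidy(cm)
#' @export
coverage_model <- function(m_max = 13, r = 2, f = 0.95, anchor = 4) {
  stopifnot(m_max >= 1)
  anchor <- min(anchor, m_max)
  m <- seq_len(m_max)
  n <- integer(m_max)
  for (i in seq_len(anchor)) n[i] <- min_reads(i, r, f)
  exact <- m <= anchor
  if (m_max > anchor) {
    for (i in (anchor + 1L):m_max) n[i] <- extrapolate_min_reads(i, r, f, anchor)
  }
  structure(
    list(table = tibble::tibble(m = m, n = n, exact = exact),
         r = r, f = f, anchor = anchor),
    class = "coverage_model"
  )
}

#' @export
print.coverage_model <- function(x, ...) {
  cat(sprintf(
    "Equiprobable-multinomial coverage model (r = %d, f = %.3g)\n", x$r, x$f))
  cat(sprintf("Exact up to m = %d loci, linear extrapolation beyond.\n",
              x$anchor))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' @rdname coverage_model
#' @param x A `coverage_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.coverage_model <- function(x, ...) x$table

#' @rdname coverage_model
#' @exportS3Method generics::glance
glance.coverage_model <- function(x, ...) {
  tibble::tibble(r = x$r, f = x$f, anchor = x$anchor,
                 m_max = max(x$table$m), n_max = max(x$table$n))
}
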