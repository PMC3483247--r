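# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use direct enumeration (substring concatenation, pathway recursion,
# all-pairs loops) rather than the package's algorithms.

jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

# Build a tagged read from its parts on the forward strand.
make_read <- function(mid_f, primer_f, insert, primer_r, mid_r) {
  paste0(mid_f, primer_f, insert, revcomp(primer_r), revcomp(mid_r))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# --- chimera oracle: try every ordered parent pair and breakpoint ----------
chimera_brute <- function(v, parents) {
  parents <- setdiff(unique(parents), v)
  for (a in parents) {
    for (b in parents) {
      if (a == b) next
      if (nchar(b) != nchar(v)) next
      for (k in seq_len(nchar(b) - 1L)) {
        if (k > nchar(a)) break
        if (paste0(substr(a, 1, k), substr(b, k + 1, nchar(b))) == v) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

single_bp_brute <- function(v, u) {
  nchar(v) == nchar(u) &&
    sum(strsplit(v, "")[[1]] != strsplit(u, "")[[1]]) == 1L
}

explainable_brute <- function(v, sc) {
  cv <- sc$count[sc$sequence == v]
  if (length(cv) == 0L) cv <- 0L
  parents <- sc$sequence[sc$count > cv]
  any(vapply(parents, single_bp_brute, logical(1), v = v)) ||
    chimera_brute(v, parents)
}

# --- whole-procedure oracle on a tiny variant table ------------------------
# Straight-line re-derivation of the five steps with nested loops.
validation_brute <- function(table, cfg) {
  tb <- table[nchar(table$sequence) %in% cfg$expected_sizes, ]
  tot <- tapply(tb$count, tb$sequence, sum)
  tb <- tb[tot[tb$sequence] >= cfg$min_global_copies, ]
  stot <- tapply(tb$count, tb$sample, sum)
  tb <- tb[stot[tb$sample] >= cfg$min_reads_per_individual, ]
  if (nrow(tb) == 0L) {
    return(tibble::tibble(sample = character(0), sequence = character(0),
                          copies = integer(0)))
  }
  tb$freq <- tb$count / tapply(tb$count, tb$sample, sum)[tb$sample]
  mp <- tapply(tb$freq, tb$sequence, max)
  drop <- character(0)
  for (v in names(mp)) {
    if (mp[[v]] < cfg$mpaf_reject) {
      drop <- c(drop, v)
    } else if (mp[[v]] <= cfg$mpaf_review) {
      car <- tb[tb$sequence == v, ]
      car <- car[order(-car$freq, car$sample), ]
      top <- head(car$sample, cfg$top_k_individuals)
      if (all(vapply(top, function(s) {
        explainable_brute(v, tb[tb$sample == s, c("sequence", "count")])
      }, logical(1)))) {
        drop <- c(drop, v)
      }
    }
  }
  tb <- tb[!tb$sequence %in% drop, ]
  keep <- logical(nrow(tb))
  for (i in seq_len(nrow(tb))) {
    sc <- tb[tb$sample == tb$sample[i], c("sequence", "count")]
    cv <- tb$count[i]
    keep[i] <- cv >= cfg$per_individual_keep ||
      (cv >= 2L && !explainable_brute(tb$sequence[i], sc))
  }
  out <- tb[keep, c("sample", "sequence", "count")]
  names(out)[3] <- "copies"
  tibble::as_tibble(out[order(out$sample, out$sequence), ])
}

# Random small variant table with planted 1-bp mutants and chimeras so the
# explainability branches are exercised.
random_small_table <- function(seq_len_ = 8L, n_samples = NULL) {
  truth <- random_dna(3, seq_len_)
  mut <- truth[1]
  p <- sample(seq_len_, 1)
  substr(mut, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(mut, p, p)), 1)
  k <- sample(seq_len_ - 1L, 1)
  chim <- paste0(substr(truth[1], 1, k),
                 substr(truth[2], k + 1, seq_len_))
  pool <- unique(c(truth, mut, chim, random_dna(3, seq_len_)))
  if (is.null(n_samples)) n_samples <- sample(1:4, 1)
  samples <- paste0("s", seq_len(n_samples))
  rows <- list()
  for (s in samples) {
    vs <- sample(pool, sample(2:min(8, length(pool)), 1))
    rows[[s]] <- tibble::tibble(
      sequence = vs, sample = s,
      count = sample(c(1:6, 10, 30, 80), length(vs), replace = TRUE))
  }
  dplyr::bind_rows(rows)
}

# --- NG86 pathway-enumeration oracle ---------------------------------------
ng86_oracle_pair <- function(sa, sb) {
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  site_count <- function(cod) {
    syn <- 0
    for (p in 1:3) {
      s_p <- 0; t_p <- 0
      for (b in c("A", "C", "G", "T")) {
        if (b == substr(cod, p, p)) next
        alt <- cod
        substr(alt, p, p) <- b
        if (gc_tab[[alt]] == "*") next
        t_p <- t_p + 1
        if (gc_tab[[alt]] == gc_tab[[cod]]) s_p <- s_p + 1
      }
      if (t_p > 0) syn <- syn + s_p / t_p
    }
    syn
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(r) c(v[i], r))
    }))
  }
  diff_count <- function(ca, cb) {
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    walk <- function(order, block_stop) {
      cur <- ca; sy <- 0; ns <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (block_stop && gc_tab[[nxt]] == "*") return(NULL)
        if (gc_tab[[cur]] == gc_tab[[nxt]]) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      c(sy, ns)
    }
    res <- Filter(Negate(is.null), lapply(perms(pos), walk, block_stop = TRUE))
    if (!length(res)) res <- lapply(perms(pos), walk, block_stop = FALSE)
    Reduce(`+`, res) / length(res)
  }
  ca <- codons(sa); cb <- codons(sb)
  S <- sum((vapply(ca, site_count, 0) + vapply(cb, site_count, 0)) / 2)
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca),
                      function(i) diff_count(ca[i], cb[i]), numeric(2)))
  ps <- d[1] / S; pn <- d[2] / N
  c(dS = -0.75 * log(1 - 4 * ps / 3), dN = -0.75 * log(1 - 4 * pn / 3))
}

# Random codon-aligned sense-codon sequences (no stops in frame 0).
random_coding <- function(n, n_codons, mut = 0.06, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  anc <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  vapply(seq_len(n), function(i) {
    repeat {
      s <- strsplit(anc, "")[[1]]
      hit <- runif(length(s)) < mut
      s[hit] <- vapply(s[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      s <- paste(s, collapse = "")
      if (mhctyper::translate_alleles(s)$stop_count == 0) return(s)
    }
  }, character(1))
}
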