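#' Encode binding-site residues as physicochemical descriptors
#'
#' Extracts the residues at the positively-selected-site (PSS) positions of
#' each allele's amino-acid sequence and concatenates their five z-descriptor
#' values, giving one row per allele and `5 * |PSS|` columns. Alleles
#' identical at every PSS encode to identical rows.
#'
#' @param aa Character vector of amino-acid sequences (equal length), named
#'   by allele id.
#' @param pss Integer vector of 1-based residue positions (the PSS mask).
#' @param descriptors Descriptor table, by default [z_descriptors]; any
#'   tibble with columns `aa`, then one column per descriptor, may be
#'   substituted.
#' @return Numeric matrix, rownames = allele ids, `5 * length(pss)` columns
#'   named `<descriptor>_p<position>`.
#' @export
encode_pss <- function(aa, pss, descriptors = z_descriptors) {
  stopifnot(length(aa) >= 1L, all(pss >= 1L))
  if (any(pss > min(nchar(aa)))) {
    stop("PSS positions exceed amino-acid sequence length")
  }
  desc_cols <- setdiff(names(descriptors), "aa")
  res_mat <- do.call(rbind, lapply(aa, function(s) {
    strsplit(s, "", fixed = TRUE)[[1]][pss]
  }))
  unknown <- setdiff(unique(as.vector(res_mat)), descriptors$aa)
  if (length(unknown)) {
    stop("residues without descriptor values: ",
         paste(unknown, collapse = ", "))
  }
  idx <- match(res_mat, descriptors$aa)
  blocks <- lapply(desc_cols, function(cl) {
    matrix(descriptors[[cl]][idx], nrow = length(aa))
  })
  out <- matrix(0, nrow = length(aa), ncol = length(desc_cols) * length(pss))
  for (j in seq_along(pss)) {
    for (d in seq_along(desc_cols)) {
      out[, (j - 1L) * length(desc_cols) + d] <- blocks[[d]][, j]
    }
  }
  colnames(out) <- as.vector(vapply(pss, function(p) {
    paste0(desc_cols, "_p", p)
  }, character(length(desc_cols))))
  rownames(out) <- if (!is.null(names(aa))) names(aa) else
    paste0("allele", seq_along(aa))
  out
}

# Total within-cluster sum of squares of a seeded k-means fit (k = 1 is the
# total sum of squares about the grand mean).
kmeans_wss <- function(x, k, n_starts) {
  if (k == 1L) {
    return(list(wss = sum(scale(x, scale = FALSE)^2),
                cluster = rep(1L, nrow(x))))
  }
  fit <- stats::kmeans(x, centers = k, nstart = n_starts, iter.max = 100L)
  list(wss = fit$tot.withinss, cluster = fit$cluster)
}

#' Choose the number of supertypes by BIC elbow
#'
#' Runs seeded K-means for `k = 1..k_max` and scores each solution with
#' `BIC(k) = n log(WSS_k / n) + k log(n)` (the convention of the
#' find.clusters approach to K-means model selection). The minimal adequate
#' k is the elbow of the BIC curve, automated as the argmax of its second
#' difference; "negligible further decrease" is subjective, so a manual `k`
#' override is available in [supertype_fit()].
#'
#' @param x Descriptor matrix from [encode_pss()].
#' @param k_max Largest cluster count examined (capped at the number of
#'   distinct rows, with a warning if that cap binds).
#' @param n_starts K-means restarts per k.
#' @param seed Integer seed.
#' @return List `k` (chosen), `bic` (tibble `k, wss, bic`), and `labels` for
#'   the chosen k.
#' @export
choose_k <- function(x, k_max = 20, n_starts = 50, seed = 1L) {
  n <- nrow(x)
  n_distinct_rows <- nrow(unique(x))
  if (n_distinct_rows == 1L) {
    return(list(k = 1L,
                bic = tibble::tibble(k = 1L, wss = 0, bic = -Inf),
                labels = rep(1L, n)))
  }
  if (k_max > n_distinct_rows) {
    warning("k_max exceeds the number of distinct rows; capping")
    k_max <- n_distinct_rows
  }
  set.seed(seed)
  fits <- lapply(seq_len(k_max), function(k) kmeans_wss(x, k, n_starts))
  wss <- vapply(fits, `[[`, numeric(1), "wss")
  bic <- n * log(pmax(wss, .Machine$double.eps) / n) +
    seq_len(k_max) * log(n)
  k <- if (k_max >= 3L) {
    d2 <- diff(bic, differences = 2L) # second difference at k = 2..k_max-1
    as.integer(which.max(d2) + 1L)
  } else {
    as.integer(which.min(bic))
  }
  list(k = k,
       bic = tibble::tibble(k = seq_len(k_max), wss = wss, bic = bic),
       labels = fits[[k]]$cluster)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' PCA of the descriptor matrix retaining the fewest components explaining at
#' least `variance_retained` of the variance, followed by linear discriminant
#' analysis on the cluster labels in PC space. Used to visualise supertype
#' separation; with `g` clusters there are `g - 1` discriminant axes.
#'
#' @param x Descriptor matrix.
#' @param labels Integer/factor cluster labels, one per row.
#' @param variance_retained Fraction of variance the retained PCs must reach
#'   (default 0.93).
#' @return List `n_pcs`, `prop_var` (cumulative at `n_pcs`), `coords`
#'   (per-row scores on the discriminant axes, columns `LD1`, `LD2`, ...).
#' @export
dapc_fit <- function(x, labels, variance_retained = 0.93) {
  stopifnot(nrow(x) == length(labels))
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  n_pcs <- which(cum >= variance_retained)[1L]
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  fit <- tryCatch({
    lda_fit <- MASS::lda(scores, grouping = factor(labels))
    list(coords = stats::predict(lda_fit, scores)$x, lda = lda_fit)
  }, error = function(e) {
    # perfectly separated clusters have zero within-group variance on some
    # axis; fall back to a ridge-regularised discriminant computation
    list(coords = ridge_discriminant(scores, labels), lda = NULL)
  })
  list(n_pcs = n_pcs, prop_var = cum[n_pcs], coords = fit$coords,
       lda = fit$lda)
}

# Discriminant axes by generalised eigendecomposition of between- vs
# within-group scatter, with a small ridge so degenerate within-group
# covariance (identical rows within a cluster) stays invertible.
ridge_discriminant <- function(scores, labels) {
  labels <- factor(labels)
  g <- nlevels(labels)
  p <- ncol(scores)
  ctr <- scale(scores, scale = FALSE)
  mu <- rowsum(ctr, labels) / as.vector(table(labels))
  B <- crossprod(mu * sqrt(as.vector(table(labels))))
  W <- crossprod(ctr - mu[labels, , drop = FALSE])
  eps <- 1e-8 * max(sum(diag(W)), sum(diag(B))) / p
  ev <- eigen(solve(W + diag(eps, p), B))
  axes <- Re(ev$vectors[, seq_len(min(g - 1L, p)), drop = FALSE])
  coords <- ctr %*% axes
  colnames(coords) <- paste0("LD", seq_len(ncol(coords)))
  rownames(coords) <- rownames(scores)
  coords
}

#' Fit a supertype model
#'
#' Full supertyping of functional alleles: z-descriptor encoding of PSS
#' residues, BIC-based choice of the cluster count (or a manual `k`), and
#' DAPC coordinates for visualisation.
#'
#' @param alleles Tibble with `allele_id` and `aa` columns (functional
#'   alleles only; exclude pseudogene/stop-bearing alleles upstream).
#' @param pss Integer PSS positions (1-based residues).
#' @param k Manual cluster count; `NULL` (default) uses the BIC elbow.
#' @param k_max,n_starts,seed As in [choose_k()].
#' @param variance_retained As in [dapc_fit()].
#' @param descriptors As in [encode_pss()].
#' @return A `supertype_model`: `k`, `labels` (tibble `allele_id,
#'   supertype`), `bic`, `n_pcs`, `coords`. `tidy()` returns per-allele
#'   labels with DAPC coordinates; `glance()` the model summary.
#' @export
supertype_fit <- function(alleles, pss, k = NULL, k_max = 20, n_starts = 50,
                          seed = 1L, variance_retained = 0.93,
                          descriptors = z_descriptors) {
  stopifnot(all(c("allele_id", "aa") %in% names(alleles)))
  x <- encode_pss(stats::setNames(alleles$aa, alleles$allele_id), pss,
                  descriptors)
  ck <- choose_k(x, k_max = k_max, n_starts = n_starts, seed = seed)
  labels <- ck$labels
  if (!is.null(k)) {
    k <- as.integer(k)
    set.seed(seed)
    labels <- kmeans_wss(x, k, n_starts)$cluster
  } else {
    k <- ck$k
  }
  dapc <- if (k >= 2L) dapc_fit(x, labels, variance_retained) else
    list(n_pcs = NA_integer_, prop_var = NA_real_, coords = NULL)
  structure(list(
    k = k,
    labels = tibble::tibble(allele_id = rownames(x),
                            supertype = as.integer(labels)),
    bic = ck$bic,
    n_pcs = dapc$n_pcs, prop_var = dapc$prop_var, coords = dapc$coords,
    pss = pss, seed = seed
  ), class = "supertype_model")
}

#' @export
print.supertype_model <- function(x, ...) {
  cat(sprintf(
    "Supertype model: %d supertypes over %d alleles (%d PSS, %s PCs retained)\n",
    x$k, nrow(x$labels), length(x$pss),
    ifelse(is.na(x$n_pcs), "no", x$n_pcs)))
  invisible(x)
}

#' @rdname supertype_fit
#' @param x A `supertype_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.supertype_model <- function(x, ...) {
  out <- x$labels
  if (!is.null(x$coords)) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(x$coords))
  }
  out
}

#' @rdname supertype_fit
#' @exportS3Method generics::glance
glance.supertype_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_alleles = nrow(x$labels),
                 n_pss = length(x$pss), n_pcs = x$n_pcs,
                 prop_var = x$prop_var,
                 bic_at_k = x$bic$bic[match(x$k, x$bic$k)])
}

#' Collapse allele genotypes to supertype genotypes
#'
#' Maps each individual's validated allele set through the supertype labels
#' and de-duplicates: two alleles of the same supertype contribute one
#' supertype. Alleles without a label (non-functional, excluded upstream)
#' are dropped.
#'
#' @param genotypes Tibble with `sample` and `allele_id`.
#' @param labels Tibble `(allele_id, supertype)` (e.g. from
#'   `tidy(supertype_fit(...))`).
#' @return Tibble `(sample, supertype)`, one row per present supertype.
#' @export
supertype_genotypes <- function(genotypes, labels) {
  genotypes |>
    dplyr::inner_join(labels[c("allele_id", "supertype")], by = "allele_id") |>
    dplyr::distinct(.data$sample, .data$supertype) |>
    dplyr::arrange(.data$sample, .data$supertype)
}
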