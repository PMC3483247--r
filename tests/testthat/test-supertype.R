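test_that("descriptor encoding has 5 columns per binding-site residue", {
  aa <- c(a1 = "ARNDCQ", a2 = "ARNDCW", a3 = "GRNDCQ")
  x <- encode_pss(aa, pss = c(1L, 3L))
  expect_identical(dim(x), c(3L, 10L))
  expect_identical(rownames(x), c("a1", "a2", "a3"))
  # alleles identical at all PSS encode identically
  expect_identical(x["a1", ], x["a2", ])
  expect_false(identical(x["a1", ], x["a3", ]))
  # values come from the descriptor table
  expect_equal(unname(x["a1", 1:5]),
               unlist(z_descriptors[z_descriptors$aa == "A", -1],
                      use.names = FALSE))
  expect_error(encode_pss(c("AX"), 1:2), "descriptor")
  expect_error(encode_pss(aa, 7L), "exceed")
})

make_blobs <- function(c_true, n = 60, p = 45, sep = 6, noise = 0.5,
                       seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(c_true * p, sd = sep), c_true, p)
  lab <- rep_len(seq_len(c_true), n)
  list(x = centers[lab, ] + matrix(rnorm(n * p, sd = noise), n, p),
       labels = lab)
}

test_that("BIC elbow recovers well-separated cluster counts", {
  b <- make_blobs(3, seed = 2)
  ck <- choose_k(b$x, k_max = 8, n_starts = 20, seed = 7)
  expect_identical(ck$k, 3L)
  expect_identical(nrow(ck$bic), 8L)
  # WSS nonincreasing in k
  expect_true(all(diff(ck$bic$wss) <= 1e-6))
})

test_that("degenerate matrices collapse to one cluster", {
  x <- matrix(1, nrow = 10, ncol = 45)
  ck <- choose_k(x, k_max = 5)
  expect_identical(ck$k, 1L)
  expect_identical(unique(ck$labels), 1L)
})

test_that("k_max below the true cluster count is capped with a warning", {
  x <- rbind(matrix(0, 3, 4), matrix(10, 3, 4))
  expect_warning(ck <- choose_k(x, k_max = 10, n_starts = 5, seed = 1),
                 "capping")
  expect_lte(ck$k, nrow(unique(x)))
})

test_that("k-means with fixed seed and restarts is deterministic", {
  b <- make_blobs(4, seed = 5)
  k1 <- choose_k(b$x, k_max = 6, n_starts = 10, seed = 3)
  k2 <- choose_k(b$x, k_max = 6, n_starts = 10, seed = 3)
  expect_identical(k1$k, k2$k)
  expect_identical(k1$labels, k2$labels)
  expect_equal(k1$bic, k2$bic)
})

test_that("DAPC retains the fewest PCs reaching the variance target", {
  b <- make_blobs(3, n = 50, seed = 6)
  fit <- dapc_fit(b$x, b$labels, variance_retained = 0.93)
  pca <- prcomp(b$x)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  expect_identical(fit$n_pcs, which(cum >= 0.93)[1])
  expect_gte(fit$prop_var, 0.93)
  # g clusters give g - 1 discriminant axes
  expect_identical(ncol(fit$coords), 2L)
  two <- dapc_fit(b$x, rep(1:2, length.out = 50))
  expect_identical(ncol(two$coords), 1L)
})

test_that("orthogonal rotation leaves cluster separation unchanged", {
  b <- make_blobs(3, n = 45, p = 20, seed = 8)
  q <- qr.Q(qr(matrix(rnorm(400), 20, 20))) # random orthogonal matrix
  xr <- b$x %*% q
  k1 <- choose_k(b$x, k_max = 6, n_starts = 20, seed = 4)
  k2 <- choose_k(xr, k_max = 6, n_starts = 20, seed = 4)
  expect_identical(k1$k, k2$k)
  expect_equal(k1$bic$wss, k2$bic$wss, tolerance = 1e-6)
})

test_that("supertype genotypes collapse allele sets through the labels", {
  labels <- tibble::tibble(allele_id = c("a", "b", "c", "d"),
                           supertype = c(1L, 1L, 2L, 3L))
  g <- tibble::tibble(sample = c("i1", "i1", "i1", "i2", "i3"),
                      allele_id = c("a", "b", "c", "d", "zz"))
  st <- supertype_genotypes(g, labels)
  expect_identical(st$supertype[st$sample == "i1"], c(1L, 2L))
  expect_identical(st$supertype[st$sample == "i2"], 3L)
  # unlabelled alleles drop out entirely
  expect_false("i3" %in% st$sample)
  # per-individual supertype count never exceeds allele count
  cnt <- table(st$sample)
  expect_true(all(cnt <= table(g$sample)[names(cnt)]))
})

test_that("full supertype fit labels every allele and is reproducible", {
  set.seed(44)
  # alleles drawn from 3 archetypal binding motifs plus point changes
  arch <- c("ARNDCQEGH", "LKMFPSTWY", "VARLKCQEG")
  aa <- vapply(1:36, function(i) {
    s <- arch[((i - 1) %% 3) + 1]
    p <- sample(9, 1)
    substr(s, p, p) <- sample(setdiff(z_descriptors$aa,
                                      substr(s, p, p)), 1)
    s
  }, character(1))
  al <- tibble::tibble(allele_id = sprintf("al%02d", 1:36), aa = aa)
  fit <- supertype_fit(al, pss = 1:9, k_max = 8, n_starts = 20, seed = 2)
  expect_identical(fit$k, 3L)
  expect_identical(sort(unique(tidy(fit)$supertype)), 1:3)
  fit2 <- supertype_fit(al, pss = 1:9, k_max = 8, n_starts = 20, seed = 2)
  expect_identical(tidy(fit)$supertype, tidy(fit2)$supertype)
  # manual override
  fit4 <- supertype_fit(al, pss = 1:9, k = 4, n_starts = 20, seed = 2)
  expect_identical(fit4$k, 4L)
  expect_identical(glance(fit4)$n_pss, 9L)
})
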