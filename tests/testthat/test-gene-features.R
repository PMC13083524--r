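test_that("significance filter keeps sets with padj strictly below alpha", {
  sets <- list(gene_set_definition("a", "g1", padj = 0.005),
               gene_set_definition("b", "g2", padj = 0.01),
               gene_set_definition("c", "g3", padj = 0.02))
  kept <- select_significant(sets, 0.01)
  expect_equal(vapply(kept, function(s) s$set_id, character(1)), "a")
  expect_length(select_significant(lapply(1:3, function(i)
    gene_set_definition(paste0("s", i), paste0("g", i), padj = 0.5))), 0L)
  expect_length(select_significant(sets, alpha = 1.0), 3L)
})

test_that("TPM columns sum to one million and match hand computation", {
  # single gene: normalization forces TPM = 1e6
  one <- matrix(7L, 1, 1, dimnames = list("g1", "P1"))
  expect_equal(tpm_log(one, c(g1 = 500L))[1, 1], log2(1e6 + 1),
               tolerance = 1e-12)

  # two genes, counts (10, 10), lengths (1000, 2000) bp:
  # rates (10, 5) -> TPM (2/3, 1/3) * 1e6
  two <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("g1", "g2"), "P1"))
  out <- tpm_log(two, c(g1 = 1000L, g2 = 2000L))
  expect_equal(as.numeric(out),
               log2(c(2 / 3, 1 / 3) * 1e6 + 1), tolerance = 1e-12)

  set.seed(8)
  cts <- matrix(rpois(60, 40), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("P", 1:6)))
  lens <- stats::setNames(sample(500:3000, 10), paste0("g", 1:10))
  tpm <- 2^tpm_log(cts, lens) - 1
  expect_equal(colSums(tpm), rep(1e6, 6), tolerance = 1e-6,
               ignore_attr = TRUE)

  cts[, 2] <- 0L
  expect_warning(z <- tpm_log(cts, lens), "all-zero")
  expect_equal(unname(z[, 2]), rep(0, 10))
})

test_that("gene-set tensors are zero-padded with exact masks", {
  sets <- list(gene_set_definition("s1", c("g1", "g2", "g3"), padj = 0),
               gene_set_definition("s2", paste0("g", 1:5), padj = 0))
  expr <- stats::setNames(c(1.5, 0.5, 2, 3, 4), paste0("g", 1:5))
  tn <- build_geneset_tensor(expr, sets, "P1")
  expect_equal(dim(tn$values), c(2L, 5L))
  expect_equal(rowSums(tn$mask), c(s1 = 3, s2 = 5))
  expect_equal(unname(tn$values[1, ]), c(1.5, 0.5, 2, 0, 0))
  expect_equal(unname(tn$mask[1, ]), c(1, 1, 1, 0, 0))
  expect_true(all(tn$values[tn$mask == 0] == 0))

  single <- build_geneset_tensor(expr, sets[2], "P1")
  expect_equal(unname(single$mask[1, ]), rep(1, 5))

  expect_error(
    build_geneset_tensor(expr[1:2],
                         list(gene_set_definition("sx", c("g1", "gZ"),
                                                  padj = 0))),
    "gZ.*sx")
})

test_that("masked MSE ignores padded positions exactly", {
  x <- matrix(c(1, 2, 7), 1)
  xh <- matrix(0, 1, 3)
  m <- matrix(c(1, 1, 0), 1)
  expect_equal(masked_mse(x, x, m), 0)
  expect_equal(masked_mse(x, xh, m), 2.5)
  x2 <- x; x2[1, 3] <- 1e6
  expect_identical(masked_mse(x, xh, m), masked_mse(x2, xh, m))
  expect_error(masked_mse(x, xh, matrix(0, 1, 3)), "mask")
})

test_that("autoencoder training is seeded, decreasing, and padding-invariant", {
  set.seed(10)
  sets <- lapply(1:4, function(i) {
    gene_set_definition(sprintf("s%d", i),
                        paste0("g", sample(1:40, sample(4:8, 1))), padj = 0)
  })
  tensors <- lapply(1:50, function(j) {
    expr <- stats::setNames(rnorm(40, mean = 5), paste0("g", 1:40))
    build_geneset_tensor(expr, sets, sprintf("P%02d", j))
  })
  ae1 <- train_autoencoder(tensors, latent_dim = 3L, hidden = 16L,
                           epochs = 50L, seed = 5L)
  ae2 <- train_autoencoder(tensors, latent_dim = 3L, hidden = 16L,
                           epochs = 50L, seed = 5L)
  expect_identical(ae1$loss_trace, ae2$loss_trace)
  expect_lt(ae1$loss_trace[50], ae1$loss_trace[1])

  # perturbing only padded entries leaves the whole trajectory unchanged
  tensors_p <- lapply(tensors, function(tn) {
    tn$values[tn$mask == 0] <- 99
    tn
  })
  ae3 <- train_autoencoder(tensors_p, latent_dim = 3L, hidden = 16L,
                           epochs = 50L, seed = 5L)
  expect_identical(ae1$loss_trace, ae3$loss_trace)
  expect_identical(ae1$layers$enc1$W$value, ae3$layers$enc1$W$value)

  expect_warning(train_autoencoder(tensors[1:2], latent_dim = 20L,
                                   hidden = 8L, epochs = 1L),
                 "no compression")

  lat <- encode_genesets(ae1, tensors[[1]])
  expect_equal(dim(lat$features), c(4L, 3L))
  # row-wise map: permuting set rows permutes latents identically
  tp <- tensors[[1]]
  perm <- c(3L, 1L, 4L, 2L)
  tp$values <- tp$values[perm, ]
  tp$mask <- tp$mask[perm, ]
  expect_equal(encode_genesets(ae1, tp)$features,
               lat$features[perm, ], tolerance = 1e-12)

  bad <- tensors[[1]]
  bad$values <- bad$values[, 1:3]
  bad$mask <- bad$mask[, 1:3]
  expect_error(encode_genesets(ae1, bad), "width")
})
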