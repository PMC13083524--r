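test_that("Mann-Whitney U matches exact enumeration on fully separated groups", {
  r <- mwu(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)           # no A-over-B pairs
  expect_equal(r$p, 0.1)         # 2 / choose(6, 3) extreme assignments

  same <- mwu(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p, 0.99)

  a <- c(0.1, 0.5, 0.9, 0.3); b <- c(0.2, 0.8, 0.4)
  expect_equal(mwu(a, b)$p, mwu(b, a)$p)
  expect_error(mwu(numeric(0), b), "non-empty")
})

test_that("normal approximation stays within 0.02 of the exact MWU p-value", {
  set.seed(31)
  for (i in 1:10) {
    na_ <- sample(8:12, 1); nb <- sample(8:12, 1)
    a <- rnorm(na_); b <- rnorm(nb, mean = runif(1, -1, 1))
    approx_p <- mwu(a, b)$p  # n >= 8 triggers the normal approximation
    exact_p <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(fdr_bh(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(fdr_bh(0.04), 0.04)
  expect_equal(fdr_bh(rep(0.3, 4)), rep(0.3, 4))

  set.seed(2)
  p <- sort(runif(20))
  adj <- fdr_bh(p)
  expect_true(all(diff(adj) >= -1e-12))  # monotone on sorted input
  expect_true(all(adj >= p))
})

test_that("permutation check is seeded and calibrated", {
  n <- 20L
  w <- cbind(c(rep(0.9, n), rep(0.1, n)), c(rep(0.1, n), rep(0.9, n)))
  dimnames(w) <- list(sprintf("P%03d", 1:(2 * n)), c("SET001", "SET002"))
  lab <- stats::setNames(rep(c(1L, 0L), each = n), rownames(w))
  tab <- attention_table(w, lab)
  p1 <- permutation_check(tab, "SET001", n_perm = 999L, seed = 5L)
  expect_equal(p1, 1 / 1000)
  expect_identical(p1, permutation_check(tab, "SET001", n_perm = 999L,
                                         seed = 5L))

  # constant column: every permuted statistic equals the observed one
  wc <- cbind(rep(0.5, 8), rep(0.5, 8))
  dimnames(wc) <- list(sprintf("Q%02d", 1:8), c("SET001", "SET002"))
  tc <- attention_table(wc, stats::setNames(rep(c(0L, 1L), 4), rownames(wc)))
  expect_equal(permutation_check(tc, "SET001", n_perm = 199L, seed = 1L), 1)

  # reduced exhaustive case: 4 + 4 patients, exact exceedance mass is 2/70
  w4 <- cbind(c(rep(0.8, 4), rep(0.2, 4)), c(rep(0.2, 4), rep(0.8, 4)))
  dimnames(w4) <- list(sprintf("R%02d", 1:8), c("SET001", "SET002"))
  t4 <- attention_table(w4, stats::setNames(rep(c(1L, 0L), each = 4),
                                            rownames(w4)))
  p4 <- permutation_check(t4, "SET001", n_perm = 4999L, seed = 3L)
  expect_equal(p4, 2 / 70, tolerance = 0.3)

  expect_warning(permutation_check(t4, "SET001", n_perm = 50L), "unreliable")
})

test_that("the significance pipeline flags shifted sets and controls type I error", {
  tab <- make_attention_table(n_per_class = 40L, n_sets = 10L,
                              shifted_sets = c(2L, 5L, 9L), effect = 3,
                              seed = 17L)
  res <- significance_analysis(tab, alpha = 0.01, n_perm = 199L, seed = 1L)
  expect_equal(sort(res$set_id[res$significant]),
               sprintf("SET%03d", c(2L, 5L, 9L)))
  expect_true(all(res$p_fdr >= res$p_raw - 1e-15))
  expect_true(all(res$perm_p[res$significant] < 0.05))
  expect_true(all(is.na(res$perm_p[!res$significant])))

  # no-signal cohort: nothing should pass the FDR threshold
  null_tab <- make_attention_table(40L, 10L, integer(0), effect = 0,
                                   seed = 23L)
  null_res <- significance_analysis(null_tab, alpha = 0.01, n_perm = 0L)
  expect_lte(mean(null_res$significant), 0.02)
})

test_that("attention collection yields normalized per-patient rows", {
  st <- micro_stack(seed = 29L)
  ids <- names(st$bags)[1:4]
  tab <- collect_attention(st$model, st$backbone, st$bags, st$genes$latents,
                           st$cohort$labels, patient_ids = ids,
                           mechanism = "self_gene")
  expect_equal(dim(tab$weights), c(4L, length(st$genes$sets_used)))
  expect_equal(unname(rowSums(tab$weights)), rep(1, 4), tolerance = 1e-9)

  # pure function: duplicating a patient duplicates its row
  tab2 <- collect_attention(st$model, st$backbone, st$bags,
                            st$genes$latents, st$cohort$labels,
                            patient_ids = c(ids[1], ids),
                            mechanism = "cross_gene_query_img")
  expect_equal(unname(tab2$weights[1, ]), unname(tab2$weights[2, ]))

  untr <- collect_attention(st$model, st$backbone, st$bags,
                            st$genes$latents, st$cohort$labels,
                            patient_ids = ids, trained = FALSE)
  expect_true("untrained_model" %in% untr$warning_flags)
})

test_that("heatmaps place scaled weights at patch origins", {
  ps <- list(fake_patch(1, 0, 0), fake_patch(1, 0, 1),
             fake_patch(1, 1, 0), fake_patch(1, 1, 1))
  bag <- structure(list(patient_id = "A", label = 0L, patches = ps,
                        budget = 4L), class = "patch_bag")
  rec <- attention_record("self_image", c(0.1, 0.4, 0.2, 0.3), 2L)
  hm <- render_heatmap(bag, rec, c(8L, 8L))
  expect_equal(hm$top_patch, c(0L, 1L))
  sw <- (c(0.1, 0.4, 0.2, 0.3) - 0.1) / 0.3
  expect_equal(hm$heatmap[1, 1], sw[1])
  expect_equal(hm$heatmap[1, 5], sw[2])
  expect_equal(hm$heatmap[5, 1], sw[3])
  expect_equal(hm$heatmap[5, 5], sw[4])

  unif <- render_heatmap(bag, attention_record("self_image", rep(0.25, 4), 2L),
                         c(8L, 8L))
  expect_true(all(unif$heatmap == 1))

  onehot <- render_heatmap(bag,
                           attention_record("self_image", c(0, 0, 1, 0), 2L),
                           c(8L, 8L))
  expect_equal(onehot$top_patch, c(1L, 0L))
  expect_equal(sum(onehot$heatmap > 0), 16L)  # a single 4x4 cell

  expect_error(render_heatmap(bag, attention_record("self_image",
                                                    c(0.5, 0.5), 2L),
                              c(8L, 8L)),
               "length")
})
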