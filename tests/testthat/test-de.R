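test_that("detection fractions equal a naive per-cluster count oracle", {
  set.seed(51)
  y <- matrix(rpois(40 * 30, 5), 40)
  m <- count_matrix(y)
  sf <- library_size_factors(m)
  e <- log2_cpm(m, sf)
  labels <- rep(c("a", "b", "c"), each = 10)
  fr <- detection_fraction(e, labels, detect_cpm = 5)
  for (g in sample(40, 5)) for (cl in c("a", "b", "c")) {
    hits <- 0
    for (c in which(labels == cl)) if (e$cpm[g, c] >= 5) hits <- hits + 1
    expect_equal(fr[g, cl], hits / 10)
  }
  # boundary: exactly 2 of 10 cells at threshold passes the 20% gate
  cpm_row <- e$cpm[1, labels == "a"]
  e$cpm[1, labels == "a"] <- c(5, 5, rep(0, 8))
  fr2 <- detection_fraction(e, labels)
  expect_equal(fr2[1, "a"], 0.2)
  expect_error(detection_fraction(e, labels[-1]), "labels")
})

test_that("dispersion estimates recover Poisson and NB truth", {
  set.seed(52)
  sim_p <- nb_null_matrix(500, 120, alpha = 0, seed = 52)
  disp_p <- estimate_dispersion(sim_p$m, rep(c("a", "b"), each = 60))
  expect_lte(median(disp_p$alpha), 0.02)

  sim_nb <- nb_null_matrix(500, 200, alpha = 0.2, seed = 53)
  disp_nb <- estimate_dispersion(sim_nb$m, rep(c("a", "b"), each = 100))
  expect_gte(median(disp_nb$alpha), 0.1)
  expect_lte(median(disp_nb$alpha), 0.3)
})

test_that("uninformative genes fall back to the dispersion trend", {
  set.seed(54)
  y <- matrix(rpois(50 * 20, 10), 50)
  y[9, ] <- 0L
  m <- count_matrix(y)
  disp <- estimate_dispersion(m, rep(c("a", "b"), each = 10))
  expect_true(is.na(disp$raw[9]))
  expect_equal(disp$alpha[9], disp$trend[9])
  expect_error(estimate_dispersion(m, c(rep("a", 18), "b", "b")),
               ">= 2 groups")
})

test_that("identical groups give unit fold change and null p-values", {
  set.seed(55)
  y0 <- matrix(rpois(100 * 15, 8), 100)
  y <- cbind(y0, y0)                    # the same cells duplicated
  m <- count_matrix(y)
  labels <- rep(c("A", "B"), each = 15)
  tab <- nb_contrast(m, library_size_factors(m), labels, "A", "B")
  expect_equal(tab$fold_change, rep(1, 100))
  expect_true(all(tab$p > 0.99))
  expect_equal(sum(tab$significant), 0)
})

test_that("swapping the contrast inverts fold change and preserves p", {
  set.seed(56)
  sim <- nb_null_matrix(150, 40, alpha = 0.1, seed = 56)
  labels <- rep(c("A", "B"), each = 20)
  sf <- library_size_factors(sim$m)
  disp <- estimate_dispersion(sim$m, labels)
  ab <- nb_contrast(sim$m, sf, labels, "A", "B", disp = disp)
  ba <- nb_contrast(sim$m, sf, labels, "B", "A", disp = disp)
  expect_equal(ab$fold_change * ba$fold_change, rep(1, 150),
               tolerance = 1e-9)
  expect_equal(ab$p, ba$p, tolerance = 1e-8)
})

test_that("within-contrast FDR equals the brute-force BH oracle", {
  set.seed(57)
  sim <- nb_null_matrix(800, 60, alpha = 0.1, seed = 57)
  labels <- rep(c("A", "B"), each = 30)
  tab <- nb_contrast(sim$m, library_size_factors(sim$m), labels, "A", "B")
  expect_equal(tab$fdr, p.adjust(tab$p, "BH"))
  expect_identical(unname(tab$fdr <= 0.05), unname(bh_oracle(tab$p, 0.05)))
})

test_that("the test is calibrated under the null", {
  set.seed(58)
  rates <- replicate(20, {
    sim <- nb_null_matrix(300, 60, alpha = 0.1,
                          seed = sample.int(1e6, 1))
    labels <- rep(c("A", "B"), each = 30)
    tab <- nb_contrast(sim$m, library_size_factors(sim$m), labels, "A", "B")
    c(mean(tab$p < 0.05), mean(tab$significant))
  })
  expect_lt(abs(mean(rates[1, ]) - 0.05), 0.02)
  # FDR-gated calls under the global null stay below the nominal rate
  expect_lte(mean(rates[2, ]), 0.05)
})

test_that("planted eightfold markers are recovered at the standard gates", {
  set.seed(59)
  n_genes <- 500; npg <- 30
  rate <- rlnorm(n_genes, 0, 1); rate <- rate / sum(rate)
  rate_b <- rate; markers <- 1:40
  rate_b[markers] <- rate_b[markers] * 8
  L <- rlnorm(2 * npg, log(3e4), 0.3)
  mu <- cbind(outer(rate, L[1:npg]), outer(rate_b, L[npg + 1:npg]))
  y <- matrix(rnbinom(length(mu), size = 10, mu = mu), n_genes)
  m <- count_matrix(y)
  labels <- rep(c("A", "B"), each = npg)
  tab <- nb_contrast(m, library_size_factors(m), labels, "B", "A")
  expect_gte(mean(tab$significant[markers]), 0.9)
})

test_that("p-value ranking agrees with the edgeR exact test on a small design", {
  set.seed(60)
  n_genes <- 300; npg <- 25
  rate <- rlnorm(n_genes, 0, 1); rate <- rate / sum(rate)
  rate_b <- rate; rate_b[1:25] <- rate_b[1:25] * 6
  mu <- cbind(outer(rate, rep(2e4, npg)), outer(rate_b, rep(2e4, npg)))
  y <- matrix(rnbinom(length(mu), size = 10, mu = mu), n_genes)
  m <- count_matrix(y)
  labels <- rep(c("A", "B"), each = npg)
  tab <- nb_contrast(m, library_size_factors(m), labels, "B", "A")
  dge <- edgeR::DGEList(counts = y, group = labels)
  dge <- edgeR::calcNormFactors(dge)
  dge <- edgeR::estimateDisp(dge)
  et <- edgeR::exactTest(dge)$table
  expect_gte(cor(rank(tab$p), rank(et$PValue), method = "spearman"), 0.8)
  expect_gte(cor(-log10(tab$p + 1e-300), -log10(et$PValue + 1e-300)), 0.95)
  top_ours <- order(tab$p)[1:25]
  top_ref <- order(et$PValue)[1:25]
  expect_gte(length(intersect(top_ours, top_ref)) / 25, 0.8)
})

test_that("zero denominators get the continuity constant and a flag", {
  y <- rbind(c(0L, 0L, 0L, 20L, 25L, 22L),
             c(10L, 12L, 9L, 11L, 10L, 12L))
  m <- count_matrix(y)
  labels <- rep(c("A", "B"), each = 3)
  tab <- nb_contrast(m, library_size_factors(m), labels, "B", "A")
  expect_true(tab$zero_adjusted[1])
  avgB <- tab$avg_cpm_A[1]; avgA <- tab$avg_cpm_B[1]
  expect_equal(tab$fold_change[1], (avgB + 0.5) / (avgA + 0.5))
})

test_that("one-vs-rest with merges sorts by FDR and validates the map", {
  run <- default_run()
  de <- run$de
  expect_true(all(c("Neuron", "Astrocyte", "Oligodendrocyte", "VAC") %in%
                    names(de)))
  for (g in names(de)) expect_false(is.unsorted(de[[g]]$fdr))
  # pan-neuronal planted markers top the combined neuron table
  top <- head(de$Neuron$gene_id[de$Neuron$significant], 30)
  ds <- default_ds()
  pan <- setdiff(ds$marker_map$Neuron, "tdTomato")
  expect_gte(length(intersect(pan, top)), 8)

  labels <- run$clustering$labels
  expect_error(neuron_combined_one_vs_rest(
    subset_counts(ds$counts, cells = run$keep_cells),
    run$size_factors, labels,
    merge_map = c(`1` = "x")), "does not cover")
  expect_error(neuron_combined_one_vs_rest(
    subset_counts(ds$counts, cells = run$keep_cells),
    run$size_factors, labels,
    merge_map = setNames(rep("all", 5), as.character(1:5))), "fewer than 2")
})

test_that("an identity merge map reproduces the plain one-vs-rest contrast", {
  set.seed(61)
  sim <- nb_null_matrix(120, 36, alpha = 0.1, seed = 61)
  labels <- rep(c("x", "y", "z"), each = 12)
  sf <- library_size_factors(sim$m)
  ident <- setNames(c("x", "y", "z"), c("x", "y", "z"))
  merged <- neuron_combined_one_vs_rest(sim$m, sf, labels, ident)
  plain <- nb_contrast(sim$m, sf, labels, "x", "rest")
  plain <- plain[order(plain$fdr, plain$p), ]
  expect_equal(merged$x$p, plain$p)
  expect_equal(merged$x$fold_change, plain$fold_change)
})
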