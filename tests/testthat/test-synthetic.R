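test_that("generation is deterministic under a fixed seed", {
  cfg <- default_simulation_config(n_genes = 300, seed = 9)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$true_type, b$true_type)
})

test_that("dispersion-zero single profile approaches the Poisson rate vector", {
  n_genes <- 200
  rate <- rep(c(5, 20, 100), length.out = n_genes)
  prof <- cell_type_profile("only", 400, rate, neuron = TRUE)
  cfg <- simulation_config(list(prof), n_genes = n_genes, n_mito_genes = 0,
                           library_size_lognormal = c(0, 0),  # L = 1 exactly
                           nb_dispersion = 0, seed = 3)
  ds <- generate_dataset(cfg)
  emp <- Matrix::rowMeans(ds$counts$counts)
  # Poisson mean-of-400 tolerance: ~4 sd
  expect_true(all(abs(emp - rate) < 4 * sqrt(rate / 400) + 1e-9))
})

test_that("planted markers are strongly enriched in their own type", {
  ds <- default_ds()
  tt <- ds$true_type
  cnt <- as.matrix(ds$counts$counts)
  for (ty in c("Astrocyte", "Oligodendrocyte", "VAC")) {
    mk <- ds$marker_map[[ty]]
    own <- rowMeans(cnt[mk, tt == ty, drop = FALSE])
    other <- rowMeans(cnt[mk, tt != ty, drop = FALSE])
    expect_true(all(own >= 4 * other),
                info = paste("marker enrichment for", ty))
  }
})

test_that("empirical marker enrichment tracks the configured fold", {
  cfg <- default_simulation_config(n_genes = 500, marker_fold = 8, seed = 21)
  ds <- generate_dataset(cfg)
  cnt <- as.matrix(ds$counts$counts)
  # normalize by the true depth multipliers to isolate the planted fold
  norm <- sweep(cnt, 2, ds$library_size, "/")
  for (ty in c("Astrocyte", "Oligodendrocyte", "VAC")) {
    mk <- ds$marker_map[[ty]]
    own <- sum(rowMeans(norm[mk, ds$true_type == ty, drop = FALSE]))
    other <- sum(rowMeans(norm[mk, !(ds$true_type %in%
                                       c(ty, "N1", "N2")), drop = FALSE]))
    fold <- own / other
    expect_lt(abs(fold - 8) / 8, 0.25)
  }
})

test_that("the reporter transcript is restricted to neuron profiles", {
  ds <- default_ds()
  rep_counts <- as.vector(ds$counts$counts["tdTomato", ])
  neuron <- ds$true_type %in% c("N1", "N2")
  expect_true(all(rep_counts[!neuron] == 0))
  expect_gt(mean(rep_counts[neuron] > 0), 0.95)

  leaky <- generate_dataset(default_simulation_config(
    n_genes = 300, reporter_leakage = 0.2, seed = 5))
  leak_counts <- as.vector(leaky$counts$counts["tdTomato", ])
  expect_gt(sum(leak_counts[!(leaky$true_type %in% c("N1", "N2"))]), 0)
})

test_that("artifact injection at zero fractions is the identity", {
  ds <- generate_dataset(default_simulation_config(n_genes = 200, seed = 4))
  out <- inject_artifacts(ds, 0, 0, seed = 1)
  expect_identical(as.matrix(out$counts$counts), as.matrix(ds$counts$counts))
  expect_identical(out$is_doublet, ds$is_doublet)
})

test_that("doublets are exact sums of their parents and flagged", {
  ds <- generate_dataset(default_simulation_config(n_genes = 200, seed = 4))
  n0 <- ncol(ds$counts$counts)
  out <- inject_artifacts(ds, 0, frac_doublets = 0.05, seed = 2)
  parents <- attr(out, "doublet_parents")
  n_db <- nrow(parents)
  expect_equal(n_db, round(0.05 * n0))
  cnt <- as.matrix(out$counts$counts)
  for (i in seq_len(n_db)) {
    expect_identical(unname(cnt[, n0 + i]),
                     unname(cnt[, parents[i, 1]] + cnt[, parents[i, 2]]))
  }
  expect_true(all(out$is_doublet[n0 + seq_len(n_db)]))
  expect_true(all(grepl("\\+", out$true_type[n0 + seq_len(n_db)])))
})

test_that("low-quality injection hits the requested count, thinning and mito targets", {
  cfg <- default_simulation_config(
    n_genes = 300,
    n_cells = c(N1 = 50, N2 = 50, Astrocyte = 40, Oligodendrocyte = 30,
                VAC = 30), seed = 8)
  ds <- generate_dataset(cfg)
  tot0 <- Matrix::colSums(ds$counts$counts)
  out <- inject_artifacts(ds, frac_low_quality = 0.1, frac_doublets = 0,
                          seed = 3, thin_frac = 0.2, mito_target = 0.5)
  expect_equal(sum(out$is_low_quality), 20)
  qc <- compute_cell_qc(out$counts)
  lq <- out$is_low_quality
  expect_true(all(qc$mito_proportion[lq] >= 0.5))
  expect_true(all(qc$total_counts[lq] < 0.25 * tot0[lq]))
})

test_that("fraction validation rejects out-of-range input", {
  ds <- generate_dataset(default_simulation_config(n_genes = 150, seed = 2))
  expect_error(inject_artifacts(ds, -0.1, 0), "fractions")
  expect_error(inject_artifacts(ds, 0, 1.5), "fractions")
  expect_error(simulation_config(list(), n_genes = 10), "empty")
  expect_error(cell_type_profile("x", 5, c(-1, 2)), "negative")
})

test_that("datasets round-trip through the on-disk format", {
  ds <- generate_dataset(default_simulation_config(n_genes = 200, seed = 6))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(as.matrix(back$counts$counts), as.matrix(ds$counts$counts))
  expect_identical(back$true_type, ds$true_type)
  expect_identical(back$counts$gene_flags, ds$counts$gene_flags)
  expect_identical(sort(names(back$marker_map)), sort(names(ds$marker_map)))

  # MTX header nnz equals an independent nonzero count
  lines <- readLines(file.path(dir, "matrix.mtx"))
  body <- lines[!startsWith(lines, "%")]
  hdr <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
  expect_equal(hdr[3], sum(as.matrix(ds$counts$counts) != 0))
  expect_equal(length(body) - 1, hdr[3])
})

test_that("an empty dataset writes valid zero-entry files", {
  prof <- cell_type_profile("none", 0, rep(1, 10))
  cfg <- simulation_config(list(prof), n_genes = 10, seed = 1)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(ncol(back$counts$counts), 0)
  expect_equal(nrow(back$counts$counts), 10)
})
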