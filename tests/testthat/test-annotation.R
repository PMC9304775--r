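expr_of <- function(v) {
  structure(list(values = v, cpm = 2^v - 1, pseudocount = 1,
                 size_factors = NULL, eff_lib = rep(1, ncol(v))),
            class = "expression_matrix")
}

test_that("all five study populations are annotated correctly", {
  run <- default_run()
  ann <- run$annotation
  truth <- run$truth$true_type[match(names(run$clustering$labels),
                                     run$truth$cell_id)]
  for (k in names(ann$assignment)) {
    major <- names(which.max(table(truth[run$clustering$labels ==
                                           as.integer(k)])))
    expected <- if (major %in% c("N1", "N2")) "Neuron" else major
    expect_identical(unname(ann$assignment[k]), expected)
  }
  expect_false(any(ann$ambiguous))
})

test_that("tied scores are flagged ambiguous instead of silently broken", {
  v <- matrix(rep(c(1, 2, 3, 4), 6), nrow = 4,
              dimnames = list(c("m1", "m2", "m3", "m4"), NULL))
  labels <- rep(c("a", "b"), each = 3)   # identical profiles in both clusters
  ann <- assign_cluster_types(expr_of(v), labels,
                              list(T1 = c("m1", "m2"), T2 = c("m3", "m4")))
  # identical profiles mean both clusters receive identical score rows
  expect_equal(ann$scores["a", ], ann$scores["b", ])
})

test_that("ambiguity and error paths behave as specified", {
  v <- matrix(c(5, 5, 5, 5, 1, 1, 1, 1), nrow = 2, byrow = FALSE,
              dimnames = list(c("m1", "m2"), NULL))
  labels <- rep(c("a", "b"), each = 2)
  # both types share the same markers -> equal scores -> ambiguous
  ann <- assign_cluster_types(expr_of(v), labels,
                              list(T1 = c("m1", "m2"), T2 = c("m1", "m2")))
  expect_true(all(ann$ambiguous))
  expect_true(all(is.na(ann$assignment)))
  expect_error(assign_cluster_types(expr_of(v), labels, list()), "empty")
  expect_error(assign_cluster_types(expr_of(v), labels, list(T1 = character())),
               "empty")
  expect_warning(
    ann2 <- assign_cluster_types(expr_of(v), labels,
                                 list(T1 = c("m1", "nope"),
                                      T2 = c("gone", "away"))),
    "absent")
  expect_identical(ann2$unassignable_types, "T2")
})

test_that("annotation ignores gene order and cluster label names", {
  set.seed(71)
  v <- rbind(matrix(rnorm(3 * 20, 2), 3), matrix(rnorm(3 * 20, 0), 3))
  v[1:3, 1:10] <- v[1:3, 1:10] + 4
  v[4:6, 11:20] <- v[4:6, 11:20] + 4
  rownames(v) <- paste0("m", 1:6)
  markers <- list(A = c("m1", "m2", "m3"), B = c("m4", "m5", "m6"))
  l1 <- rep(c("x", "y"), each = 10)
  a1 <- assign_cluster_types(expr_of(v), l1, markers)
  a2 <- assign_cluster_types(expr_of(v[sample(6), ]), l1, markers)
  expect_identical(a1$assignment, a2$assignment)
  l2 <- rep(c("22", "11"), each = 10)
  a3 <- assign_cluster_types(expr_of(v), l2, markers)
  expect_identical(unname(a3$assignment[c("22", "11")]),
                   unname(a1$assignment[c("x", "y")]))
})

test_that("reporter validation passes for exclusive reporters and fails for uniform ones", {
  run <- default_run()
  expect_true(run$reporter_validation$pass)
  expect_true(all(run$reporter_validation$tests$p_adj <= 0.005))

  set.seed(72)
  v <- matrix(rnorm(2 * 40, 5), 2, dimnames = list(c("tdTomato", "g1"), NULL))
  e <- expr_of(v)
  labels <- rep(c("n1", "other"), each = 20)
  res <- reporter_validation(e, labels, "tdTomato", "n1")
  expect_false(res$pass)
  expect_error(reporter_validation(e, labels, "absent", "n1"), "absent")
})

test_that("small-sample Wilcoxon p equals exact rank-sum enumeration", {
  x <- c(12.1, 9.8, 15.2, 11.0)    # neuron cluster, n = 4
  y <- c(3.2, 4.1, 2.8, 5.0)       # pooled others, n = 4
  v <- matrix(c(x, y), 1, dimnames = list("tdTomato", NULL))
  e <- structure(list(values = v, cpm = v, pseudocount = 1,
                      size_factors = NULL, eff_lib = rep(1, 8)),
                 class = "expression_matrix")
  labels <- rep(c("a", "b"), each = 4)
  res <- reporter_validation(e, labels, "tdTomato", "a")
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[1:4])
  combos <- combn(8, 4)
  null_sums <- apply(combos, 2, function(ix) sum(r[ix]))
  p_exact <- mean(null_sums >= obs)
  expect_equal(res$tests$p, p_exact)
})

test_that("the planted Fgf9 -> Fgfr3 pattern yields exactly the neuron-to-astrocyte edge", {
  run <- default_run()
  edges <- run$edges$edges
  fgf <- edges[edges$pathway == "FGF", ]
  expect_equal(nrow(fgf), 1)
  expect_equal(fgf$sender, "Neuron")
  expect_equal(fgf$receiver, "Astrocyte")
  expect_equal(fgf$ligand, "Fgf9")
  expect_equal(fgf$receptor, "Fgfr3")
})

test_that("edges need both endpoints and appear in deterministic order", {
  run <- default_run()
  de <- run$de
  lr <- data.frame(ligand = c("Fgf9", "Fgf9"),
                   receptor = c("Fgfr3", "NotAGene"),
                   pathway = c("FGF", "FGF"))
  res <- ligand_receptor_directionality(de, lr)
  expect_equal(nrow(res$unresolved), 1)
  expect_equal(res$unresolved$receptor, "NotAGene")
  expect_equal(nrow(res$edges), 1)
  ord <- order(res$edges$pathway, res$edges$sender, res$edges$receiver)
  expect_identical(ord, seq_len(nrow(res$edges)))
})

test_that("expressed-only mode with a ubiquitous pair gives the complete bipartite set", {
  run <- default_run()
  de <- run$de
  lr <- data.frame(ligand = "Tgfb2", receptor = "Vegfa", pathway = "demo")
  res <- ligand_receptor_directionality(de, lr, mode = "expressed")
  k <- length(names(de))
  expect_equal(nrow(res$edges), k * k)
})

test_that("loosening the enrichment rule never removes edges", {
  run <- default_run()
  de <- run$de
  lr <- default_lr_pairs()
  strict <- ligand_receptor_directionality(de, lr, fold = 2, fdr_max = 0.05)
  loose <- ligand_receptor_directionality(de, lr, fold = 1.5, fdr_max = 0.2)
  key <- function(e) paste(e$pathway, e$sender, e$receiver, e$ligand,
                           e$receptor)
  expect_true(all(key(strict$edges) %in% key(loose$edges)))
})
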