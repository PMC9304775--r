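# shared fixtures, computed once per test run
fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache))
    assign(name, expr, envir = fixture_cache)
  get(name, envir = fixture_cache)
}

default_ds <- function(seed = 42) {
  cached(paste0("ds", seed),
         generate_dataset(default_simulation_config(seed = seed)))
}

default_run <- function(seed = 42) {
  cached(paste0("run", seed),
         suppressMessages(run_pipeline(default_ds(seed),
                                       pipeline_config(seed = seed))))
}

# tiny hand-checkable matrix: 4 genes (one mito) x 3 cells
tiny_counts <- function() {
  m <- rbind(c(5L, 0L, 2L),
             c(0L, 3L, 1L),
             c(10L, 0L, 0L),
             c(1L, 1L, 1L))
  rownames(m) <- c("mt-1", "geneA", "geneB", "geneC")
  colnames(m) <- c("c1", "c2", "c3")
  count_matrix(m)
}

# DE-free NB matrix with known depths; returns list(m, depth)
nb_null_matrix <- function(n_genes, n_cells, alpha = 0.1, seed = 42,
                           depth_sd = 0.3) {
  set.seed(seed)
  rate <- rlnorm(n_genes, 0, 1)
  rate <- rate / sum(rate)
  depth <- rlnorm(n_cells, log(2e4), depth_sd)
  mu <- outer(rate, depth)
  y <- if (alpha > 0)
    matrix(rnbinom(length(mu), size = 1 / alpha, mu = mu), n_genes)
  else matrix(rpois(length(mu), mu), n_genes)
  list(m = count_matrix(y), depth = depth, rate = rate)
}

# brute-force BH step-up oracle
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  rej <- rep(FALSE, m)
  kmax <- 0
  for (i in seq_len(m)) if (p[o[i]] <= q * i / m) kmax <- i
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  rej
}
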