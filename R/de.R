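#' Per-cluster detection fractions
#'
#' Fraction of cells in each cluster in which a gene is detected at or
#' above a CPM threshold (linear CPM, after size-factor normalization).
#' The workflow's gate — detected at >= 5 CPM in >= 20% of a cluster —
#' guards contrasts against genes driven by a few outlier cells.
#'
#' @param e an `expression_matrix`.
#' @param labels cluster labels covering all cells.
#' @param detect_cpm CPM threshold (default 5).
#' @return genes x clusters matrix of fractions.
#' @export
detection_fraction <- function(e, labels, detect_cpm = 5) {
  stopifnot(inherits(e, "expression_matrix"))
  if (length(labels) != ncol(e$cpm))
    stop("labels do not cover the cells", call. = FALSE)
  cl <- sort(unique(labels))
  out <- vapply(cl, function(g) {
    cells <- labels == g
    if (!any(cells)) stop("empty cluster: ", g, call. = FALSE)
    rowMeans(e$cpm[, cells, drop = FALSE] >= detect_cpm)
  }, numeric(nrow(e$cpm)))
  colnames(out) <- as.character(cl)
  out
}

#' Trended, shrunken method-of-moments NB dispersions
#'
#' Per-gene dispersion alpha (variance mu + alpha mu^2) estimated by the
#' method of moments on depth-normalized counts within each group,
#' combined across groups by degrees-of-freedom weights, then shrunk
#' toward a LOESS trend over mean expression. Genes without information
#' (all zero) fall back to the trend.
#'
#' @param m a [count_matrix()].
#' @param labels group labels (>= 2 groups of >= 3 cells).
#' @param sf optional `size_factors`; defaults to library-size factors.
#' @param shrink weight toward the trend in `[0, 1]` (default 0.7).
#' @param span LOESS span for the trend.
#' @return object of class `dispersion_model`: `alpha` (final per-gene),
#'   `raw`, `trend`, `shrink`.
#' @export
estimate_dispersion <- function(m, labels, sf = NULL, shrink = 0.7,
                                span = 0.4) {
  stopifnot(inherits(m, "count_matrix"))
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 3))
    stop("need >= 2 groups with >= 3 cells each", call. = FALSE)
  y <- as.matrix(m$counts)
  L <- if (is.null(sf)) {
    lib <- colSums(y); lib / mean(lib)
  } else sf$factor
  z <- sweep(y, 2, L, "/")
  num <- rep(0, nrow(y)); den <- rep(0, nrow(y))
  for (g in names(tab)) {
    cells <- labels == g
    nk <- sum(cells)
    zi <- z[, cells, drop = FALSE]
    lam <- rowMeans(zi)
    s2 <- rowSums((zi - lam)^2) / (nk - 1)
    invL <- mean(1 / L[cells])
    ok <- lam > 0
    a <- ifelse(ok, (s2 - lam * invL) / lam^2, NA_real_)
    w <- nk - 1
    num <- num + ifelse(ok, w * a, 0)
    den <- den + ifelse(ok, w, 0)
  }
  raw <- ifelse(den > 0, num / den, NA_real_)
  ml <- log2(rowMeans(z) + 1)
  ok <- !is.na(raw)
  trend <- rep(0, nrow(y))
  if (sum(ok) >= 10) {
    fit <- stats::loess(pmax(raw[ok], 0) ~ ml[ok], span = span, degree = 1,
                        family = "symmetric")
    pr <- stats::predict(fit, ml)
    # extrapolate flatly beyond the fitted support
    pr[is.na(pr)] <- stats::approx(ml[ok], fit$fitted, xout = ml[is.na(pr)],
                                   rule = 2, ties = mean)$y
    trend <- pmax(pr, 0)
  } else if (any(ok)) {
    trend <- rep(max(stats::median(raw[ok]), 0), nrow(y))
  }
  alpha <- (1 - shrink) * pmax(raw, 0) + shrink * trend
  alpha[!ok] <- trend[!ok]
  structure(list(alpha = pmax(alpha, 0), raw = raw, trend = trend,
                 shrink = shrink),
            class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf("dispersion_model: %d genes; median alpha %.3g (shrink %.2f)\n",
              length(x$alpha), stats::median(x$alpha), x$shrink))
  invisible(x)
}

# vectorized per-gene NB mean fit with offsets (Fisher scoring on log mean);
# returns log-likelihood and fitted mean rate per gene
nb_group_fit <- function(y, L, alpha, iter = 50, tol = 1e-10) {
  ys <- rowSums(y)
  lam <- ys / sum(L)
  b <- ifelse(ys > 0, log(lam), -Inf)
  act <- which(ys > 0 & alpha > 1e-12)   # Poisson/zero rows are closed form
  if (length(act)) {
    ba <- b[act]
    ya <- y[act, , drop = FALSE]
    aa <- alpha[act]
    for (i in seq_len(iter)) {
      mu <- exp(ba) %o% L
      am <- 1 + aa * mu
      step <- rowSums((ya - mu) / am) / pmax(rowSums(mu / am), 1e-12)
      step <- pmin(pmax(step, -5), 5)
      ba <- ba + step
      if (max(abs(step)) < tol) break
    }
    b[act] <- ba
  }
  lamhat <- exp(b)
  mu <- ifelse(is.finite(b), 1, 0) * (pmax(lamhat, 0) %o% L)
  ll <- nb_loglik(y, mu, alpha)
  list(lambda = lamhat, ll = ll)
}

nb_loglik <- function(y, mu, alpha) {
  n <- ncol(y)
  a <- rep(alpha, times = n)
  yy <- as.vector(y); mm <- as.vector(mu)
  ll <- numeric(length(yy))
  pois <- a < 1e-12
  if (any(pois))
    ll[pois] <- stats::dpois(yy[pois], pmax(mm[pois], 1e-300), log = TRUE)
  if (any(!pois))
    ll[!pois] <- stats::dnbinom(yy[!pois], size = 1 / a[!pois],
                                mu = pmax(mm[!pois], 1e-300), log = TRUE)
  ll[yy == 0 & mm == 0] <- 0
  rowSums(matrix(ll, nrow = nrow(y)))
}

#' Negative-binomial contrast between two cell groups
#'
#' Per-gene likelihood-ratio test of equal group means under a negative
#' binomial with offsets equal to the log effective library size and
#' dispersions from a [estimate_dispersion()] model (chi-square with one
#' degree of freedom; BH FDR within the contrast). The reported fold
#' change is, by the workflow's convention, the ratio of average CPM in
#' group A over average CPM in group B (or the rest) — independent of the
#' test statistic; a zero average in either side adds a continuity
#' constant (default 0.5 CPM) to both sides and flags the gene. A gene is
#' called significant iff the fold change passes `fold` in either
#' direction, `fdr <= fdr_max`, and the detection gate holds in at least
#' one of the two groups.
#'
#' @param m a [count_matrix()].
#' @param sf `size_factors` aligned to the cells.
#' @param labels group labels per cell.
#' @param A label of the focal group.
#' @param B label of the comparison group, or `"rest"` for all others.
#' @param disp optional `dispersion_model` (estimated from the two groups
#'   when missing).
#' @param expr optional precomputed `expression_matrix` (must match `m`
#'   and `sf`).
#' @param fold,fdr_max,detect_cpm,detect_frac significance gates
#'   (defaults 2, 0.05, 5 CPM, 0.2).
#' @param continuity CPM continuity constant for zero averages.
#' @return data.frame of class `de_table`, one row per gene, ordered as
#'   in `m`: `gene_id`, `avg_cpm_A`, `avg_cpm_B`, `fold_change`,
#'   `log2_fc`, `p`, `fdr`, `detect_frac_A`, `detect_frac_B`,
#'   `zero_adjusted`, `significant`; attributes `contrast` and
#'   `thresholds`.
#' @export
nb_contrast <- function(m, sf, labels, A, B = "rest", disp = NULL,
                        expr = NULL, fold = 2, fdr_max = 0.05,
                        detect_cpm = 5, detect_frac = 0.2,
                        continuity = 0.5) {
  stopifnot(inherits(m, "count_matrix"), inherits(sf, "size_factors"))
  inA <- labels == A
  inB <- if (identical(B, "rest")) labels != A else labels == B
  if (!any(inA) || !any(inB)) stop("empty contrast group", call. = FALSE)
  y <- as.matrix(m$counts)
  eff <- if (!is.null(expr)) expr$eff_lib
         else sf$factor * mean(colSums(y))
  cpm <- if (!is.null(expr)) expr$cpm else sweep(y, 2, eff, "/") * 1e6
  if (is.null(disp)) {
    sub <- inA | inB
    grp <- ifelse(inA, "A", "B")[sub]
    disp <- estimate_dispersion(subset_counts(m, cells = which(sub)), grp,
                                sf = structure(list(factor = sf$factor[sub]),
                                               class = "size_factors"))
  }
  alpha <- disp$alpha

  fitA <- nb_group_fit(y[, inA, drop = FALSE], eff[inA], alpha)
  fitB <- nb_group_fit(y[, inB, drop = FALSE], eff[inB], alpha)
  both <- inA | inB
  fit0 <- nb_group_fit(y[, both, drop = FALSE], eff[both], alpha)
  lrt <- pmax(2 * (fitA$ll + fitB$ll - fit0$ll), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, "BH")

  avgA <- rowMeans(cpm[, inA, drop = FALSE])
  avgB <- rowMeans(cpm[, inB, drop = FALSE])
  zero <- avgA == 0 | avgB == 0
  fc <- (avgA + continuity * zero) / (avgB + continuity * zero)
  detA <- rowMeans(cpm[, inA, drop = FALSE] >= detect_cpm)
  detB <- rowMeans(cpm[, inB, drop = FALSE] >= detect_cpm)
  sig <- (fc >= fold | fc <= 1 / fold) & fdr <= fdr_max &
    (detA >= detect_frac | detB >= detect_frac)

  out <- data.frame(gene_id = gene_ids(m), avg_cpm_A = avgA,
                    avg_cpm_B = avgB, fold_change = fc, log2_fc = log2(fc),
                    p = p, fdr = fdr, detect_frac_A = detA,
                    detect_frac_B = detB, zero_adjusted = zero,
                    significant = sig, row.names = NULL)
  attr(out, "contrast") <- c(A = as.character(A), B = as.character(B))
  attr(out, "thresholds") <- list(fold = fold, fdr_max = fdr_max,
                                  detect_cpm = detect_cpm,
                                  detect_frac = detect_frac,
                                  continuity = continuity)
  class(out) <- c("de_table", "data.frame")
  out
}

#' One-vs-rest contrasts after merging similar clusters
#'
#' Applies a raw-label to reporting-group merge map (e.g. combining the
#' two neuronal clusters, whose pairwise contrast is nearly empty) and
#' runs [nb_contrast()] of each reporting group against the rest. Each
#' table is sorted by ascending FDR, the presentation order of the
#' workflow's top-gene tables.
#'
#' @param m,sf,labels as in [nb_contrast()].
#' @param merge_map named vector mapping each raw label to its reporting
#'   group; every observed label must be mapped.
#' @param ... gates passed to [nb_contrast()].
#' @return named list of `de_table` objects, class `de_table_set`.
#' @export
neuron_combined_one_vs_rest <- function(m, sf, labels, merge_map, ...) {
  merged <- unname(merge_map[as.character(labels)])
  if (anyNA(merged))
    stop("merge_map does not cover labels: ",
         paste(setdiff(unique(as.character(labels)), names(merge_map)),
               collapse = ", "), call. = FALSE)
  groups <- sort(unique(merged))
  if (length(groups) < 2)
    stop("merge yields fewer than 2 groups", call. = FALSE)
  out <- lapply(groups, function(g) {
    tab <- nb_contrast(m, sf, merged, A = g, B = "rest", ...)
    tab[order(tab$fdr, tab$p), ]
  })
  names(out) <- groups
  class(out) <- "de_table_set"
  out
}

#' @export
print.de_table_set <- function(x, ...) {
  for (g in names(x))
    cat(sprintf("%s vs rest: %d significant genes\n", g,
                sum(x[[g]]$significant)))
  invisible(x)
}
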