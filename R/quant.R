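#' Percent positive area of an image plane
#'
#' Background is estimated by a grayscale morphological opening with a
#' flat disc structuring element of the given radius (the opening removes
#' bright features smaller than the disc, leaving the smooth background,
#' which is then subtracted and the result clipped at zero). The
#' percentage of suprathreshold pixels is computed inside the ROI (the
#' full frame by default). Whether the threshold applies to the
#' background-subtracted (default) or raw intensities is recorded in the
#' result rather than assumed.
#'
#' @param img numeric matrix of nonnegative intensities.
#' @param threshold intensity threshold (>= 0); pixels strictly above it
#'   count as positive.
#' @param rolling_ball_radius radius of the structuring element in
#'   pixels; `<= 0` skips background subtraction.
#' @param roi optional logical matrix of the same dimension.
#' @param threshold_on `"subtracted"` (default) or `"raw"`.
#' @return percentage in `[0, 100]` with attribute `threshold_on`.
#' @export
percent_positive_area <- function(img, threshold, rolling_ball_radius = 25,
                                  roi = NULL,
                                  threshold_on = c("subtracted", "raw")) {
  threshold_on <- match.arg(threshold_on)
  stopifnot(is.matrix(img), threshold >= 0)
  if (any(!is.finite(img))) stop("non-finite intensities", call. = FALSE)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(img), ncol(img))
  if (!identical(dim(roi), dim(img)))
    stop("ROI dimensions do not match the image", call. = FALSE)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  work <- img
  if (rolling_ball_radius > 0 && threshold_on == "subtracted") {
    bg <- subtract_background(img, rolling_ball_radius)
    work <- bg
  }
  pct <- 100 * sum(work > threshold & roi) / sum(roi)
  attr(pct, "threshold_on") <- threshold_on
  pct
}

#' Morphological background subtraction
#'
#' @param img numeric matrix.
#' @param radius structuring-element radius in pixels.
#' @return the image minus its opening, clipped at 0.
#' @export
subtract_background <- function(img, radius) {
  if (radius <= 0) return(img)
  scale <- max(img, 1)                       # EBImage expects [0, 1]
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  bg <- EBImage::opening(img / scale, brush) * scale
  pmax(img - bg, 0)
}

#' Volume fraction of a boolean mask
#'
#' `100 * true voxels / ROI voxels`; voxel dimensions cancel for a
#' fraction, so anisotropy does not matter.
#'
#' @param mask logical array (any dimension).
#' @param roi optional logical array of the same shape; defaults to the
#'   full grid.
#' @return percentage in `[0, 100]`.
#' @export
volume_fraction <- function(mask, roi = NULL) {
  if (!is.logical(mask)) stop("mask must be logical", call. = FALSE)
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  if (is.null(roi)) roi <- array(TRUE, dim(mask) %||% length(mask))
  if (!identical(dim(roi), dim(mask)) && length(roi) != length(mask))
    stop("ROI shape does not match the mask", call. = FALSE)
  n_roi <- sum(roi)
  if (n_roi == 0) stop("zero ROI volume", call. = FALSE)
  100 * sum(mask & roi) / n_roi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Krieger-Yekutieli two-stage adaptive FDR
#'
#' Stage one runs BH step-up at `q' = q / (1 + q)`; the number of
#' non-rejections estimates the count of true nulls `m0`. If stage one
#' rejects nothing (or everything) the procedure stops there; otherwise
#' stage two reruns BH at the inflated rate `q * m / m0` and its
#' rejections are final. Never more conservative than plain BH at the
#' same `q` once stage one rejects anything.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param q target FDR (default 0.01, the q = 1% used for the imaging
#'   statistics).
#' @return object of class `multi_test_result`: `p`, `procedure`, `q`,
#'   `rejected` (logical, input order), `m0_hat`, `stage1_rejections`.
#' @export
bky_two_stage <- function(p, q = 0.01) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]",
                                             call. = FALSE)
  m <- length(p)
  if (m == 0)
    return(structure(list(p = p, procedure = "BKY-two-stage", q = q,
                          rejected = logical(0), m0_hat = 0,
                          stage1_rejections = 0L),
                     class = "multi_test_result"))
  q1 <- q / (1 + q)
  r1 <- bh_step_up(p, q1)
  n1 <- sum(r1)
  if (n1 == 0) {
    rejected <- rep(FALSE, m); m0 <- m
  } else if (n1 == m) {
    rejected <- rep(TRUE, m); m0 <- 0
  } else {
    m0 <- m - n1
    rejected <- bh_step_up(p, q1 * m / m0)
  }
  structure(list(p = p, procedure = "BKY-two-stage", q = q,
                 rejected = rejected, m0_hat = m0,
                 stage1_rejections = n1),
            class = "multi_test_result")
}

#' BH step-up rejection set
#'
#' @param p p-values.
#' @param q rate.
#' @return logical rejection vector in input order.
#' @export
bh_step_up <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= q * seq_len(m) / m)
  rej <- rep(FALSE, m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

#' @export
print.multi_test_result <- function(x, ...) {
  cat(sprintf("%s at q = %g: %d of %d rejected (m0_hat = %g)\n",
              x$procedure, x$q, sum(x$rejected), length(x$p), x$m0_hat))
  invisible(x)
}

#' Welch t tests with BKY correction
#'
#' The statistic used for the imaging time-series comparisons: an
#' unequal-variance t test per comparison, with the two-stage adaptive
#' FDR applied across comparisons at q (1% by default). Standard tests
#' are called, not re-derived.
#'
#' @param values numeric measurements.
#' @param group group label per measurement.
#' @param comparisons list of `c(groupA, groupB)` pairs; all pairs by
#'   default.
#' @param q FDR rate.
#' @return list: `comparisons` data.frame (A, B, t, p, rejected) and the
#'   `multi_test_result`.
#' @export
welch_bky <- function(values, group, comparisons = NULL, q = 0.01) {
  group <- as.character(group)
  if (is.null(comparisons)) {
    g <- sort(unique(group))
    comparisons <- utils::combn(g, 2, simplify = FALSE)
  }
  res <- lapply(comparisons, function(cmp) {
    tt <- stats::t.test(values[group == cmp[1]], values[group == cmp[2]],
                        var.equal = FALSE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  tab <- data.frame(A = vapply(comparisons, `[`, "", 1),
                    B = vapply(comparisons, `[`, "", 2),
                    t = vapply(res, `[[`, 0, "t"),
                    p = vapply(res, `[[`, 0, "p"))
  mt <- bky_two_stage(tab$p, q)
  tab$rejected <- mt$rejected
  list(comparisons = tab, multi_test = mt)
}
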