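#' Percent root difference (PRD)
#'
#' Consistency metric between a reference signal `x` and a candidate `y`,
#' reported on the x100 scale:
#' `PRD = 100 * sum((x - y)^2) / sum(x^2)`.
#' The default is the ratio of sums of squares; `root = TRUE` gives the
#' classical square-root variant `100 * sqrt(sum((x - y)^2) / sum(x^2))`.
#' Larger values mean poorer agreement; identical signals give 0.
#'
#' @param x Reference sample vector (must not be all zero).
#' @param y Candidate sample vector of the same length.
#' @param root Use the classical square-root definition (default `FALSE`).
#' @return Nonnegative scalar.
#' @examples
#' prd(c(1, 2, 3), c(1, 2, 3))  # 0
#' prd(c(1, 2, 3), c(0, 0, 0))  # 100
#' @export
prd <- function(x, y, root = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("signals must be nonempty")
  denom <- sum(x^2)
  if (denom == 0) stop("reference signal is identically zero; PRD undefined")
  r <- sum((x - y)^2) / denom
  100 * if (root) sqrt(r) else r
}

#' Variance-ratio R-squared
#'
#' Similarity metric `R^2 = sum((y - mean(x))^2) / sum((x - mean(x))^2)`:
#' the candidate's energy about the reference mean relative to the
#' reference's. Equals 1 for perfect agreement and — unlike the regression
#' coefficient of determination — can exceed 1 when the candidate varies more
#' than the reference (e.g. a drift-contaminated signal scores ~4 against the
#' clean one).
#'
#' @param x Reference vector (must not be constant).
#' @param y Candidate vector of the same length.
#' @return Nonnegative scalar (not clipped to \[0, 1\]).
#' @examples
#' x <- sin(1:100)
#' r_squared(x, x)                     # 1
#' r_squared(x, rep(mean(x), 100))     # 0
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  xbar <- mean(x)
  denom <- sum((x - xbar)^2)
  if (denom == 0) stop("reference signal is constant; R^2 undefined")
  sum((y - xbar)^2) / denom
}

.image_values <- function(img) {
  if (inherits(img, "eit_image")) as.numeric(img$pixels) else as.numeric(img)
}

.common_mask <- function(...) {
  imgs <- list(...)
  d <- dim(if (inherits(imgs[[1L]], "eit_image")) imgs[[1L]]$pixels else imgs[[1L]])
  vals <- lapply(imgs, .image_values)
  if (any(vapply(vals, length, integer(1)) != prod(d))) {
    stop("images must have identical dimensions")
  }
  mask <- Reduce(`&`, lapply(vals, is.finite))
  list(values = vals, mask = mask)
}

#' Image error
#'
#' Normalized total absolute pixel difference between two images,
#' `sum(|A - B|) / sum(|R|)`, where `R` is the artifact-free reference
#' reconstruction. Computed over the pixels that are on-mask (finite) in all
#' three images. Zero iff `A` and `B` agree on-mask.
#'
#' @param a,b Images to compare (matrices or [reconstruct()] outputs).
#' @param r Normalizing reference image (must not be all zero on-mask).
#' @return Nonnegative scalar.
#' @export
image_error <- function(a, b, r) {
  cm <- .common_mask(a, b, r)
  denom <- sum(abs(cm$values[[3L]][cm$mask]))
  if (denom == 0) stop("reference image is identically zero on-mask")
  sum(abs(cm$values[[1L]][cm$mask] - cm$values[[2L]][cm$mask])) / denom
}

#' Image correlation
#'
#' Two-dimensional Pearson correlation of the on-mask pixel values:
#' `sum((A - mean(A)) (B - mean(B))) / sqrt(sum((A - mean(A))^2) *
#' sum((B - mean(B))^2))`. Ranges from -1 to 1; 1 means complete positive
#' correlation.
#'
#' @param a,b Images (matrices or [reconstruct()] outputs), non-constant
#'   on the shared mask.
#' @return Scalar in \[-1, 1\].
#' @export
image_corr <- function(a, b) {
  cm <- .common_mask(a, b)
  av <- cm$values[[1L]][cm$mask]
  bv <- cm$values[[2L]][cm$mask]
  da <- av - mean(av)
  db <- bv - mean(bv)
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) stop("image is constant on-mask; correlation undefined")
  sum(da * db) / den
}

#' Relative improvement in percent
#'
#' `(before - after) / before * 100`: the percentage by which a
#' quality-deficit metric (PRD, image error, |R^2 - 1|, ...) dropped after
#' processing. Full precision is kept; round only for display.
#'
#' @param before,after Metric values before and after processing
#'   (`before != 0`).
#' @return Percent scalar (negative if the metric got worse).
#' @examples
#' improvement_pct(1.8653, 0.1310)  # 92.98 (to 2 decimals)
#' @export
improvement_pct <- function(before, after) {
  if (any(before == 0)) stop("'before' must be nonzero")
  (before - after) / before * 100
}

#' Before/after metrics report for a cleaning run
#'
#' Convenience bundle of the signal-level metrics for a
#' truth/contaminated/cleaned triple.
#'
#' @param truth Ground-truth signal.
#' @param contaminated Signal with artifacts.
#' @param cleaned Signal after artifact removal.
#' @return An object of class `"metrics_report"`: PRD and R^2 before/after
#'   plus the relative improvement percentages of both raw values.
#' @export
metrics_report <- function(truth, contaminated, cleaned) {
  prd_before <- prd(truth, contaminated)
  prd_after <- prd(truth, cleaned)
  r2_before <- r_squared(truth, contaminated)
  r2_after <- r_squared(truth, cleaned)
  structure(list(
    prd_before = prd_before, prd_after = prd_after,
    r2_before = r2_before, r2_after = r2_after,
    prd_improvement_pct = improvement_pct(prd_before, prd_after),
    r2_improvement_pct = improvement_pct(r2_before, r2_after)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Signal quality before -> after cleaning\n")
  cat(sprintf("  PRD: %.4f -> %.4f  (improved %.2f%%)\n",
              x$prd_before, x$prd_after, x$prd_improvement_pct))
  cat(sprintf("  R^2: %.4f -> %.4f  (improved %.2f%%)\n",
              x$r2_before, x$r2_after, x$r2_improvement_pct))
  invisible(x)
}
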