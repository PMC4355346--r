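## Iterative mean-split (isodata) thresholding. Used twice: on the
## diffused red channel to isolate the optic disc, and on the
## maximum-response image to binarise the enhanced vessels. The threshold
## is repeatedly replaced by the midpoint of the two class means until it
## stops moving.

#' Iterative mean-split (isodata) threshold
#'
#' Starting from \code{t0} (an out-of-range start falls back to the
#' midpoint of the value range), the image is
#' split into M1 (values > T) and M2 (values <= T), and T is updated to
#' \code{(mean(M1) + mean(M2)) / 2} until successive thresholds differ by
#' less than \code{tol} or 100 iterations have run. If either class is
#' empty at some step its mean is taken as the current T, which keeps T
#' fixed and guarantees termination on near-constant images. The sequence
#' of thresholds is bounded by the value range, so the loop always
#' terminates.
#'
#' A constant image is not an error: the threshold is that constant, the
#' mask is empty, and \code{degenerate} is flagged.
#'
#' @param img \code{ChannelImage} or numeric matrix.
#' @param t0 initial threshold in grey levels.
#' @param tol convergence tolerance in grey levels (> 0).
#' @param mask optional \code{BinaryMask}: class means are computed over
#'   (and the output mask restricted to) these pixels only. Restricting to
#'   the field of view keeps the dark surround out of the histogram.
#' @param maxIterations iteration cap.
#' @return A \code{\link{ThresholdResult-class}} object; its \code{mask}
#'   marks pixels strictly above the converged threshold.
#' @export
iterativeThreshold <- function(img, t0 = 15, tol = 0.5, mask = NULL,
                               maxIterations = 100L) {
  x <- as.matrix(img)
  if (length(x) == 0L) stop("image must be non-empty")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  sel <- if (is.null(mask)) rep(TRUE, length(x)) else as.vector(as.matrix(mask))
  if (!any(sel)) stop("analysis mask selects no pixels")
  v <- as.vector(x)[sel]
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    return(new("ThresholdResult", threshold = lo, mask = BinaryMask(out),
               t0 = as.numeric(t0), tol = as.numeric(tol),
               iterationsRun = 1L, degenerate = TRUE))
  }
  ## out-of-range starts fall back to the range midpoint: snapping to an
  ## extreme would put every pixel in one class and park the iteration on
  ## a degenerate fixed point at the minority tail
  t <- if (t0 >= lo && t0 <= hi) as.numeric(t0) else (lo + hi) / 2
  t0used <- t
  iters <- 0L
  repeat {
    iters <- iters + 1L
    m1 <- if (any(v > t)) mean(v[v > t]) else t
    m2 <- if (any(v <= t)) mean(v[v <= t]) else t
    tNew <- (m1 + m2) / 2
    delta <- abs(tNew - t)
    t <- tNew
    if (delta < tol || iters >= maxIterations) break
  }
  out <- x > t
  if (!is.null(mask)) out <- out & as.matrix(mask)
  new("ThresholdResult", threshold = t, mask = BinaryMask(out),
      t0 = t0used, tol = as.numeric(tol), iterationsRun = iters,
      degenerate = FALSE)
}
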