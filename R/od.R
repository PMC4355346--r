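## Optic-disc detection, segmentation and elimination. The disc is the
## dominant bright blob of the (red-channel) image after edge-preserving
## diffusion; it must be removed before vessel extraction because every
## vessel converges on it.

#' Segment the optic disc
#'
#' Pipeline: diffuse the chosen channel (red by default; the disc is
#' clearest there) with \code{\link{diffuse}}, threshold the diffused
#' image with \code{\link{iterativeThreshold}} (class means over FOV
#' pixels when \code{fovOnly}), AND the raw candidates with the dilated
#' FOV mask to drop frame noise, and keep the largest surviving
#' 8-connected component. An image with no bright region yields an empty
#' result (area 0), not an error.
#'
#' @param img a \code{FundusImage}.
#' @param fov a \code{\link{FovMasks-class}} triple from
#'   \code{\link{buildFovMask}}.
#' @param params \code{\link{diffusionParams}} for the smoothing stage.
#' @param channel channel to diffuse, \code{"red"} (default) or
#'   \code{"green"}.
#' @param t0,tol threshold stage parameters.
#' @param fovOnly restrict the threshold histogram to FOV pixels.
#' @return An \code{\link{ODResult-class}} object.
#' @export
segmentOD <- function(img, fov, params = diffusionParams(),
                      channel = c("red", "green"), t0 = 15, tol = 0.5,
                      fovOnly = TRUE) {
  stopifnot(is(img, "FundusImage"), is(fov, "FovMasks"))
  channel <- match.arg(channel)
  if (!all(dim(img@pixels)[1:2] == dim(fov@fov)))
    stop("image and FOV mask shapes differ")
  if (!any(fov@fov)) stop("FOV mask is empty")
  plane <- extractChannel(img, channel)
  diffused <- diffuse(plane, params)
  th <- iterativeThreshold(diffused, t0 = t0, tol = tol,
                           mask = if (fovOnly) fov@fov else NULL)
  cand <- as.matrix(th@mask) & as.matrix(fov@fovDilated)
  if (!any(cand)) {
    return(new("ODResult", odMask = BinaryMask(cand),
               thresholdUsed = th@threshold,
               centroid = c(NA_real_, NA_real_), area = 0L))
  }
  lab <- labelComponents(cand, 8)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  od <- lab == keep
  idx <- which(od, arr.ind = TRUE)
  new("ODResult", odMask = BinaryMask(od), thresholdUsed = th@threshold,
      centroid = c(mean(idx[, 1]), mean(idx[, 2])),
      area = as.integer(sum(od)))
}

#' Eliminate the optic disc from a channel image
#'
#' Pixels inside the disc mask are replaced by 0 (the default,
#' "subtracting" the region) or by the mean of non-disc FOV pixels
#' (avoids the artificial edge a zero fill creates); every other pixel is
#' returned bit-identical.
#'
#' @param green \code{ChannelImage} (typically the green plane).
#' @param od an \code{\link{ODResult-class}} object.
#' @param fill \code{"zero"} or \code{"mean"}.
#' @param fov optional \code{BinaryMask} defining the background for the
#'   mean fill (defaults to all non-disc pixels).
#' @return A \code{ChannelImage}.
#' @export
eliminateOD <- function(green, od, fill = c("zero", "mean"), fov = NULL) {
  fill <- match.arg(fill)
  g <- as.matrix(green)
  m <- as.matrix(od@odMask)
  if (!all(dim(g) == dim(m))) stop("image and OD mask shapes differ")
  if (!any(m)) return(ChannelImage(g))
  val <- if (fill == "zero") 0 else {
    bg <- if (is.null(fov)) !m else as.matrix(fov) & !m
    if (!any(bg)) 0 else mean(g[bg])
  }
  g[m] <- val
  ChannelImage(g)
}
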