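## Binary and greyscale morphological primitives with explicitly defined
## structuring elements, plus the field-of-view mask construction.
##
## Conventions, fixed package-wide:
##  - disc(r) contains exactly the integer offsets at Euclidean distance
##    <= r from the origin (library disc definitions differ; this one is
##    documented and tested);
##  - erosion treats out-of-image cells as foreground (+Inf in greyscale),
##    so the frame never erodes the FOV artificially; dilation treats them
##    as background (-Inf);
##  - openings are erosion followed by dilation and are idempotent.

#' Disc structuring element
#'
#' Footprint of side \code{2r + 1}; a cell is true iff its Euclidean
#' distance from the centre is at most \code{radius}.
#'
#' @param radius positive integer radius in pixels.
#' @return A \code{\link{StructuringElement-class}} object.
#' @export
makeDisc <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1 ||
      radius != round(radius))
    stop("radius must be a positive integer")
  r <- as.integer(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  fp <- matrix(off$dr^2 + off$dc^2 <= r^2, nrow = 2L * r + 1L)
  new("StructuringElement", footprint = fp, origin = c(r + 1L, r + 1L),
      descriptor = list(shape = "disc", radius = r))
}

#' Line structuring element
#'
#' Exactly \code{length} true cells on the rasterised segment through the
#' origin at \code{angle_deg} degrees counterclockwise from the +col
#' (horizontal) axis; the raster steps along the dominant axis so every
#' cell is distinct (Bresenham-style). 180 degrees coincides with 0
#' (horizontal).
#'
#' @param length positive integer number of cells.
#' @param angle_deg orientation in degrees.
#' @return A \code{\link{StructuringElement-class}} object.
#' @export
makeLine <- function(length, angle_deg) {
  if (!is.numeric(length) || length(length) != 1L || length < 1 ||
      length != round(length))
    stop("length must be a positive integer")
  L <- as.integer(length)
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  t <- seq_len(L) - 1L - (L - 1L) %/% 2L  # centred, origin included
  if (abs(co) >= abs(si)) {
    # step along columns; row offset follows the slope (row axis points
    # down, angles run counterclockwise, hence the minus sign)
    dc <- t
    dr <- as.integer(round(-t * (si / co)))
  } else {
    dr <- -t
    dc <- as.integer(round(-dr * (co / si)))
  }
  rr <- max(abs(dr)); cr <- max(abs(dc))
  fp <- matrix(FALSE, 2L * rr + 1L, 2L * cr + 1L)
  fp[cbind(dr + rr + 1L, dc + cr + 1L)] <- TRUE
  new("StructuringElement", footprint = fp,
      origin = c(rr + 1L, cr + 1L),
      descriptor = list(shape = "line", length = L, angle = angle_deg))
}

## offsets (dr, dc) of true cells relative to the origin
seOffsets <- function(s) {
  idx <- which(s@footprint, arr.ind = TRUE)
  cbind(idx[, 1] - s@origin[1], idx[, 2] - s@origin[2])
}

## shift-and-reduce engine shared by erosion and dilation.
## out(p) = reduce over offsets o of x(p + o); pad supplies out-of-image
## values.
morphoReduce <- function(x, off, op = c("min", "max"), pad) {
  op <- match.arg(op)
  H <- nrow(x); W <- ncol(x)
  rp <- max(0L, max(abs(off[, 1]))); cp <- max(0L, max(abs(off[, 2])))
  lx <- is.logical(x)
  P <- matrix(pad, H + 2L * rp, W + 2L * cp)
  P[(rp + 1L):(rp + H), (cp + 1L):(cp + W)] <- x
  acc <- NULL
  for (i in seq_len(nrow(off))) {
    sub <- P[(rp + 1L + off[i, 1]):(rp + H + off[i, 1]),
             (cp + 1L + off[i, 2]):(cp + W + off[i, 2]), drop = FALSE]
    acc <- if (is.null(acc)) sub
           else if (op == "min") { if (lx) acc & sub else pmin(acc, sub) }
           else                  { if (lx) acc | sub else pmax(acc, sub) }
  }
  dim(acc) <- c(H, W)
  acc
}

## dispatch helper: run `f` on the raw matrix of a mask/channel and
## rewrap in the input's class
sameKind <- function(img, m) {
  if (is(img, "BinaryMask")) BinaryMask(m)
  else if (is(img, "ChannelImage")) ChannelImage(m)
  else if (is.logical(img)) BinaryMask(m)
  else ChannelImage(m)
}

#' Morphological erosion
#'
#' Binary: a pixel survives iff the translated structuring element fits
#' inside the foreground. Greyscale: per-pixel minimum over the footprint.
#' Out-of-image cells count as foreground, so the frame border never
#' erodes structures touching it.
#'
#' @param img \code{BinaryMask}, \code{ChannelImage}, or plain matrix.
#' @param s a \code{StructuringElement}.
#' @return Same kind as the input.
#' @export
erodeImage <- function(img, s) {
  x <- as.matrix(img)
  pad <- if (is.logical(x)) TRUE else Inf
  sameKind(img, morphoReduce(x, seOffsets(s), "min", pad))
}

#' Morphological dilation
#'
#' Binary: a pixel lights up iff the reflected structuring element hits
#' the foreground. Greyscale: per-pixel maximum. Out-of-image cells count
#' as background.
#'
#' @inheritParams erodeImage
#' @return Same kind as the input.
#' @export
dilateImage <- function(img, s) {
  x <- as.matrix(img)
  pad <- if (is.logical(x)) FALSE else -Inf
  sameKind(img, morphoReduce(x, -seOffsets(s), "max", pad))
}

#' Morphological opening (erosion then dilation)
#'
#' Removes structures that cannot contain the structuring element;
#' anti-extensive and idempotent.
#'
#' @inheritParams erodeImage
#' @return Same kind as the input.
#' @export
openImage <- function(img, s) dilateImage(erodeImage(img, s), s)

## 4-connected binary reconstruction by dilation of `marker` under `mask`
reconstructBinary <- function(marker, mask) {
  cur <- marker & mask
  plus <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L), c(0L, 0L))
  repeat {
    nxt <- morphoReduce(cur, plus, "max", FALSE) & mask
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

## greyscale reconstruction by dilation (4-connected), marker <= image
reconstructGrey <- function(marker, image) {
  cur <- pmin(marker, image); dim(cur) <- dim(image)
  plus <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L), c(0L, 0L))
  repeat {
    nxt <- pmin(morphoReduce(cur, plus, "max", -Inf), image)
    dim(nxt) <- dim(image)
    if (isTRUE(all.equal(nxt, cur, tolerance = 0))) return(cur)
    cur <- nxt
  }
}

borderIndicator <- function(H, W) {
  b <- matrix(FALSE, H, W)
  b[1, ] <- TRUE; b[H, ] <- TRUE; b[, 1] <- TRUE; b[, W] <- TRUE
  b
}

#' Suppress structures connected to the image border
#'
#' Binary: removes every foreground component 4-connected to the border;
#' interior components are untouched. Greyscale: structures lighter than
#' their surroundings that are connected to the border are flattened via
#' morphological reconstruction from a border marker (the reconstruction,
#' floored at the image minimum, is subtracted).
#'
#' @param img \code{BinaryMask}, \code{ChannelImage}, or plain matrix.
#' @return Same kind as the input.
#' @export
clearBorderStructures <- function(img) {
  x <- as.matrix(img)
  H <- nrow(x); W <- ncol(x)
  b <- borderIndicator(H, W)
  if (is.logical(x)) {
    reach <- reconstructBinary(x & b, x)
    sameKind(img, x & !reach)
  } else {
    lo <- min(x)
    marker <- matrix(lo, H, W)
    marker[b] <- x[b]
    recon <- reconstructGrey(marker, x)
    sameKind(img, x - (recon - lo))
  }
}

#' Fill internal holes of a binary mask
#'
#' Background components with no 4-connected path to the border are
#' holes and are filled.
#'
#' @param mask \code{BinaryMask} or logical matrix.
#' @return A \code{BinaryMask}.
#' @export
fillHoles <- function(mask) {
  m <- as.matrix(mask)
  bg <- !m
  reach <- reconstructBinary(bg & borderIndicator(nrow(m), ncol(m)), bg)
  BinaryMask(!reach)
}

#' Build the field-of-view mask triple from the green channel
#'
#' Pixels strictly above \code{greenThreshold} (default 10 grey levels;
#' \code{"auto"} runs \code{\link{iterativeThreshold}} instead) form the
#' raw mask; it is opened with a 1-px disc to drop isolated noise,
#' cleared of border-connected structures (4-connectivity), and its
#' internal holes are filled so vessel shadows do not punch through. The
#' triple also carries the 15-px-disc dilation (used to clean the raw
#' optic-disc candidates) and the 10-px-disc erosion (used to trim the
#' bright outer circle from the vessel mask).
#'
#' @param green \code{ChannelImage} (8-bit range) of the green plane.
#' @param greenThreshold numeric threshold or \code{"auto"}.
#' @param openRadius,dilateRadius,erodeRadius disc radii in pixels.
#' @param holeFill fill internal holes after border clearing.
#' @return A \code{\link{FovMasks-class}} object.
#' @export
buildFovMask <- function(green, greenThreshold = 10, openRadius = 1,
                         dilateRadius = 15, erodeRadius = 10,
                         holeFill = TRUE) {
  g <- as.matrix(green)
  thr <- if (identical(greenThreshold, "auto")) {
    iterativeThreshold(g)@threshold
  } else as.numeric(greenThreshold)
  raw <- g > thr
  if (!any(raw))
    stop("empty field of view: no pixel brighter than ", thr, " grey levels")
  fov <- as.matrix(openImage(BinaryMask(raw), makeDisc(openRadius)))
  fov <- as.matrix(clearBorderStructures(BinaryMask(fov)))
  if (holeFill) fov <- as.matrix(fillHoles(fov))
  if (!any(fov))
    stop("empty field of view after cleanup")
  fovM <- BinaryMask(fov)
  new("FovMasks", fov = fovM,
      fovDilated = dilateImage(fovM, makeDisc(dilateRadius)),
      fovEroded = erodeImage(fovM, makeDisc(erodeRadius)))
}
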