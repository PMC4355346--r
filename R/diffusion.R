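## Eight-neighbour Perona-Malik anisotropic diffusion. The red channel is
## smoothed with edge-preserving weights before the optic disc is
## thresholded: each pixel moves towards its eight neighbours with a
## conductance that vanishes across strong edges, so the disc boundary
## survives while background texture flattens.

## (row, col) offsets of the eight neighbourhood directions; row axis
## points down, so N is row - 1
.directions <- list(
  N  = c(-1L,  0L), S  = c(1L,  0L), E  = c(0L,  1L), W  = c(0L, -1L),
  NE = c(-1L,  1L), NW = c(-1L, -1L), SE = c(1L,  1L), SW = c(1L, -1L)
)

## the published 9-digit template codes, one per direction
.kernelCodes <- c(
  N = "0100-10000", S = "0000-10010", E = "0000-11000", W = "0001-10000",
  NE = "0010-10000", SE = "0000-10001", SW = "0000-10100", NW = "1000-10000"
)

#' Decode a 9-digit directional filter template
#'
#' Codes are read row-major over a 3 x 3 mask, with \code{"-1"} occupying
#' the centre position; the single \code{+1} marks the neighbour the
#' kernel differences against.
#'
#' @param code 9-entry string such as \code{"0100-10000"}.
#' @return A \code{\link{DirectionalKernel-class}} object.
#' @examples
#' decodeKernel("0100-10000")  # North: centre -1, +1 above
#' @export
decodeKernel <- function(code) {
  chars <- strsplit(code, "")[[1]]
  vals <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "-") {
      if (i == length(chars) || chars[i + 1L] != "1")
        stop("cannot decode template code '", code, "'")
      vals <- c(vals, -1L)
      i <- i + 2L
    } else if (chars[i] %in% c("0", "1")) {
      vals <- c(vals, as.integer(chars[i]))
      i <- i + 1L
    } else stop("cannot decode template code '", code, "'")
  }
  if (length(vals) != 9L || sum(vals) != 0L)
    stop("template code '", code, "' must decode to nine entries summing to 0")
  w <- matrix(vals, nrow = 3L, byrow = TRUE)
  if (w[2, 2] != -1L) stop("template code '", code, "' has no centre -1")
  pos <- which(w == 1L, arr.ind = TRUE)
  off <- c(pos[1, 1] - 2L, pos[1, 2] - 2L)
  dir <- names(Filter(function(d) all(d == off), .directions))
  new("DirectionalKernel", direction = dir, weights = w)
}

#' The eight directional kernels
#'
#' @return Named list of \code{DirectionalKernel} objects
#'   (N, S, E, W, NE, SE, SW, NW).
#' @export
directionalKernels <- function() lapply(.kernelCodes, decodeKernel)

## shift a matrix by (dr, dc) with edge replication: out(p) = x(p + d)
shiftReplicate <- function(x, dr, dc) {
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  x[ri, ci, drop = FALSE]
}

#' Directional first-difference (neighbour minus centre)
#'
#' Correlates the image with a directional kernel; with edge replication
#' the output has the input's shape and border gradients are zero.
#'
#' @param img \code{ChannelImage} or numeric matrix, at least 3 x 3.
#' @param k a \code{DirectionalKernel}.
#' @return A \code{ChannelImage} of per-pixel differences.
#' @export
directionalGradient <- function(img, k) {
  x <- as.matrix(img)
  if (nrow(x) < 3L || ncol(x) < 3L) stop("image must be at least 3 x 3")
  d <- .directions[[k@direction]]
  ChannelImage(shiftReplicate(x, d[1], d[2]) - x)
}

#' Diffusivity (kappa coefficient)
#'
#' \code{1 / (1 + (grad/kappa)^2)}: 1 at zero gradient, 1/2 at
#' \code{grad == kappa}, vanishing across strong edges. \code{kappa}
#' separates edge from non-edge gradient magnitudes.
#'
#' @param grad grey-level difference(s).
#' @param kappa positive edge scale in grey levels.
#' @return Values in (0, 1], same shape as \code{grad}.
#' @export
kappaCoefficient <- function(grad, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("kappa must be a single positive value")
  1 / (1 + (grad / kappa)^2)
}

#' Eight-neighbour anisotropic diffusion
#'
#' Explicit scheme: for each iteration,
#' \code{I <- I + psi * sum_dir C(grad_dir) * grad_dir} over the eight
#' directions, with \code{grad_dir} the neighbour-minus-centre difference
#' (edge-replicated at the frame) and \code{C} the diffusivity of
#' \code{\link{kappaCoefficient}}. With \code{psi <= 1/8} the update obeys
#' the discrete maximum principle: values never leave the input range.
#'
#' @param img \code{ChannelImage} or numeric matrix, at least 3 x 3.
#' @param params a \code{\link{diffusionParams}} object.
#' @return The diffused \code{ChannelImage} (real-valued; quantisation to
#'   8 bits happens only at image export).
#' @export
diffuse <- function(img, params = diffusionParams()) {
  x <- as.matrix(img)
  if (nrow(x) < 3L || ncol(x) < 3L) stop("image must be at least 3 x 3")
  storage.mode(x) <- "double"
  validObject(params)
  k <- params@kappa
  for (it in seq_len(params@iterations)) {
    flux <- 0
    for (d in .directions) {
      g <- shiftReplicate(x, d[1], d[2]) - x
      flux <- flux + g / (1 + (g / k)^2)
    }
    x <- x + params@psi * flux
  }
  ChannelImage(x)
}
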