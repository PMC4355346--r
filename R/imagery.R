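## Image and mask I/O plus channel extraction. All readers return
## row-major H x W (x 3) arrays of integer grey levels in [0, 255];
## all binary/raster outputs are written as lossless PNG (or PNM for
## .ppm/.pgm paths).

imageExt <- function(path) tolower(tools::file_ext(path))

## decode to an H x W (x C) array in [0, 1] using the codec matching the
## file extension
decodeRaster <- function(path) {
  if (!file.exists(path)) stop("cannot read image, file not found: ", path)
  ext <- imageExt(path)
  vals <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    ppm  = ,
    pgm  = ,
    pnm  = return(readPNM(path)),
    gif  = stop("GIF decoding is not supported; convert '", path,
                "' to PNG/TIFF/PPM first"),
    stop("unsupported image format '.", ext, "' for ", path)
  )
  # readers return [0,1]; an 8-bit source maps exactly onto k/255
  scaled <- vals * 255
  if (max(abs(scaled - round(scaled))) > 1e-6)
    stop("unsupported bit depth in ", path,
         " (intensities are not 8-bit; likely a 16-bit image)")
  a <- round(scaled)
  if (length(dim(a)) == 3L && dim(a)[3] == 2L) a <- a[, , 1L]  # grey+alpha
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3]  # drop alpha
  a
}

#' Read an 8-bit RGB fundus image
#'
#' Decodes PNG, TIFF, JPEG, or PPM/PGM rasters. Greyscale inputs are
#' replicated to three channels. Intensities are returned exactly as
#' stored (8 bits per plane); deeper bit depths raise a format error.
#'
#' @param path path to the image file.
#' @return A \code{\link{FundusImage}}.
#' @export
readFundus <- function(path) {
  a <- decodeRaster(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] != 3L)
    stop("expected 1 or 3 channels in ", path, ", got ", dim(a)[3])
  FundusImage(a)
}

#' Write a fundus image losslessly
#'
#' PNG for \code{.png} paths, binary PPM for \code{.ppm}, TIFF for
#' \code{.tif}/\code{.tiff}. Never JPEG-compresses.
#'
#' @param img a \code{FundusImage}.
#' @param path destination path; the extension selects the codec.
#' @return \code{path}, invisibly.
#' @export
writeFundus <- function(img, path) {
  stopifnot(is(img, "FundusImage"))
  ext <- imageExt(path)
  a <- img@pixels / 255
  switch(ext,
    png = png::writePNG(a, path),
    tif = ,
    tiff = tiff::writeTIFF(a, path, bits.per.sample = 8L),
    ppm = writePNM(img@pixels, path),
    stop("refusing to write format '.", ext, "' (lossless PNG/TIFF/PPM only)")
  )
  invisible(path)
}

#' Extract one colour plane
#'
#' The green channel carries the highest vessel/background contrast; the
#' optic disc is most visible in the red channel.
#'
#' @param img a \code{FundusImage}.
#' @param channel \code{"red"}, \code{"green"}, or \code{"blue"}.
#' @return A \code{\link{ChannelImage}} with the plane unchanged.
#' @export
extractChannel <- function(img, channel = c("red", "green", "blue")) {
  stopifnot(is(img, "FundusImage"))
  channel <- match.arg(channel)
  idx <- c(red = 1L, green = 2L, blue = 3L)[[channel]]
  ChannelImage(img@pixels[, , idx])
}

#' Read a binary mask image
#'
#' Any pixel with intensity strictly greater than zero (in any channel for
#' RGB inputs) maps to \code{TRUE}; DRIVE/STARE manual labels are 0/255.
#'
#' @param path path to the mask image.
#' @return A \code{\link{BinaryMask}}.
#' @export
readMaskImage <- function(path) {
  a <- decodeRaster(path)
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), max)
  BinaryMask(a > 0)
}

#' Write a binary mask as a 0/255 image
#'
#' @param mask a \code{BinaryMask} (or logical matrix).
#' @param path destination path (\code{.png} or \code{.pgm}).
#' @return \code{path}, invisibly.
#' @export
writeMaskImage <- function(mask, path) {
  m <- as.matrix(mask)
  ext <- imageExt(path)
  if (ext == "png") {
    png::writePNG(m * 1, path)
  } else if (ext %in% c("pgm", "ppm")) {
    writePNM(matrix(as.integer(m) * 255L, nrow(m), ncol(m)), path)
  } else stop("refusing to write mask format '.", ext, "'")
  invisible(path)
}

## template substitution for dataset layouts: "{id}" -> case id
fillTemplate <- function(template, id) gsub("{id}", id, template, fixed = TRUE)

defaultLayoutMaps <- function() {
  list(
    drive = list(
      image  = c("images/{id}_test.tif", "images/{id}_training.tif"),
      truth  = c("1st_manual/{id}_manual1.gif"),
      fov    = c("mask/{id}_test_mask.gif", "mask/{id}_training_mask.gif")
    ),
    stare = list(
      image = c("im{id}.ppm"),
      truth = c("labels-ah/im{id}.ah.ppm"),
      fov   = character(0)
    )
  )
}

#' Load one case from a DRIVE/STARE-style dataset directory
#'
#' File name patterns follow the published dataset layouts and can be
#' overridden through \code{layoutMap} (a list with character vectors
#' \code{image}, \code{truth}, \code{fov} of \code{"{id}"} templates
#' relative to \code{root}); overriding is needed e.g. when DRIVE's GIF
#' masks have been converted to PNG, since no GIF decoder is available.
#' Missing optional files (ground truth, FOV) yield \code{NULL}, not
#' errors.
#'
#' @param root dataset directory.
#' @param layout \code{"drive"} or \code{"stare"}.
#' @param caseId case identifier substituted into the templates
#'   (e.g. \code{"21"} for DRIVE, \code{"0001"} for STARE).
#' @param layoutMap optional template override (see above).
#' @return A list with elements \code{image} (\code{FundusImage}),
#'   \code{truth} and \code{fov} (\code{BinaryMask} or \code{NULL}).
#' @export
loadDatasetCase <- function(root, layout = c("drive", "stare"), caseId,
                            layoutMap = NULL) {
  layout <- match.arg(layout)
  lm <- defaultLayoutMaps()[[layout]]
  if (!is.null(layoutMap)) lm[names(layoutMap)] <- layoutMap
  firstExisting <- function(templates) {
    for (tpl in templates) {
      p <- file.path(root, fillTemplate(tpl, caseId))
      if (file.exists(p)) return(p)
    }
    NULL
  }
  imgPath <- firstExisting(lm$image)
  if (is.null(imgPath)) {
    tried <- file.path(root, vapply(lm$image, fillTemplate, "", id = caseId))
    stop("case image not found; expected one of: ",
         paste(tried, collapse = ", "))
  }
  truthPath <- firstExisting(lm$truth)
  fovPath <- firstExisting(lm$fov)
  list(
    image = readFundus(imgPath),
    truth = if (is.null(truthPath)) NULL else readMaskImage(truthPath),
    fov   = if (is.null(fovPath)) NULL else readMaskImage(fovPath)
  )
}
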