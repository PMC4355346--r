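## Minimal portable-anymap (PGM/PPM) codec: P2/P3 (ASCII) and P5/P6
## (binary), maxval <= 255. STARE ships its images and labels as PPM.

readPNM <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 2L) stop("not a PNM file (file too short): ", path)
  # header tokens: magic, width, height, [maxval], separated by whitespace
  # and '#' comments
  pos <- 1L
  nextToken <- function() {
    repeat {
      while (pos <= length(raw) && raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L)))
        pos <<- pos + 1L
      if (pos <= length(raw) && raw[pos] == as.raw(35L)) {  # '#'
        while (pos <= length(raw) && raw[pos] != as.raw(10L)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= length(raw) && !(raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L))))
      pos <<- pos + 1L
    if (start >= pos) stop("truncated PNM header: ", path)
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- nextToken()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path)
  w <- as.integer(nextToken())
  h <- as.integer(nextToken())
  maxval <- as.integer(nextToken())
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stop("invalid PNM dimensions in ", path)
  if (is.na(maxval) || maxval > 255L)
    stop("unsupported PNM bit depth (maxval ", maxval, ") in ", path)
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L  # single whitespace after maxval
    if (length(raw) - pos + 1L < n) stop("truncated PNM pixel data in ", path)
    vals <- as.integer(raw[pos:(pos + n - 1L)])
  } else {
    txt <- rawToChar(raw[pos:length(raw)])
    vals <- suppressWarnings(as.integer(strsplit(txt, "[ \t\r\n]+")[[1]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < n) stop("truncated PNM pixel data in ", path)
    vals <- vals[seq_len(n)]
  }
  # pixel order: rows top to bottom, channels interleaved
  if (nch == 3L) {
    a <- array(0L, dim = c(h, w, 3L))
    for (ch in 1:3)
      a[, , ch] <- matrix(vals[seq(ch, n, by = 3L)], nrow = h, ncol = w,
                          byrow = TRUE)
    a
  } else {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  }
}

writePNM <- function(pixels, path) {
  if (length(dim(pixels)) == 3L) {
    h <- dim(pixels)[1]; w <- dim(pixels)[2]
    inter <- integer(h * w * 3L)
    for (ch in 1:3)
      inter[seq(ch, length(inter), by = 3L)] <- as.integer(t(pixels[, , ch]))
    header <- sprintf("P6\n%d %d\n255\n", w, h)
  } else {
    h <- nrow(pixels); w <- ncol(pixels)
    inter <- as.integer(t(pixels))
    header <- sprintf("P5\n%d %d\n255\n", w, h)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(as.raw(inter), con)
  invisible(path)
}
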