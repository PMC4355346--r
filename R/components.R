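## Connected-component labelling and size filtering. Labelling is built
## on igraph components over the pixel-adjacency graph; vessels are thin
## diagonal structures, so 8-connectivity is the default (4 would
## fragment them).

#' Label connected components of a binary mask
#'
#' @param mask \code{BinaryMask} or logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix: 0 for background, 1..k for components
#'   (labelled in raster order of their first pixel).
#' @export
labelComponents <- function(mask, connectivity = 8) {
  m <- as.matrix(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  fg <- which(m)
  if (length(fg) == 0L) return(lab)
  vid <- integer(H * W)
  vid[fg] <- seq_along(fg)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- NULL
  for (d in offs) {
    dr <- d[1]; dc <- d[2]
    rs <- max(1L, 1L - dr):min(H, H - dr)
    cs <- max(1L, 1L - dc):min(W, W - dc)
    a <- m[rs, cs, drop = FALSE] & m[rs + dr, cs + dc, drop = FALSE]
    hit <- which(a)
    if (length(hit)) {
      # linear indices in the full matrix for both endpoints
      rr <- rs[(hit - 1L) %% length(rs) + 1L]
      cc <- cs[(hit - 1L) %/% length(rs) + 1L]
      i1 <- (cc - 1L) * H + rr
      i2 <- (cc + dc - 1L) * H + rr + dr
      edges <- rbind(edges, cbind(vid[i1], vid[i2]))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel in raster order of first occurrence
  first <- !duplicated(memb)
  remap <- integer(max(memb))
  remap[memb[first]] <- seq_len(sum(first))
  lab[fg] <- remap[memb]
  lab
}

#' Remove small connected components
#'
#' Components with fewer than \code{minSize} pixels are removed;
#' components with exactly \code{minSize} or more are kept.
#'
#' @param mask \code{BinaryMask} or logical matrix.
#' @param minSize positive integer pixel-count threshold.
#' @param connectivity 4 or 8 (default 8).
#' @return A \code{BinaryMask}.
#' @export
removeSmallComponents <- function(mask, minSize = 50, connectivity = 8) {
  if (!is.numeric(minSize) || minSize < 1) stop("minSize must be >= 1")
  m <- as.matrix(mask)
  lab <- labelComponents(m, connectivity)
  if (max(lab) == 0L) return(BinaryMask(m & FALSE))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minSize)
  BinaryMask(matrix(lab %in% keep, nrow(m), ncol(m)))
}
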