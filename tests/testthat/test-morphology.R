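test_that("disc elements contain exactly the lattice points within radius", {
  d1 <- makeDisc(1)
  expect_equal(dim(d1@footprint), c(3L, 3L))
  expect_equal(sum(d1@footprint), 5)  # plus shape
  expect_true(d1@footprint[1, 2] && d1@footprint[2, 1] && d1@footprint[2, 2])
  expect_false(d1@footprint[1, 1])

  expect_equal(sum(makeDisc(2)@footprint), 13)  # lattice points, x^2+y^2 <= 4
  # independent count for a larger radius
  r <- 7
  cnt <- sum(outer((-r:r)^2, (-r:r)^2, "+") <= r^2)
  expect_equal(sum(makeDisc(r)@footprint), cnt)
  expect_error(makeDisc(0), "positive")
})

test_that("line elements are rasterised with the exact cell count and slope", {
  h <- makeLine(10, 180)
  expect_equal(nrow(h@footprint), 1L)  # horizontal: a single row
  expect_equal(sum(h@footprint), 10)

  v <- makeLine(10, 90)
  expect_equal(ncol(v@footprint), 1L)
  expect_equal(sum(v@footprint), 10)

  d <- makeLine(10, 45)
  off <- seFootprintOffsets(d)
  expect_equal(nrow(off), 10)
  expect_true(all(off[, 1] == -off[, 2]))  # up-right diagonal
  expect_true(any(off[, 1] == 0 & off[, 2] == 0))  # passes through origin

  # every bank angle yields exactly L distinct collinear-rasterised cells
  for (a in seq(15, 180, by = 15))
    expect_equal(sum(makeLine(10, a)@footprint), 10, label = paste(a, "deg"))
})

test_that("erosion, dilation and opening match brute-force set definitions", {
  set.seed(123)
  elements <- list(makeDisc(1), makeDisc(2), makeLine(5, 90), makeLine(7, 45))
  for (rep in 1:25) {
    H <- sample(6:16, 1); W <- sample(6:16, 1)
    m <- randomMask(H, W)
    s <- elements[[sample(length(elements), 1)]]
    off <- seFootprintOffsets(s)
    er <- as.matrix(erodeImage(BinaryMask(m), s))
    di <- as.matrix(dilateImage(BinaryMask(m), s))
    expect_identical(er, oracleErode(m, off))
    expect_identical(di, oracleDilate(m, off))
    # duality: dilate(!m, s) == !erode(m, reflected s)
    sRef <- s; sRef@footprint <- s@footprint[nrow(s@footprint):1,
                                             ncol(s@footprint):1, drop = FALSE]
    expect_identical(as.matrix(dilateImage(BinaryMask(!m), sRef)),
                     !as.matrix(erodeImage(BinaryMask(m), s)))
    # extensivity ordering
    expect_true(all(er <= m) && all(m <= di))
    # opening: anti-extensive and idempotent
    op <- as.matrix(openImage(BinaryMask(m), s))
    expect_true(all(op <= m))
    expect_identical(as.matrix(openImage(BinaryMask(op), s)), op)
  }
})

test_that("greyscale erosion is a min filter with protective borders", {
  set.seed(9)
  x <- matrix(runif(144, 0, 255), 12, 12)
  s <- makeDisc(2)
  expect_equal(as.matrix(erodeImage(ChannelImage(x), s)),
               oracleErodeGrey(x, seFootprintOffsets(s)), tolerance = 1e-12)
  # all-true mask survives erosion thanks to the foreground border rule
  expect_true(all(erodeImage(BinaryMask(matrix(TRUE, 8, 8)), makeDisc(1))))
  # a single pixel cannot contain a disc
  one <- matrix(FALSE, 7, 7); one[4, 4] <- TRUE
  expect_false(any(erodeImage(BinaryMask(one), makeDisc(1))))
  # dilation of a single centre pixel stamps the plus shape
  expect_equal(sum(dilateImage(BinaryMask(one), makeDisc(1))), 5)
  expect_false(any(dilateImage(BinaryMask(matrix(FALSE, 5, 5)), makeDisc(1))))
})

test_that("opening removes speckle but keeps thick structures", {
  spot <- matrix(FALSE, 9, 9); spot[5, 5] <- TRUE
  expect_false(any(openImage(BinaryMask(spot), makeDisc(1))))
  stripe <- matrix(FALSE, 9, 9); stripe[4:6, ] <- TRUE
  off <- seFootprintOffsets(makeDisc(1))
  expect_identical(as.matrix(openImage(BinaryMask(stripe), makeDisc(1))),
                   oracleDilate(oracleErode(stripe, off), off))
  expect_true(all(as.matrix(openImage(BinaryMask(stripe),
                                      makeDisc(1)))[5, ]))
})

test_that("border clearing equals the 4-connected flood-fill oracle", {
  m <- matrix(FALSE, 8, 8)
  m[1, 1:3] <- TRUE   # touches row 1
  m[4:5, 4:5] <- TRUE # interior blob
  got <- as.matrix(clearBorderStructures(BinaryMask(m)))
  expect_false(any(got[1, ]))
  expect_true(all(got[4:5, 4:5]))

  expect_false(any(clearBorderStructures(BinaryMask(matrix(FALSE, 5, 5)))))

  set.seed(31)
  for (rep in 1:25) {
    r <- randomMask(sample(6:16, 1), sample(6:16, 1), 0.4)
    expect_identical(as.matrix(clearBorderStructures(BinaryMask(r))),
                     oracleClearBorder(r))
  }
})

test_that("diagonal-only contact does not clear interior structures", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE   # border blob
  m[2, 2] <- TRUE   # diagonal neighbour: NOT 4-connected to it
  got <- as.matrix(clearBorderStructures(BinaryMask(m)))
  expect_false(got[1, 1])
  expect_true(got[2, 2])
})

test_that("component labelling agrees with BFS and EBImage oracles", {
  set.seed(77)
  for (rep in 1:15) {
    m <- randomMask(sample(6:14, 1), sample(6:14, 1), 0.45)
    for (conn in c(4, 8)) {
      lab <- labelComponents(m, conn)
      ref <- oracleLabel(m, conn)
      # same partition (labels may be permuted)
      expect_equal(max(lab), max(ref))
      if (max(lab) > 0) {
        pairs <- unique(cbind(lab[m], ref[m]))
        expect_equal(nrow(pairs), max(ref))
      }
    }
  }
  # independent cross-check against EBImage's 4-connected labeller
  skip_if_not_installed("EBImage")
  set.seed(78)
  m <- randomMask(12, 12, 0.45)
  ours <- labelComponents(m, 4)
  ebi <- EBImage::bwlabel(t(m))  # EBImage images are (x, y)-indexed
  expect_equal(max(ours), max(ebi))
})

test_that("components below the size threshold are removed, at and above kept", {
  m <- matrix(FALSE, 40, 40)
  m[2:8, 2:8] <- TRUE                  # 49 px
  m[12:18, 12:18] <- TRUE; m[12, 19] <- TRUE  # 50 px
  m[22:28, 22:28] <- TRUE; m[22, 29:30] <- TRUE  # 51 px
  out <- as.matrix(removeSmallComponents(m, minSize = 50))
  expect_false(any(out[2:8, 2:8]))
  expect_true(all(out[12:18, 12:18]))
  expect_true(all(out[22:28, 22:28]))

  expect_false(any(removeSmallComponents(matrix(FALSE, 5, 5), 10)))

  set.seed(55)
  for (rep in 1:10) {
    r <- randomMask(14, 14, 0.4)
    got <- as.matrix(removeSmallComponents(r, minSize = 4, connectivity = 8))
    lab <- oracleLabel(r, 8)
    sizes <- tabulate(lab[lab > 0])
    ref <- matrix(lab > 0 & sizes[pmax(lab, 1)] >= 4, nrow(r), ncol(r))
    expect_identical(got, ref)
  }
})

test_that("hole filling closes enclosed background only", {
  m <- matrix(FALSE, 9, 9)
  m[3:7, 3:7] <- TRUE; m[5, 5] <- FALSE  # ring with one hole
  filled <- as.matrix(fillHoles(m))
  expect_true(filled[5, 5])
  expect_equal(sum(filled), sum(m) + 1)
  skip_if_not_installed("EBImage")
  expect_identical(filled, t(EBImage::fillHull(t(m)) > 0))
})

test_that("FOV construction recovers a bright disc and orders its variants", {
  H <- 128
  ctr <- (H + 1) / 2
  d2 <- outer((seq_len(H) - ctr)^2, (seq_len(H) - ctr)^2, "+")
  g <- matrix(3, H, H); g[d2 <= 40^2] <- 120
  fm <- buildFovMask(ChannelImage(g))
  fov <- as.matrix(fm@fov)
  truth <- d2 <= 40^2
  expect_lt(sum(xor(fov, truth)) / sum(truth), 0.02)  # +/- 1 px boundary band
  # morphological ordering of the triple
  expect_true(all(as.matrix(fm@fovEroded) <= fov))
  expect_true(all(fov <= as.matrix(fm@fovDilated)))
  # all-dark image: empty-FOV error
  expect_error(buildFovMask(ChannelImage(matrix(4, 32, 32))), "empty field")
})

test_that("direct FOV recipe equals the double-inversion route on a fundus-like fixture", {
  # The published recipe zeroes pixels > 10 and inverts, so its binary
  # mask is (green > 10) | (green == 0): true surround zeros come along
  # as speckle and are what the 1-px opening and border clearing remove.
  # After those steps the direct (green > 10) form must coincide.
  H <- 96; ctr <- (H + 1) / 2
  set.seed(61)
  d2 <- outer((seq_len(H) - ctr)^2, (seq_len(H) - ctr)^2, "+")
  g <- matrix(sample(0:8, H * H, TRUE), H, H)   # noisy dark surround with 0s
  g[d2 <= 30^2] <- sample(60:140, sum(d2 <= 30^2), TRUE)
  route <- function(raw) {
    m <- as.matrix(openImage(BinaryMask(raw), makeDisc(1)))
    as.matrix(clearBorderStructures(BinaryMask(m)))
  }
  direct <- route(g > 10)
  doubleInv <- route(g > 10 | g == 0)
  # surround zeros 4-adjacent to the disc rim survive the opening, so the
  # two forms may differ inside a 1-px rim band but nowhere else
  diffs <- xor(direct, doubleInv)
  rim <- as.matrix(dilateImage(BinaryMask(direct), makeDisc(1))) & !direct
  expect_true(all(!diffs | rim))
  expect_lt(sum(diffs) / sum(direct), 0.01)
})
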