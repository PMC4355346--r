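test_that("published directional template codes decode to the expected masks", {
  expect_equal(decodeKernel("0100-10000")@weights,
               matrix(c(0, 1, 0, 0, -1, 0, 0, 0, 0), 3, byrow = TRUE))
  expect_equal(decodeKernel("0100-10000")@direction, "N")
  expect_equal(decodeKernel("0000-11000")@weights,
               matrix(c(0, 0, 0, 0, -1, 1, 0, 0, 0), 3, byrow = TRUE))
  expect_equal(decodeKernel("0000-11000")@direction, "E")
  expect_equal(decodeKernel("1000-10000")@weights,
               matrix(c(1, 0, 0, 0, -1, 0, 0, 0, 0), 3, byrow = TRUE))
  expect_equal(decodeKernel("1000-10000")@direction, "NW")

  ks <- directionalKernels()
  expect_setequal(vapply(ks, function(k) k@direction, ""),
                  c("N", "S", "E", "W", "NE", "NW", "SE", "SW"))
  for (k in ks) {
    expect_equal(sum(k@weights), 0)
    expect_equal(k@weights[2, 2], -1)
  }
  expect_error(decodeKernel("0100-1000"), "nine entries")
  expect_error(decodeKernel("01x0-10000"), "cannot decode")
})

test_that("directional gradients equal neighbour minus centre", {
  x <- matrix(0, 3, 3); x[2, 2] <- 10; x[1, 2] <- 14
  gN <- directionalGradient(ChannelImage(x), decodeKernel("0100-10000"))
  expect_equal(as.matrix(gN)[2, 2], 4)  # 14 - 10

  # constant image: zero gradient in every direction
  const <- ChannelImage(matrix(5, 4, 4))
  for (k in directionalKernels())
    expect_true(all(directionalGradient(const, k) == 0))

  # random image vs brute-force loop, all eight directions
  set.seed(1)
  y <- matrix(runif(64, 0, 255), 8, 8)
  dirs <- list(N = c(-1, 0), S = c(1, 0), E = c(0, 1), W = c(0, -1),
               NE = c(-1, 1), NW = c(-1, -1), SE = c(1, 1), SW = c(1, -1))
  ks <- directionalKernels()
  for (nm in names(dirs)) {
    got <- as.matrix(directionalGradient(ChannelImage(y), ks[[nm]]))
    expect_equal(got, oracleDirGrad(y, dirs[[nm]][1], dirs[[nm]][2]),
                 tolerance = 1e-12, label = nm)
  }
})

test_that("diffusivity hits its closed-form anchor points", {
  expect_identical(kappaCoefficient(0, 30), 1)
  expect_identical(kappaCoefficient(30, 30), 0.5)
  expect_identical(kappaCoefficient(90, 30), 0.1)
  expect_error(kappaCoefficient(1, -2), "positive")
  # vectorised, always in (0, 1]
  g <- seq(-300, 300, by = 7)
  v <- kappaCoefficient(g, 30)
  expect_true(all(v > 0 & v <= 1))
})

test_that("diffusion fixes constant images and matches the loop oracle", {
  const <- matrix(42, 5, 5)
  out <- diffuse(ChannelImage(const), diffusionParams(iterations = 7))
  expect_equal(as.matrix(out), const, tolerance = 1e-12)

  set.seed(99)
  for (rep in 1:5) {
    x <- matrix(runif(256, 0, 255), 16, 16)
    got <- as.matrix(diffuse(ChannelImage(x),
                             diffusionParams(psi = 1 / 8, kappa = 30,
                                             iterations = 5)))
    expect_equal(got, oracleDiffuse(x, 1 / 8, 30, 5), tolerance = 1e-9)
    # max principle at psi = 1/8
    expect_gte(min(got), min(x) - 1e-9)
    expect_lte(max(got), max(x) + 1e-9)
  }
})

test_that("single hot pixel stays within range after one step", {
  x <- matrix(0, 9, 9); x[5, 5] <- 255
  got <- as.matrix(diffuse(ChannelImage(x), diffusionParams(iterations = 1)))
  expect_equal(got, oracleDiffuse(x, 1 / 8, 30, 1), tolerance = 1e-9)
  expect_true(all(got >= 0 & got <= 255))
})

test_that("strong edges persist while weak edges smooth away", {
  kappa <- 30
  mk <- function(step) {
    x <- matrix(100, 16, 32)
    x[, 17:32] <- 100 + step
    x
  }
  run <- function(step) as.matrix(diffuse(ChannelImage(mk(step)),
                                          diffusionParams(kappa = kappa,
                                                          iterations = 10)))
  # |step| = 10 kappa: plateau interiors move by < 1% of the step
  strong <- run(10 * kappa)
  expect_lt(max(abs(strong[, 1:8] - 100)), 0.01 * 10 * kappa)
  expect_lt(max(abs(strong[, 25:32] - (100 + 10 * kappa))), 0.01 * 10 * kappa)
  # |step| = 0.1 kappa: contrast across the interface drops by > 50%
  weak <- run(0.1 * kappa)
  contrast <- mean(weak[, 17]) - mean(weak[, 16])
  expect_lt(contrast, 0.5 * 0.1 * kappa)
})

test_that("mean is conserved on symmetric inputs", {
  # symmetric bump: fluxes cancel pairwise, mean drift stays at rounding level
  x <- matrix(10, 15, 15)
  x[6:10, 6:10] <- 60
  out <- as.matrix(diffuse(ChannelImage(x), diffusionParams(iterations = 8)))
  expect_equal(mean(out), mean(x), tolerance = 1e-9)
})

test_that("invalid diffusion parameters are rejected", {
  expect_error(diffusionParams(psi = 0), "psi")
  expect_error(diffusionParams(psi = 1.5), "psi")
  expect_error(diffusionParams(kappa = -1), "kappa")
  expect_error(diffusionParams(iterations = 0), "iterations")
  expect_error(diffuse(ChannelImage(matrix(1, 2, 2))), "3 x 3")
})
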