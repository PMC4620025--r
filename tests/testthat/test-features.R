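test_that("raw feature has the canonical 54-element geometry and is monotone", {
  set.seed(31)
  p <- matrix(runif(32 * 32, 0.1, 0.9), 32, 32)

  v <- raw_feature(p)
  expect_length(v, 54)
  expect_equal(attr(v, "feature_name"), "RAW")

  # purity: identical input, identical output
  expect_identical(raw_feature(p), raw_feature(p + 0))

  # constant patch maps to a constant vector
  vc <- raw_feature(matrix(0.4, 20, 20))
  expect_equal(unclass(vc), rep(0.4, 54), tolerance = 1e-9, ignore_attr = TRUE)

  # a brighter-everywhere patch maps to an entrywise >= vector
  v2 <- raw_feature(pmin(p + 0.05, 1))
  expect_true(all(v2 >= v - 1e-12))

  # other geometries follow the configured shape
  expect_length(raw_feature(p, out_shape = c(8, 8)), 64)
})

test_that("HoG concentrates on edge orientation and matches a brute-force oracle", {
  # constant patch: zero gradients, all-zero histograms
  expect_true(all(hog_feature(matrix(0.5, 24, 24)) == 0))

  # vertical step edge: gradient is horizontal (orientation bin 1 of [0, pi))
  edge <- cbind(matrix(0.1, 24, 12), matrix(0.9, 24, 12))
  v <- hog_feature(edge, cells = c(2, 2), orientations = 8)
  m <- matrix(v, nrow = 8)   # columns = cells within the single 2x2 block
  nz <- which(rowSums(m) > 1e-9)
  expect_equal(nz, 1L)

  # independent per-pixel oracle (plain loops), including a rotated patch
  brute_hog <- function(p, cells, orientations) {
    h <- nrow(p); w <- ncol(p)
    gx <- matrix(0, h, w); gy <- matrix(0, h, w)
    for (i in 1:h) for (j in 2:(w - 1)) gx[i, j] <- (p[i, j + 1] - p[i, j - 1]) / 2
    for (i in 2:(h - 1)) for (j in 1:w) gy[i, j] <- (p[i + 1, j] - p[i - 1, j]) / 2
    hist <- array(0, c(cells[1], cells[2], orientations))
    for (i in 1:h) {
      for (j in 1:w) {
        mag <- sqrt(gx[i, j]^2 + gy[i, j]^2)
        if (mag > 0) {
          ori <- atan2(gy[i, j], gx[i, j]) %% pi
          b <- min(floor(ori / (pi / orientations)), orientations - 1) + 1
          ci <- min(ceiling(i / (h / cells[1])), cells[1])
          cj <- min(ceiling(j / (w / cells[2])), cells[2])
          hist[ci, cj, b] <- hist[ci, cj, b] + mag
        }
      }
    }
    out <- c()
    for (br in 1:(cells[1] - 1)) {
      for (bc in 1:(cells[2] - 1)) {
        block <- c()
        for (bi in br:(br + 1)) for (bj in bc:(bc + 1)) {
          block <- c(block, hist[bi, bj, ])
        }
        # package layout: orientation fastest, then cell col, then cell row
        block <- as.vector(aperm(array(block, c(orientations, 2, 2)), c(1, 2, 3)))
        nrm <- sqrt(sum(block^2))
        if (nrm > 0) block <- block / nrm
        out <- c(out, block)
      }
    }
    out
  }
  set.seed(7)
  p <- matrix(runif(24 * 24), 24, 24)
  rot <- t(p)[, rev(seq_len(24))]  # p rotated by 90 degrees
  for (q in list(p, rot, edge)) {
    got <- hog_feature(q, cells = c(3, 3), orientations = 8)
    want <- brute_hog(q, c(3, 3), 8)
    expect_equal(unclass(got), want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("Gabor-bank feature has the configured length and orientation selectivity", {
  # length = scales * orientations * grid cells
  set.seed(3)
  p <- matrix(runif(32 * 32), 32, 32)
  v <- gist_feature(p, scales = 4, orientations = 8, grid = c(4, 4))
  expect_length(v, 512)

  # constant patch: zero-mean kernels give (near-)zero response
  expect_lt(max(abs(gist_feature(matrix(0.7, 32, 32)))), 1e-8)

  # stripes varying along rows are best matched by the aligned orientation
  stripes <- matrix(rep(0.5 + 0.4 * sin(2 * pi * (1:32) / 6), 32), 32, 32)
  vs <- gist_feature(stripes, scales = 3, orientations = 4, grid = c(2, 2))
  resp <- array(vs, c(4, 4 * 3))  # grid cells x (orientation within scale)
  band_means <- sapply(1:4, function(o) {
    mean(vs[rep(seq(0, 2) * 16, each = 4) + (o - 1) * 4 + rep(1:4, 3)])
  })
  # orientations are pi*(o-1)/4; stripes along rows match theta = pi/2 (o = 3)
  expect_equal(which.max(band_means), 3L)
})

test_that("dense SIFT descriptor is fixed-length, contrast-invariant, zero on flat input", {
  set.seed(11)
  p <- matrix(runif(32 * 32, 0.2, 0.8), 32, 32)
  v <- sift_feature(p)
  expect_length(v, 128)

  # constant patch: zero descriptor
  expect_true(all(sift_feature(matrix(0.3, 32, 32)) == 0))

  # doubling intensities leaves the normalized descriptor unchanged
  v2 <- sift_feature(p * 0.5 + 0.25)  # affine remap preserves gradients up to scale
  expect_equal(unclass(v), unclass(v2), tolerance = 1e-9, ignore_attr = TRUE)

  # length independent of patch size
  expect_length(sift_feature(matrix(runif(24 * 24), 24, 24)), 128)
})

test_that("feature assembly stacks, standardizes and rejects mixed input", {
  set.seed(19)
  vecs <- lapply(1:10, function(i) raw_feature(matrix(runif(16 * 16), 16, 16)))
  m <- assemble_feature_matrix(vecs, standardize = FALSE)
  expect_equal(dim(m), c(54L, 10L))
  expect_equal(attr(m, "feature_name"), "RAW")

  ms <- assemble_feature_matrix(vecs, standardize = TRUE)
  expect_equal(rowMeans(ms), rep(0, 54), tolerance = 1e-12)
  sds <- apply(ms, 1, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-12))

  # held-out transform reuses the training centre/scale
  new <- do.call(cbind, lapply(vecs[1:3], as.numeric))
  tr <- apply_standardization(new, ms)
  expect_equal(tr, ms[, 1:3], ignore_attr = TRUE)

  expect_error(assemble_feature_matrix(list()), "empty")
  hogs <- lapply(1:2, function(i) hog_feature(matrix(runif(24 * 24), 24, 24)))
  expect_error(assemble_feature_matrix(c(vecs, hogs)), "mixed")
})
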