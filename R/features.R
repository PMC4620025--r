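#' Resampled raw-intensity feature
#'
#' The pixel-wise intensity descriptor: the ROI patch is resampled to
#' `out_shape` by bilinear interpolation, flattened row-major, and clamped
#' to \[0, 1\] (frames already live on the \[0, 1\] intensity scale, so no
#' per-patch rescaling is applied — per-patch min-max would destroy the
#' ordering of absolute intensities between patches and is undefined on
#' constant patches). The default `9 x 6` geometry gives the canonical
#' 54-element vector.
#'
#' @param patch A `roi_patch` or bare numeric matrix.
#' @param out_shape Resample target `(rows, cols)`; default `c(9, 6)`.
#' @return A numeric vector of length `prod(out_shape)` with attribute
#'   `feature_name = "RAW"`.
#' @export
raw_feature <- function(patch, out_shape = c(9, 6)) {
  p <- patch_matrix(patch)
  small <- as.matrix(EBImage::resize(EBImage::Image(p),
                                     w = out_shape[1], h = out_shape[2]))
  v <- as.vector(t(matrix(small, out_shape[1], out_shape[2])))  # row-major
  v <- pmin(pmax(v, 0), 1)
  feature_vec(v, "RAW")
}

patch_matrix <- function(patch) {
  if (inherits(patch, "roi_patch")) patch$patch else as.matrix(patch)
}

feature_vec <- function(v, name) {
  structure(as.numeric(v), feature_name = name)
}

# Central-difference gradients on the patch interior; borders are zero so
# gradient content commutes with 90-degree rotations of square patches.
patch_gradients <- function(p) {
  h <- nrow(p); w <- ncol(p)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  if (w >= 3) gx[, 2:(w - 1)] <- (p[, 3:w] - p[, 1:(w - 2)]) / 2
  if (h >= 3) gy[2:(h - 1), ] <- (p[3:h, ] - p[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy,
       mag = sqrt(gx^2 + gy^2),
       ori = atan2(gy, gx) %% pi)   # unsigned orientation in [0, pi)
}

#' Histogram-of-oriented-gradients feature
#'
#' Classic HoG shape descriptor: unsigned gradient orientations (range
#' `[0, pi)`) are histogrammed per cell of a `cells` grid, weighted by
#' gradient magnitude; overlapping 2 x 2 blocks of cells are L2-normalized
#' and concatenated. Output length is
#' `(cells[1]-1) * (cells[2]-1) * 4 * orientations`.
#'
#' @param patch ROI patch or numeric matrix, larger than one cell.
#' @param cells Cell grid `(rows, cols)`, default `c(3, 3)`.
#' @param orientations Orientation bins over `[0, pi)`, default 8.
#' @return Numeric feature vector with `feature_name = "HoG"`.
#' @export
hog_feature <- function(patch, cells = c(3, 3), orientations = 8) {
  p <- patch_matrix(patch)
  if (nrow(p) < cells[1] * 2 || ncol(p) < cells[2] * 2) {
    abort("patch must be larger than one HoG cell")
  }
  g <- patch_gradients(p)
  bin <- pmin(floor(g$ori / (pi / orientations)), orientations - 1) + 1
  row_cell <- pmin(ceiling(seq_len(nrow(p)) / (nrow(p) / cells[1])), cells[1])
  col_cell <- pmin(ceiling(seq_len(ncol(p)) / (ncol(p) / cells[2])), cells[2])
  hist <- array(0, c(cells[1], cells[2], orientations))
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (g$mag[i, j] > 0) {
        k <- c(row_cell[i], col_cell[j], bin[i, j])
        hist[k[1], k[2], k[3]] <- hist[k[1], k[2], k[3]] + g$mag[i, j]
      }
    }
  }
  out <- numeric(0)
  for (br in seq_len(cells[1] - 1)) {
    for (bc in seq_len(cells[2] - 1)) {
      block <- as.vector(aperm(hist[br:(br + 1), bc:(bc + 1), , drop = FALSE],
                               c(3, 2, 1)))
      nrm <- sqrt(sum(block^2))
      if (nrm > 0) block <- block / nrm
      out <- c(out, block)
    }
  }
  feature_vec(out, "HoG")
}

# Zero-mean Gabor kernel (real part), unit L2 norm.
gabor_kernel <- function(size, wavelength, theta, sigma = 0.56 * wavelength,
                         gamma_aspect = 0.8) {
  half <- (size - 1) / 2
  y <- matrix(rep(-half:half, size), size, size)
  x <- t(y)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  k <- exp(-(xr^2 + gamma_aspect^2 * yr^2) / (2 * sigma^2)) *
    cos(2 * pi * xr / wavelength)
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

#' Gabor filter-bank (GIST-style) feature
#'
#' A scene-texture descriptor: the patch is filtered with a bank of
#' zero-mean Gabor kernels (`scales` wavelengths x `orientations`
#' directions) and the absolute responses are averaged over a `grid[1] x
#' grid[2]` spatial grid. Length is `scales * orientations * prod(grid)`; a
#' constant patch gives a (near-)zero vector because the kernels have no DC
#' response.
#'
#' @param patch ROI patch or numeric matrix.
#' @param scales Number of wavelengths (default 4).
#' @param orientations Number of directions (default 8).
#' @param grid Spatial averaging grid (default `c(4, 4)`).
#' @return Numeric feature vector with `feature_name = "GIST"`.
#' @export
gist_feature <- function(patch, scales = 4, orientations = 8, grid = c(4, 4)) {
  p <- patch_matrix(patch)
  waves <- 3 * 1.6^(seq_len(scales) - 1)
  thetas <- pi * (seq_len(orientations) - 1) / orientations
  row_cell <- pmin(ceiling(seq_len(nrow(p)) / (nrow(p) / grid[1])), grid[1])
  col_cell <- pmin(ceiling(seq_len(ncol(p)) / (ncol(p) / grid[2])), grid[2])
  out <- numeric(0)
  ksize <- min(11, 2 * floor((min(dim(p)) - 1) / 2) + 1)
  for (wl in waves) {
    for (th in thetas) {
      kern <- gabor_kernel(ksize, wl, th)
      resp <- abs(as.matrix(EBImage::filter2(EBImage::Image(p), kern)))
      cellmeans <- sapply(seq_len(grid[2]), function(cj) {
        sapply(seq_len(grid[1]), function(ci) {
          mean(resp[row_cell == ci, col_cell == cj])
        })
      })
      out <- c(out, as.vector(cellmeans))
    }
  }
  feature_vec(out, "GIST")
}

#' Dense SIFT-style descriptor
#'
#' A keypoint-free variant of the SIFT descriptor: at each point of an
#' `r x c` grid over the patch, gradient magnitudes in a local window are
#' accumulated into 4 x 4 spatial bins x 8 orientation bins (signed
#' orientations over `[0, 2*pi)`), giving the classic 128-element
#' descriptor; descriptors are contrast-normalized (L2, clipped at 0.2,
#' renormalized) and averaged over the grid points. Doubling the patch
#' intensities leaves the output unchanged; a constant patch gives the zero
#' vector.
#'
#' @param patch ROI patch or numeric matrix.
#' @param grid Descriptor grid `(r, c)`, default `c(2, 2)`.
#' @return Numeric vector of length 128 with `feature_name = "SIFT"`.
#' @export
sift_feature <- function(patch, grid = c(2, 2)) {
  p <- patch_matrix(patch)
  gx <- matrix(0, nrow(p), ncol(p)); gy <- gx
  if (ncol(p) >= 3) gx[, 2:(ncol(p) - 1)] <- (p[, 3:ncol(p)] - p[, 1:(ncol(p) - 2)]) / 2
  if (nrow(p) >= 3) gy[2:(nrow(p) - 1), ] <- (p[3:nrow(p), ] - p[1:(nrow(p) - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) %% (2 * pi)
  obin <- pmin(floor(ori / (pi / 4)), 7) + 1
  win <- floor(min(dim(p)) / (max(grid) + 1))
  win <- max(win, 4)
  centres_r <- round(seq(win, nrow(p) - win + 1, length.out = grid[1]))
  centres_c <- round(seq(win, ncol(p) - win + 1, length.out = grid[2]))
  acc <- numeric(128)
  n_desc <- 0L
  for (cr in centres_r) {
    for (cc in centres_c) {
      rr <- max(1, cr - win + 1):min(nrow(p), cr + win)
      cc2 <- max(1, cc - win + 1):min(ncol(p), cc + win)
      desc <- array(0, c(4, 4, 8))
      for (i in rr) {
        for (j in cc2) {
          if (mag[i, j] > 0) {
            sr <- min(ceiling((i - rr[1] + 1) / (length(rr) / 4)), 4)
            sc <- min(ceiling((j - cc2[1] + 1) / (length(cc2) / 4)), 4)
            desc[sr, sc, obin[i, j]] <- desc[sr, sc, obin[i, j]] + mag[i, j]
          }
        }
      }
      v <- as.vector(desc)
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) {
        v <- pmin(v / nrm, 0.2)
        v <- v / sqrt(sum(v^2))
      }
      acc <- acc + v
      n_desc <- n_desc + 1L
    }
  }
  feature_vec(acc / n_desc, "SIFT")
}

#' Assemble feature vectors into a sample matrix
#'
#' Column-stacks per-nucleus feature vectors into the d x N matrix fed to
#' sparse coding (columns are samples). All vectors must share the same
#' extractor tag and length. With `standardize = TRUE` each row is centred
#' and scaled to unit standard deviation (constant rows are centred only);
#' the centring/scale used is recorded in attributes so held-out data can
#' be transformed identically with [apply_standardization()].
#'
#' @param vectors List of feature vectors from the extractors above.
#' @param standardize Per-row standardization (default `TRUE`).
#' @return A d x N numeric matrix with attributes `feature_name` and, when
#'   standardized, `center` and `scale`.
#' @export
assemble_feature_matrix <- function(vectors, standardize = TRUE) {
  if (length(vectors) == 0) abort("cannot assemble an empty feature set")
  names_ <- unique(vapply(vectors, function(v) attr(v, "feature_name") %||% NA_character_,
                          character(1)))
  lens <- unique(lengths(vectors))
  if (length(names_) != 1 || anyNA(names_)) abort("mixed or missing feature names")
  if (length(lens) != 1) abort("feature vectors have mixed lengths")
  m <- do.call(cbind, lapply(vectors, as.numeric))
  attr(m, "feature_name") <- names_
  if (standardize) {
    ctr <- rowMeans(m)
    scl <- apply(m, 1, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    m <- (m - ctr) / scl
    attr(m, "feature_name") <- names_
    attr(m, "center") <- ctr
    attr(m, "scale") <- scl
  }
  m
}

#' Apply a recorded standardization to new feature vectors
#'
#' @param m A d x N matrix of un-standardized features.
#' @param reference The standardized training matrix whose `center`/`scale`
#'   attributes should be reused.
#' @return The transformed matrix.
#' @export
apply_standardization <- function(m, reference) {
  ctr <- attr(reference, "center")
  scl <- attr(reference, "scale")
  if (is.null(ctr) || is.null(scl)) return(m)
  out <- (m - ctr) / scl
  attr(out, "feature_name") <- attr(m, "feature_name")
  out
}
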