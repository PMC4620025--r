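#' Binarize a grayscale frame
#'
#' Thresholds a frame to foreground/background: a pixel is foreground iff
#' its intensity is at or above the threshold. The threshold is derived by
#' Otsu's method (`method = "otsu"`) or given directly (`method = "manual"`).
#' A morphological opening with a disc structuring element is applied
#' afterwards to remove speckle; set `opening_radius = 0` to skip it.
#'
#' Frames are numeric matrices on the \[0, 1\] intensity scale (see
#' [read_tiff_stack()] / [generate_cell_frames()]); a `manual_threshold` is
#' given on the same scale.
#'
#' @param frame Numeric matrix in \[0, 1\].
#' @param method `"otsu"` (default) or `"manual"`.
#' @param manual_threshold Threshold intensity; required iff
#'   `method = "manual"`.
#' @param opening_radius Disc radius in pixels of the post-threshold opening
#'   (default 2).
#' @return A logical matrix of the same shape. A constant frame under Otsu
#'   yields an all-`FALSE` mask with a warning (degenerate threshold).
#' @export
binarize <- function(frame, method = c("otsu", "manual"),
                     manual_threshold = NULL, opening_radius = 2) {
  method <- match.arg(method)
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0) {
    abort("`frame` must be a nonempty numeric matrix")
  }
  thr <- if (method == "manual") {
    if (is.null(manual_threshold)) abort("manual_threshold required for method = \"manual\"")
    manual_threshold
  } else {
    if (diff(range(frame)) == 0) {
      warn("constant frame: Otsu threshold is degenerate, returning an empty mask")
      return(matrix(FALSE, nrow(frame), ncol(frame)))
    }
    EBImage::otsu(EBImage::Image(frame), range = range(frame))
  }
  mask <- frame >= thr
  if (opening_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    mask <- EBImage::opening(EBImage::Image(mask * 1), brush) > 0.5
    mask <- matrix(as.logical(mask), nrow(frame), ncol(frame))
  }
  mask
}

# Local maxima of the distance map with greedy minimum-distance suppression:
# candidate pixels that equal the running maximum of their neighbourhood are
# accepted in decreasing height order if no accepted peak lies within
# min_dist. Contiguous plateau maxima are first collapsed to one candidate.
find_seeds <- function(dist, min_dist) {
  win <- max(3, 2 * floor(min_dist / 2) + 1)
  mx <- EBImage::dilate(EBImage::Image(dist),
                        EBImage::makeBrush(win, shape = "box"))
  cand_mask <- dist > 0 & abs(dist - as.matrix(mx)) < 1e-9
  if (!any(cand_mask)) return(matrix(numeric(0), 0, 2))
  plateaus <- EBImage::bwlabel(EBImage::Image(cand_mask * 1))
  plateaus <- matrix(as.integer(plateaus), nrow(dist), ncol(dist))
  cand <- do.call(rbind, lapply(seq_len(max(plateaus)), function(l) {
    idx <- which(plateaus == l, arr.ind = TRUE)
    colMeans(idx)  # plateau centroid
  }))
  heights <- dist[cbind(round(cand[, 1]), round(cand[, 2]))]
  ord <- order(-heights)
  kept <- matrix(numeric(0), 0, 2)
  for (i in ord) {
    p <- cand[i, , drop = FALSE]
    if (nrow(kept) == 0 ||
        all(sqrt(rowSums(sweep(kept, 2, as.numeric(p))^2)) >= min_dist)) {
      kept <- rbind(kept, p)
    }
  }
  kept
}

#' Segment nuclei by seeded watershed
#'
#' Splits the binary foreground into nuclei: the Euclidean distance
#' transform of the mask is computed, seeds are placed at its local maxima
#' (suppressed so accepted seeds are at least `min_seed_distance` apart),
#' and the mask is partitioned by watershed flooding from the seeds
#' (seeded region growing on the distance map via `EBImage::propagate`,
#' which splits touching objects along the distance-transform ridge).
#' Regions smaller than `min_area` pixels are removed and labels are
#' recompacted to the contiguous range `1..n`.
#'
#' @param frame The source frame (used only for shape checking).
#' @param mask Logical matrix from [binarize()].
#' @param min_seed_distance Minimum seed separation in pixels (default 5).
#' @param min_area Minimum region area in pixels (default 10).
#' @param fill_holes Fill enclosed holes in the mask before the distance
#'   transform (default `TRUE`); textured nuclei otherwise fragment into
#'   spurious maxima.
#' @return An integer label matrix; 0 is background. An empty mask yields
#'   an all-zero mask (0 regions), not an error.
#' @export
segment_nuclei <- function(frame, mask, min_seed_distance = 5, min_area = 10,
                           fill_holes = TRUE) {
  if (!all(dim(mask) == dim(frame))) abort("mask shape must match frame")
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  if (fill_holes) {
    mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  }
  dist <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  seeds_xy <- find_seeds(dist, min_seed_distance)
  seed_img <- matrix(0L, nrow(mask), ncol(mask))
  if (nrow(seeds_xy) > 0) {
    seed_img[cbind(round(seeds_xy[, 1]), round(seeds_xy[, 2]))] <- seq_len(nrow(seeds_xy))
  }
  labels <- EBImage::propagate(EBImage::Image(dist), EBImage::Image(seed_img),
                               mask = EBImage::Image(mask * 1), lambda = 1e4)
  labels <- matrix(as.integer(labels), nrow(mask), ncol(mask))
  compact_labels(prune_small(labels, min_area))
}

prune_small <- function(labels, min_area) {
  if (max(labels) == 0) return(labels)
  sizes <- tabulate(labels, nbins = max(labels))
  drop <- which(sizes > 0 & sizes < min_area)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}

compact_labels <- function(labels) {
  present <- sort(unique(labels[labels > 0]))
  if (!length(present)) return(labels)
  remap <- integer(max(present))
  remap[present] <- seq_along(present)
  out <- labels
  out[out > 0] <- remap[out[out > 0]]
  out
}

#' Region properties of a label mask
#'
#' @param labels Integer label matrix.
#' @return A tibble with `cell_id`, `area`, centroid `row`/`col`, and the
#'   half-open, 0-based bounding box (`min_row`, `min_col`, `max_row`,
#'   `max_col`).
#' @export
region_table <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  dplyr::bind_rows(lapply(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    tibble::tibble(cell_id = id, area = nrow(idx),
                   row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1,
                   min_row = min(idx[, 1]) - 1L, min_col = min(idx[, 2]) - 1L,
                   max_row = max(idx[, 1]), max_col = max(idx[, 2]))
  }))
}

#' Extract fixed-size ROI patches around segmented nuclei
#'
#' For each labeled region, a square window centred on the bounding-box
#' centre with side `max(bbox height, bbox width)` (plus a small margin) is
#' cropped from the frame, padded with `background_level` where it extends
#' past the frame edge, and resampled to `roi_shape` by bilinear
#' interpolation.
#'
#' @param frame Numeric frame matrix.
#' @param labels Integer label matrix matching `frame`.
#' @param roi_shape `(rows, cols)` of the output patches (default `c(32, 32)`).
#' @param background_level Pad value; defaults to the frame's median
#'   intensity.
#' @param margin Fractional enlargement of the crop window (default 0.15).
#' @return A list of `roi_patch` objects (`cell_id`, `patch`, `centroid`,
#'   `bbox`); empty list for an empty label mask.
#' @export
extract_rois <- function(frame, labels, roi_shape = c(32, 32),
                         background_level = NULL, margin = 0.15) {
  if (!all(dim(labels) == dim(frame))) abort("labels shape must match frame")
  regs <- region_table(labels)
  if (nrow(regs) == 0) return(list())
  bg <- background_level %||% median(frame)
  lapply(seq_len(nrow(regs)), function(i) {
    r <- regs[i, ]
    side <- ceiling(max(r$max_row - r$min_row, r$max_col - r$min_col) * (1 + margin))
    side <- max(side, 4)
    cr <- (r$min_row + r$max_row) / 2   # 0-based bbox centre
    cc <- (r$min_col + r$max_col) / 2
    r0 <- round(cr - side / 2)
    c0 <- round(cc - side / 2)
    win <- matrix(bg, side, side)
    rr <- (r0 + 1):(r0 + side)          # 1-based frame rows
    cc2 <- (c0 + 1):(c0 + side)
    in_r <- rr >= 1 & rr <= nrow(frame)
    in_c <- cc2 >= 1 & cc2 <= ncol(frame)
    win[in_r, in_c] <- frame[rr[in_r], cc2[in_c]]
    patch <- as.matrix(EBImage::resize(EBImage::Image(win),
                                       w = roi_shape[1], h = roi_shape[2]))
    structure(list(cell_id = r$cell_id,
                   patch = matrix(patch, roi_shape[1], roi_shape[2]),
                   centroid = c(row = r$row, col = r$col),
                   bbox = c(min_row = r$min_row, min_col = r$min_col,
                            max_row = r$max_row, max_col = r$max_col)),
              class = "roi_patch")
  })
}
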