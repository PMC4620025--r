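#' Cell-cycle phase labels
#'
#' The four phases recognized by the pipeline, in canonical order. Used as
#' factor levels everywhere a phase label appears.
#' @export
phase_levels <- c("interphase", "prophase", "metaphase", "anaphase")

# Per-phase shape parameters of the default synthetic classes. a/b are
# semi-axis ranges in pixels, texture the multiplicative speckle amplitude,
# peak the peak-intensity range. The classes are designed to differ in cues
# that survive the crop-and-resample ROI normalization (which removes
# absolute size) and random orientation: interphase is a dim near-flat
# plateau, prophase a bright strongly speckled blob, metaphase a dark
# elongated body with a very bright central band (bimodal intensities), and
# anaphase two bright cores joined by a dim waist.
default_class_shapes <- function() {
  list(
    interphase = list(a = c(14, 18), b = c(12, 16), texture = 0.05,
                      peak = c(0.50, 0.60), kind = "smooth"),
    prophase   = list(a = c(11, 14), b = c(9, 12),  texture = 0.40,
                      peak = c(0.85, 0.95), kind = "textured"),
    metaphase  = list(a = c(17, 21), b = c(5, 7),   texture = 0.05,
                      peak = c(0.45, 0.55), kind = "band"),
    anaphase   = list(a = c(7, 9),  b = c(7, 9),    texture = 0.05,
                      peak = c(0.80, 0.90), kind = "double")
  )
}

#' Configuration for synthetic microscopy frames
#'
#' Describes the synthetic time-lapse: frames of noisy background with
#' `n_cells_per_frame` nucleus-like blobs whose phase class is drawn
#' uniformly from the four cell-cycle phases. The four classes are rendered
#' as anisotropic Gaussian-shaded ellipses that differ in eccentricity,
#' area and internal texture: interphase nuclei are large and smooth,
#' prophase nuclei carry strong speckle texture, metaphase nuclei are
#' elongated with a bright central band, and anaphase nuclei are two
#' adjacent sub-blobs. These morphologies are stand-ins chosen so that all
#' four feature families can separate the classes; they do not attempt to
#' model phase-contrast optics.
#'
#' @param frame_height,frame_width Frame size in pixels.
#' @param n_cells_per_frame Nuclei per frame (0 gives pure background).
#' @param n_frames Number of frames.
#' @param class_shape_params Per-phase shape list; see
#'   `topocode:::default_class_shapes()` for the expected structure. Must
#'   name exactly the four phases.
#' @param noise_sd Additive Gaussian noise, on the \[0, 1\] intensity scale
#'   (default 0.02).
#' @param background_level Background intensity (default 0.1).
#' @param min_separation Minimum centroid-to-centroid distance in pixels
#'   (default 40).
#' @param seed Integer seed.
#' @return A list of class `synth_image_config`.
#' @export
synth_image_config <- function(frame_height = 256, frame_width = 256,
                               n_cells_per_frame = 6, n_frames = 12,
                               class_shape_params = default_class_shapes(),
                               noise_sd = 0.02, background_level = 0.1,
                               min_separation = 40, seed = 1L) {
  if (!identical(sort(names(class_shape_params)), sort(phase_levels))) {
    abort("class_shape_params must define exactly the four phases")
  }
  structure(list(
    frame_height = stopifnot_scalar_count(frame_height, "frame_height"),
    frame_width = stopifnot_scalar_count(frame_width, "frame_width"),
    n_cells_per_frame = stopifnot_scalar_count(n_cells_per_frame,
                                               "n_cells_per_frame", min = 0),
    n_frames = stopifnot_scalar_count(n_frames, "n_frames"),
    class_shape_params = class_shape_params,
    noise_sd = stopifnot_positive(noise_sd, "noise_sd", strict = FALSE),
    background_level = stopifnot_positive(background_level, "background_level",
                                          strict = FALSE),
    min_separation = stopifnot_positive(min_separation, "min_separation",
                                        strict = FALSE),
    seed = as.integer(seed)
  ), class = "synth_image_config")
}

# Rejection-sample n centres pairwise >= min_sep apart, >= margin from the
# border. Errors after 1000 failed draws (placement infeasible).
place_centroids <- function(n, h, w, min_sep, margin) {
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  if (h - 2 * margin < 1 || w - 2 * margin < 1) {
    abort("frame too small for the requested nuclei")
  }
  pts <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L) {
      abort(sprintf("could not place %d nuclei with min_separation after 1000 attempts", n))
    }
    cand <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
    if (placed == 0L ||
        all(sqrt(rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2, cand)^2)) >= min_sep)) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  pts
}

# Render one nucleus into `img`, returning list(img, mask) for its footprint.
render_nucleus <- function(img, centre, phase, shp) {
  h <- nrow(img); w <- ncol(img)
  a <- runif(1, shp$a[1], shp$a[2])
  b <- runif(1, shp$b[1], shp$b[2])
  theta <- runif(1, 0, pi)
  peak <- runif(1, shp$peak[1], shp$peak[2])
  ext <- ceiling(max(a, b) * (if (shp$kind == "double") 2.6 else 1.3)) + 2
  rr <- max(1, floor(centre[1] - ext)):min(h, ceiling(centre[1] + ext))
  cc <- max(1, floor(centre[2] - ext)):min(w, ceiling(centre[2] + ext))
  dy <- outer(rr - centre[1], rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - centre[2])
  # rotate into the ellipse frame
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy

  if (shp$kind == "double") {
    # two bright cores along the u axis, overlapping just enough to stay
    # connected, with a visibly dim waist between them
    off <- 1.7 * a
    r2a <- ((u - off / 2)^2 + v^2) / a^2
    r2b <- ((u + off / 2)^2 + v^2) / a^2
    bridge <- 0.45 * peak * exp(-0.5 * (v / (a / 2))^2) * (abs(u) <= off / 2)
    inside <- pmin(r2a, r2b) <= 1 | bridge > 0.25 * peak
    shade <- pmax(peak * pmax(exp(-3 * r2a), exp(-3 * r2b)), bridge)
  } else {
    r2 <- (u / a)^2 + (v / b)^2
    inside <- r2 <= 1
    shade <- switch(shp$kind,
      smooth = peak * (0.85 + 0.15 * exp(-1.6 * r2)),      # near-flat plateau
      band = peak * (0.8 + 0.2 * exp(-1.6 * r2)) +
        0.9 * peak * exp(-0.5 * (v / (b / 3))^2) * (abs(u) <= a),
      peak * exp(-1.6 * r2))
  }
  if (shp$texture > 0) {
    speckle <- matrix(runif(length(shade), 1 - shp$texture, 1 + shp$texture),
                      nrow(shade), ncol(shade))
    shade <- shade * speckle
  }
  shade[!inside] <- 0
  img[rr, cc] <- pmax(img[rr, cc], shade)
  list(img = img, rows = rr, cols = cc, inside = inside)
}

#' Generate synthetic labeled microscopy frames
#'
#' Produces `n_frames` ground-truth scenes: a noisy grayscale frame on the
#' \[0, 1\] intensity scale (quantized to the 16-bit grid so TIFF round-trips
#' are exact), a label mask (0 = background, 1..n = nuclei) and a per-cell
#' tibble of phase labels and centroids. Phase classes are drawn uniformly;
#' centroid placement uses rejection sampling under `min_separation` and
#' errors out after 1000 failed attempts. Deterministic given the seed.
#'
#' @param config A [synth_image_config()].
#' @return A list of `topo_scene` objects, each with elements `frame`
#'   (numeric matrix in \[0, 1\], `bit_depth` attribute 16), `label_mask`
#'   (integer matrix) and `cells` (tibble: `cell_id`, `phase`, `row`,
#'   `col`).
#' @examples
#' scenes <- generate_cell_frames(synth_image_config(n_frames = 1, seed = 7))
#' scenes[[1]]$cells
#' @export
generate_cell_frames <- function(config = synth_image_config()) {
  cfg <- config
  margin <- ceiling(max(vapply(cfg$class_shape_params,
                               function(s) max(s$a[2], s$b[2]), numeric(1))) * 1.6) + 3
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_frames), function(f) {
      img <- matrix(cfg$background_level, cfg$frame_height, cfg$frame_width)
      labels <- matrix(0L, cfg$frame_height, cfg$frame_width)
      centres <- place_centroids(cfg$n_cells_per_frame, cfg$frame_height,
                                 cfg$frame_width, cfg$min_separation, margin)
      phases <- if (cfg$n_cells_per_frame > 0) {
        phase_levels[sample.int(4, cfg$n_cells_per_frame, replace = TRUE)]
      } else {
        character(0)
      }
      for (i in seq_len(cfg$n_cells_per_frame)) {
        res <- render_nucleus(img, centres[i, ], phases[i],
                              cfg$class_shape_params[[phases[i]]])
        img <- res$img
        sub <- labels[res$rows, res$cols]
        sub[res$inside] <- i
        labels[res$rows, res$cols] <- sub
      }
      if (cfg$noise_sd > 0) {
        img <- img + matrix(rnorm(length(img), sd = cfg$noise_sd),
                            nrow(img), ncol(img))
      }
      img <- pmin(pmax(img, 0), 1)
      img <- round(img * 65535) / 65535   # 16-bit grid: exact TIFF round-trip
      attr(img, "bit_depth") <- 16L
      structure(list(
        frame = img,
        label_mask = labels,
        cells = tibble::tibble(
          cell_id = seq_len(cfg$n_cells_per_frame),
          phase = factor(phases, levels = phase_levels),
          row = centres[, "row"], col = centres[, "col"])
      ), class = "topo_scene")
    })
  })
}

#' Tabulate the ground truth of a scene list
#'
#' @param scenes A list of scenes from [generate_cell_frames()].
#' @return A tibble with `frame_id`, `cell_id`, `phase`, `row`, `col`.
#' @export
scene_ground_truth <- function(scenes) {
  dplyr::bind_rows(lapply(seq_along(scenes), function(i) {
    dplyr::mutate(scenes[[i]]$cells, frame_id = i, .before = 1)
  }))
}
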