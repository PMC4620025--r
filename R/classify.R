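#' RBF kernel
#'
#' Similarity between two feature vectors. The default (`form = "rbf"`) is
#' the Gaussian radial basis kernel `exp(-||u - v||^2 / delta)`, positive
#' definite and decreasing in distance. `form = "literal"` returns the bare
#' scaled squared distance `||u - v||^2 / delta`, which increases with
#' distance and is not positive definite; it is kept only for fidelity
#' experiments with that parameterization and is not used by the
#' classifier.
#'
#' @param u,v Numeric vectors of equal length.
#' @param delta Kernel width, `> 0`.
#' @param form `"rbf"` (default) or `"literal"`.
#' @return A scalar.
#' @export
rbf_kernel <- function(u, v, delta, form = c("rbf", "literal")) {
  form <- match.arg(form)
  if (length(u) != length(v)) abort("u and v must have equal length")
  delta <- stopifnot_positive(delta, "delta")
  d2 <- sum((u - v)^2)
  if (form == "rbf") exp(-d2 / delta) else d2 / delta
}

#' Kernel matrix on sample columns
#'
#' @param m d x N matrix (columns are samples).
#' @param delta Kernel width.
#' @return The N x N RBF kernel matrix.
#' @export
rbf_kernel_matrix <- function(m, delta) {
  nsq <- colSums(m^2)
  d2 <- outer(nsq, nsq, "+") - 2 * crossprod(m)
  exp(-pmax(d2, 0) / delta)
}

#' Configuration for the phase classifier
#'
#' Neither the kernel width nor the soft-margin weight is canonical; both
#' are package defaults, tunable here. `delta = NULL` selects the median
#' heuristic: the median pairwise squared distance between training
#' columns.
#'
#' @param delta Kernel width (squared feature-space units), or `NULL` for
#'   the median heuristic.
#' @param C_svm Soft-margin weight (default 10).
#' @param seed Integer seed (kept for interface symmetry; the underlying
#'   solver is deterministic).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(delta = NULL, C_svm = 10, seed = 1L) {
  if (!is.null(delta)) delta <- stopifnot_positive(delta, "delta")
  structure(list(delta = delta,
                 C_svm = stopifnot_positive(C_svm, "C_svm"),
                 seed = as.integer(seed)),
            class = "svm_config")
}

median_sq_dist <- function(m, max_pairs = 2000L) {
  N <- ncol(m)
  if (N < 2) return(1)
  pairs <- utils::combn(min(N, 64L), 2)
  cols <- if (N > 64L) round(seq(1, N, length.out = 64L)) else seq_len(N)
  d2 <- apply(pairs, 2, function(p) sum((m[, cols[p[1]]] - m[, cols[p[2]]])^2))
  max(median(d2), 1e-8)
}

#' Train a one-vs-rest RBF-kernel SVM on phase labels
#'
#' Fits one binary soft-margin SVM per class (that class against the rest,
#' via libsvm) with the Gaussian kernel `exp(-||u - v||^2 / delta)`.
#' Prediction assigns the class with the highest one-vs-rest decision
#' value. Deterministic given the data.
#'
#' @param features d x N matrix, columns are samples.
#' @param labels Vector of phase labels, one per column; at least two
#'   distinct classes must be present.
#' @param cfg An [svm_config()].
#' @return A `topo_svm` model object.
#' @export
train_svm <- function(features, labels, cfg = svm_config()) {
  if (!is.matrix(features)) features <- as.matrix(features)
  labels <- as.character(labels)
  if (length(labels) != ncol(features)) abort("one label per feature column required")
  classes <- intersect(phase_levels, unique(labels))
  if (length(classes) == 0) classes <- sort(unique(labels))
  if (length(unique(labels)) < 2) abort("training needs at least two classes")
  delta <- cfg$delta %||% median_sq_dist(features)
  dat <- t(features)
  fits <- lapply(classes, function(cls) {
    y <- factor(ifelse(labels == cls, "pos", "rest"), levels = c("pos", "rest"))
    fit <- e1071::svm(dat, y, type = "C-classification", kernel = "radial",
                      gamma = 1 / delta, cost = cfg$C_svm, scale = FALSE)
    # orient decision values so positive means `cls`
    dv <- attr(predict(fit, dat, decision.values = TRUE), "decision.values")[, 1]
    flip <- mean(dv[y == "pos"]) < mean(dv[y == "rest"])
    list(fit = fit, flip = flip)
  })
  structure(list(fits = fits, classes = classes, delta = delta,
                 config = cfg, dim = nrow(features)),
            class = "topo_svm")
}

# Highest decision value wins; near-ties (within 1e-9) go to the earliest
# class in canonical order.
choose_label <- function(decision, classes) {
  apply(decision, 1, function(dv) {
    best <- max(dv)
    classes[which(dv >= best - 1e-9)[1]]
  })
}

#' Predict phase labels
#'
#' @param object A `topo_svm` model.
#' @param features d x N matrix with the training feature dimension.
#' @param ... Unused.
#' @return A factor of labels (levels = the model's class list) with the
#'   N x n_classes decision-value matrix in attribute `decision`.
#' @export
predict.topo_svm <- function(object, features, ...) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) != object$dim) abort("feature dimension does not match the trained model")
  if (ncol(features) == 0) abort("no samples to predict (zero columns)")
  dat <- t(features)
  decision <- vapply(object$fits, function(f) {
    dv <- attr(predict(f$fit, dat, decision.values = TRUE), "decision.values")[, 1]
    if (f$flip) -dv else dv
  }, numeric(nrow(dat)))
  decision <- matrix(decision, nrow = nrow(dat),
                     dimnames = list(NULL, object$classes))
  labs <- choose_label(decision, object$classes)
  structure(factor(labs, levels = object$classes), decision = decision)
}
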