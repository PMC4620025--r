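#' Read a single-channel TIFF stack
#'
#' Reads an 8- or 16-bit grayscale TIFF (single frame or multi-page stack)
#' into a list of numeric matrices on the \[0, 1\] intensity scale, pages in
#' file order, with the source bit depth preserved in the `bit_depth`
#' attribute of every frame. Multi-channel (e.g. RGB) files are rejected.
#'
#' @param path Path to a TIFF file.
#' @return A list of numeric matrices.
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(pg) {
    if (length(dim(pg)) == 3 && dim(pg)[3] > 1) {
      abort(sprintf("unsupported TIFF variant: %d-channel image (grayscale required)",
                    dim(pg)[3]))
    }
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    bits <- attr(pg, "bits.per.sample") %||% 16L
    if (!bits %in% c(8L, 16L)) {
      abort(sprintf("unsupported TIFF variant: %d bits per sample", bits))
    }
    m <- matrix(as.numeric(pg), nrow(pg), ncol(pg))
    attr(m, "bit_depth") <- as.integer(bits)
    m
  })
}

#' Write frames as a TIFF stack
#'
#' Writes a list of \[0, 1\] frame matrices as an uncompressed multi-page
#' TIFF at the given bit depth (default: each frame's `bit_depth`
#' attribute, falling back to 16).
#'
#' @param frames A frame matrix or list of frame matrices.
#' @param path Output path.
#' @param bits_per_sample 8 or 16; `NULL` uses each frame's attribute.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, bits_per_sample = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  bits <- bits_per_sample %||% (attr(frames[[1]], "bit_depth") %||% 16L)
  tiff::writeTIFF(lapply(frames, function(f) pmin(pmax(f, 0), 1)),
                  path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Write label masks as a 16-bit TIFF
#'
#' Integer labels are stored as intensities `label / 65535`, exact for up
#' to 65535 regions.
#' @param masks Integer label matrix or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(masks, path) {
  if (is.matrix(masks)) masks <- list(masks)
  tiff::writeTIFF(lapply(masks, function(m) m / 65535),
                  path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read label masks from a 16-bit TIFF written by [write_label_tiff()]
#' @param path Path.
#' @return A list of integer label matrices.
#' @export
read_label_tiff <- function(path) {
  lapply(read_tiff_stack(path), function(m) {
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  })
}

matrix_header <- function(m, tag) {
  c(tag %||% attr(m, "feature_name") %||% "matrix", nrow(m), ncol(m))
}

#' Write a numeric matrix (dictionary, codes, features) to disk
#'
#' Two containers: `format = "binary"` is a small headered raw container
#' (magic `TCMX`, a tag string, the dimensions, then the doubles in column
#' order) that round-trips bit-exactly; `format = "text"` is
#' tab-separated with a one-line `# tag nrow ncol` header and 17
#' significant digits, round-tripping to full double precision.
#'
#' @param m Numeric matrix with finite entries.
#' @param path Output path.
#' @param format `"binary"` or `"text"`.
#' @param tag Optional tag stored in the header (defaults to the matrix's
#'   `feature_name` attribute, else `"matrix"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("binary", "text"), tag = NULL) {
  format <- match.arg(format)
  if (!is.matrix(m)) m <- as.matrix(m)
  if (!all(is.finite(m))) abort("matrix entries must be finite")
  hdr <- matrix_header(m, tag)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("TCMX"), con)
    tag_raw <- charToRaw(hdr[1])
    writeBin(length(tag_raw), con, size = 4L)
    writeBin(tag_raw, con)
    writeBin(as.integer(hdr[2:3]), con, size = 4L)
    writeBin(as.vector(m), con, size = 8L)
  } else {
    lines <- c(sprintf("# %s %s %s", hdr[1], hdr[2], hdr[3]),
               apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path Path to the container; the format is detected from the
#'   magic/header.
#' @return The matrix, with the stored tag in attribute `tag`.
#' @export
read_matrix <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 5) abort("not a matrix container: file missing or too short")
  con <- file(path, "rb")
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (identical(magic, "TCMX")) {
    on.exit(close(con))
    tlen <- readBin(con, "integer", 1L, size = 4L)
    tag <- rawToChar(readBin(con, "raw", tlen))
    dims <- readBin(con, "integer", 2L, size = 4L)
    if (any(dims <= 0) || length(dims) != 2) abort("corrupt matrix header")
    vals <- readBin(con, "double", prod(dims), size = 8L)
    if (length(vals) != prod(dims)) abort("matrix payload shorter than its header claims")
    m <- matrix(vals, dims[1], dims[2])
    attr(m, "tag") <- tag
    return(m)
  }
  close(con)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# ")) abort("not a matrix container (missing header)")
  hdr <- strsplit(sub("^# ", "", first), " ")[[1]]
  if (length(hdr) != 3) abort("corrupt matrix header")
  dims <- as.integer(hdr[2:3])
  body <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                            colClasses = "numeric")
  m <- as.matrix(body)
  dimnames(m) <- NULL
  if (!all(dim(m) == dims)) abort("matrix payload does not match its header")
  attr(m, "tag") <- hdr[1]
  m
}

#' Write an optimization or pipeline table as delimited text
#' @param df A data frame (list-columns are flattened to comma strings).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_txt <- function(df, path) {
  df <- as.data.frame(lapply(df, function(col) {
    if (is.list(col)) vapply(col, function(x) paste(x, collapse = ","), character(1)) else col
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
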