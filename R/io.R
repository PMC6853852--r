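#' Read a grayscale B-scan from TIFF or PNG
#'
#' 8- and 16-bit grayscale images are loaded with intensities preserved
#' exactly at native bit depth (`L` = 256 or 65536); nothing is rescaled.
#' RGB input is an error unless `convert_rgb = TRUE`, in which case channels
#' are averaged.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param convert_rgb Average RGB channels instead of erroring.
#' @return An `oct_bscan`.
#' @export
read_bscan <- function(path, convert_rgb = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    px <- img
    scale <- 1
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    px <- img
    scale <- 2^bits - 1
  } else {
    stop("unsupported format '", ext, "': use grayscale TIFF or PNG")
  }
  if (length(dim(px)) == 3L) {
    if (!convert_rgb)
      stop("format error: multi-channel image; pass convert_rgb = TRUE to average")
    px <- (px[, , 1L] + px[, , 2L] + px[, , 3L]) / 3
  }
  bscan(round(px * scale), L = 2^bits)
}

#' Write a B-scan to TIFF or PNG
#'
#' Continuous intensities are rounded to the image's grey-level grid on
#' export; 16-bit depth is preserved. `read_bscan(write_bscan(x))` is the
#' identity for integer-valued scans.
#'
#' @param image An `oct_bscan`.
#' @param path Destination ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_bscan <- function(image, path) {
  image <- as_bscan(image)
  bits <- if (image$L > 256) 16L else 8L
  v <- round(image$pixels) / (2^bits - 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v, path, bits.per.sample = bits)
  } else if (ext == "png") {
    png::writePNG(v, path)
  } else {
    stop("unsupported format '", ext, "': use TIFF or PNG")
  }
  invisible(path)
}

#' Write boundary rows to CSV
#'
#' One row per image column, eight columns headed by the boundary labels.
#' Rows are exported 0-based, top-left origin, in ORIGINAL (pre-crop) image
#' coordinates: the segmentation's `crop_offset` is added back.
#'
#' @param x An `oct_segmentation`, or a `W x 8` matrix of 1-based rows
#'   already in the original frame.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(x, path) {
  m <- if (inherits(x, "oct_segmentation"))
    boundary_matrix(x, original_coords = TRUE) else as.matrix(x)
  if (ncol(m) != 8L) stop("expected 8 boundary columns")
  colnames(m) <- boundary_labels()
  utils::write.csv(as.data.frame(m - 1), path, row.names = FALSE)
  invisible(path)
}

#' Read boundary rows from CSV
#'
#' Validates the 8-label header and returns 1-based rows in the original
#' image frame (the stored values are 0-based).
#'
#' @param path CSV written by [write_boundaries()].
#' @return Numeric `W x 8` matrix with boundary-label column names.
#' @export
read_boundaries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(boundary_labels(), names(df))
  if (length(missing))
    stop("boundary CSV schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  as.matrix(df[, boundary_labels()]) + 1
}

#' Write a color overlay PNG of segmented boundaries
#'
#' Renders the B-scan as grayscale and draws each of the 8 boundaries in a
#' distinct color for visual quality control.
#'
#' @param image The `oct_bscan` the segmentation was computed on (same
#'   frame: pass the cropped image for a cropped-frame segmentation).
#' @param seg An `oct_segmentation`.
#' @param path Destination PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(image, seg, path) {
  image <- as_bscan(image)
  H <- nrow(image$pixels)
  W <- ncol(image$pixels)
  g <- image$pixels / (image$L - 1)
  arr <- array(rep(g, 3L), dim = c(H, W, 3L))
  cols <- grDevices::col2rgb(c("red", "orange", "yellow", "green",
                               "cyan", "blue", "magenta", "white")) / 255
  m <- boundary_matrix(seg, original_coords = FALSE)
  for (k in seq_len(8L)) {
    r <- pmin(pmax(round(m[, k]), 1L), H)
    for (ch in 1:3)
      arr[cbind(r, seq_len(W), ch)] <- cols[ch, k]
  }
  png::writePNG(arr, path)
  invisible(path)
}
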