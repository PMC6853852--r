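#' Construct a B-scan image object
#'
#' A B-scan is a single cross-sectional OCT image stored as a numeric matrix
#' with rows indexing axial depth (row 1 = shallowest, nearest the vitreous)
#' and columns indexing lateral position. Intensities live on the grey-level
#' scale `[0, L - 1]`; `L` is 256 for 8-bit and 65536 for 16-bit scans.
#' Intermediate processing keeps intensities as doubles; quantization happens
#' only on image export.
#'
#' @param pixels Numeric matrix of non-negative intensities, rows = depth.
#' @param L Integer grey-level count (256 for 8-bit, 65536 for 16-bit).
#' @param crop_offset Number of rows already removed from the top of the
#'   original scan; used to report boundary positions in original coordinates.
#' @return An object of class `oct_bscan`.
#' @seealso [crop_top()], [read_bscan()], [fhh_enhance()]
#' @examples
#' img <- bscan(matrix(c(0, 50, 100, 200), 2, 2))
#' dim(img)
#' @export
bscan <- function(pixels, L = 256, crop_offset = 0L) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("a B-scan needs at least 2 rows and 2 columns")
  if (L < 2) stop("`L` must be at least 2")
  if (anyNA(pixels)) stop("`pixels` contains missing values")
  if (min(pixels) < 0 || max(pixels) > L - 1)
    stop("intensities must lie in [0, L - 1]")
  structure(
    list(pixels = pixels, L = L, crop_offset = as.integer(crop_offset)),
    class = "oct_bscan"
  )
}

#' @export
dim.oct_bscan <- function(x) dim(x$pixels)

#' @export
print.oct_bscan <- function(x, ...) {
  cat(sprintf(
    "<oct_bscan> %d x %d, L = %d, crop_offset = %d, range [%.6g, %.6g]\n",
    nrow(x$pixels), ncol(x$pixels), x$L, x$crop_offset,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Test or coerce B-scan objects
#'
#' @param x A matrix or `oct_bscan`.
#' @param ... Passed to [bscan()] when coercing a matrix.
#' @return `as_bscan()` returns an `oct_bscan`; `is_bscan()` a logical.
#' @export
as_bscan <- function(x, ...) {
  if (inherits(x, "oct_bscan")) return(x)
  bscan(x, ...)
}

#' @rdname as_bscan
#' @export
is_bscan <- function(x) inherits(x, "oct_bscan")

#' Crop low-signal rows from the top of a B-scan
#'
#' Acquisition leaves a band of low signal above the inner limiting membrane;
#' removing the top fraction of rows before segmentation avoids spurious
#' graph paths there. The number of rows removed is recorded in
#' `crop_offset` so boundaries can be exported in original image coordinates.
#'
#' @param image An `oct_bscan`.
#' @param fraction Fraction of the image height to remove, in `[0, 0.5)`.
#' @return The cropped `oct_bscan` with an updated `crop_offset`.
#' @examples
#' img <- bscan(matrix(runif(100 * 20, 0, 255), 100, 20))
#' cropped <- crop_top(img, 0.15)
#' nrow(cropped$pixels)   # 85
#' cropped$crop_offset    # 15
#' @export
crop_top <- function(image, fraction = 0.15) {
  image <- as_bscan(image)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 0.5)
    stop("`fraction` must be a single number in [0, 0.5)")
  n <- floor(fraction * nrow(image$pixels))
  if (n == 0L) return(image)
  bscan(image$pixels[-seq_len(n), , drop = FALSE], L = image$L,
        crop_offset = image$crop_offset + n)
}
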