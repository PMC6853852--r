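#' Specification of a synthetic B-scan phantom
#'
#' Describes a piecewise-layered axial reflectivity profile with known
#' per-column interface rows, emulating the features of macular SD-OCT
#' B-scans that matter to gradient-based segmentation: bright NFL, IS-OS
#' complex and RPE bands, darker nuclear layers, multiplicative correlated
#' speckle and vertical vessel shadows. Default interfaces are gently
#' sloped/bowed low-order polynomials with an optional foveal dip; default
#' reflectivities keep headroom below `L - 1` so speckle rarely clips.
#'
#' @param height,width Phantom dimensions in pixels.
#' @param base_rows Named or ordered vector of 8 interface rows at the
#'   nominal (untilted) position, vitreous to choroid.
#' @param tilt Lateral tilt: total row shift from the left to the right
#'   edge, applied rigidly to all interfaces (px).
#' @param bow Quadratic bowing: row shift of the lateral edges relative to
#'   the center, applied rigidly (px).
#' @param foveal_dip Depth of an optional central dip (px) applied to the
#'   inner interfaces (full at ILM, fading to zero at IS-OS); 0 disables it.
#' @param reflectivities Mean grey level of background (vitreous), the 7
#'   layers, and choroid — 9 values, in `[0, L - 1]`.
#' @param L Grey-level count.
#' @param speckle_looks Gamma-speckle looks parameter `L_s` (severity;
#'   larger = milder, variance of the raw noise field is `1 / L_s`).
#' @param vessels List of vessel shadows, each a list with `center` (column),
#'   `width` (px), `attenuation` in `(0, 1]`, and optional `start_row`.
#' @param seed RNG seed used by [simulate_bscan()].
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(height = 256, width = 512,
                         base_rows = c(ILM = 60, `NFL-GCL` = 80,
                                       `IPL-INL` = 110, `INL-OPL` = 130,
                                       `OPL-ONL` = 148, `IS-OS` = 185,
                                       `OS-RPE` = 200, `RPE-Choroid` = 215),
                         tilt = 8, bow = 10, foveal_dip = 0,
                         reflectivities = c(background = 8, NFL = 160,
                                            `GCL+IPL` = 75, INL = 40,
                                            OPL = 85, `ONL+IS` = 30,
                                            OS = 145, RPE = 175,
                                            choroid = 25),
                         L = 256, speckle_looks = 4,
                         vessels = list(
                           list(center = round(0.3 * width), width = 12,
                                attenuation = 0.55),
                           list(center = round(0.7 * width), width = 16,
                                attenuation = 0.65)),
                         seed = 1L) {
  if (length(base_rows) != 8L) stop("need 8 interface rows")
  if (length(reflectivities) != 9L)
    stop("need 9 reflectivities: background, 7 layers, choroid")
  if (any(reflectivities < 0) || any(reflectivities > L - 1))
    stop("reflectivities must lie in [0, L - 1]")
  if (speckle_looks < 1) stop("`speckle_looks` must be >= 1")
  for (v in vessels) {
    if (v$center < 1 || v$center > width) stop("vessel center outside image")
    if (v$attenuation <= 0 || v$attenuation > 1)
      stop("vessel attenuation must lie in (0, 1]")
  }
  x <- seq(-0.5, 0.5, length.out = width)
  offset <- tilt * x + bow * (x^2 - 0.25)
  dipw <- exp(-(x / 0.08)^2)
  fade <- c(1, 0.9, 0.7, 0.5, 0.3, 0, 0, 0)   # dip fades out by IS-OS
  rows <- vapply(seq_len(8L), function(k) {
    round(base_rows[[k]] + offset + foveal_dip * fade[k] * dipw)
  }, numeric(width))
  colnames(rows) <- boundary_labels()
  if (any(apply(rows, 1L, function(r) any(diff(r) < 2))))
    stop("interface profiles must keep >= 2 px separation everywhere")
  if (min(rows) < 2 || max(rows) > height - 1)
    stop("interface profiles leave the image")
  structure(list(height = height, width = width, boundaries = rows,
                 reflectivities = reflectivities, L = L,
                 speckle_looks = speckle_looks, vessels = vessels,
                 seed = seed),
            class = "phantom_spec")
}

#' Render the noise-free phantom image
#'
#' Paints each column's axial profile piecewise-constant from the interface
#' rows: rows above ILM are background (vitreous), the band from each
#' interface (inclusive) to the next (exclusive) is one layer, rows from
#' RPE-Choroid down are choroid. The exact interface rows are the ground
#' truth returned alongside.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (an `oct_bscan`) and `boundaries` (the
#'   `W x 8` ground-truth row matrix).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  H <- spec$height
  W <- spec$width
  rowmat <- matrix(seq_len(H), H, W)
  li <- matrix(1L, H, W)
  for (k in seq_len(8L))
    li <- li + (rowmat >= matrix(spec$boundaries[, k], H, W, byrow = TRUE))
  px <- matrix(spec$reflectivities[li], H, W)
  list(image = bscan(px, L = spec$L), boundaries = spec$boundaries)
}

#' Add multiplicative correlated speckle
#'
#' OCT speckle is non-Gaussian, multiplicative and neighborhood-correlated.
#' Each pixel is multiplied by a unit-mean gamma-distributed factor (shape
#' `looks`, rate `looks`) whose field is first smoothed with a 3x3 box to
#' introduce short-range spatial correlation; smoothing preserves the unit
#' mean, so expected pixel values are unchanged. Output is clipped to
#' `[0, L - 1]`.
#'
#' @param image An `oct_bscan`.
#' @param looks Gamma looks parameter `L_s >= 1`; variance of the raw field
#'   is `1 / L_s`, so the noise vanishes as `L_s` grows.
#' @param seed Optional RNG seed.
#' @return The speckled `oct_bscan`.
#' @export
add_speckle <- function(image, looks = 4, seed = NULL) {
  image <- as_bscan(image)
  if (looks < 1) stop("`looks` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  H <- nrow(image$pixels)
  W <- ncol(image$pixels)
  field <- matrix(stats::rgamma(H * W, shape = looks, rate = looks), H, W)
  field <- box_smooth3(field)
  px <- pmin(pmax(image$pixels * field, 0), image$L - 1)
  bscan(px, L = image$L, crop_offset = image$crop_offset)
}

# 3x3 box mean with replicated borders (separable passes)
box_smooth3 <- function(m) {
  pass <- function(m) {
    up <- rbind(m[1L, , drop = FALSE], m[-nrow(m), , drop = FALSE])
    dn <- rbind(m[-1L, , drop = FALSE], m[nrow(m), , drop = FALSE])
    (up + m + dn) / 3
  }
  t(pass(t(pass(m))))
}

#' Add vertical vessel shadows
#'
#' Retinal blood vessels sit in the inner layers and cast attenuation
#' shadows down the remaining depth of the scan. Each vessel multiplies the
#' intensities of its column band, below its `start_row`, by a smooth
#' lateral Gaussian attenuation profile that reaches the given `attenuation`
#' factor at the vessel center and 1 far from it. Shadows change intensity
#' only; ground-truth boundary rows are unaffected.
#'
#' @param image An `oct_bscan`.
#' @param vessels List of vessels as in [phantom_spec()]; each may carry a
#'   `start_row` (default 1 = whole column).
#' @return The shadowed `oct_bscan`.
#' @export
add_vessel_shadows <- function(image, vessels) {
  image <- as_bscan(image)
  H <- nrow(image$pixels)
  W <- ncol(image$pixels)
  px <- image$pixels
  for (v in vessels) {
    if (v$center < 1 || v$center > W) stop("vessel center outside image")
    sr <- if (is.null(v$start_row)) 1L else max(1L, round(v$start_row))
    sigma <- v$width / 2
    fac <- 1 - (1 - v$attenuation) * exp(-((seq_len(W) - v$center)^2) /
                                           (2 * sigma^2))
    rows <- sr:H
    px[rows, ] <- sweep(px[rows, , drop = FALSE], 2L, fac, `*`)
  }
  bscan(px, L = image$L, crop_offset = image$crop_offset)
}

#' Simulate a full synthetic B-scan
#'
#' Renders the phantom, applies gamma speckle at the spec's `speckle_looks`,
#' and adds the spec's vessel shadows (starting just below the ILM at each
#' vessel's center column). Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (noisy `oct_bscan`) and `boundaries`
#'   (ground-truth `W x 8` row matrix).
#' @examples
#' sim <- simulate_bscan(phantom_spec(height = 64, width = 96,
#'   base_rows = c(12, 18, 26, 32, 37, 46, 51, 56), tilt = 2, bow = 2,
#'   vessels = list()))
#' dim(sim$image)
#' @export
simulate_bscan <- function(spec) {
  ph <- generate_phantom(spec)
  img <- add_speckle(ph$image, looks = spec$speckle_looks, seed = spec$seed)
  vessels <- lapply(spec$vessels, function(v) {
    if (is.null(v$start_row))
      v$start_row <- spec$boundaries[v$center, "ILM"] + 2
    v
  })
  img <- add_vessel_shadows(img, vessels)
  list(image = img, boundaries = ph$boundaries)
}
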