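#' Fuzzy histogram hyperbolization (FHH) settings
#'
#' The FHH fuzzifier beta controls the shape of the hyperbolic grey-level
#' transform: values near 0 behave like histogram equalization, values of 5
#' and above quantize the image towards a segmentation-like result. The
#' package derives an initial beta from the image's linear index of
#' fuzziness (`beta0 = k * gamma`), then stabilizes it with an additive
#' constant `C` and clamps it to the admissible window `[t_min, t_max]`,
#' so each scan receives an adaptive fuzzifier without user input.
#'
#' @param t_min,t_max Lower and upper clamp for the stabilized fuzzifier.
#' @param C Stabilizer constant added to the initial beta before clamping.
#' @param k Multiplier mapping the fuzziness index gamma to the initial beta.
#' @param beta_override Optional fixed beta; when set it is used verbatim
#'   (no stabilization, no clamping).
#' @return A list of class `fhh_config`.
#' @export
fhh_config <- function(t_min = 0.5, t_max = 5, C = 0.5, k = 4,
                       beta_override = NULL) {
  if (!(t_min > 0 && t_min <= t_max)) stop("need 0 < t_min <= t_max")
  if (!is.finite(C)) stop("`C` must be finite")
  if (!is.null(beta_override) && beta_override <= 0)
    stop("`beta_override` must be positive")
  structure(list(t_min = t_min, t_max = t_max, C = C, k = k,
                 beta_override = beta_override),
            class = "fhh_config")
}

#' Min-max fuzzy membership of each pixel
#'
#' Maps grey levels to the fuzzy plane: `mu = (g - g_min) / (g_max - g_min)`,
#' where `g_min` and `g_max` are the image minimum and maximum. The minimum
#' maps to membership 0 and the maximum to 1.
#'
#' @param image An `oct_bscan` or numeric matrix.
#' @return Numeric matrix of memberships in `[0, 1]`, same shape as the image.
#' @examples
#' compute_membership(matrix(c(0, 50, 100, 200), 2, 2))
#' @export
compute_membership <- function(image) {
  px <- as_bscan(image)$pixels
  g_min <- min(px)
  g_max <- max(px)
  if (g_max <= g_min)
    stop("degenerate input: constant image has no membership (g_max = g_min)")
  (px - g_min) / (g_max - g_min)
}

#' Linear index of fuzziness
#'
#' `gamma = (2 / (M * N)) * sum(min(mu, 1 - mu))`: 0 for a crisp image whose
#' memberships are all 0 or 1, and 1 when every membership is 0.5. Symmetric
#' under membership inversion `mu -> 1 - mu`.
#'
#' @param membership Numeric matrix of memberships in `[0, 1]`.
#' @return A scalar in `[0, 1]`.
#' @export
fuzziness_index <- function(membership) {
  membership <- as.matrix(membership)
  if (anyNA(membership) || min(membership) < 0 || max(membership) > 1)
    stop("memberships must lie in [0, 1]")
  2 * mean(pmin(membership, 1 - membership))
}

#' Select the stabilized fuzzifier beta
#'
#' Computes the initial fuzzifier `beta0 = k * gamma` from the fuzziness
#' index, adds the stabilizer `C`, and clamps to `[t_min, t_max]`. When
#' `beta_override` is set in the config it is returned unchanged.
#'
#' @param gamma Linear index of fuzziness, in `[0, 1]`.
#' @param config An [fhh_config()].
#' @return The fuzzifier beta to apply.
#' @export
select_beta <- function(gamma, config = fhh_config()) {
  if (!is.null(config$beta_override)) return(config$beta_override)
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1]")
  min(max(config$k * gamma + config$C, config$t_min), config$t_max)
}

#' Hyperbolic grey-level transform
#'
#' Applies `g' = ((L - 1) / (exp(-1) - 1)) * (exp(-mu^beta) - 1)` per pixel.
#' The transform is monotone non-decreasing in the membership, maps
#' membership 0 to grey level 0 and membership 1 to `L - 1`, and is kept at
#' full floating-point precision (quantization happens only on export).
#'
#' @param membership Numeric matrix of memberships in `[0, 1]`.
#' @param beta Positive fuzzifier exponent.
#' @param L Grey-level count of the output scale.
#' @return An `oct_bscan` with continuous intensities in `[0, L - 1]`.
#' @export
hyperbolize <- function(membership, beta, L = 256) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be a single positive number")
  if (L < 2) stop("`L` must be at least 2")
  membership <- as.matrix(membership)
  g <- ((L - 1) / (exp(-1) - 1)) * (exp(-membership^beta) - 1)
  # guard against tiny negative round-off at mu = 0
  g[g < 0] <- 0
  g[g > L - 1] <- L - 1
  bscan(g, L = L)
}

#' Enhance a B-scan by fuzzy histogram hyperbolization
#'
#' Composes [compute_membership()], [fuzziness_index()], [select_beta()] and
#' [hyperbolize()]: speckled OCT scans are mapped through an adaptive
#' hyperbolic transform that raises contrast between layers while preserving
#' edges. The applied beta and the fuzziness index are returned for logging.
#'
#' @param image An `oct_bscan` or numeric matrix.
#' @param config An [fhh_config()].
#' @return A list with elements `image` (the enhanced `oct_bscan`), `beta`
#'   (the fuzzifier actually applied) and `gamma` (the fuzziness index).
#' @examples
#' img <- bscan(matrix(rep(c(10, 200), each = 50), 10, 10))
#' enh <- fhh_enhance(img)
#' enh$beta
#' @export
fhh_enhance <- function(image, config = fhh_config()) {
  image <- as_bscan(image)
  mu <- compute_membership(image)
  gamma <- fuzziness_index(mu)
  beta <- select_beta(gamma, config)
  out <- hyperbolize(mu, beta, L = image$L)
  out$crop_offset <- image$crop_offset
  list(image = out, beta = beta, gamma = gamma)
}
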