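#' Porosity-permeability correlations for fibrous tissue
#'
#' Closed-form empirical correlations between porosity and directional
#' hydraulic permeability of fibrous meniscal tissue, in log-exponential
#' form (natural logarithm):
#' \deqn{K_L = \exp(4.719 \log\phi + \phi + 5.097)}
#' \deqn{K_T = \exp(5.567 \log\phi + \phi + 4.239)}
#' with porosity fraction \eqn{\phi} and permeability in Darcy. Longitudinal
#' means along the dominant fibre direction; over the physiological porosity
#' range the longitudinal permeability is roughly twice the transverse one.
#' The coefficients are fixed constants of the package; [fit_permeability_correlation()]
#' fits the same functional form to user data.
#'
#' @param phi Porosity fraction(s), strictly inside (0, 1).
#' @return Permeability in Darcy.
#' @examples
#' predict_KL(0.61) # about 29 Darcy
#' predict_KT(0.61) # about 8 Darcy
#' @export
predict_KL <- function(phi) {
  check_phi_open(phi)
  exp(4.719 * log(phi) + phi + 5.097)
}

#' @rdname predict_KL
#' @export
predict_KT <- function(phi) {
  check_phi_open(phi)
  exp(5.567 * log(phi) + phi + 4.239)
}

check_phi_open <- function(phi) {
  if (any(!is.finite(phi)) || any(phi <= 0) || any(phi >= 1))
    stop("porosity must lie strictly in (0, 1)", call. = FALSE)
  invisible(phi)
}

#' Porosity-dependent normalized Young's modulus
#'
#' Quadratic model for stiffness relative to the fully dense material,
#' \deqn{E_n = 1 - 1.1456 \phi^2 + 0.0853 \phi,}
#' which equals 1 at zero porosity and decays towards zero at high porosity,
#' reflecting the loss of stiffness in sparse fibre arrangements. The raw
#' quadratic dips slightly below zero as \eqn{\phi \to 1} (a fit artefact);
#' `clamp = TRUE` truncates at zero.
#'
#' @param phi Porosity fraction(s) in `[0, 1]`.
#' @param clamp Truncate negative values to 0 (default `FALSE`).
#' @return Dimensionless normalized modulus.
#' @examples
#' predict_En(0)    # exactly 1
#' predict_En(0.5)  # 0.75625
#' @export
predict_En <- function(phi, clamp = FALSE) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("porosity must lie in [0, 1]", call. = FALSE)
  en <- 1 - 1.1456 * phi^2 + 0.0853 * phi
  if (clamp) en <- pmax(en, 0)
  en
}

#' Stress-induced permeability reduction ratio
#'
#' Fractional loss of permeability between an initial state and a deformed
#' (for example compressed) state: `(K_start - K_end) / K_start`.
#'
#' @param K_start Initial permeability (> 0).
#' @param K_end Final permeability (>= 0).
#' @return The reduction fraction.
#' @export
permeability_reduction <- function(K_start, K_end) {
  if (any(K_start <= 0)) stop("`K_start` must be positive", call. = FALSE)
  if (any(K_end < 0)) stop("`K_end` must be non-negative", call. = FALSE)
  (K_start - K_end) / K_start
}

#' Porosity map from a CT image by linear calibration
#'
#' Maps per-pixel CT numbers to porosity fractions by the straight line
#' through two user-supplied calibration anchors, clipping the result to
#' `[0, 1]`. Masked pixels (for example the vascular region or background)
#' propagate as missing values.
#'
#' @param image A 2D numeric matrix of CT numbers.
#' @param calibration A list or data frame with two anchors: columns/fields
#'   `ct` and `porosity`, each length 2, with distinct `ct` values.
#' @param mask Optional logical matrix, `TRUE` = exclude pixel.
#' @param pixel_size Pixel edge length in micrometres (metadata only).
#' @return A `porosity_map`: list with `porosity` matrix (NA where masked)
#'   and `pixel_size`.
#' @export
porosity_from_ct <- function(image, calibration, mask = NULL, pixel_size = NULL) {
  stopifnot(is.matrix(image))
  ct <- calibration$ct
  ph <- calibration$porosity
  if (length(ct) != 2L || length(ph) != 2L)
    stop("`calibration` needs exactly two (ct, porosity) anchors", call. = FALSE)
  if (ct[1] == ct[2])
    stop("calibration anchors must have distinct CT values", call. = FALSE)
  slope <- (ph[2] - ph[1]) / (ct[2] - ct[1])
  p <- ph[1] + slope * (image - ct[1])
  p <- pmin(pmax(p, 0), 1)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), identical(dim(mask), dim(image)))
    p[mask] <- NA_real_
  }
  structure(list(porosity = p, pixel_size = pixel_size), class = "porosity_map")
}

#' Property maps from a porosity map
#'
#' Element-wise application of [predict_KL()], [predict_KT()] and
#' [predict_En()] to a porosity map. Missing porosity propagates to all three
#' outputs; pixels with porosity outside the open interval (0, 1) are flagged
#' missing in the permeability maps (the correlations' domain) but still
#' evaluated in the modulus map where they lie in `[0, 1]`.
#'
#' @param pmap A `porosity_map`.
#' @return A `property_maps` object: matrices `KL` (Darcy), `KT` (Darcy) and
#'   `En` (dimensionless) sharing the porosity map geometry.
#' @export
property_maps <- function(pmap) {
  stopifnot(inherits(pmap, "porosity_map"))
  p <- pmap$porosity
  ok_k <- is.finite(p) & p > 0 & p < 1
  ok_e <- is.finite(p) & p >= 0 & p <= 1
  KL <- KT <- En <- array(NA_real_, dim = dim(p))
  KL[ok_k] <- predict_KL(p[ok_k])
  KT[ok_k] <- predict_KT(p[ok_k])
  En[ok_e] <- predict_En(p[ok_e])
  structure(list(KL = KL, KT = KT, En = En, pixel_size = pmap$pixel_size),
            class = "property_maps")
}

#' Refit the correlation forms on user data
#'
#' Least-squares fits of the package's two functional forms on user-provided
#' (porosity, property) data: the log-exponential permeability form
#' `K = exp(a log(phi) + phi + c)` (linear in `a`, `c` after moving `phi` to
#' the left-hand side) and the constrained quadratic modulus form
#' `En = 1 + b2 phi^2 + b1 phi`. These produce *user* coefficients; they do
#' not alter the built-in constants of [predict_KL()] and friends.
#'
#' @param data A data frame with columns `phi` and `K` (Darcy), or `phi` and
#'   `En`.
#' @return An object of class `fibro_fit` wrapping the underlying `lm`, with
#'   [generics::tidy()] and [generics::glance()] methods and a `predict()`
#'   method on porosity.
#' @export
fit_permeability_correlation <- function(data) {
  stopifnot(all(c("phi", "K") %in% names(data)))
  check_phi_open(data$phi)
  m <- stats::lm(I(log(K) - phi) ~ log(phi), data = data)
  cf <- stats::coef(m)
  structure(list(model = m, form = "permeability",
                 coef = c(a = unname(cf[2]), c = unname(cf[1]))),
            class = "fibro_fit")
}

#' @rdname fit_permeability_correlation
#' @export
fit_modulus_correlation <- function(data) {
  stopifnot(all(c("phi", "En") %in% names(data)))
  m <- stats::lm(I(En - 1) ~ 0 + I(phi^2) + phi, data = data)
  cf <- stats::coef(m)
  structure(list(model = m, form = "modulus",
                 coef = c(b2 = unname(cf[1]), b1 = unname(cf[2]))),
            class = "fibro_fit")
}

#' @export
predict.fibro_fit <- function(object, phi, ...) {
  if (object$form == "permeability")
    exp(object$coef[["a"]] * log(phi) + phi + object$coef[["c"]])
  else
    1 + object$coef[["b2"]] * phi^2 + object$coef[["b1"]] * phi
}

#' @export
#' @method print fibro_fit
print.fibro_fit <- function(x, ...) {
  cat(sprintf("<fibro_fit:%s> coefficients: %s\n", x$form,
              paste(sprintf("%s = %.4f", names(x$coef), x$coef), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.fibro_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.fibro_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, df.residual = x$model$df.residual,
                 nobs = length(x$model$residuals))
}
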