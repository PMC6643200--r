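#' Build a transform specification for one component
#'
#' Dietary amounts are modelled on a transformed scale: a natural log for the
#' fatty-acid ratio and a Box-Cox transform with parameter 0.25 for the food
#' groups, sodium, empty calories and energy; each transformed series is then
#' centered to mean 0 and scaled to variance 2. Zeros entering the power
#' transform are handled by a shift of half the smallest positive observed
#' value (zero when all observations are positive); the shift, center and
#' scale are stored so the transform is invertible.
#'
#' @param x Observed positive-part amounts used to calibrate shift, center
#'   and scale (for episodic components, consumption-day amounts only).
#' @param kind \code{"boxcox"} or \code{"log"}.
#' @param component Component id, recorded for bookkeeping.
#' @param lambda Box-Cox exponent, fixed at 0.25.
#' @param target_var Variance of the scaled series (2 by convention).
#' @return A \code{transform_spec} list with fields \code{component},
#'   \code{kind}, \code{lambda}, \code{delta}, \code{center}, \code{scale}.
#' @export
make_transform_spec <- function(x, kind = c("boxcox", "log"),
                                component = NA_character_, lambda = 0.25,
                                target_var = 2) {
  kind <- match.arg(kind)
  x <- x[is.finite(x)]
  if (kind == "log" && any(x <= 0)) {
    stop("log transform requires strictly positive values")
  }
  delta <- 0
  if (kind == "boxcox" && any(x == 0)) {
    pos <- x[x > 0]
    if (length(pos) == 0) stop("cannot calibrate a transform on all-zero data")
    delta <- min(pos) / 2
  }
  raw <- if (kind == "log") log(x) else ((x + delta)^lambda - 1) / lambda
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) s <- 1
  spec <- list(component = component, kind = kind, lambda = lambda,
               delta = delta, center = mean(raw),
               scale = s / sqrt(target_var))
  class(spec) <- "transform_spec"
  spec
}

#' Apply a component transform
#'
#' @param x Amounts on the natural scale.
#' @param spec A \code{transform_spec}.
#' @return Transformed, centered and scaled values.
#' @export
transform_amount <- function(x, spec) {
  raw <- if (spec$kind == "log") {
    if (any(x <= 0, na.rm = TRUE)) stop("log transform of non-positive amount")
    log(x)
  } else {
    ((x + spec$delta)^spec$lambda - 1) / spec$lambda
  }
  (raw - spec$center) / spec$scale
}

#' Invert a component transform
#'
#' Exact inverse of [transform_amount()] using the stored shift, center and
#' scale; Box-Cox inversion clamps at zero when the linearized argument falls
#' below the transform's domain.
#'
#' @param z Transformed values.
#' @param spec A \code{transform_spec}.
#' @return Amounts on the natural scale.
#' @export
inverse_transform <- function(z, spec) {
  raw <- z * spec$scale + spec$center
  if (spec$kind == "log") return(exp(raw))
  base <- pmax(0, 1 + spec$lambda * raw)
  pmax(0, base^(1 / spec$lambda) - spec$delta)
}
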