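#' Two-compartment tissue density constants
#'
#' Densities used by the two-compartment (fat / fat-free) densitometric
#' model: fat mass density is constant at 0.9007 g/ml, while fat-free mass
#' density rises linearly with postnatal age from 1.063 g/ml at birth to
#' 1.067 g/ml at six months (182.5 days).
#'
#' @param d_fm Fat-mass density, g/ml.
#' @param d_ffm_birth Fat-free-mass density at birth, g/ml.
#' @param d_ffm_6mo Fat-free-mass density at six months, g/ml.
#' @param age_span Days over which FFM density interpolates.
#' @return A named list of class \code{density_constants}.
#' @export
density_constants <- function(d_fm = 0.9007, d_ffm_birth = 1.063,
                              d_ffm_6mo = 1.067, age_span = 182.5) {
  if (!(d_fm > 0 && d_fm < d_ffm_birth && d_ffm_birth <= d_ffm_6mo))
    stop("require 0 < d_fm < d_ffm_birth <= d_ffm_6mo", call. = FALSE)
  if (age_span <= 0) stop("age_span must be positive", call. = FALSE)
  structure(list(d_fm = d_fm, d_ffm_birth = d_ffm_birth,
                 d_ffm_6mo = d_ffm_6mo, age_span = age_span),
            class = "density_constants")
}

#' Age-dependent fat-free mass density
#'
#' Linear interpolation of FFM density from its value at birth to its value
#' at six months; clamped to the six-month value beyond \code{age_span}.
#'
#' @param age Postnatal age in days (vectorized, non-negative).
#' @param constants See [density_constants()].
#' @return FFM density in g/ml.
#' @export
ffm_density <- function(age, constants = density_constants()) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  frac <- pmin(age / constants$age_span, 1)
  constants$d_ffm_birth + frac * (constants$d_ffm_6mo - constants$d_ffm_birth)
}

#' Whole-body density from mass and volume
#'
#' @param mass Body mass in g (positive).
#' @param volume Body volume in ml (positive).
#' @return Density in g/ml (\code{mass / volume}).
#' @export
body_density <- function(mass, volume) {
  if (any(mass <= 0) || any(volume <= 0))
    stop("mass and volume must be positive", call. = FALSE)
  mass / volume
}

#' Body-fat percentage from whole-body density
#'
#' Solves the two-compartment identity
#' \deqn{1/D = f/d_{FM} + (1-f)/d_{FFM}(age)}
#' for the fat fraction \eqn{f}, i.e.
#' \eqn{f = d_{FM} (d_{FFM} - D) / (D (d_{FFM} - d_{FM}))}, and returns
#' \eqn{100 f}. Densities outside the physical interval
#' \eqn{[d_{FM}, d_{FFM}]} — which measurement noise can produce — are
#' clamped to 0–100% and flagged via the \code{"clamped"} attribute (a
#' logical vector) together with a warning.
#'
#' @param density Whole-body density, g/ml (vectorized).
#' @param age Postnatal age in days.
#' @param constants See [density_constants()].
#' @return Body-fat percentage (0–100), with attribute \code{clamped}.
#' @export
bf_from_density <- function(density, age = 0, constants = density_constants()) {
  if (any(density <= 0)) stop("density must be positive", call. = FALSE)
  d_ffm <- ffm_density(age, constants)
  f <- constants$d_fm * (d_ffm - density) / (density * (d_ffm - constants$d_fm))
  clamped <- f < 0 | f > 1
  if (any(clamped))
    warning(sum(clamped), " density value(s) outside [d_fm, d_ffm]; ",
            "fat fraction clamped to [0, 100]%", call. = FALSE)
  out <- 100 * pmin(pmax(f, 0), 1)
  attr(out, "clamped") <- clamped
  out
}

#' Split body weight into fat and fat-free mass
#'
#' \code{fm = weight * bf_pct / 100} and \code{ffm = weight - fm}; mass is
#' conserved exactly.
#'
#' @param weight Body weight in g (positive).
#' @param bf_pct Body-fat percentage in \[0, 100\].
#' @return A list with numeric components \code{fm} and \code{ffm} (g).
#' @export
decompose_weight <- function(weight, bf_pct) {
  if (any(weight <= 0)) stop("weight must be positive", call. = FALSE)
  if (any(bf_pct < 0 | bf_pct > 100))
    stop("bf_pct must be within [0, 100]", call. = FALSE)
  fm <- weight * bf_pct / 100
  list(fm = fm, ffm = weight - fm)
}

#' Body volume implied by a fat / fat-free composition
#'
#' Exact inverse of the two-compartment model,
#' \code{fm / d_fm + ffm / d_ffm(age)}; used to simulate air-displacement
#' plethysmography readings. The full roundtrip through [body_density()],
#' [bf_from_density()] and [decompose_weight()] reproduces \code{(fm, ffm)}
#' to well below 0.5 g.
#'
#' @param fm Fat mass, g (non-negative).
#' @param ffm Fat-free mass, g (positive).
#' @param age Postnatal age in days.
#' @param constants See [density_constants()].
#' @return Volume in ml.
#' @export
volume_from_composition <- function(fm, ffm, age = 0,
                                    constants = density_constants()) {
  if (any(fm < 0)) stop("fm must be non-negative", call. = FALSE)
  if (any(ffm <= 0)) stop("ffm must be positive", call. = FALSE)
  fm / constants$d_fm + ffm / ffm_density(age, constants)
}
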