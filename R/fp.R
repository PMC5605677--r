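# Fractional-polynomial (FP) basis construction and least-squares fitting
# for the mean and residual-SD curves of a centile standard.

#' The fractional-polynomial power set
#'
#' The canonical set of candidate powers \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\},
#' with the convention that power 0 denotes the natural logarithm.
#'
#' @return A numeric vector of the eight powers.
#' @export
fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Evaluate a fractional-polynomial basis
#'
#' For each power \eqn{p} the basis term is \eqn{x^p}, with \eqn{x^0 \equiv
#' \ln x}; a repeated power \eqn{(p, p)} contributes \eqn{x^p} and
#' \eqn{x^p \ln x}. Powers must be non-decreasing.
#'
#' @param x Positive numeric vector.
#' @param powers Numeric vector of powers (non-decreasing).
#' @return A matrix with \code{length(powers)} columns of basis values.
#' @examples
#' fp_basis(4, c(0, 2))   # ln 4, 16
#' fp_basis(4, c(1, 1))   # 4, 4 log(4)
#' @export
fp_basis <- function(x, powers) {
  if (any(x <= 0)) stop("x must be strictly positive", call. = FALSE)
  if (is.unsorted(powers)) stop("powers must be non-decreasing", call. = FALSE)
  lx <- log(x)
  B <- matrix(NA_real_, nrow = length(x), ncol = length(powers))
  for (j in seq_along(powers)) {
    if (j > 1 && powers[j] == powers[j - 1]) {
      B[, j] <- B[, j - 1] * lx
    } else if (powers[j] == 0) {
      B[, j] <- lx
    } else {
      B[, j] <- x^powers[j]
    }
  }
  B
}

# all 36 FP2 candidates (8 repeated pairs + 28 distinct), ordered by the
# deterministic tie-break: closeness to (1, 2), then lexicographic
fp2_candidates <- function() {
  P <- fp_power_set()
  pairs <- list()
  for (i in seq_along(P)) for (j in i:length(P))
    pairs[[length(pairs) + 1]] <- c(P[i], P[j])
  d <- vapply(pairs, function(p) (p[1] - 1)^2 + (p[2] - 2)^2, numeric(1))
  p1 <- vapply(pairs, `[`, numeric(1), 1)
  p2 <- vapply(pairs, `[`, numeric(1), 2)
  pairs[order(d, p1, p2)]
}

fp_ls <- function(X, y, weights = NULL) {
  fit <- if (is.null(weights)) stats::lm.fit(X, y)
  else stats::lm.wfit(X, y, w = weights)
  rss <- if (is.null(weights)) sum(fit$residuals^2)
  else sum(weights * fit$residuals^2)
  list(coef = fit$coefficients, rss = rss, rank = fit$rank,
       residuals = fit$residuals)
}

#' Fit the best two-power fractional polynomial to a mean curve
#'
#' Enumerates all 36 FP2 candidates (8 repeated and 28 distinct power
#' pairs), fits each by (weighted) least squares with an intercept, and
#' returns the candidate with the smallest (weighted) residual sum of
#' squares. Ties are broken toward the power pair closest to (1, 2), then
#' lexicographically; numerically singular candidates are skipped with a
#' log message.
#'
#' @param x Strictly positive predictor (e.g. scaled gestational age).
#' @param y Response.
#' @param weights Optional positive case weights.
#' @return A list with \code{powers} (length 2), \code{coef} (intercept and
#'   two basis coefficients), \code{rss} and \code{residuals}.
#' @export
fit_fp_mean <- function(x, y, weights = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(y) <= 10) stop("need more than 10 observations", call. = FALSE)
  best <- NULL
  for (pw in fp2_candidates()) {
    X <- cbind(1, fp_basis(x, pw))
    fit <- fp_ls(X, y, weights)
    if (fit$rank < ncol(X) || anyNA(fit$coef)) {
      message("fp2 candidate (", pw[1], ", ", pw[2], ") singular; skipped")
      next
    }
    # strict improvement beyond numerical noise; candidate order breaks ties
    if (is.null(best) || fit$rss < best$rss * (1 - 1e-9) - 1e-12) {
      best <- list(powers = pw, coef = unname(fit$coef), rss = fit$rss,
                   residuals = fit$residuals)
    }
  }
  if (is.null(best)) stop("no admissible FP2 candidate", call. = FALSE)
  best
}

#' Fit a one-power fractional polynomial to the residual SD
#'
#' Regresses the absolute residuals on an intercept plus the best
#' single-power FP basis of \code{x}; fitted values are multiplied by
#' \eqn{\sqrt{\pi/2}} (the half-normal correction, since
#' \eqn{E|r| = \sigma\sqrt{2/\pi}} for Gaussian residuals) to estimate
#' \eqn{\sigma(x)}. The power minimising the residual sum of squares among
#' the eight candidates is selected, subject to the fitted \eqn{\sigma}
#' being strictly positive over the observed range of \code{x} (the fit is
#' monotone in \code{x}, so the endpoints suffice). If no candidate
#' qualifies, a constant \eqn{\sigma} is returned with a warning.
#'
#' @param x Strictly positive predictor.
#' @param residuals Residuals from a fitted mean model.
#' @return A list with \code{power} (NA for the constant fallback),
#'   \code{coef} (coefficients on the \eqn{\sigma} scale, i.e. already
#'   including the half-normal factor) and \code{rss}.
#' @export
fit_fp_sd <- function(x, residuals) {
  a <- abs(residuals)
  hn <- sqrt(pi / 2)
  xr <- range(x)
  best <- NULL
  for (p in fp_power_set()) {
    X <- cbind(1, fp_basis(x, p))
    fit <- fp_ls(X, a)
    if (fit$rank < 2 || anyNA(fit$coef)) next
    co <- unname(fit$coef) * hn
    ends <- drop(cbind(1, fp_basis(xr, p)) %*% co)
    if (any(ends <= 0)) next
    if (is.null(best) || fit$rss < best$rss * (1 - 1e-9) - 1e-12)
      best <- list(power = p, coef = co, rss = fit$rss)
  }
  if (is.null(best)) {
    warning("no FP1 SD candidate keeps sigma positive; using constant SD",
            call. = FALSE)
    best <- list(power = NA_real_, coef = hn * mean(a),
                 rss = sum((a - mean(a))^2))
  }
  best
}
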