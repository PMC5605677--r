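#' Default synthetic-cohort configuration
#'
#' Returns the packaged parameterization of the synthetic newborn cohort
#' generator. The defaults are calibrated to the published population moments
#' of a large single-site newborn body-composition cohort: 49.2% boys,
#' gestational age (GA) mean 39.4 / SD 1.6 weeks, per-sex fat-free mass (FFM)
#' means of 2,965 g (boys) and 2,739 g (girls) at the mean GA with weekly GA
#' slopes of 169 and 155 g, fat mass (FM) means of 332 / 343 g with slopes of
#' 33 / 36 g per week, exam-age mean 20.0 / SD 15.8 h, and length / head
#' circumference models reproducing the per-sex anthropometric means.
#'
#' Residual SDs of the FM and FFM models are back-computed so the marginal
#' SDs match the published values, i.e. \code{resid = sqrt(marginal^2 -
#' slope^2 * ga_sd^2)}.
#'
#' @return An object of class \code{nbc_config}: a named list of generator
#'   parameters. Per-sex parameters are length-2 named vectors
#'   (\code{male}, \code{female}).
#' @seealso [generate_cohort()], [validate_config()]
#' @examples
#' cfg <- default_config()
#' cfg$ffm_slope[["female"]]  # 155 g/week
#' @export
default_config <- function() {
  ga_sd <- 1.6
  ffm_slope <- c(male = 169, female = 155)
  fm_slope <- c(male = 33, female = 36)
  ffm_marginal_sd <- c(male = 422, female = 390)
  fm_marginal_sd <- c(male = 172, female = 167)
  cfg <- list(
    n_boys_fraction = 0.492,
    ga_mean = 39.4,
    ga_sd = ga_sd,
    # 28 weeks to 43 weeks + 6 days
    ga_range = c(28, 307 / 7),
    ga_model = "truncnorm",
    # optional two-component mixture reproducing a higher preterm rate
    ga_mixture = list(w_early = 0.07, mean_main = 39.5, sd_main = 1.4,
                      mean_early = 36.0, sd_early = 1.5),
    ffm_mean = c(male = 2965, female = 2739),
    ffm_slope = ffm_slope,
    ffm_sd = sqrt(ffm_marginal_sd^2 - ffm_slope^2 * ga_sd^2),
    fm_mean = c(male = 332, female = 343),
    fm_slope = fm_slope,
    fm_sd = sqrt(fm_marginal_sd^2 - fm_slope^2 * ga_sd^2),
    fm_floor = 20,
    fm_lognormal = FALSE,
    # length (cm) = intercept + cbrt_ffm * FFM^(1/3) + N(0, length_sd)
    length_coef = c(intercept = 7.1283, cbrt_ffm = 2.9423),
    length_sd = 1.0,
    # head circumference (cm) = sex intercept + per_g_ffm * FFM + noise
    head_coef = c(male = 27.058, female = 26.725, per_g_ffm = 0.00251),
    head_sd = 1.0,
    # exam age: log-normal truncated to (0, exam_max]; parameters solved so
    # the truncated distribution has mean 20.0 h and SD 15.8 h
    exam_meanlog = 2.737574,
    exam_sdlog = 0.7951537,
    exam_max = 96,
    # postnatal loss: linear fraction of birth weight, 9% at 96 h,
    # 80% of lost mass taken from FFM
    loss_frac_max = 0.09,
    loss_ffm_share = 0.8,
    low_risk_fraction = 0.2424,
    n_ultrasound = 3L,
    malformation_rate = 0,
    volume_noise_sd = 0,
    seed = 1L
  )
  class(cfg) <- "nbc_config"
  cfg
}

#' Validate a synthetic-cohort configuration
#'
#' Checks the structural invariants of an [default_config()]-style list:
#' strictly positive SDs, boys fraction in (0, 1), GA range inside
#' (26, 44) weeks, non-negative fat-mass floor, loss share in \[0, 1\] and an
#' exam-age support bounded by 96 h.
#'
#' @param config An \code{nbc_config} list.
#' @return The config, invisibly, if valid; otherwise an error is thrown
#'   naming the violated invariant.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg, call. = FALSE)
  chk(config$n_boys_fraction > 0 && config$n_boys_fraction < 1,
      "n_boys_fraction must be in (0, 1)")
  chk(config$ga_sd > 0, "ga_sd must be positive")
  chk(length(config$ga_range) == 2 && config$ga_range[1] < config$ga_range[2],
      "ga_range must be increasing")
  chk(config$ga_range[1] > 26 && config$ga_range[2] < 44,
      "ga_range must lie within (26, 44) weeks")
  chk(all(config$ffm_sd > 0) && all(config$fm_sd > 0),
      "FM/FFM residual SDs must be positive")
  chk(config$length_sd > 0 && config$head_sd > 0,
      "length_sd and head_sd must be positive")
  chk(config$fm_floor >= 0, "fm_floor must be non-negative")
  chk(config$loss_ffm_share >= 0 && config$loss_ffm_share <= 1,
      "loss_ffm_share must be in [0, 1]")
  chk(config$loss_frac_max >= 0 && config$loss_frac_max < 1,
      "loss_frac_max must be in [0, 1)")
  chk(config$exam_max > 0 && config$exam_max <= 96,
      "exam-age support must be (0, 96] hours")
  chk(config$low_risk_fraction >= 0 && config$low_risk_fraction <= 1,
      "low_risk_fraction must be in [0, 1]")
  chk(config$exam_sdlog > 0, "exam_sdlog must be positive")
  chk(config$volume_noise_sd >= 0, "volume_noise_sd must be non-negative")
  invisible(config)
}

#' @export
print.nbc_config <- function(x, ...) {
  cat("Synthetic newborn cohort configuration\n")
  cat(sprintf("  boys fraction        %.3f\n", x$n_boys_fraction))
  cat(sprintf("  GA (weeks)           %.1f (SD %.1f), range %.1f-%.1f [%s]\n",
              x$ga_mean, x$ga_sd, x$ga_range[1], x$ga_range[2], x$ga_model))
  cat(sprintf("  FFM at mean GA (g)   M %.0f / F %.0f; slope %.0f / %.0f g per week\n",
              x$ffm_mean[["male"]], x$ffm_mean[["female"]],
              x$ffm_slope[["male"]], x$ffm_slope[["female"]]))
  cat(sprintf("  FM at mean GA (g)    M %.0f / F %.0f; slope %.0f / %.0f g per week\n",
              x$fm_mean[["male"]], x$fm_mean[["female"]],
              x$fm_slope[["male"]], x$fm_slope[["female"]]))
  cat(sprintf("  postnatal loss       %.0f%% of birth weight at %d h, %.0f%% from FFM\n",
              100 * x$loss_frac_max, as.integer(x$exam_max),
              100 * x$loss_ffm_share))
  cat(sprintf("  low-risk fraction    %.3f\n", x$low_risk_fraction))
  invisible(x)
}
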