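#' Generate a seeded synthetic newborn cohort
#'
#' Draws \code{n} newborn records with the statistical structure the analysis
#' pipeline assumes: sex, gestational age (truncated normal or an optional
#' two-component mixture), exam age (truncated log-normal), fat-free and fat
#' mass linear in GA within sex, a postnatal weight-loss process (linear in
#' exam age, reaching \code{loss_frac_max} of birth weight at 96 h, taken
#' mostly from FFM), recumbent length allometric in the cube root of FFM,
#' head circumference linear in FFM, and an air-displacement body volume
#' consistent with the two-compartment densitometric model.
#'
#' Composition is parameterized on the exam scale: the configured per-sex
#' means and GA slopes describe FM and FFM as measured at the cohort-average
#' postnatal loss, and each record's individual loss is applied around that
#' reference. This keeps the configured means and slopes unbiased targets for
#' sample moments and ordinary least squares while encoding the decline of
#' exam weight and FFM with postnatal age.
#'
#' @param config Generator parameterization, see [default_config()].
#' @param n Number of records (positive integer).
#' @param seed Integer seed; the same (config, n, seed) always yields a
#'   bit-identical table. Defaults to \code{config$seed}.
#' @return A \code{data.frame} with one row per newborn and columns
#'   \code{id}, \code{sex} ("M"/"F"), \code{ga_birth_weeks},
#'   \code{exam_age_hours}, \code{birth_weight_g}, \code{exam_weight_g},
#'   \code{length_cm}, \code{head_circ_cm}, \code{body_volume_ml},
#'   \code{fm_g}, \code{ffm_g}, \code{bf_pct}, \code{low_risk},
#'   \code{malformation} and \code{ultrasound_z} (semicolon-joined z-scores).
#'   \code{fm_g + ffm_g == exam_weight_g} holds exactly for every row.
#' @examples
#' coh <- generate_cohort(default_config(), n = 200, seed = 42)
#' all.equal(coh$fm_g + coh$ffm_g, coh$exam_weight_g)
#' @export
generate_cohort <- function(config = default_config(), n, seed = config$seed) {
  validate_config(config)
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)

  # seed the draw without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  sex <- ifelse(stats::runif(n) < config$n_boys_fraction, "M", "F")
  ga <- draw_ga(n, config)
  exam_age <- draw_exam_age(n, config)

  key <- ifelse(sex == "M", "male", "female")
  dga <- ga - config$ga_mean
  f_ref <- config$ffm_mean[key] + config$ffm_slope[key] * dga +
    stats::rnorm(n, 0, config$ffm_sd[key])
  m_mu <- config$fm_mean[key] + config$fm_slope[key] * dga
  if (isTRUE(config$fm_lognormal)) {
    # right-skewed alternative: shifted log-normal with the same mean and SD
    mu_sh <- pmax(m_mu - config$fm_floor, 1)
    sdl <- sqrt(log(1 + (config$fm_sd[key] / mu_sh)^2))
    m_ref <- config$fm_floor + stats::rlnorm(n, log(mu_sh) - sdl^2 / 2, sdl)
  } else {
    m_ref <- pmax(m_mu + stats::rnorm(n, 0, config$fm_sd[key]), config$fm_floor)
  }

  # postnatal loss: fraction of birth weight, linear in exam age
  lf <- config$loss_frac_max * exam_age / config$exam_max
  lbar <- mean(lf)
  birth_weight <- (f_ref + m_ref) / (1 - lbar)
  sh <- config$loss_ffm_share
  exam_ffm <- f_ref + sh * (lbar - lf) * birth_weight
  exam_fm <- m_ref + (1 - sh) * (lbar - lf) * birth_weight
  exam_fm <- pmax(exam_fm, 0.5)
  exam_weight <- birth_weight * (1 - lf)
  exam_ffm <- exam_weight - exam_fm  # exact mass closure

  length_cm <- config$length_coef[["intercept"]] +
    config$length_coef[["cbrt_ffm"]] * f_ref^(1 / 3) +
    stats::rnorm(n, 0, config$length_sd)
  head_circ <- config$head_coef[key] + config$head_coef[["per_g_ffm"]] * f_ref +
    stats::rnorm(n, 0, config$head_sd)

  volume <- volume_from_composition(exam_fm, exam_ffm, exam_age / 24)
  if (config$volume_noise_sd > 0)
    volume <- volume + stats::rnorm(n, 0, config$volume_noise_sd)

  low_risk <- stats::runif(n) < config$low_risk_fraction
  malformation <- stats::runif(n) < config$malformation_rate
  usz <- if (config$n_ultrasound > 0) {
    z <- matrix(stats::rnorm(n * config$n_ultrasound), nrow = n)
    apply(round(z, 4), 1, paste, collapse = ";")
  } else rep("", n)

  data.frame(
    id = sprintf("NB%05d", seq_len(n)),
    sex = sex,
    ga_birth_weeks = ga,
    exam_age_hours = exam_age,
    birth_weight_g = birth_weight,
    exam_weight_g = exam_weight,
    length_cm = length_cm,
    head_circ_cm = head_circ,
    body_volume_ml = volume,
    fm_g = exam_fm,
    ffm_g = exam_ffm,
    bf_pct = 100 * exam_fm / exam_weight,
    low_risk = low_risk,
    malformation = malformation,
    ultrasound_z = usz,
    stringsAsFactors = FALSE
  )
}

# truncated-normal (inverse-CDF) or two-component mixture GA draw
draw_ga <- function(n, config) {
  lo <- config$ga_range[1]; hi <- config$ga_range[2]
  if (identical(config$ga_model, "mixture")) {
    mx <- config$ga_mixture
    early <- stats::runif(n) < mx$w_early
    mu <- ifelse(early, mx$mean_early, mx$mean_main)
    sd <- ifelse(early, mx$sd_early, mx$sd_main)
    u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
    stats::qnorm(u, mu, sd)
  } else {
    u <- stats::runif(n, stats::pnorm(lo, config$ga_mean, config$ga_sd),
                      stats::pnorm(hi, config$ga_mean, config$ga_sd))
    stats::qnorm(u, config$ga_mean, config$ga_sd)
  }
}

# truncated log-normal exam age on (0, exam_max]
draw_exam_age <- function(n, config) {
  u <- stats::runif(n, 0, stats::plnorm(config$exam_max, config$exam_meanlog,
                                        config$exam_sdlog))
  pmin(stats::qlnorm(u, config$exam_meanlog, config$exam_sdlog), config$exam_max)
}
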