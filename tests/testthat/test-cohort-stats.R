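test_that("GA slope fits are exact on noiseless data and guarded", {
  d <- make_records(20, ga = seq(34, 42, length.out = 20))
  d$ffm_g <- 100 + 155 * d$ga_birth_weeks
  res <- fit_ga_slope(d, "ffm_g", "female")
  expect_equal(unname(res$coefficients["ga_birth_weeks"]), 155)
  expect_equal(unname(res$se["ga_birth_weeks"]), 0, tolerance = 1e-8)
  # CI construction: estimate +/- 1.95996 * se
  coh <- default_cohort()
  res <- fit_ga_slope(coh, "ffm_g", "female")
  expect_equal(res$ci95["ga_birth_weeks", "low"],
               unname(res$coefficients["ga_birth_weeks"] -
                        qnorm(0.975) * res$se["ga_birth_weeks"]))
  d0 <- make_records(5, ga = 39)
  expect_error(fit_ga_slope(d0, "ffm_g", "female"), "zero variance")
  expect_error(fit_ga_slope(d0[1:2, ], "ffm_g", "female"), "at least 3")
})

test_that("sex contrast at mean GA recovers constructed offsets", {
  d <- make_records(40, ga = rep(seq(36, 42, length.out = 20), 2),
                    sex = rep(c("M", "F"), each = 20))
  d$bf_pct <- 5 + 0.6 * d$ga_birth_weeks + ifelse(d$sex == "F", 1, 0)
  res <- sex_contrast_at_mean_ga(d, "bf_pct")
  expect_equal(res$difference, 1.0, tolerance = 1e-10)
  expect_error(sex_contrast_at_mean_ga(d[d$sex == "F", ], "bf_pct"),
               "both sexes")
  # on the default cohort girls have higher BF% with p < 0.001
  coh <- default_cohort()
  res <- sex_contrast_at_mean_ga(coh, "bf_pct")
  expect_gt(res$difference, 0)
  expect_lt(res$p_value, 0.001)
  # and lower FFM
  res <- sex_contrast_at_mean_ga(coh, "ffm_g")
  expect_lt(res$difference, 0)
  expect_lt(res$p_value, 0.001)
})

test_that("sex contrast rejects at the nominal rate under the null", {
  set.seed(808)
  n_sim <- 1000
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    d <- data.frame(sex = rep(c("M", "F"), each = 30),
                    ga_birth_weeks = runif(60, 36, 42))
    d$y <- rnorm(60)
    rej[i] <- sex_contrast_at_mean_ga(d, "y")$p_value < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 1.96 * sqrt(0.05 * 0.95 / n_sim) + 0.005)
})

test_that("adjusted group differences are exact on constructed data", {
  d <- make_records(60, ga = rep(seq(36, 42, length.out = 30), 2))
  d$grp <- rep(c("treated", "control"), each = 30)
  d$exam_age_hours <- runif(60, 1, 90)
  d$y <- 2000 + 30 * d$ga_birth_weeks + 0.5 * d$exam_age_hours +
    ifelse(d$grp == "treated", -500, 0)
  res <- adjusted_group_difference(d, "grp", "y",
                                   c("ga_birth_weeks", "exam_age_hours"),
                                   ref = "control")
  expect_equal(unname(res$coefficients[".grouptreated"]), -500,
               tolerance = 1e-9)
  # identical groups -> difference 0
  d$y2 <- 10 + d$ga_birth_weeks
  res0 <- adjusted_group_difference(d, "grp", "y2", "ga_birth_weeks",
                                    ref = "control")
  expect_equal(unname(res0$coefficients[".grouptreated"]), 0,
               tolerance = 1e-10)
  expect_error(adjusted_group_difference(d[d$grp == "treated", ], "grp", "y"),
               "two non-empty levels")
})

test_that("preterm-term adjusted difference has the expected sign and size", {
  coh <- default_cohort()
  coh$preterm_grp <- ifelse(coh$ga_birth_weeks < 37, "preterm", "term")
  res <- adjusted_group_difference(coh, "preterm_grp", "exam_weight_g",
                                   c("sex", "exam_age_hours"), ref = "term")
  diff <- unname(res$coefficients[".grouppreterm"])
  expect_lt(diff, -300)
  expect_gt(diff, -1200)
})

test_that("tissue decomposition reproduces the printed worked examples", {
  d <- decompose_weight_difference(-693, -112, -581, 348, 2906)
  expect_equal(round(d$fm_share), 16)
  expect_equal(round(d$ffm_share), 84)
  expect_equal(round(d$ffm_relative), 20)
  d <- decompose_weight_difference(-680, -184, -496, 332, 2868,
                                   group_fm = 140, group_ffm = 2256)
  expect_equal(round(d$fm_share), 27)
  expect_equal(round(d$ffm_share), 73)
  expect_equal(round(d$fm_pct_of_comparator), 42)
  expect_equal(round(d$ffm_pct_of_comparator), 79)
})

test_that("decomposition shares close to 100 and are sign-invariant", {
  set.seed(5)
  for (i in 1:20) {
    dfm <- rnorm(1, -150, 40); dffm <- rnorm(1, -500, 80)
    dw <- dfm + dffm
    d <- decompose_weight_difference(dw, dfm, dffm, 350, 2900)
    expect_equal(d$fm_share + d$ffm_share, 100)
    flip <- decompose_weight_difference(-dw, -dfm, -dffm, 350, 2900)
    expect_equal(flip$fm_share, d$fm_share)
    expect_equal(flip$ffm_relative, d$ffm_relative)
  }
  expect_error(decompose_weight_difference(0, -10, 10, 350, 2900),
               "non-zero")
})

test_that("postnatal age table flags FFM-dominated loss and handles nulls", {
  # constructed cohort: FFM loss only, FM constant across bands
  set.seed(99)
  n <- 300
  d <- make_records(n, sex = rep(c("M", "F"), length.out = n),
                    ga = runif(n, 37, 41))
  d$exam_age_hours <- runif(n, 1, 90)
  band_num <- as.integer(categorize_exam_age(d$exam_age_hours))
  d$fm_g <- 330 + rnorm(n, 0, 5)  # no band structure in FM
  d$ffm_g <- 2900 - 100 * (band_num - 1)
  d$exam_weight_g <- d$fm_g + d$ffm_g
  d$bf_pct <- 100 * d$fm_g / d$exam_weight_g
  tab <- postnatal_age_table(d, outcomes = c("fm_g", "ffm_g"))
  fm_means <- tab$mean[tab$outcome == "fm_g" & tab$sex == "F"]
  ffm_means <- tab$mean[tab$outcome == "ffm_g" & tab$sex == "F"]
  expect_lt(max(abs(fm_means - 330)), 3)
  expect_true(all(diff(ffm_means) < 0))
  # FM carries no band effect, FFM a large one
  p_fm <- tab$p_vs_ref[tab$outcome == "fm_g" & !is.na(tab$p_vs_ref)]
  expect_true(all(p_fm > 0.01))
  p_ffm <- tab$p_vs_ref[tab$outcome == "ffm_g" & !is.na(tab$p_vs_ref)]
  expect_true(all(p_ffm < 1e-6))
  # missing reference band is rejected
  d2 <- d[d$exam_age_hours >= 12, ]
  expect_error(postnatal_age_table(d2), "reference band")
})
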