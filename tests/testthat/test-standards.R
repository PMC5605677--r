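test_that("fractional-polynomial basis follows the power conventions", {
  expect_equal(drop(fp_basis(4, c(0, 2))), c(log(4), 16))
  expect_equal(drop(fp_basis(4, -0.5)), 0.5)
  expect_equal(drop(fp_basis(4, c(1, 1))), c(4, 4 * log(4)))
  expect_equal(drop(fp_basis(4, c(0, 0))), c(log(4), log(4)^2))
  expect_error(fp_basis(-1, 1), "positive")
  expect_error(fp_basis(4, c(2, 1)), "non-decreasing")
  expect_equal(length(fp2_candidates <- nbcomp:::fp2_candidates()), 36)
  expect_equal(fp2_candidates[[1]], c(1, 2))  # tie-break order
})

test_that("noiseless FP2 curves are recovered exactly", {
  x <- seq(3.0, 4.3, length.out = 60)
  cases <- list(
    list(powers = c(0, 2), coef = c(2, 3, 0.5)),
    list(powers = c(-2, 1), coef = c(1, 4, -2)),
    list(powers = c(0.5, 3), coef = c(-1, 2, 0.1)),
    list(powers = c(2, 2), coef = c(0.5, 1.5, -0.7))
  )
  for (cs in cases) {
    y <- drop(cbind(1, fp_basis(x, cs$powers)) %*% cs$coef)
    fit <- fit_fp_mean(x, y)
    expect_equal(fit$powers, cs$powers)
    expect_equal(fit$coef, cs$coef, tolerance = 1e-6)
    expect_lt(fit$rss, 1e-10)
  }
})

test_that("FP2 power selection is stable under small noise", {
  # the log component must stand clear of the noise floor for the pair to
  # be identifiable; here each basis contribution spans >> the noise SD
  x <- seq(26, 44, length.out = 120)
  y0 <- 2 + 300 * log(x) + 0.5 * x^2
  set.seed(314)
  hits <- 0
  for (i in 1:100) {
    fit <- fit_fp_mean(x, y0 + rnorm(length(x), 0, 0.01))
    if (identical(fit$powers, c(0, 2))) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("constant response selects the tie-break candidate with ~0 slopes", {
  x <- seq(3, 4.3, length.out = 40)
  fit <- fit_fp_mean(x, rep(5, 40))
  expect_equal(fit$powers, c(1, 2))
  expect_equal(fit$coef[2:3], c(0, 0), tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)
})

test_that("the half-normal correction and SD recovery behave as expected", {
  # E|r| of a half-normal with sigma = 1 is sqrt(2/pi)
  set.seed(21)
  r <- rnorm(2e5)
  expect_equal(sqrt(pi / 2) * mean(abs(r)), 1, tolerance = 0.01)
  # sigma(x) = 0.1 x over an identifiable range: power 1, slope within 10%
  n <- 5000
  x <- runif(n, 1, 10)
  res <- rnorm(n, 0, 0.1 * x)
  sfit <- fit_fp_sd(x, res)
  expect_equal(sfit$power, 1)
  expect_lt(abs(sfit$coef[2] - 0.1) / 0.1, 0.10)
  # homoscedastic residuals -> near-constant fitted sigma, z SD ~ 1
  res2 <- rnorm(n, 0, 2)
  sfit2 <- fit_fp_sd(x, res2)
  sig <- nbcomp:::eval_sd(sfit2, x)
  expect_lt(diff(range(sig)) / mean(sig), 0.2)
  expect_equal(sd(res2 / sig), 1, tolerance = 0.05)
})

test_that("a standard fitted on data from a known FP model recovers its curves", {
  set.seed(404)
  n <- 5000
  ga <- runif(n, 33, 43)
  x <- ga / 10
  mu <- -2000 + 900 * x^2 - 60 * x^3
  sig <- 50 + 80 * x
  d <- data.frame(sex = "F", ga_birth_weeks = ga,
                  y = rnorm(n, mu, sig))
  std <- fit_standard(d, "y", "female")
  grid <- seq(33.5, 42.5, by = 0.5)
  gx <- grid / 10
  mu_true <- -2000 + 900 * gx^2 - 60 * gx^3
  sig_true <- 50 + 80 * gx
  mu_hat <- predict(std, grid, type = "mean")
  sig_hat <- predict(std, grid, type = "sd")
  expect_lt(sqrt(mean((mu_hat - mu_true)^2)) / mean(abs(mu_true)), 0.02)
  expect_lt(sqrt(mean((sig_hat - sig_true)^2)) / mean(sig_true), 0.02)
  # fitted z-scores are calibrated on the training data
  expect_lt(abs(mean(std$z)), 0.05)
  expect_lt(abs(sd(std$z) - 1), 0.05)
})

test_that("ML refinement agrees with the two-stage fit on well-specified data", {
  set.seed(77)
  n <- 2000
  ga <- runif(n, 33, 43)
  x <- ga / 10
  d <- data.frame(sex = "M", ga_birth_weeks = ga,
                  y = rnorm(n, 500 + 600 * x, 30 + 40 * x))
  s2 <- fit_standard(d, "y", "male")
  sml <- fit_standard(d, "y", "male", ml = TRUE)
  grid <- seq(34, 42, by = 1)
  expect_lt(max(abs(predict(sml, grid, "mean") - predict(s2, grid, "mean")) /
                  predict(s2, grid, "sd")), 0.1)
  expect_lt(max(abs(predict(sml, grid, "sd") / predict(s2, grid, "sd") - 1)),
            0.05)
})

test_that("z-scores and centile curves are mutual inverses with flags", {
  coh <- default_cohort()
  std <- fit_standard(coh, "ffm_g", "female")
  ga <- c(36, 39, 41)
  mu <- predict(std, ga, type = "mean")
  expect_equal(as.numeric(zscore(mu, ga, std)), rep(0, 3))
  expect_equal(as.numeric(centile_curve(50, ga, std)), mu)
  # qnorm oracle: 97th centile at mu 6.5, sigma 0.5 is 6.5 + 0.5 * 1.880794
  expect_equal(6.5 + 0.5 * qnorm(0.97), 7.44040, tolerance = 1e-5)
  v <- as.numeric(centile_curve(80, ga, std))
  z <- as.numeric(zscore(v, ga, std))
  expect_equal(as.numeric(centile_curve(100 * pnorm(z), ga, std)), v)
  # flags
  lowga <- std$ga_domain[1] - 1
  z2 <- zscore(3000, c(lowga, 27, 39), std)
  expect_equal(attr(z2, "outside_domain")[1], TRUE)
  expect_equal(attr(z2, "caution"), c(FALSE, TRUE, FALSE))
  expect_error(centile_curve(0, 39, std), "0, 100")
})

test_that("centile curves increase in p and the tabulation is consistent", {
  coh <- default_cohort()
  std <- fit_standard(coh, "ffm_g", "male")
  tab <- tabulate_centiles(std, seq(35, 42), centiles = c(3, 10, 50, 90, 97))
  for (w in unique(tab$ga_weeks)) {
    v <- tab$value[tab$ga_weeks == w][order(tab$centile[tab$ga_weeks == w])]
    expect_true(all(diff(v) > 0))
  }
  expect_equal(tab$value[tab$centile == 50],
               as.numeric(predict(std, unique(tab$ga_weeks), type = "mean")))
  expect_true(all(tab$region == ifelse(tab$ga_weeks >= 33, "standard",
                                       ifelse(tab$ga_weeks >= 28,
                                              "reference", "caution"))))
})

test_that("Q statistics match the hand formula and null structure", {
  # two groups {1,-1} and {2,0}: Q_mean = 2*0^2 + 2*1^2 = 2
  z <- c(1, -1, 2, 0)
  ga <- c(30, 31, 40, 41)
  q <- q_statistics(z, ga, n_groups = 3, df_mean = 0, df_sd = 0)
  expect_equal(q$q_mean$statistic, 2)
  # all group means zero -> Q_mean = 0
  z0 <- c(1, -1, 0.5, -0.5, 2, -2)
  q0 <- q_statistics(z0, rep(c(30, 35, 40), each = 2), n_groups = 3,
                     df_mean = 0, df_sd = 0)
  expect_equal(q0$q_mean$statistic, 0)
  # df floors at 1
  q1 <- q_statistics(rnorm(60), runif(60, 30, 42), n_groups = 3,
                     df_mean = 5, df_sd = 5)
  expect_equal(q1$q_mean$df, 1)
})

test_that("Q statistics are chi-square calibrated under the null", {
  set.seed(2718)
  n_sim <- 1000
  n <- 600
  rej_m <- rej_s <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    z <- rnorm(n)
    ga <- runif(n, 33, 43)
    q <- q_statistics(z, ga, n_groups = 6, df_mean = 0, df_sd = 0)
    rej_m[i] <- q$q_mean$p < 0.05
    rej_s[i] <- q$q_sd$p < 0.05
  }
  band <- 1.96 * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(mean(rej_m) - 0.05), band + 0.005)
  expect_lt(abs(mean(rej_s) - 0.05), band + 0.012)
})

test_that("worm coordinates detect shifts and scale changes", {
  set.seed(12)
  ga <- runif(200, 33, 43)
  n_g <- 4
  # z equal to the theoretical quantiles within each group -> deviations 0
  grp <- nbcomp:::ga_groups(ga, n_g)
  z <- numeric(200)
  for (g in unique(grp$index)) {
    i <- which(grp$index == g)
    z[i] <- qnorm((rank(runif(length(i))) - 0.5) / length(i))
  }
  w <- worm_plot_data(z, ga, n_g)
  expect_lt(max(abs(w$deviation)), 1e-10)
  # constant shift moves the worm bodily
  w2 <- worm_plot_data(z + 0.5, ga, n_g)
  expect_equal(w2$deviation, w$deviation + 0.5)
  # scaling by 2 tilts the worm with slope ~ 1 in the theoretical quantile
  w3 <- worm_plot_data(2 * z, ga, n_g)
  sl <- coef(lm(deviation ~ theoretical, data = w3))["theoretical"]
  expect_equal(unname(sl), 1, tolerance = 0.05)
})

test_that("smoothed centiles agree with empirical centiles on self-generated data", {
  coh <- default_cohort()
  std <- fit_standard(coh, "ffm_g", "female")
  set.seed(55)
  n <- 10000
  ga <- runif(n, std$ga_domain[1] + 0.2, std$ga_domain[2] - 0.2)
  y <- simulate(std, ga = ga)$sim_1
  d <- data.frame(sex = "F", ga_birth_weeks = ga, ffm_g = y)
  cmp <- compare_empirical(std, d, centiles = c(3, 50, 97))
  sig_bar <- mean(predict(std, seq(35, 42), type = "sd"))
  expect_lt(cmp$mean_abs[["50"]], 0.05 * sig_bar)
})

test_that("degenerate inputs are refused", {
  coh <- default_cohort()
  expect_error(fit_standard(coh[1:10, ], "ffm_g", "female"), "more than 30")
  narrow <- coh[abs(coh$ga_birth_weeks - 39.4) < 0.8, ]
  expect_error(fit_standard(narrow, "ffm_g", "female"), "narrower than 2")
  expect_error(q_statistics(rnorm(10), runif(10, 30, 40), n_groups = 2),
               "at least 3")
})

test_that("standard methods expose the model idiomatically", {
  coh <- default_cohort()
  std <- fit_standard(coh, "ffm_g", "female")
  expect_s3_class(std, "fp_standard")
  expect_output(print(std), "centile standard")
  expect_output(print(summary(std)), "Q statistics")
  expect_named(coef(std), c("mean", "sd"))
  expect_equal(residuals(std), std$z)
  expect_equal(length(fitted(std)), std$n)
  sims <- simulate(std, nsim = 2, seed = 1, ga = c(38, 40))
  expect_equal(dim(sims), c(2, 2))
  sims2 <- simulate(std, nsim = 2, seed = 1, ga = c(38, 40))
  expect_identical(sims, sims2)
  pdf(NULL)
  expect_silent(plot(std))
  dev.off()
})
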