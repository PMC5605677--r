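# Descriptive and adjusted inferential statistics of the cohort analysis:
# per-sex GA slopes, sex contrasts at the mean GA, covariate-adjusted group
# differences, postnatal-age tables and tissue decomposition of weight
# differences.

z975 <- stats::qnorm(0.975)

# package a fitted lm as a light-weight regression result
new_reg_result <- function(fit, robust = FALSE) {
  est <- stats::coef(fit)
  V <- if (robust) sandwich::vcovHC(fit, type = "HC1") else stats::vcov(fit)
  se <- sqrt(diag(V))
  sm <- summary(fit)
  adj_r2 <- sm$adj.r.squared
  structure(list(
    coefficients = est,
    se = se,
    ci95 = cbind(low = est - z975 * se, high = est + z975 * se),
    p = 2 * stats::pnorm(-abs(est / se)),
    adj_r2 = adj_r2,
    adj_r2_clipped = adj_r2 < 0,
    n = length(stats::fitted(fit)),
    robust = robust,
    fit = fit
  ), class = "nbc_reg")
}

#' @export
print.nbc_reg <- function(x, digits = 4, ...) {
  cat(sprintf("Linear model (n = %d, %s SEs)\n", x$n,
              if (x$robust) "robust HC1" else "classical"))
  tab <- cbind(estimate = x$coefficients, se = x$se,
               ci_low = x$ci95[, "low"], ci_high = x$ci95[, "high"], p = x$p)
  print(round(tab, digits))
  cat(sprintf("adjusted R-squared: %.4f%s\n", max(x$adj_r2, 0),
              if (x$adj_r2_clipped) " (clipped from negative)" else ""))
  invisible(x)
}

#' Per-sex gestational-age slope of an outcome
#'
#' Ordinary least squares of an outcome on gestational age (weeks) within
#' one sex, giving the average change per week of gestation with classical
#' standard errors and 95% confidence interval.
#'
#' @param records Cohort table.
#' @param outcome Name of the outcome column (e.g. \code{"ffm_g"}).
#' @param sex \code{"male"} or \code{"female"} (records coded "M"/"F").
#' @param adjust_exam_age Also adjust for exam age in hours (default FALSE).
#' @return An object of class \code{nbc_reg}; the GA slope is the
#'   \code{ga_birth_weeks} coefficient.
#' @export
fit_ga_slope <- function(records, outcome, sex = c("female", "male"),
                         adjust_exam_age = FALSE) {
  sex <- match.arg(sex)
  d <- records[records$sex == if (sex == "male") "M" else "F", , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 records of the given sex", call. = FALSE)
  if (stats::var(d$ga_birth_weeks) == 0)
    stop("gestational age has zero variance", call. = FALSE)
  rhs <- c("ga_birth_weeks", if (adjust_exam_age) "exam_age_hours")
  fit <- stats::lm(stats::reformulate(rhs, outcome), data = d)
  new_reg_result(fit)
}

#' Sex contrast of an outcome at the mean gestational age
#'
#' Fits \code{outcome ~ sex + (GA - mean GA) + sex:(GA - mean GA)}; because
#' GA is centred at the pooled mean, the sex main effect is the contrast
#' between the two sex-specific regression lines evaluated at the mean GA.
#' The returned difference is female minus male.
#'
#' @inheritParams fit_ga_slope
#' @return A list with \code{difference}, \code{se}, \code{p_value} (Wald)
#'   and \code{n}.
#' @export
sex_contrast_at_mean_ga <- function(records, outcome) {
  if (length(unique(records$sex)) < 2)
    stop("both sexes must be present", call. = FALSE)
  d <- records
  d$.sex <- factor(d$sex, levels = c("M", "F"))
  d$.ga_c <- d$ga_birth_weeks - mean(d$ga_birth_weeks)
  fit <- stats::lm(stats::reformulate(".sex * .ga_c", outcome), data = d)
  res <- new_reg_result(fit)
  list(difference = unname(res$coefficients[".sexF"]),
       se = unname(res$se[".sexF"]),
       p_value = unname(res$p[".sexF"]),
       n = res$n)
}

#' Covariate-adjusted mean difference between groups
#'
#' OLS of the outcome on group indicator(s) plus covariates; each non-
#' reference group coefficient is the adjusted mean difference against the
#' reference level, with 95% confidence interval.
#'
#' @inheritParams fit_ga_slope
#' @param group Name of the grouping column (coerced to factor).
#' @param covariates Character vector of adjustment columns (may be empty).
#' @param ref Reference level of the group (default: first factor level).
#' @param robust Use HC1 sandwich standard errors (default FALSE).
#' @return An \code{nbc_reg}; group coefficients are named
#'   \code{<group><level>}.
#' @export
adjusted_group_difference <- function(records, group, outcome,
                                      covariates = character(0), ref = NULL,
                                      robust = FALSE) {
  g <- factor(records[[group]])
  if (any(table(g) == 0) || nlevels(g) < 2)
    stop("group must have at least two non-empty levels", call. = FALSE)
  if (!is.null(ref)) g <- stats::relevel(g, ref = ref)
  d <- records
  d$.group <- g
  fit <- stats::lm(stats::reformulate(c(".group", covariates), outcome),
                   data = d)
  new_reg_result(fit, robust = robust)
}

#' Decompose a weight difference into its tissue components
#'
#' Expresses a between-group weight difference in terms of its fat and
#' fat-free parts: the share of the weight difference carried by each tissue
#' (\code{fm_share + ffm_share = 100} whenever the deltas close), each delta
#' relative to the comparator group's tissue mass, and — when raw group
#' means are supplied — the group mean as a percentage of the comparator
#' mean and the corresponding percent reduction.
#'
#' @param delta_weight,delta_fm,delta_ffm Group differences in g
#'   (non-zero total weight difference required).
#' @param comparator_fm,comparator_ffm Comparator-group mean FM and FFM, g.
#' @param group_fm,group_ffm Optional index-group mean FM and FFM, g.
#' @return An object of class \code{nbc_decomp}: a list with
#'   \code{fm_share}, \code{ffm_share}, \code{fm_relative},
#'   \code{ffm_relative} (all %), and when group means are given also
#'   \code{fm_pct_of_comparator}, \code{ffm_pct_of_comparator},
#'   \code{fm_reduction_pct}, \code{ffm_reduction_pct}. Values are exact;
#'   rounding happens only in printing.
#' @examples
#' d <- decompose_weight_difference(-693, -112, -581, 348, 2906)
#' round(c(d$fm_share, d$ffm_share, d$ffm_relative))  # 16 84 20
#' @export
decompose_weight_difference <- function(delta_weight, delta_fm, delta_ffm,
                                        comparator_fm, comparator_ffm,
                                        group_fm = NULL, group_ffm = NULL) {
  if (delta_weight == 0) stop("delta_weight must be non-zero", call. = FALSE)
  if (comparator_fm <= 0 || comparator_ffm <= 0)
    stop("comparator masses must be positive", call. = FALSE)
  out <- list(
    delta_weight = delta_weight, delta_fm = delta_fm, delta_ffm = delta_ffm,
    fm_share = 100 * abs(delta_fm) / abs(delta_weight),
    ffm_share = 100 * abs(delta_ffm) / abs(delta_weight),
    fm_relative = 100 * abs(delta_fm) / comparator_fm,
    ffm_relative = 100 * abs(delta_ffm) / comparator_ffm
  )
  if (!is.null(group_fm) && !is.null(group_ffm)) {
    out$fm_pct_of_comparator <- 100 * group_fm / comparator_fm
    out$ffm_pct_of_comparator <- 100 * group_ffm / comparator_ffm
    out$fm_reduction_pct <- 100 * (comparator_fm - group_fm) / comparator_fm
    out$ffm_reduction_pct <- 100 * (comparator_ffm - group_ffm) / comparator_ffm
  }
  class(out) <- "nbc_decomp"
  out
}

#' @export
print.nbc_decomp <- function(x, ...) {
  cat(sprintf("Weight difference %0.f g: %.0f%% FM, %.0f%% FFM\n",
              x$delta_weight, x$fm_share, x$ffm_share))
  cat(sprintf("  vs comparator tissue: FM %.0f%%, FFM %.0f%%\n",
              x$fm_relative, x$ffm_relative))
  if (!is.null(x$fm_pct_of_comparator))
    cat(sprintf("  group/comparator means: FM %.0f%% (reduction %.0f%%), FFM %.0f%% (reduction %.0f%%)\n",
                x$fm_pct_of_comparator, x$fm_reduction_pct,
                x$ffm_pct_of_comparator, x$ffm_reduction_pct))
  invisible(x)
}

#' Body composition by postnatal exam-age band
#'
#' Per sex and exam-age band (\code{"<12"}, \code{"12-24"},
#' \code{">24 to <96"}): sample size, mean and SD of each outcome, and for
#' the non-reference bands a p-value for the mean difference against the
#' \code{"<12"} band from OLS of the outcome on band indicators plus
#' gestational age (weeks), fitted within sex with classical SEs.
#'
#' @param records Cohort table.
#' @param outcomes Outcome columns to summarize.
#' @return A long \code{data.frame} with columns \code{sex}, \code{band},
#'   \code{n}, \code{outcome}, \code{mean}, \code{sd}, \code{p_vs_ref}.
#' @export
postnatal_age_table <- function(records,
                                outcomes = c("exam_weight_g", "fm_g",
                                             "bf_pct", "ffm_g")) {
  d <- records
  d$.band <- categorize_exam_age(d$exam_age_hours)
  rows <- list()
  for (s in c("M", "F")) {
    ds <- d[d$sex == s, , drop = FALSE]
    if (nrow(ds) == 0) next
    if (sum(ds$.band == "<12") == 0)
      stop("reference band '<12' is empty for sex ", s, call. = FALSE)
    for (oc in outcomes) {
      fit <- stats::lm(stats::reformulate(c(".band", "ga_birth_weeks"), oc),
                       data = ds)
      res <- new_reg_result(fit)
      for (b in levels(ds$.band)) {
        v <- ds[[oc]][ds$.band == b]
        cf <- paste0(".band", b)
        rows[[length(rows) + 1]] <- data.frame(
          sex = s, band = b, n = length(v),
          outcome = oc, mean = mean(v), sd = stats::sd(v),
          p_vs_ref = if (b == "<12") NA_real_ else unname(res$p[cf]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
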