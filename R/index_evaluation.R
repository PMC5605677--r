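# Evaluation of anthropometric indices (weight/length, BMI, ponderal index)
# as predictors of body-composition outcomes, with HC1 robust standard
# errors and adjusted R-squared model comparison.

nbc_index_cols <- c(weight_length = "weight_length", bmi = "bmi",
                    ponderal = "ponderal")

# attach birth-anthropometry index columns if absent
with_indices <- function(records) {
  if (!all(nbc_index_cols %in% names(records))) {
    ix <- compute_indices(records$birth_weight_g, records$length_cm)
    records <- cbind(records, ix[, setdiff(nbc_index_cols, names(records)),
                                 drop = FALSE])
  }
  records
}

#' Regress a body-composition outcome on an anthropometric index
#'
#' OLS of the outcome on one index, optionally adjusted for gestational age
#' at delivery (weeks), age at examination (hours) and sex, with
#' heteroscedasticity-consistent (HC1 sandwich) standard errors. The
#' adjusted R-squared is that of the full fitted model.
#'
#' @param records Cohort table; index columns (\code{weight_length},
#'   \code{bmi}, \code{ponderal}) are derived from birth weight and length
#'   when absent.
#' @param index Index column name.
#' @param outcome Outcome column name (e.g. \code{"ffm_g"}).
#' @param adjusted Include the GA / exam-age / sex covariates (default TRUE).
#' @param robust HC1 sandwich SEs (default TRUE).
#' @param sex Optionally restrict the fit to \code{"male"} or
#'   \code{"female"} records (stratified analysis).
#' @return An \code{nbc_reg}; the index coefficient carries the index name.
#' @export
fit_index_model <- function(records, index, outcome, adjusted = TRUE,
                            robust = TRUE, sex = NULL) {
  d <- with_indices(records)
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("male", "female"))
    d <- d[d$sex == if (sex == "male") "M" else "F", , drop = FALSE]
  }
  if (nrow(d) < 10) stop("need at least 10 records", call. = FALSE)
  if (!index %in% names(d)) stop("unknown index column: ", index, call. = FALSE)
  rhs <- c(index,
           if (adjusted) c("ga_birth_weeks", "exam_age_hours",
                           if (is.null(sex) && length(unique(d$sex)) > 1)
                             "sex"))
  fit <- stats::lm(stats::reformulate(rhs, outcome), data = d)
  if (fit$rank < length(stats::coef(fit)) || anyNA(stats::coef(fit)))
    stop("collinear design: coefficients not estimable for terms ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  new_reg_result(fit, robust = robust)
}

#' Compare the three indices across body-composition outcomes
#'
#' Fits all index-by-outcome regressions via [fit_index_model()] and ranks
#' the indices for each outcome by descending adjusted R-squared.
#'
#' @inheritParams fit_index_model
#' @param outcomes Outcome columns (default FM, BF% and FFM).
#' @param indices Index columns (default all three).
#' @return An object of class \code{nbc_index_comparison}: a list with a
#'   \code{rows} data.frame (index, outcome, beta, ci_low, ci_high, adj_r2)
#'   and a \code{ranking} list of index names per outcome.
#' @export
rank_indices <- function(records, outcomes = c("fm_g", "bf_pct", "ffm_g"),
                         indices = unname(nbc_index_cols), adjusted = TRUE,
                         robust = TRUE) {
  rows <- list()
  for (oc in outcomes) {
    for (ix in indices) {
      res <- fit_index_model(records, ix, oc, adjusted = adjusted,
                             robust = robust)
      rows[[length(rows) + 1]] <- data.frame(
        index = ix, outcome = oc,
        beta = unname(res$coefficients[ix]),
        ci_low = res$ci95[ix, "low"], ci_high = res$ci95[ix, "high"],
        adj_r2 = res$adj_r2, stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  ranking <- lapply(split(rows, rows$outcome), function(d)
    d$index[order(-d$adj_r2)])
  structure(list(rows = rows, ranking = ranking[outcomes]),
            class = "nbc_index_comparison")
}

#' @export
print.nbc_index_comparison <- function(x, ...) {
  cat("Anthropometric index comparison (adjusted R-squared)\n")
  for (oc in unique(x$rows$outcome)) {
    d <- x$rows[x$rows$outcome == oc, ]
    cat(sprintf("  %s:\n", oc))
    for (i in seq_len(nrow(d)))
      cat(sprintf("    %-14s beta %8.1f (%.1f, %.1f)   adj R2 %.2f\n",
                  d$index[i], d$beta[i], d$ci_low[i], d$ci_high[i],
                  d$adj_r2[i]))
    cat(sprintf("    ranking: %s\n",
                paste(x$ranking[[oc]], collapse = " > ")))
  }
  invisible(x)
}
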