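#' Anthropometric indices
#'
#' Weight/length ratio (kg/m), body mass index (kg/m^2) and ponderal index
#' (kg/m^3) from weight in grams and recumbent length in centimetres. The
#' three indices satisfy \code{bmi = weight_length / length_m} and
#' \code{ponderal = bmi / length_m} exactly.
#'
#' @param weight Weight in g (vectorized, positive).
#' @param length Length in cm (positive).
#' @return A \code{data.frame} with columns \code{weight_length},
#'   \code{bmi} and \code{ponderal}.
#' @examples
#' compute_indices(3500, 50)  # 7, 14, 28
#' @export
compute_indices <- function(weight, length) {
  if (any(weight <= 0) || any(length <= 0))
    stop("weight and length must be positive", call. = FALSE)
  w_kg <- weight / 1000
  l_m <- length / 100
  data.frame(weight_length = w_kg / l_m,
             bmi = w_kg / l_m^2,
             ponderal = w_kg / l_m^3)
}

#' Apply the cohort exclusion rules
#'
#' Removes, in order: records flagged with a congenital malformation,
#' records examined after \code{exam_age_limit} hours, and records whose fat
#' or fat-free mass lies more than \code{fm_ffm_z_limit} within-sex sample
#' SDs from the within-sex mean (moments computed among the records
#' remaining after the first two rules). The z-screen uses the raw
#' within-sex SD of FM and FFM, not GA-adjusted residuals, and is iterated
#' to a fixed point — after removal the moments are recomputed and the rule
#' re-applied until no record exceeds the threshold — so that applying the
#' exclusions twice equals applying them once.
#'
#' @param records Cohort table with columns \code{sex}, \code{exam_age_hours},
#'   \code{fm_g}, \code{ffm_g} and optionally \code{malformation}.
#' @param fm_ffm_z_limit Outlier threshold in SD units (default 3).
#' @param exam_age_limit Latest admissible exam age in hours (default 96).
#' @return A list with the retained table (\code{kept}) and an integer
#'   \code{audit} vector counting removals by reason, in application order
#'   (\code{malformation}, \code{late_exam}, \code{outlier}).
#' @export
apply_exclusions <- function(records, fm_ffm_z_limit = 3, exam_age_limit = 96) {
  audit <- c(malformation = 0L, late_exam = 0L, outlier = 0L)
  if (nrow(records) == 0) return(list(kept = records, audit = audit))

  malf <- if ("malformation" %in% names(records))
    as.logical(records$malformation) else rep(FALSE, nrow(records))
  malf[is.na(malf)] <- FALSE
  audit["malformation"] <- sum(malf)
  records <- records[!malf, , drop = FALSE]

  late <- records$exam_age_hours > exam_age_limit
  audit["late_exam"] <- sum(late)
  records <- records[!late, , drop = FALSE]

  if (nrow(records) > 0) {
    if (any(is.na(records$fm_g)) || any(is.na(records$ffm_g)))
      stop("fm_g and ffm_g must be present for the z-score screen",
           call. = FALSE)
    repeat {
      out <- rep(FALSE, nrow(records))
      for (s in unique(records$sex)) {
        i <- records$sex == s
        zf <- abs(scale(records$fm_g[i]))
        zl <- abs(scale(records$ffm_g[i]))
        out[i] <- (!is.na(zf) & zf > fm_ffm_z_limit) |
          (!is.na(zl) & zl > fm_ffm_z_limit)
      }
      if (!any(out)) break
      audit["outlier"] <- audit["outlier"] + sum(out)
      records <- records[!out, , drop = FALSE]
    }
  }
  list(kept = records, audit = audit)
}

#' Select the prescriptive (chart-building) subset
#'
#' Keeps records flagged as low-risk whose antenatal ultrasound biometry was
#' unremarkable: a record is excluded when any ultrasound z-score exceeds 4
#' in absolute value, or when two or more exceed 3. Records without
#' ultrasound data incur no ultrasound exclusion.
#'
#' @param records Cohort table with a logical \code{low_risk} column and an
#'   optional \code{ultrasound_z} column (semicolon-joined decimals).
#' @return The retained subset of \code{records}.
#' @export
select_prescriptive <- function(records) {
  keep_us <- rep(TRUE, nrow(records))
  if ("ultrasound_z" %in% names(records)) {
    zl <- parse_ultrasound_z(records$ultrasound_z)
    keep_us <- vapply(zl, function(z) {
      if (length(z) == 0) return(TRUE)
      az <- abs(z)
      !(any(az > 4) || sum(az > 3) >= 2)
    }, logical(1))
  }
  records[as.logical(records$low_risk) & keep_us, , drop = FALSE]
}

parse_ultrasound_z <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Classify newborn phenotypes against centile standards
#'
#' Assigns per-record flags against supplied sex-specific centile standards:
#' small for gestational age (SGA, birth weight strictly below the 10th
#' centile), large for gestational age (LGA, strictly above the 90th),
#' otherwise appropriate (AGA); wasting (BMI strictly below the 3rd
#' centile); stunting (length strictly below the 3rd centile); and preterm
#' birth (gestational age below 37.0 weeks). Ties classify to the central
#' category. A record may be simultaneously wasted and stunted.
#'
#' When a record's GA falls outside a standard's fitted domain the
#' corresponding classification is refused (\code{NA}) and flagged.
#'
#' @param records Cohort table (needs \code{sex}, \code{ga_birth_weeks},
#'   \code{birth_weight_g}, \code{length_cm}).
#' @param weight_std,length_std,bmi_std Named lists with components
#'   \code{male} and \code{female}, each an [fp_standard] for birth weight
#'   (g), length (cm) and BMI (kg/m^2) respectively.
#' @return A \code{data.frame} with columns \code{size_class}
#'   ("SGA"/"AGA"/"LGA"), \code{wasted}, \code{stunted}, \code{preterm} and
#'   logical refusal flags \code{flag_weight}, \code{flag_length},
#'   \code{flag_bmi} (TRUE where GA was outside that standard's domain).
#' @seealso [fit_standard()]
#' @export
classify_cohort <- function(records, weight_std, length_std, bmi_std) {
  n <- nrow(records)
  key <- ifelse(records$sex == "M", "male", "female")
  bmi <- compute_indices(records$birth_weight_g, records$length_cm)$bmi
  out <- data.frame(size_class = rep(NA_character_, n),
                    wasted = rep(NA, n), stunted = rep(NA, n),
                    preterm = records$ga_birth_weeks < 37.0,
                    flag_weight = rep(FALSE, n), flag_length = rep(FALSE, n),
                    flag_bmi = rep(FALSE, n), stringsAsFactors = FALSE)
  for (s in c("male", "female")) {
    i <- which(key == s)
    if (length(i) == 0) next
    ga <- records$ga_birth_weeks[i]

    dom <- weight_std[[s]]$ga_domain
    ok <- ga >= dom[1] & ga <= dom[2]
    out$flag_weight[i] <- !ok
    p10 <- centile_curve(10, ga, weight_std[[s]])
    p90 <- centile_curve(90, ga, weight_std[[s]])
    w <- records$birth_weight_g[i]
    cls <- ifelse(w < p10, "SGA", ifelse(w > p90, "LGA", "AGA"))
    out$size_class[i] <- ifelse(ok, cls, NA_character_)

    dom <- length_std[[s]]$ga_domain
    ok <- ga >= dom[1] & ga <= dom[2]
    out$flag_length[i] <- !ok
    p3 <- centile_curve(3, ga, length_std[[s]])
    out$stunted[i] <- ifelse(ok, records$length_cm[i] < p3, NA)

    dom <- bmi_std[[s]]$ga_domain
    ok <- ga >= dom[1] & ga <= dom[2]
    out$flag_bmi[i] <- !ok
    p3 <- centile_curve(3, ga, bmi_std[[s]])
    out$wasted[i] <- ifelse(ok, bmi[i] < p3, NA)
  }
  out
}

#' @rdname classify_cohort
#' @param record A single-row cohort table.
#' @export
classify_newborn <- function(record, weight_std, length_std, bmi_std) {
  if (nrow(record) != 1) stop("record must be a single row", call. = FALSE)
  classify_cohort(record, weight_std, length_std, bmi_std)
}

#' Postnatal exam-age band
#'
#' Assigns the exam age to the reporting bands \code{"<12"} (under 12 h),
#' \code{"12-24"} (12 h to 24 h inclusive) and \code{">24 to <96"}.
#'
#' @param exam_age Exam age in hours, in (0, 96].
#' @return A factor with the three band levels.
#' @export
categorize_exam_age <- function(exam_age) {
  if (any(exam_age <= 0 | exam_age > 96))
    stop("exam_age must be in (0, 96] hours", call. = FALSE)
  bands <- ifelse(exam_age < 12, "<12",
                  ifelse(exam_age <= 24, "12-24", ">24 to <96"))
  factor(bands, levels = c("<12", "12-24", ">24 to <96"))
}
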