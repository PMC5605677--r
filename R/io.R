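# Cohort CSV schema, readers/writers and the end-to-end pipeline.

cohort_required_cols <- c("id", "sex", "ga_birth_weeks", "exam_age_hours",
                          "birth_weight_g", "exam_weight_g", "length_cm",
                          "head_circ_cm", "low_risk", "malformation")
cohort_optional_cols <- c("body_volume_ml", "fm_g", "ffm_g", "bf_pct",
                          "ultrasound_z")

#' Read a cohort CSV
#'
#' Reads a newborn cohort table in the package schema (one row per newborn;
#' units fixed by the column names: GA in decimal weeks, exam age in hours,
#' masses in g, lengths in cm). Missing optional fields are empty strings in
#' the file and become \code{NA} (or \code{""} for \code{ultrasound_z}).
#' Rows with out-of-range values (GA outside 26–44 weeks, length outside
#' 30–65 cm) are loaded but flagged with a warning naming the rows.
#'
#' @param path CSV file path.
#' @return A cohort \code{data.frame}; flagged row indices are attached as
#'   attribute \code{"flagged_rows"}.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  missing <- setdiff(cohort_required_cols, names(d))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("ga_birth_weeks", "exam_age_hours", "birth_weight_g",
                "exam_weight_g", "length_cm", "head_circ_cm",
                intersect(c("body_volume_ml", "fm_g", "ffm_g", "bf_pct"),
                          names(d)))) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad) > 0)
        stop("unparseable value in column ", col, " at data row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      d[[col]] <- conv
    }
  }
  d$low_risk <- as.logical(d$low_risk) | d$low_risk == 1
  d$malformation <- as.logical(d$malformation) | d$malformation == 1
  if (!"ultrasound_z" %in% names(d)) d$ultrasound_z <- ""
  d$ultrasound_z[is.na(d$ultrasound_z)] <- ""
  flagged <- which(d$ga_birth_weeks < 26 | d$ga_birth_weeks > 44 |
                     d$length_cm < 30 | d$length_cm > 65)
  if (length(flagged) > 0)
    warning("out-of-range GA or length in row(s): ",
            paste(flagged, collapse = ", "), call. = FALSE)
  attr(d, "flagged_rows") <- flagged
  d
}

#' Write a cohort CSV
#'
#' Writes the table in the package schema at full floating-point precision
#' (presentation rounding is confined to report rendering);
#' \code{read_cohort(write_cohort(t))} reproduces \code{t}.
#'
#' @param records Cohort table.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(records, path) {
  d <- records
  d$low_risk <- as.integer(d$low_risk)
  d$malformation <- as.integer(d$malformation)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) format(v, digits = 17, trim = TRUE,
                                              scientific = FALSE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

pipeline_stages <- c("simulate", "densitometry", "exclusions", "classify",
                     "cohort_tables", "indices", "standards")

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis on a configuration: simulate (or
#' read) a cohort, derive body composition densitometrically from body
#' volume, apply the exclusion rules, classify phenotypes against
#' internally fitted standards, produce the descriptive and adjusted cohort
#' tables, the anthropometric index comparison, and the prescriptive
#' centile standards with goodness-of-fit diagnostics. All outputs are CSV
#' files in the configured output directory; a fixed seed makes them
#' byte-identical across reruns. Stage progress and timings are logged to
#' stderr with machine-parsable \code{[stage]} prefixes.
#'
#' The pipeline configuration is a JSON object (or an equivalent R list)
#' with fields \code{output_dir}, either \code{simulate} (\code{n},
#' \code{seed}, optional generator overrides) or \code{input} (a cohort
#' CSV), and optional \code{stages} (subset of \code{"simulate"},
#' \code{"densitometry"}, \code{"exclusions"}, \code{"classify"},
#' \code{"cohort_tables"}, \code{"indices"}, \code{"standards"}),
#' \code{centiles} and \code{n_groups}.
#'
#' @param config Path to a JSON configuration file, or a list.
#' @return Invisibly, a list with the final cohort, the exclusion audit and
#'   the paths of all files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config must name an output_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  centiles <- config$centiles %||% c(3, 10, 50, 90, 97)
  n_groups <- config$n_groups %||% 6
  paths <- character(0)
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    stage_log(stage, "done in %.2f s", proc.time()[["elapsed"]] - t0)
    r
  }

  cohort <- run_stage("simulate", {
    if (!is.null(config$simulate)) {
      cfg <- default_config()
      ov <- config$simulate
      for (nm in setdiff(names(ov), c("n", "seed")))
        cfg[[nm]] <- if (is.list(cfg[[nm]])) utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
      generate_cohort(cfg, n = ov$n, seed = ov$seed %||% cfg$seed)
    } else if (!is.null(config$input)) {
      read_cohort(config$input)
    } else stop("config must contain a 'simulate' block or an 'input' path")
  })
  stage_log("simulate", "%d records", nrow(cohort))
  if ("simulate" %in% stages || !is.null(config$simulate)) {
    p <- file.path(out_dir, "cohort.csv")
    write_cohort(cohort, p)
    paths <- c(paths, p)
  }
  if (identical(stages, "simulate") ||
      (length(stages) == 1 && stages == "simulate")) {
    return(invisible(list(cohort = cohort, audit = NULL, paths = paths)))
  }

  if ("densitometry" %in% stages) {
    cohort <- run_stage("densitometry", {
      if (all(!is.na(cohort$body_volume_ml))) {
        D <- body_density(cohort$exam_weight_g, cohort$body_volume_ml)
        bf <- suppressWarnings(bf_from_density(D, cohort$exam_age_hours / 24))
        comp <- decompose_weight(cohort$exam_weight_g, as.numeric(bf))
        cohort$bf_pct <- as.numeric(bf)
        cohort$fm_g <- comp$fm
        cohort$ffm_g <- comp$ffm
      }
      cohort
    })
  }

  audit <- NULL
  if ("exclusions" %in% stages) {
    ex <- run_stage("exclusions", apply_exclusions(cohort))
    audit <- ex$audit
    stage_log("exclusions",
              "removed %d malformation, %d late exam, %d outlier; kept %d",
              audit["malformation"], audit["late_exam"], audit["outlier"],
              nrow(ex$kept))
    cohort <- ex$kept
    p <- file.path(out_dir, "exclusion_audit.csv")
    utils::write.csv(data.frame(reason = names(audit), n = as.integer(audit)),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }

  pheno <- NULL
  if ("classify" %in% stages) {
    pheno <- run_stage("classify", {
      stds <- fit_phenotype_standards(cohort)
      classify_cohort(cohort, stds$weight, stds$length, stds$bmi)
    })
    cohort <- cbind(cohort, pheno[c("size_class", "wasted", "stunted",
                                    "preterm")])
    p <- file.path(out_dir, "cohort_classified.csv")
    write_cohort(cohort, p)
    paths <- c(paths, p)
  }

  if ("cohort_tables" %in% stages) {
    paths <- c(paths, run_stage("cohort_tables", {
      written <- character(0)
      tab3 <- postnatal_age_table(cohort)
      p <- file.path(out_dir, "postnatal_age_table.csv")
      utils::write.csv(tab3, p, row.names = FALSE)
      written <- c(written, p)
      if (!is.null(pheno)) {
        comp <- group_comparison_tables(cohort)
        p <- file.path(out_dir, "group_comparisons.csv")
        utils::write.csv(comp, p, row.names = FALSE)
        written <- c(written, p)
      }
      written
    }))
  }

  if ("indices" %in% stages) {
    paths <- c(paths, run_stage("indices", {
      cmp <- rank_indices(cohort)
      p <- file.path(out_dir, "index_comparison.csv")
      utils::write.csv(cmp$rows, p, row.names = FALSE)
      p
    }))
  }

  if ("standards" %in% stages) {
    paths <- c(paths, run_stage("standards", {
      presc <- select_prescriptive(cohort)
      base <- if (nrow(presc) > 100) presc else cohort
      written <- character(0)
      cent <- list(); gof <- list()
      for (oc in c("fm_g", "bf_pct", "ffm_g")) {
        for (sx in c("male", "female")) {
          std <- fit_standard(base, oc, sx)
          grid <- seq(ceiling(std$ga_domain[1]), floor(std$ga_domain[2]))
          tab <- tabulate_centiles(std, grid, centiles)
          tab$outcome <- oc
          cent[[length(cent) + 1]] <- tab
          qs <- q_statistics(std$z, std$ga, n_groups = n_groups)
          gof[[length(gof) + 1]] <- data.frame(
            outcome = oc, sex = sx, n = std$n,
            z_mean = mean(std$z), z_sd = stats::sd(std$z),
            q_mean = qs$q_mean$statistic, q_mean_df = qs$q_mean$df,
            q_mean_p = qs$q_mean$p,
            q_sd = qs$q_sd$statistic, q_sd_df = qs$q_sd$df,
            q_sd_p = qs$q_sd$p)
        }
      }
      p1 <- file.path(out_dir, "centile_tables.csv")
      utils::write.csv(do.call(rbind, cent), p1, row.names = FALSE)
      p2 <- file.path(out_dir, "gof_report.csv")
      utils::write.csv(do.call(rbind, gof), p2, row.names = FALSE)
      c(written, p1, p2)
    }))
  }

  invisible(list(cohort = cohort, audit = audit, paths = paths))
}

# adjusted group-difference tables for preterm/term, SGA/LGA vs AGA,
# wasted and stunted comparisons
group_comparison_tables <- function(cohort) {
  rows <- list()
  add <- function(label, d, group, ref, covs) {
    for (oc in c("exam_weight_g", "fm_g", "bf_pct", "ffm_g")) {
      res <- adjusted_group_difference(d, group, oc, covariates = covs,
                                       ref = ref)
      cf <- grep("^\\.group", names(res$coefficients), value = TRUE)
      for (co in cf) {
        rows[[length(rows) + 1]] <<- data.frame(
          comparison = label, level = sub("^\\.group", "", co), outcome = oc,
          difference = unname(res$coefficients[co]),
          ci_low = res$ci95[co, "low"], ci_high = res$ci95[co, "high"],
          p = unname(res$p[co]), stringsAsFactors = FALSE)
      }
    }
  }
  d <- cohort
  d$.preterm <- ifelse(d$preterm, "preterm", "term")
  add("preterm_vs_term", d, ".preterm", "term", c("sex", "exam_age_hours"))
  if (!all(is.na(d$size_class)) && length(unique(stats::na.omit(d$size_class))) > 1) {
    ds <- d[!is.na(d$size_class), ]
    add("size_vs_aga", ds, "size_class", "AGA",
        c("sex", "exam_age_hours", "ga_birth_weeks"))
  }
  for (fl in c("wasted", "stunted")) {
    if (sum(d[[fl]], na.rm = TRUE) >= 5) {
      ds <- d[!is.na(d[[fl]]), ]
      ds$.flag <- ifelse(ds[[fl]], "yes", "no")
      add(fl, ds, ".flag", "no", c("sex", "exam_age_hours", "ga_birth_weeks"))
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
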